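# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for
# the package's fitted-object classes.

#' Tidy a hydrolysis-rate fit
#'
#' @param x A `hydrolysis_fit` from [hydrolysis_rate()].
#' @param ... Unused.
#' @return One-row tibble with `rate_pmol_s`, `slope_m_per_s`, `r.squared`,
#'   `window_n`, `n_points`.
#' @export
tidy.hydrolysis_fit <- function(x, ...) {
  tibble(rate_pmol_s = x$rate_pmol_s, slope_m_per_s = x$slope_m_per_s,
         r.squared = x$r2, window_n = x$window_n, n_points = nrow(x$data))
}

#' @rdname tidy.hydrolysis_fit
#' @export
glance.hydrolysis_fit <- function(x, ...) tidy.hydrolysis_fit(x)

#' Tidy a survey summary
#'
#' @param x A `survey_summary` from [summarize_survey()].
#' @param ... Unused.
#' @return Long tibble of summary statistics (`statistic`, `group`,
#'   `value`).
#' @export
tidy.survey_summary <- function(x, ...) {
  dplyr::bind_rows(
    tibble(statistic = "fraction_alkaline",
           group = names(x$fractions_alkaline),
           value = unname(x$fractions_alkaline)),
    tibble(statistic = "fraction_ge1",
           group = names(x$fraction_ge1_by_family),
           value = unname(x$fraction_ge1_by_family)),
    tibble(statistic = c("slope", "intercept", "r.squared"),
           group = "regression",
           value = c(x$regression$slope, x$regression$intercept,
                     x$regression$r.squared)),
    tibble(statistic = c("statistic", "p.value"),
           group = "kruskal",
           value = c(x$kruskal$statistic, x$kruskal$p.value))
  )
}

#' @rdname tidy.survey_summary
#' @export
glance.survey_summary <- function(x, ...) {
  tibble(n_genomes = x$n_genomes,
         r.squared = x$regression$r.squared,
         kw_statistic = x$kruskal$statistic,
         kw_p.value = x$kruskal$p.value)
}

#' Plot a hydrolysis kinetics fit
#'
#' Shows the time series, the fitted initial-phase line, and shades the
#' window used for the fit.
#'
#' @param object A `hydrolysis_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hydrolysis_fit <- function(object, ...) {
  dat <- object$data
  win <- dat[seq_len(object$window_n), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time,
                                    y = .data$concentration * 1e6)) +
    ggplot2::annotate("rect", xmin = min(win$time), xmax = max(win$time),
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = coef(object$fit)[1] * 1e6,
                         slope = coef(object$fit)[2] * 1e6,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "time (s)", y = "product (µM)",
      title = sprintf("hydrolysis rate %.2f pmol/s (R² = %.3f)",
                      object$rate_pmol_s, object$r2)
    )
}

#' Plot a genome survey
#'
#' Total phosphatase gene count against genome size with the least-squares
#' line, coloured by phylum.
#'
#' @param object A survey tibble from [build_survey()] or [gen_survey()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_survey <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$genome_length / 1e6,
                                       y = .data$total,
                                       colour = .data$phylum)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "genome size (Mb)", y = "phosphatase genes",
                  colour = "phylum")
}

#' Plot motif hits along an upstream region
#'
#' @param hits Tibble from [scan_upstream()].
#' @param region_length Length of the scanned region (nt).
#' @return A ggplot object.
#' @export
plot_motif_hits <- function(hits, region_length) {
  ggplot2::ggplot(hits) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$rel_begin, xend = .data$rel_end,
      y = .data$tf_name, yend = .data$tf_name,
      colour = -log10(.data$pvalue)
    ), linewidth = 3) +
    ggplot2::xlim(-region_length, 0) +
    ggplot2::labs(x = "position relative to gene start (nt)", y = NULL,
                  colour = "-log10 p")
}
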