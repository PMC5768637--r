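# Multi-genome phosphatase repertoire survey: per-family prevalence,
# gene densities, size-count regression and a Kruskal-Wallis test of counts
# across genome-size bins.

#' Build a survey table from per-genome annotations
#'
#' @param annotations Tibble of family annotations across genomes, with
#'   columns `genome_id` and `family` (one row per annotated gene, e.g. the
#'   concatenated output of [annotate_proteome()] over genomes).
#' @param metadata Tibble with `genome_id`, `phylum`, `genome_length` (bp);
#'   one row per genome (genomes without annotations get zero counts).
#' @return Tibble with one row per genome: `genome_id`, `phylum`,
#'   `genome_length`, one count column per family, and `total` (all
#'   families) and `alkaline` (PhoA + PhoK + PhoD + PhoX) aggregates.
#' @export
build_survey <- function(annotations, metadata) {
  if (anyDuplicated(metadata$genome_id)) {
    abort("duplicate genome_id in metadata")
  }
  if (nrow(metadata) == 0) {
    out <- tibble(genome_id = character(), phylum = character(),
                  genome_length = numeric())
    for (f in PHOSPHATASE_FAMILIES) out[[f]] <- integer()
    out$total <- integer(); out$alkaline <- integer()
    return(out)
  }
  counts <- dplyr::count(annotations, .data$genome_id, .data$family)
  wide <- tidyr::pivot_wider(counts, names_from = "family",
                             values_from = "n", values_fill = 0L)
  out <- dplyr::left_join(metadata, wide, by = "genome_id")
  for (f in PHOSPHATASE_FAMILIES) {
    if (!f %in% names(out)) out[[f]] <- 0L
    out[[f]][is.na(out[[f]])] <- 0L
  }
  out <- out[, c("genome_id", "phylum", "genome_length",
                 PHOSPHATASE_FAMILIES)]
  out$total <- as.integer(rowSums(out[, PHOSPHATASE_FAMILIES]))
  out$alkaline <- as.integer(rowSums(out[, ALKALINE_FAMILIES]))
  as_tibble(out)
}

#' Gene density per megabase
#'
#' @param count Gene count(s).
#' @param genome_length Genome length(s) in bp.
#' @return Genes per Mb.
#' @examples
#' gene_density(4, 4e6) # 1
#' @export
gene_density <- function(count, genome_length) {
  if (any(genome_length <= 0)) abort("genome_length must be > 0")
  count / (genome_length / 1e6)
}

#' Summarise a phosphatase repertoire survey
#'
#' Computes, over a survey table: the fraction of genomes with at least `k`
#' alkaline-phosphatase genes and at least one gene per family; per-genome
#' alkaline and per-family densities with the focal genome's percentile;
#' the least-squares regression of total phosphatase gene count on genome
#' size; and a Kruskal-Wallis test of counts across genome-size quantile
#' bins.
#'
#' @param table Survey tibble from [build_survey()].
#' @param k_values Thresholds for the at-least-k alkaline fractions.
#' @param n_size_bins Number of genome-size quantile bins for the
#'   Kruskal-Wallis test (default 5, i.e. quintiles).
#' @param focal Optional `genome_id` whose density percentile is reported.
#' @return Object of class `survey_summary`: list with `fractions_alkaline`
#'   (named by k), `fraction_ge1_by_family`, `regression` (slope, intercept,
#'   r.squared), `kruskal` (statistic, p.value, df; `NA` when fewer than two
#'   bins), `densities` (per-genome tibble), `focal`.
#' @export
summarize_survey <- function(table, k_values = c(1, 4, 5), n_size_bins = 5,
                             focal = NULL) {
  if (nrow(table) < 3) abort("at least 3 genomes are required")
  fr_alk <- vapply(k_values, function(k) mean(table$alkaline >= k),
                   numeric(1))
  names(fr_alk) <- paste0("ge", k_values)
  fr_fam <- vapply(PHOSPHATASE_FAMILIES, function(f) mean(table[[f]] >= 1),
                   numeric(1))
  fit <- lm(total ~ genome_length, data = table)
  reg <- suppressWarnings(  # summary.lm warns on noise-free perfect fits
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r.squared = summary(fit)$r.squared)
  )
  qs <- quantile(table$genome_length, probs = seq(0, 1, length.out =
                                                    n_size_bins + 1))
  qs <- unique(qs)
  kw <- list(statistic = NA_real_, p.value = NA_real_, df = NA_real_)
  if (length(qs) >= 3) {
    bins <- cut(table$genome_length, breaks = qs, include.lowest = TRUE)
    if (nlevels(droplevels(bins)) >= 2) {
      k <- kruskal.test(table$total, droplevels(bins))
      kw <- list(statistic = unname(k$statistic), p.value = k$p.value,
                 df = unname(k$parameter))
    }
  }
  dens <- tibble(
    genome_id = table$genome_id,
    alkaline_density = gene_density(table$alkaline, table$genome_length),
    PhoX_density = gene_density(table$PhoX, table$genome_length)
  )
  focal_out <- NULL
  if (!is.null(focal)) {
    i <- match(focal, dens$genome_id)
    if (is.na(i)) abort(sprintf("focal genome '%s' not in the table", focal))
    focal_out <- list(
      genome_id = focal,
      alkaline_density = dens$alkaline_density[i],
      alkaline_percentile = mean(dens$alkaline_density <=
                                   dens$alkaline_density[i]),
      frac_higher_alkaline_density = mean(dens$alkaline_density >
                                            dens$alkaline_density[i]),
      PhoX_density_rank = sum(dens$PhoX_density > dens$PhoX_density[i]) + 1L
    )
  }
  structure(
    list(fractions_alkaline = fr_alk, fraction_ge1_by_family = fr_fam,
         regression = reg, kruskal = kw, densities = dens, focal = focal_out,
         n_genomes = nrow(table)),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("<survey_summary> %d genomes\n", x$n_genomes))
  cat("  alkaline-phosphatase prevalence:",
      paste(sprintf(">=%s: %.0f%%", sub("ge", "", names(x$fractions_alkaline)),
                    100 * x$fractions_alkaline), collapse = ", "), "\n")
  cat(sprintf("  total-count vs size regression: R^2 = %.3f\n",
              x$regression$r.squared))
  if (!is.na(x$kruskal$statistic)) {
    cat(sprintf("  Kruskal-Wallis across size bins: chi^2 = %.2f, p = %.3g\n",
                x$kruskal$statistic, x$kruskal$p.value))
  }
  invisible(x)
}
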