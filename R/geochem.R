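# Hydroxyapatite saturation-index geochemistry and enzymatic hydrolysis
# kinetics.
#
# The speciation is a documented simplified model: orthophosphate
# protonation equilibria plus water autoionisation, Davies activity
# coefficients, ionic strength by fixed-point iteration.  Ca-phosphate ion
# pairs and carbonate equilibria are neglected (a known upward bias of at
# most about one SI unit for these media).

#' Speciate a Ca/orthophosphate solution
#'
#' Distributes total orthophosphate over H3PO4 / H2PO4- / HPO4^2- / PO4^3-
#' using the 25 C dissociation constants (pKa 2.148, 7.199, 12.35), computes
#' OH- from Kw, and applies Davies activity coefficients
#' `log10 gamma_z = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)` with A = 0.509.
#' Ionic strength includes free Ca2+, the phosphate species, H+/OH- and an
#' inert monovalent counter-ion supplied to balance charge (plus any
#' explicit background electrolyte), and is solved by fixed-point iteration.
#'
#' @param total_ca Total dissolved calcium (mol/L).
#' @param total_pi Total dissolved orthophosphate (mol/L).
#' @param pH Solution pH (defined on the activity scale).
#' @param background_ionic_strength Additional ionic strength from an inert
#'   background electrolyte (mol/L), e.g. a buffer; default 0.
#' @param davies Apply Davies activity corrections (default TRUE); with
#'   FALSE all activity coefficients are 1 (ideal solution).
#' @param tol Convergence tolerance on ionic strength (mol/L).
#' @param I_init Starting value of the ionic-strength fixed-point iteration
#'   (mol/L); the converged result does not depend on it.
#' @return Object of class `speciation`: list with `concentrations` (named,
#'   mol/L), `activities` (named), `gamma` (by charge 1..3), `ionic_strength`
#'   and the inputs.
#' @export
speciate <- function(total_ca, total_pi, pH,
                     background_ionic_strength = 0, davies = TRUE,
                     tol = 1e-8, I_init = 0.001) {
  if (pH <= 0 || pH >= 14) abort("pH must lie in (0, 14)")
  if (total_ca < 0 || total_pi < 0) abort("totals must be >= 0")
  K <- unname(10^(-PHOSPHORIC_PKA))
  aH <- 10^(-pH)
  gamma_z <- function(I, z) {
    if (!davies || I <= 0) return(1)
    10^(-DAVIES_A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
  }
  I <- I_init
  for (iter in 1:200) {
    g1 <- gamma_z(I, 1); g2 <- gamma_z(I, 2); g3 <- gamma_z(I, 3)
    # concentration ratios from mixed (activity) constants:
    # [H2PO4]/[H3PO4] = K1 / (aH) * g0/g1, etc.  g0 = 1.
    r1 <- K[1] / aH / g1
    r2 <- K[2] / aH * g1 / g2
    r3 <- K[3] / aH * g2 / g3
    f0 <- 1 / (1 + r1 + r1 * r2 + r1 * r2 * r3)
    c_h3 <- total_pi * f0
    c_h2 <- c_h3 * r1
    c_h1 <- c_h2 * r2
    c_p  <- c_h1 * r3
    c_oh <- KW_25C / aH / g1
    c_h <- aH / g1
    c_ca <- total_ca
    # charge balance via an inert monovalent counter-ion
    net <- 2 * c_ca + c_h - (c_h2 + 2 * c_h1 + 3 * c_p + c_oh)
    counter <- abs(net)
    I_new <- 0.5 * (4 * c_ca + c_h + c_oh + c_h2 + 4 * c_h1 + 9 * c_p +
                      counter) + background_ionic_strength
    if (abs(I_new - I) < tol) {
      I <- I_new
      break
    }
    I <- I_new
  }
  g1 <- gamma_z(I, 1); g2 <- gamma_z(I, 2); g3 <- gamma_z(I, 3)
  conc <- c(Ca = c_ca, H3PO4 = c_h3, H2PO4 = c_h2, HPO4 = c_h1, PO4 = c_p,
            OH = c_oh, H = c_h)
  act <- c(Ca = c_ca * g2, H3PO4 = c_h3, H2PO4 = c_h2 * g1,
           HPO4 = c_h1 * g2, PO4 = c_p * g3, OH = c_oh * g1, H = aH)
  structure(
    list(concentrations = conc, activities = act,
         gamma = c(`1` = g1, `2` = g2, `3` = g3), ionic_strength = I,
         total_ca = total_ca, total_pi = total_pi, pH = pH,
         davies = davies),
    class = "speciation"
  )
}

#' @export
print.speciation <- function(x, ...) {
  cat(sprintf(
    "<speciation> pH %.2f, I = %.4g M, gamma(1,2,3) = %.3f/%.3f/%.3f\n",
    x$pH, x$ionic_strength, x$gamma[1], x$gamma[2], x$gamma[3]))
  cat(sprintf("  log10 a(Ca2+) = %.3f, log10 a(PO4 3-) = %.3f\n",
              log10(x$activities["Ca"]), log10(x$activities["PO4"])))
  invisible(x)
}

#' Saturation index with respect to hydroxyapatite
#'
#' `SI = log10(IAP / Ks)` with `IAP = a(Ca2+)^5 a(PO4^3-)^3 a(OH-)` for
#' Ca5(PO4)3OH and `log10 Ks = -57.74`.  The SI is not computed (returns
#' `NA`) when total calcium or total orthophosphate is zero or below the
#' detection limit, matching the assay-analysis convention.
#'
#' @inheritParams speciate
#' @param logKs log10 solubility product of hydroxyapatite.
#' @param detection_limit_ca,detection_limit_pi Detection limits (mol/L)
#'   below which the SI is reported as `NA`.
#' @return SI in log10 units (`NA` when undefined); the `speciation` object
#'   is attached as attribute `"speciation"`.
#' @export
saturation_index_hydroxyapatite <- function(total_ca, total_pi, pH = 7.5,
                                            background_ionic_strength = 0,
                                            davies = TRUE,
                                            logKs = LOGK_HYDROXYAPATITE,
                                            detection_limit_ca = DETECTION_LIMIT_CA,
                                            detection_limit_pi = DETECTION_LIMIT_PI) {
  if (total_ca <= 0 || total_pi <= 0 ||
      total_ca < detection_limit_ca || total_pi < detection_limit_pi) {
    return(NA_real_)
  }
  sp <- speciate(total_ca, total_pi, pH,
                 background_ionic_strength = background_ionic_strength,
                 davies = davies)
  a <- sp$activities
  log_iap <- 5 * log10(a[["Ca"]]) + 3 * log10(a[["PO4"]]) + log10(a[["OH"]])
  structure(log_iap - logKs, speciation = sp)
}

#' Convert absorbance at 405 nm to product concentration
#'
#' Beer-Lambert conversion `c = A / (epsilon * l)` with the p-nitrophenol
#' molar extinction coefficient (18,000 per M per cm at 405 nm) as default;
#' one p-nitrophenol is released per orthophosphate.
#'
#' @param A405 Absorbance value(s), >= 0.
#' @param epsilon Molar extinction coefficient (per M per cm).
#' @param path_length Optical path (cm).
#' @return Concentration(s) in mol/L.
#' @export
absorbance_to_concentration <- function(A405, epsilon = 18000,
                                        path_length = 1) {
  if (any(A405 < 0)) abort("absorbance must be >= 0")
  A405 / (epsilon * path_length)
}

#' Hydrolysis rate from a kinetics time series
#'
#' Converts absorbance to concentration if needed, restricts the fit to the
#' initial linear phase (the longest prefix of at least `min_points` points
#' whose ordinary least-squares fit has R^2 >= `r2_min`), and reports the
#' slope as a release rate in pmol/s for the stated reaction volume.
#'
#' @param series Tibble or data frame with columns `time` (s) and either
#'   `absorbance` or `concentration` (mol/L).
#' @param volume_l Reaction volume in litres.
#' @param epsilon,path_length Beer-Lambert parameters used when the series
#'   is absorbance.
#' @param r2_min Minimum R^2 of the initial-phase fit (default 0.98).
#' @param min_points Minimum points in the fitted window (default 4).
#' @return Object of class `hydrolysis_fit`: list with `rate_pmol_s`,
#'   `slope_m_per_s`, `r2`, `window_n`, `data` (time/concentration tibble),
#'   `fit` (the `lm` object).
#' @export
hydrolysis_rate <- function(series, volume_l = 1e-3, epsilon = 18000,
                            path_length = 1, r2_min = 0.98, min_points = 4) {
  if (!"time" %in% names(series)) abort("series must have a 'time' column")
  if (is.unsorted(series$time, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  conc <- if ("concentration" %in% names(series)) {
    series$concentration
  } else if ("absorbance" %in% names(series)) {
    absorbance_to_concentration(series$absorbance, epsilon, path_length)
  } else {
    abort("series must have a 'concentration' or 'absorbance' column")
  }
  n <- length(conc)
  if (n < min_points) {
    abort(sprintf("at least %d points are required", min_points))
  }
  dat <- tibble(time = series$time, concentration = conc)
  best_n <- NA_integer_
  for (k in n:min_points) {
    fit <- lm(concentration ~ time, data = dat[seq_len(k), ])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # noise-free fits warn
    if (is.nan(r2)) r2 <- 1  # zero-variance (perfectly flat) prefix
    if (r2 >= r2_min) {
      best_n <- k
      break
    }
  }
  if (is.na(best_n)) best_n <- min_points
  fit <- lm(concentration ~ time, data = dat[seq_len(best_n), ])
  slope <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(rate_pmol_s = slope * volume_l * 1e12, slope_m_per_s = slope,
         r2 = r2, window_n = best_n, data = dat, fit = fit,
         volume_l = volume_l),
    class = "hydrolysis_fit"
  )
}

#' @export
print.hydrolysis_fit <- function(x, ...) {
  cat(sprintf(
    "<hydrolysis_fit> %.3g pmol/s (slope %.3g M/s, R^2 = %.4f, %d/%d points)\n",
    x$rate_pmol_s, x$slope_m_per_s, x$r2, x$window_n, nrow(x$data)))
  invisible(x)
}
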