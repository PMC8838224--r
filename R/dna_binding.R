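# Benesi-Hildebrand estimation of the DNA binding constant from an
# absorption titration at fixed compound concentration and increasing
# CT-DNA concentration, plus chromism classification.

#' Benesi-Hildebrand fit of a DNA absorption titration
#'
#' Linearizes the 1:1 binding isotherm as
#' `A0/(A - A0) = eps_ratio + eps_ratio / (K [DNA])`
#' where `eps_ratio = epsG / (epsHG - epsG)` is the ratio built from the
#' molar absorptivities of the free drug and the drug-DNA adduct, and fits
#' the double-reciprocal line `y = A0/(A - A0)` against `x = 1/[DNA]` by
#' unweighted ordinary least squares. The binding constant is the intercept
#' to slope ratio, `K_b = intercept/slope`.
#'
#' Points whose absorbance change `|A - A0|` falls below `floor` are excluded
#' (the transform diverges near `A0`) and reported in the result. If the
#' usable points mix hyper- and hypochromic deviations the fit proceeds on
#' the majority-sign subset with a warning and the chromism is reported
#' indeterminate.
#'
#' @param data A data frame with the DNA concentration and absorbance
#'   columns, concentrations strictly positive and increasing, at least three
#'   points.
#' @param a0 Absorbance of the compound alone (no DNA). Defaults to the
#'   `a0` attribute of `data` when present (as set by [gen_titration()]).
#' @param conc,absorbance Unquoted column names (defaults `dna_M`,
#'   `absorbance`).
#' @param lambda_free,lambda_bound Band maxima (nm) of the free and
#'   DNA-bound forms; metadata used only for the shift label. Default to the
#'   matching attributes of `data` when present.
#' @param floor Exclusion floor on `|A - A0|` (absorbance units).
#' @param chromism_threshold Relative change in absorbance below which the
#'   chromism is indeterminate; see [classify_chromism()].
#' @param nonlinear_check If `TRUE`, additionally refit the untransformed
#'   isotherm by nonlinear least squares, starting from the linear estimates,
#'   and store the result as a cross-check (`k_b_nls`).
#' @return A `bh_fit` object; see [tidy()] and [glance()] methods, and
#'   [autoplot.bh_fit()] for the double-reciprocal diagnostic plot.
#' @examples
#' tt <- gen_titration(true_k = 1.4e6, noise_sd = 0)
#' fit <- benesi_hildebrand_fit(tt)
#' glance(fit)
#' @export
benesi_hildebrand_fit <- function(data, a0 = attr(data, "a0"),
                                  conc = dna_M, absorbance = absorbance,
                                  lambda_free = attr(data, "lambda_free"),
                                  lambda_bound = attr(data, "lambda_bound"),
                                  floor = 1e-3,
                                  chromism_threshold = 0.01,
                                  nonlinear_check = FALSE) {
  data <- tibble::as_tibble(data)
  D <- dplyr::pull(data, {{ conc }})
  A <- dplyr::pull(data, {{ absorbance }})
  if (is.null(a0) || !is.finite(a0)) {
    stop_input("`a0` (absorbance without DNA) is required.", "missing_a0")
  }
  if (any(D <= 0) || any(diff(D) <= 0)) {
    stop_input("DNA concentrations must be strictly positive and increasing.",
               "bad_concentration_grid")
  }
  if (length(D) < 3L) {
    stop_input("At least 3 titration points are required.", "insufficient_data")
  }
  d <- A - a0
  if (all(abs(d) < .Machine$double.eps * pmax(abs(A), 1))) {
    stop_input("Absorbance equals a0 at every point; transform undefined.",
               "no_absorbance_change")
  }
  usable <- abs(d) > floor
  mixed <- FALSE
  if (any(usable)) {
    sgn <- sign(d[usable])
    if (length(unique(sgn)) > 1L) {
      mixed <- TRUE
      maj <- if (sum(sgn > 0) >= sum(sgn < 0)) 1 else -1
      rlang::warn(paste(
        "Mixed signs of (A - A0) across titration points;",
        "fitting the majority-sign subset, chromism indeterminate."))
      usable <- usable & sign(d) == maj
    }
  }
  if (sum(usable) < 3L) {
    stop_input("Fewer than 3 usable points after exclusion.", "insufficient_data")
  }
  x <- 1 / D[usable]
  y <- a0 / d[usable]
  fit <- stats::lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || abs(slope) < 1e-14 * max(abs(y))) {
    stop_input("No concentration dependence (slope ~ 0).", "zero_slope")
  }
  r2 <- if (var(y) == 0) 1 else lm_r_squared(fit)
  chrom <- classify_chromism(data, a0 = a0, conc = {{ conc }},
                             absorbance = {{ absorbance }},
                             lambda_free = lambda_free,
                             lambda_bound = lambda_bound,
                             threshold = chromism_threshold)
  chromism <- if (mixed) "indeterminate" else chrom$chromism
  res <- list(
    k_b = intercept / slope,
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    epsilon_ratio = intercept,
    chromism = chromism,
    shift = chrom$shift,
    a0 = a0,
    lambda_free = if (is.null(lambda_free)) NA_real_ else lambda_free,
    lambda_bound = if (is.null(lambda_bound)) NA_real_ else lambda_bound,
    n_used = sum(usable),
    data = tibble::tibble(dna_M = D, absorbance = A, delta = d,
                          used = usable,
                          x = ifelse(usable, 1 / D, NA_real_),
                          y = ifelse(usable, a0 / d, NA_real_)),
    fit = fit
  )
  if (nonlinear_check) {
    nl <- try(stats::nls(
      A ~ a0 + a0 / (eps * (1 + 1 / (K * D))),
      data = list(A = A[usable], D = D[usable], a0 = a0),
      start = list(eps = intercept, K = res$k_b)), silent = TRUE)
    res$k_b_nls <- if (inherits(nl, "try-error")) NA_real_ else unname(coef(nl)["K"])
  }
  structure(res, class = "bh_fit")
}

#' Classify chromism and band shift of a titration
#'
#' Compares the final absorbance of the series with `a0`: hyperchromic when
#' the relative increase exceeds `threshold`, hypochromic when the relative
#' decrease does, indeterminate otherwise. Hyperchromism is conventionally
#' read as electrostatic or groove binding, hypochromism as intercalation.
#' The band shift is blue when the bound-form maximum lies below the free
#' maximum, red when above, none when equal, and unknown when no bound-form
#' wavelength is supplied.
#'
#' @inheritParams benesi_hildebrand_fit
#' @param threshold Relative absorbance change defining a real effect.
#' @return A one-row tibble with columns `chromism` and `shift`.
#' @examples
#' classify_chromism(tibble::tibble(dna_M = 1:3, absorbance = c(.62, .66, .70)),
#'                   a0 = 0.6, lambda_free = 265, lambda_bound = 259)
#' @export
classify_chromism <- function(data, a0 = attr(data, "a0"),
                              conc = dna_M, absorbance = absorbance,
                              lambda_free = attr(data, "lambda_free"),
                              lambda_bound = attr(data, "lambda_bound"),
                              threshold = 0.01) {
  data <- tibble::as_tibble(data)
  A <- dplyr::pull(data, {{ absorbance }})
  if (is.null(a0) || !is.finite(a0)) {
    stop_input("`a0` is required.", "missing_a0")
  }
  rel <- (A[length(A)] - a0) / a0
  chromism <- if (rel > threshold) "hyperchromic"
              else if (rel < -threshold) "hypochromic"
              else "indeterminate"
  shift <- if (is.null(lambda_bound) || is.null(lambda_free) ||
               is.na(lambda_bound) || is.na(lambda_free)) "unknown"
           else if (lambda_bound < lambda_free) "blue"
           else if (lambda_bound > lambda_free) "red"
           else "none"
  tibble::tibble(chromism = chromism, shift = shift)
}

#' @export
print.bh_fit <- function(x, ...) {
  cat("Benesi-Hildebrand binding fit\n")
  cat(sprintf("  K_b       = %s M^-1  (intercept/slope)\n",
              format(signif(x$k_b, 3), scientific = TRUE)))
  cat(sprintf("  r^2       = %.4f  (n = %d used)\n", x$r_squared, x$n_used))
  cat(sprintf("  chromism  = %s, shift = %s\n", x$chromism, x$shift))
  invisible(x)
}

#' @method tidy bh_fit
#' @export
tidy.bh_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @method glance bh_fit
#' @export
glance.bh_fit <- function(x, ...) {
  tibble::tibble(
    k_b = x$k_b,
    epsilon_ratio = x$epsilon_ratio,
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    n_used = x$n_used,
    chromism = x$chromism,
    shift = x$shift
  )
}
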