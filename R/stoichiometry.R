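# Molar-ratio determination of metal:ligand stoichiometry. Absorbance is
# plotted against the metal mole fraction x = [M]/([M]+[L]); under strong
# complex formation the curve is two straight branches meeting at
# x = 1/(n+1) for an ML_n complex: 1/2 for 1:1, 1/3 for 1:2.

#' Two-segment breakpoint fit of a molar-ratio series
#'
#' Fits every admissible split of the ordered series into a left and a right
#' branch, each by ordinary least squares, and keeps the split minimizing the
#' total residual sum of squares (ties broken towards the smaller
#' breakpoint). The breakpoint is the intersection of the two fitted lines;
#' it is labelled `1:1` when within `label_tolerance` of 1/2, `1:2` when
#' within tolerance of 1/3, and `unassigned` otherwise (including parallel
#' branches and intersections at or outside the endpoints).
#'
#' @param data A data frame holding the series; at least 5 points, mole
#'   fractions within `[0, 1]` and strictly increasing.
#' @param mole_fraction,absorbance Unquoted column names (defaults
#'   `mole_fraction_metal`, `absorbance`).
#' @param label_tolerance Half-width around the canonical fractions for
#'   ratio labelling.
#' @param min_points_per_side Minimum points per branch.
#' @return A `molar_ratio_fit` object with `breakpoint`, `ratio_label` and a
#'   `branches` tibble (slope, intercept, r-squared per side); see
#'   [tidy()], [glance()] and [autoplot.molar_ratio_fit()].
#' @examples
#' s <- gen_molar_ratio("1:2", noise_sd = 0)
#' glance(fit_breakpoint(s))
#' @export
fit_breakpoint <- function(data, mole_fraction = mole_fraction_metal,
                           absorbance = absorbance, label_tolerance = 0.05,
                           min_points_per_side = 3L) {
  data <- tibble::as_tibble(data)
  x <- dplyr::pull(data, {{ mole_fraction }})
  y <- dplyr::pull(data, {{ absorbance }})
  n <- length(x)
  if (n < 5L) {
    stop_input("At least 5 points are required.", "insufficient_data")
  }
  if (any(x < 0) || any(x > 1) || any(diff(x) <= 0)) {
    stop_input("Mole fractions must be strictly increasing within [0, 1].",
               "bad_series")
  }
  ks <- seq(min_points_per_side, n - min_points_per_side)
  if (length(ks) == 0L) {
    stop_input("Too few points for two branches of the requested size.",
               "insufficient_data")
  }
  fits <- lapply(ks, function(k) {
    l <- stats::lm(y[1:k] ~ x[1:k])
    r <- stats::lm(y[(k + 1):n] ~ x[(k + 1):n])
    bl <- unname(coef(l)); br <- unname(coef(r))
    bp <- if (abs(bl[2] - br[2]) < 1e-10 * max(abs(c(bl[2], br[2], 1)))) {
      NA_real_
    } else {
      (br[1] - bl[1]) / (bl[2] - br[2])
    }
    list(k = k, rss = sum(resid(l)^2) + sum(resid(r)^2), bp = bp,
         left = l, right = r)
  })
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  bps <- vapply(fits, `[[`, numeric(1), "bp")
  near <- rss <= min(rss) + 1e-12 * max(min(rss), 1)
  # among (numerically) tied splits the smallest breakpoint wins
  cand <- which(near)
  cand <- cand[order(ifelse(is.na(bps[cand]), Inf, bps[cand]))]
  best <- fits[[cand[1]]]
  bp <- best$bp
  parallel <- is.na(bp)
  if (parallel) {
    rlang::warn("Branch lines are parallel; no breakpoint, ratio unassigned.")
  }
  label <- if (parallel || bp <= 0 || bp >= 1) {
    "unassigned"
  } else if (abs(bp - 0.5) <= label_tolerance) {
    "1:1"
  } else if (abs(bp - 1 / 3) <= label_tolerance) {
    "1:2"
  } else {
    "unassigned"
  }
  r2 <- function(f, yy) {
    if (var(yy) == 0) 1 else lm_r_squared(f)
  }
  k <- best$k
  branches <- tibble::tibble(
    side = c("left", "right"),
    slope = c(unname(coef(best$left)[2]), unname(coef(best$right)[2])),
    intercept = c(unname(coef(best$left)[1]), unname(coef(best$right)[1])),
    r_squared = c(r2(best$left, y[1:k]), r2(best$right, y[(k + 1):n])),
    n = c(k, n - k)
  )
  structure(list(
    breakpoint = if (parallel) NA_real_ else bp,
    ratio_label = label,
    branches = branches,
    split_index = k,
    rss = best$rss,
    data = tibble::tibble(mole_fraction_metal = x, absorbance = y,
                          side = rep(c("left", "right"), c(k, n - k)))
  ), class = "molar_ratio_fit")
}

#' @export
print.molar_ratio_fit <- function(x, ...) {
  cat("Molar-ratio breakpoint fit\n")
  cat(sprintf("  breakpoint [M]/([M]+[L]) = %s   label = %s\n",
              ifelse(is.na(x$breakpoint), "NA", sprintf("%.3f", x$breakpoint)),
              x$ratio_label))
  invisible(x)
}

#' @method tidy molar_ratio_fit
#' @export
tidy.molar_ratio_fit <- function(x, ...) x$branches

#' @method glance molar_ratio_fit
#' @export
glance.molar_ratio_fit <- function(x, ...) {
  tibble::tibble(breakpoint = x$breakpoint, ratio_label = x$ratio_label,
                 rss = x$rss, n = nrow(x$data))
}
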