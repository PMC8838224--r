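# Thermogravimetric analysis: step segmentation of a thermogram,
# stoichiometric checking of step losses, and non-isothermal first-order
# decomposition kinetics by the Coats-Redfern and Horowitz-Metzger
# single-heating-rate linearizations, with the derived activation
# thermodynamics (Eyring-type dH, dS, dG at the peak-rate temperature).

#' Segment a thermogram into mass-loss steps
#'
#' Finds decomposition steps from the smoothed derivative (DTG) of the
#' remaining-mass curve: contiguous regions where `|d(mass)/dT|` exceeds
#' `threshold_frac` of the global DTG peak are taken as step cores, merged
#' when separated by less than `merge_gap` kelvin, extended outward to the
#' surrounding plateaus (where the local rate falls below `plateau_frac` of
#' the step's own peak rate), and kept when the associated loss is at least
#' `min_loss_percent`.
#'
#' @param data A data frame with columns `temperature` (kelvin, strictly
#'   increasing) and `mass_percent` (remaining mass, percent of initial).
#' @param min_loss_percent Minimum step loss (percentage points) to keep.
#' @param sg_window,sg_order Savitzky-Golay window (points, odd) and
#'   polynomial order for smoothing before differentiation.
#' @param threshold_frac Fraction of the global DTG peak defining step cores.
#' @param plateau_frac Fraction of a step's own DTG peak defining its
#'   plateau boundaries.
#' @param merge_gap Merge step cores separated by less than this many kelvin.
#' @param monotone_tol Maximum tolerated increase (percentage points) of the
#'   smoothed mass curve before the curve is rejected as non-monotone.
#' @return A tibble with one row per step: `step`, `t_start`, `t_end`,
#'   `t_peak` (kelvin), `percent_loss`, and a `data` list-column holding the
#'   per-step `temperature`, `mass_percent` and conversion `alpha`
#'   (`(m_start - m)/(m_start - m_end)`, non-decreasing on `[0, 1]`).
#'   Zero rows for a flat curve.
#' @examples
#' tg <- gen_thermogram(steps = list(list(loss = 9.44, e_a = 120, a = 1e10)))
#' segment_steps(tg)
#' @export
segment_steps <- function(data, min_loss_percent = 1, sg_window = 11,
                          sg_order = 3, threshold_frac = 0.05,
                          plateau_frac = 0.002, merge_gap = 20,
                          monotone_tol = 0.5) {
  data <- tibble::as_tibble(data)
  if (!all(c("temperature", "mass_percent") %in% names(data))) {
    stop_input("`data` needs `temperature` and `mass_percent` columns.",
               "bad_thermogram")
  }
  if (min_loss_percent <= 0) {
    stop_input("`min_loss_percent` must be positive.", "bad_thermogram")
  }
  Tg <- data$temperature
  m <- data$mass_percent
  n <- length(Tg)
  if (n < sg_window + 2L || any(diff(Tg) <= 0)) {
    stop_input("Temperatures must be strictly increasing with enough points.",
               "bad_thermogram")
  }
  ms <- signal::sgolayfilt(m, p = sg_order, n = sg_window)
  if (max(ms - cummin(ms)) > monotone_tol) {
    stop_input("Mass curve increases beyond smoothing tolerance; not a valid thermogram.",
               "non_monotone_curve")
  }
  dtg <- c(NA_real_, (ms[-(1:2)] - ms[1:(n - 2)]) / (Tg[-(1:2)] - Tg[1:(n - 2)]),
           NA_real_)
  dtg[1] <- dtg[2]; dtg[n] <- dtg[n - 1]
  rate <- -dtg                        # positive where mass is being lost
  peak <- max(rate, 0)
  total_span <- ms[1] - ms[n]
  if (peak <= 0 || total_span < min(min_loss_percent, 0.1)) {
    return(empty_step_tbl())
  }
  core <- rate >= threshold_frac * peak
  # merge cores separated by small gaps
  idx <- which(core)
  if (length(idx) == 0L) return(empty_step_tbl())
  breaks <- which(diff(idx) > 1L)
  starts <- c(idx[1], idx[breaks + 1L])
  ends <- c(idx[breaks], idx[length(idx)])
  if (length(starts) > 1L) {
    keep_s <- starts[1]; out_s <- c(); out_e <- c()
    cur_s <- starts[1]; cur_e <- ends[1]
    for (k in seq_along(starts)[-1]) {
      if (Tg[starts[k]] - Tg[cur_e] < merge_gap) {
        cur_e <- ends[k]
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- starts[k]; cur_e <- ends[k]
      }
    }
    starts <- c(out_s, cur_s); ends <- c(out_e, cur_e)
  }
  # expand each region to its plateaus, not crossing neighbour midpoints
  nreg <- length(starts)
  rows <- list()
  for (k in seq_len(nreg)) {
    s <- starts[k]; e <- ends[k]
    pk <- max(rate[s:e])
    lo_lim <- if (k == 1L) 1L else floor((ends[k - 1L] + starts[k]) / 2)
    hi_lim <- if (k == nreg) n else ceiling((ends[k] + starts[k + 1L]) / 2)
    while (s > lo_lim && rate[s - 1L] > plateau_frac * pk) s <- s - 1L
    while (e < hi_lim && rate[e + 1L] > plateau_frac * pk) e <- e + 1L
    loss <- ms[s] - ms[e]
    if (loss < min_loss_percent) next
    seg <- tibble::tibble(
      temperature = Tg[s:e],
      mass_percent = m[s:e],
      alpha = pmin(pmax((ms[s] - ms[s:e]) / loss, 0), 1)
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      t_start = Tg[s], t_end = Tg[e],
      t_peak = Tg[s:e][which.max(rate[s:e])],
      percent_loss = loss,
      data = list(seg)
    )
  }
  if (length(rows) == 0L) return(empty_step_tbl())
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, step = dplyr::row_number(), .before = 1)
}

empty_step_tbl <- function() {
  tibble::tibble(step = integer(), t_start = double(), t_end = double(),
                 t_peak = double(), percent_loss = double(), data = list())
}

#' Check a step loss against a candidate fragment
#'
#' Compares an observed mass-loss percentage with the stoichiometric loss
#' expected for a departing fragment, `mass_loss_percent(fragment, parent)`.
#'
#' @param step Observed loss: a number (percent) or a one-row step tibble
#'   from [segment_steps()] (its `percent_loss` is used).
#' @param fragment,parent Formula strings or `mol_formula` objects.
#' @param tolerance Pass/fail half-width, percentage points.
#' @return A one-row tibble: `observed`, `expected`, `deviation`, `pass`.
#' @examples
#' check_step_assignment(9.44, "VO2", "C42H52Cl2N4O9V", tolerance = 0.1)
#' @export
check_step_assignment <- function(step, fragment, parent, tolerance = 0.5) {
  observed <- if (is.data.frame(step)) step$percent_loss[1] else as.numeric(step)
  expected <- mass_loss_percent(fragment, parent)
  dev <- observed - expected
  tibble::tibble(observed = observed, expected = expected,
                 deviation = dev, pass = abs(dev) <= tolerance)
}

# Normalize a step argument into list(temperature, alpha, t_peak).
step_arrays <- function(step) {
  if (is.data.frame(step) && "data" %in% names(step)) {
    if (nrow(step) != 1L) {
      stop_input("Pass a single step (one row of segment_steps() output).",
                 "bad_step")
    }
    seg <- step$data[[1]]
    list(temperature = seg$temperature, alpha = seg$alpha,
         t_peak = step$t_peak[1])
  } else if (is.data.frame(step) && all(c("temperature", "alpha") %in% names(step))) {
    rate <- c(diff(step$alpha) / diff(step$temperature), NA_real_)
    list(temperature = step$temperature, alpha = step$alpha,
         t_peak = step$temperature[which.max(rate)])
  } else {
    stop_input("`step` must be a segment_steps() row or a data frame with `temperature` and `alpha`.",
               "bad_step")
  }
}

new_kinetic_fit <- function(method, e_a_j, a_min, r2, t_s, beta, n_pts, fit, used) {
  a_s <- a_min / 60                              # s^-1 for the Eyring terms
  dh <- (e_a_j - .const$r_gas * t_s) / 1000      # kJ mol^-1
  ds <- .const$r_gas * log(a_s * .const$h / (.const$k_b * t_s))  # J mol^-1 K^-1
  dg <- dh - t_s * ds / 1000                     # kJ mol^-1
  structure(list(
    method = method,
    e_a = e_a_j / 1000,
    pre_exponential_a = a_min,
    r_squared = r2,
    t_s = t_s,
    delta_h = dh,
    delta_s = ds,
    delta_g = dg,
    beta = beta,
    n_points = n_pts,
    fit = fit,
    data = used
  ), class = "kinetic_fit")
}

#' Coats-Redfern kinetic fit of a mass-loss step
#'
#' First-order (n = 1) Coats-Redfern linearization:
#' `ln[-ln(1 - alpha) / T^2]` is regressed on `1/T`; the activation energy is
#' `E_a = -slope * R` and the pre-exponential factor follows from
#' `intercept = ln[A R / (beta E_a)]` (the small correction factor
#' `(1 - 2RT/E_a)` is neglected by default, per common practice, and can be
#' switched on). Activation thermodynamics are evaluated at the peak-rate
#' temperature `T_s`: `dH = E_a - R T_s`,
#' `dS = R ln(A h / (k_B T_s))` (with `A` in s^-1), `dG = dH - T_s dS`.
#'
#' @param step A one-row step from [segment_steps()] or a data frame with
#'   `temperature` (K) and `alpha` columns.
#' @param beta Heating rate, K min^-1.
#' @param alpha_range Conversion window used for the regression; at least 5
#'   interior points are required.
#' @param correction Apply the `(1 - 2RT/E_a)` intercept correction when
#'   recovering `A`.
#' @return A `kinetic_fit` object with elements `e_a` (kJ mol^-1),
#'   `pre_exponential_a` (min^-1), `r_squared`, `t_s` (K), `delta_h`
#'   (kJ mol^-1), `delta_s` (J mol^-1 K^-1), `delta_g` (kJ mol^-1).
#' @examples
#' tg <- gen_thermogram(steps = list(list(loss = 20, e_a = 120, a = 1e10)))
#' st <- segment_steps(tg)
#' coats_redfern_fit(st[1, ], beta = 10)
#' @export
coats_redfern_fit <- function(step, beta = 10, alpha_range = c(0.05, 0.95),
                              correction = FALSE) {
  arr <- step_arrays(step)
  use <- arr$alpha > alpha_range[1] & arr$alpha < alpha_range[2]
  if (sum(use) < 5L) {
    stop_input("Fewer than 5 points inside the conversion window.",
               "insufficient_conversion")
  }
  Tt <- arr$temperature[use]
  al <- arr$alpha[use]
  y <- log(-log(1 - al) / Tt^2)
  x <- 1 / Tt
  fit <- stats::lm(y ~ x)
  e_a <- -unname(coef(fit)[2]) * .const$r_gas
  if (e_a <= 0) {
    stop_input("Non-positive fitted activation energy; step is not Arrhenius-like.",
               "bad_kinetics")
  }
  intc <- unname(coef(fit)[1])
  corr <- if (correction) 1 - 2 * .const$r_gas * mean(Tt) / e_a else 1
  a_min <- exp(intc) * beta * e_a / .const$r_gas / corr
  new_kinetic_fit("coats_redfern", e_a, a_min, lm_r_squared(fit),
                  arr$t_peak, beta, sum(use), fit,
                  tibble::tibble(temperature = Tt, alpha = al, x = x, y = y))
}

#' Horowitz-Metzger kinetic fit of a mass-loss step
#'
#' First-order Horowitz-Metzger linearization about the peak-rate
#' temperature `T_s`: `ln[ln(1/(1 - alpha))]` is regressed on
#' `theta = T - T_s`. The textbook estimator reads
#' `E_a = slope * R * T_s^2`; because the chord of the exact first-order
#' model carries an intrinsic `+2 R T_s` contribution from the `T^2`
#' prefactor of the temperature integral, the default applies the corrected
#' form `E_a = slope * R * T_s^2 - 2 R T_s` (`ts_correction = FALSE`
#' restores the textbook estimator). The default conversion window is
#' narrower than for Coats-Redfern because the linearization is local to
#' `T_s`. Thermodynamics as in [coats_redfern_fit()].
#'
#' @inheritParams coats_redfern_fit
#' @param ts_correction Apply the `-2 R T_s` temperature-integral correction
#'   (default `TRUE`).
#' @return A `kinetic_fit` object.
#' @examples
#' tg <- gen_thermogram(steps = list(list(loss = 20, e_a = 120, a = 1e10)))
#' st <- segment_steps(tg)
#' horowitz_metzger_fit(st[1, ], beta = 10)
#' @export
horowitz_metzger_fit <- function(step, beta = 10, alpha_range = c(0.2, 0.8),
                                 ts_correction = TRUE) {
  arr <- step_arrays(step)
  use <- arr$alpha > alpha_range[1] & arr$alpha < alpha_range[2]
  if (sum(use) < 5L) {
    stop_input("Fewer than 5 points inside the conversion window.",
               "insufficient_conversion")
  }
  t_s <- arr$t_peak
  Tt <- arr$temperature[use]
  al <- arr$alpha[use]
  theta <- Tt - t_s
  y <- log(log(1 / (1 - al)))
  fit <- stats::lm(y ~ theta)
  slope <- unname(coef(fit)[2])
  e_a <- slope * .const$r_gas * t_s^2
  if (ts_correction) e_a <- e_a - 2 * .const$r_gas * t_s
  if (e_a <= 0) {
    stop_input("Non-positive fitted activation energy; step is not Arrhenius-like.",
               "bad_kinetics")
  }
  intc <- unname(coef(fit)[1])
  a_min <- exp(intc + e_a / (.const$r_gas * t_s)) * beta * e_a /
    (.const$r_gas * t_s^2)
  new_kinetic_fit("horowitz_metzger", e_a, a_min, lm_r_squared(fit),
                  t_s, beta, sum(use), fit,
                  tibble::tibble(temperature = Tt, alpha = al, x = theta, y = y))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  lab <- c(coats_redfern = "Coats-Redfern", horowitz_metzger = "Horowitz-Metzger")
  cat(sprintf("%s kinetic fit (first order, beta = %g K/min)\n",
              lab[[x$method]], x$beta))
  cat(sprintf("  E_a  = %.1f kJ/mol   A = %.3g 1/min   r^2 = %.5f\n",
              x$e_a, x$pre_exponential_a, x$r_squared))
  cat(sprintf("  T_s  = %.1f K   dH = %.1f kJ/mol   dS = %.1f J/mol/K   dG = %.1f kJ/mol\n",
              x$t_s, x$delta_h, x$delta_s, x$delta_g))
  invisible(x)
}

#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("e_a", "pre_exponential_a", "t_s", "delta_h", "delta_s", "delta_g"),
    estimate = c(x$e_a, x$pre_exponential_a, x$t_s, x$delta_h, x$delta_s,
                 x$delta_g),
    unit = c("kJ/mol", "1/min", "K", "kJ/mol", "J/mol/K", "kJ/mol")
  )
}

#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, e_a = x$e_a, pre_exponential_a = x$pre_exponential_a,
    r_squared = x$r_squared, t_s = x$t_s, delta_h = x$delta_h,
    delta_s = x$delta_s, delta_g = x$delta_g, n_points = x$n_points
  )
}
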