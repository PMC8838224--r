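# ggplot2 diagnostics for each fitted-result type.

#' Plot a Benesi-Hildebrand double-reciprocal fit
#'
#' Used points of `A0/(A - A0)` against `1/[DNA]` with the fitted line;
#' excluded points are hollow.
#'
#' @param object A `bh_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bh_fit
#' @export
autoplot.bh_fit <- function(object, ...) {
  d <- object$data
  d$x_all <- 1 / d$dna_M
  d$y_all <- object$a0 / d$delta
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_all, y = .data$y_all)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = expression(1 / "[DNA]" ~ (M^-1)),
                  y = expression(A[0] / (A - A[0])),
                  title = sprintf("Benesi-Hildebrand fit: K_b = %.3g 1/M, r² = %.4f",
                                  object$k_b, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a kinetic linearization
#'
#' The Coats-Redfern (`ln[-ln(1-alpha)/T^2]` vs `1/T`) or Horowitz-Metzger
#' (`ln[ln(1/(1-alpha))]` vs `theta`) scatter with its fitted line.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  lab <- if (object$method == "coats_redfern") {
    list(x = expression(1 / T ~ (K^-1)),
         y = expression(ln(-ln(1 - alpha) / T^2)))
  } else {
    list(x = expression(theta == T - T[s] ~ (K)),
         y = expression(ln(ln(1 / (1 - alpha)))))
  }
  co <- coef(object$fit)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(intercept = co[1], slope = co[2], colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = lab$x, y = lab$y,
                  title = sprintf("%s: E_a = %.1f kJ/mol, r² = %.5f",
                                  object$method, object$e_a, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a molar-ratio breakpoint fit
#'
#' The absorbance series, the two branch lines, and the breakpoint.
#'
#' @param object A `molar_ratio_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot molar_ratio_fit
#' @export
autoplot.molar_ratio_fit <- function(object, ...) {
  br <- object$branches
  g <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$mole_fraction_metal,
                                    y = .data$absorbance)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = br$intercept[1], slope = br$slope[1],
                         colour = "steelblue") +
    ggplot2::geom_abline(intercept = br$intercept[2], slope = br$slope[2],
                         colour = "firebrick") +
    ggplot2::labs(x = "[M] / ([M] + [L])", y = "Absorbance",
                  title = sprintf("Molar ratio: breakpoint %.3f (%s)",
                                  object$breakpoint, object$ratio_label)) +
    ggplot2::theme_minimal()
  if (!is.na(object$breakpoint)) {
    g <- g + ggplot2::geom_vline(xintercept = object$breakpoint,
                                 linetype = "dashed", colour = "grey50")
  }
  g
}

#' Plot observed vs fitted activity for a QSAR model
#'
#' @param object A `qsar_mlr`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qsar_mlr
#' @export
autoplot.qsar_mlr <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(colour = "grey50", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed activity", y = "Fitted activity",
                  title = sprintf("QSAR MLR: R² = %.4f (n = %d)",
                                  object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a thermogram with its segmented steps
#'
#' Remaining mass against temperature; detected steps are shaded and their
#' peak-rate temperatures marked.
#'
#' @param data Thermogram tibble (`temperature` in K, `mass_percent`).
#' @param steps Optional output of [segment_steps()].
#' @return A ggplot.
#' @export
plot_thermogram <- function(data, steps = NULL) {
  g <- ggplot2::ggplot(tibble::as_tibble(data),
                       ggplot2::aes(x = .data$temperature,
                                    y = .data$mass_percent)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (K)", y = "Remaining mass (%)") +
    ggplot2::theme_minimal()
  if (!is.null(steps) && nrow(steps) > 0) {
    g <- g +
      ggplot2::geom_rect(data = steps,
                         ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, alpha = 0.1, fill = "steelblue") +
      ggplot2::geom_vline(data = steps,
                          ggplot2::aes(xintercept = .data$t_peak),
                          linetype = "dotted", colour = "grey50")
  }
  g
}
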