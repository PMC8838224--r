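# Four-descriptor multiple-linear-regression QSAR model linking molecular
# descriptors (polar surface area ASA_P, hydrophobic surface area ASA_H,
# protonation basicity h_pkp, dipole moment) to anticancer activity (IC50).

qsar_default_descriptors <- c("asa_p", "asa_h", "h_pkp", "dipole")

# Accept common header spellings: case-insensitive, h_pkb == h_pkp, IC50.
standardize_qsar_names <- function(data) {
  nm <- tolower(names(data))
  nm[nm == "h_pkb"] <- "h_pkp"
  nm[nm == "ic_50"] <- "ic50"
  names(data) <- nm
  data
}

#' Fit the multiple-linear-regression QSAR model
#'
#' Ordinary least squares with intercept, `Y = b1 x1 + ... + b4 x4 + C`,
#' regressing the activity (IC50, or its log10 when
#' `transform = "log10"`) on the descriptor columns. Descriptors are used in
#' their natural units (no standardization), so coefficients match the
#' printed model form.
#'
#' @param data Training table with one row per compound: descriptor columns,
#'   the response column, and optionally `compound_id`. Header spellings are
#'   normalized case-insensitively and `h_pkb` is accepted for `h_pkp`.
#'   Rows with missing descriptors or response are dropped with a message.
#' @param response Name of the response column (default `"ic50"`).
#' @param descriptors Character vector of descriptor column names.
#' @param transform `"none"` (regress the activity directly) or `"log10"`.
#' @return A `qsar_mlr` object with `coefficients`, `intercept`, `r`,
#'   `r_squared` and a per-compound `residuals` tibble; see [tidy()],
#'   [glance()], [predict.qsar_mlr()], [validate_qsar()].
#' @examples
#' tr <- gen_qsar_table(n = 30, noise_sd = 0, seed = 1)
#' m <- fit_mlr(tr)
#' glance(m)
#' @export
fit_mlr <- function(data, response = "ic50",
                    descriptors = qsar_default_descriptors,
                    transform = c("none", "log10")) {
  transform <- match.arg(transform)
  data <- standardize_qsar_names(tibble::as_tibble(data))
  response <- tolower(response)
  missing_cols <- setdiff(c(descriptors, response), names(data))
  if (length(missing_cols) > 0L) {
    stop_input(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
               "missing_columns")
  }
  keep <- stats::complete.cases(data[c(descriptors, response)])
  if (!all(keep)) {
    rlang::inform(sprintf("Dropping %d incomplete record(s).", sum(!keep)))
    data <- data[keep, ]
  }
  n <- nrow(data)
  p <- length(descriptors)
  if (n < 6L || n <= p + 1L) {
    stop_input(sprintf(
      "Need more than %d complete records to fit %d coefficients plus intercept (got %d).",
      max(5L, p + 1L), p, n), "insufficient_data")
  }
  X <- as.matrix(data[descriptors])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    aliased <- descriptors[qrX$pivot[seq(qrX$rank + 1L, p + 1L)] - 1L]
    stop_input(paste0("Descriptor matrix is rank deficient; collinear column(s): ",
                      paste(aliased, collapse = ", ")), "rank_deficient")
  }
  y_raw <- data[[response]]
  y <- if (transform == "log10") log10(y_raw) else y_raw
  constant_response <- var(y) == 0
  df_fit <- data.frame(.y = y, X)
  fit <- stats::lm(.y ~ ., data = df_fit)
  fitted_y <- unname(fit$fitted.values)
  r2 <- if (constant_response) {
    rlang::warn("Response is constant across records; R^2 is undefined.")
    NA_real_
  } else {
    lm_r_squared(fit)
  }
  co <- coef(fit)
  res <- tibble::tibble(
    compound_id = if ("compound_id" %in% names(data)) data$compound_id
                  else as.character(seq_len(n)),
    observed = y,
    fitted = fitted_y,
    residual = y - fitted_y
  )
  structure(list(
    fit = fit,
    coefficients = setNames(unname(co[-1]), descriptors),
    intercept = unname(co[1]),
    r = if (is.na(r2)) NA_real_ else sqrt(r2),
    r_squared = r2,
    residuals = res,
    transform = transform,
    response = response,
    descriptors = descriptors,
    constant_response = constant_response,
    n = n,
    training = data
  ), class = "qsar_mlr")
}

#' Predict activity for new compounds
#'
#' Evaluates `Y = sum(b x) + C` per record and back-transforms
#' (`10^Y`) when the model was fitted on log10 activity. Records with a
#' missing descriptor yield `NA` predictions with a warning; the others
#' proceed.
#'
#' @param object A `qsar_mlr` model.
#' @param newdata Table with the model's descriptor columns (header
#'   spellings normalized as in [fit_mlr()]).
#' @param ... Unused.
#' @return A tibble mirroring the two-column predicted-activity table:
#'   `compound_id` and `pred_activity` (IC50 scale).
#' @export
predict.qsar_mlr <- function(object, newdata, ...) {
  newdata <- standardize_qsar_names(tibble::as_tibble(newdata))
  missing_cols <- setdiff(object$descriptors, names(newdata))
  if (length(missing_cols) > 0L) {
    stop_input(paste0("Missing descriptor column(s): ",
                      paste(missing_cols, collapse = ", ")), "missing_columns")
  }
  X <- as.matrix(newdata[object$descriptors])
  bad <- !stats::complete.cases(X)
  if (any(bad)) {
    rlang::warn(sprintf("%d record(s) have missing descriptors; predictions set to NA.",
                        sum(bad)))
  }
  yhat <- as.numeric(X %*% object$coefficients) + object$intercept
  yhat[bad] <- NA_real_
  if (object$transform == "log10") yhat <- 10^yhat
  tibble::tibble(
    compound_id = if ("compound_id" %in% names(newdata)) newdata$compound_id
                  else as.character(seq_len(nrow(newdata))),
    pred_activity = yhat
  )
}

#' Validate a QSAR model
#'
#' Recomputes the fit diagnostics from scratch (Pearson R between observed
#' and fitted, its square, and the per-compound residual table mirroring the
#' predicted-vs-experimental comparison) and adds a leave-one-out
#' cross-validated `q_squared = 1 - PRESS/TSS`, the standard internal
#' validation statistic for small QSAR training sets.
#'
#' @param model A `qsar_mlr` object.
#' @return A `qsar_validation` object: `r`, `r_squared`, `q_squared`,
#'   `press`, and the `residuals` tibble.
#' @export
validate_qsar <- function(model) {
  stopifnot(inherits(model, "qsar_mlr"))
  data <- model$training
  y <- model$residuals$observed
  fitted_y <- model$residuals$fitted
  r <- if (model$constant_response) NA_real_ else cor(y, fitted_y)
  n <- length(y)
  loo <- vapply(seq_len(n), function(i) {
    m <- fit_mlr(data[-i, ], response = model$response,
                 descriptors = model$descriptors, transform = model$transform)
    # prediction kept on the fitted (possibly log10) scale to match `y`
    X <- as.numeric(as.matrix(data[i, model$descriptors, drop = FALSE]))
    sum(X * m$coefficients) + m$intercept
  }, numeric(1))
  press <- sum((y - loo)^2)
  tss <- sum((y - mean(y))^2)
  q2 <- if (tss == 0) NA_real_ else 1 - press / tss
  structure(list(
    r = r,
    r_squared = if (is.na(r)) NA_real_ else r^2,
    q_squared = q2,
    press = press,
    residuals = dplyr::mutate(model$residuals, loo_predicted = loo)
  ), class = "qsar_validation")
}

#' @export
print.qsar_mlr <- function(x, ...) {
  cat("QSAR multiple linear regression\n")
  cat("  ", paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  intercept = %.4g   R = %.4f   R^2 = %.4f   n = %d\n",
              x$intercept, x$r, x$r_squared, x$n))
  if (x$transform == "log10") cat("  (fitted on log10 activity)\n")
  invisible(x)
}

#' @method tidy qsar_mlr
#' @export
tidy.qsar_mlr <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", x$descriptors),
    estimate = c(x$intercept, unname(x$coefficients)),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @method glance qsar_mlr
#' @export
glance.qsar_mlr <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r_squared, n = x$n,
                 transform = x$transform)
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat(sprintf("QSAR validation: R = %.4f, R^2 = %.4f, LOO q^2 = %.4f\n",
              x$r, x$r_squared, x$q_squared))
  invisible(x)
}

#' @method glance qsar_validation
#' @export
glance.qsar_validation <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r_squared, q_squared = x$q_squared,
                 press = x$press)
}
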