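# Shared internal helpers.

# Round half away from zero, the convention used in elemental-analysis tables.
# A tiny relative nudge guards against binary-float half-cases (e.g. 2.675
# stored as 2.67499...).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9 * pmax(abs(x), 1)) / p
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of their config.
run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
      } else {
        assign(".Random.seed", old, envir = .GlobalEnv)
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Cumulative trapezoidal integral of y over x; same length as x, starts at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# Coefficient of determination computed directly from the fit, avoiding
# summary.lm()'s near-perfect-fit warning on noise-free synthetic data.
lm_r_squared <- function(fit) {
  y <- fit$model[[1]]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  max(0, min(1, 1 - sum(resid(fit)^2) / tss))
}

stop_input <- function(msg, class) {
  rlang::abort(msg, class = c(class, "vanchar_error"))
}
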