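test_that("zero-noise tables recover the generating model exactly", {
  tr <- gen_qsar_table(n = 40, noise_sd = 0, seed = 2)
  m <- fit_mlr(tr)
  expect_equal(unname(m$coefficients), c(0.5, -0.2, 3, 1), tolerance = 1e-8)
  expect_equal(m$intercept, 7, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_equal(m$r^2, m$r_squared, tolerance = 1e-10)
  expect_lt(abs(mean(m$residuals$residual)), 1e-8)
})

test_that("residuals are orthogonal to every descriptor column", {
  tr <- gen_qsar_table(n = 60, noise_sd = 3, seed = 5)
  m <- fit_mlr(tr)
  res <- m$residuals$residual
  for (d in names(m$coefficients)) {
    expect_lt(abs(sum(res * tr[[d]])) / max(abs(tr[[d]])), 1e-6)
  }
  expect_lt(abs(sum(res)), 1e-8)
})

test_that("predictions satisfy the OLS identities and the generator oracle", {
  tr <- gen_qsar_table(n = 40, noise_sd = 2, seed = 8)
  m <- fit_mlr(tr)
  # training predictions equal observed minus residual exactly
  pr <- predict(m, tr)
  expect_equal(pr$pred_activity, m$residuals$observed - m$residuals$residual,
               tolerance = 1e-10)
  # held-out zero-noise records fall on the generating plane
  te <- gen_qsar_table(n = 10, noise_sd = 0, seed = 9)
  m0 <- fit_mlr(gen_qsar_table(n = 40, noise_sd = 0, seed = 10))
  pr0 <- predict(m0, te)
  expect_equal(pr0$pred_activity, te$ic50, tolerance = 1e-8)
  # an all-zero descriptor record predicts the intercept
  zero <- tibble::tibble(compound_id = "z", asa_p = 0, asa_h = 0,
                         h_pkp = 0, dipole = 0)
  expect_equal(predict(m0, zero)$pred_activity, m0$intercept, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected or flagged", {
  tr <- gen_qsar_table(n = 20, noise_sd = 0, seed = 3)
  dup <- dplyr::mutate(tr, asa_h = 2 * asa_p)   # collinear with asa_p
  expect_error(fit_mlr(dup), "asa_h", class = "rank_deficient")
  expect_error(fit_mlr(tr[1:4, ]), class = "insufficient_data")
  const <- dplyr::mutate(tr, ic50 = 5)
  expect_warning(mc <- fit_mlr(const), "constant")
  expect_true(is.na(mc$r_squared))
  expect_equal(unname(mc$coefficients), rep(0, 4), tolerance = 1e-10)
  expect_equal(mc$intercept, 5, tolerance = 1e-10)
})

test_that("alternate header spellings are accepted", {
  tr <- gen_qsar_table(n = 20, noise_sd = 0, seed = 4)
  names(tr) <- c("compound_id", "ASA_P", "ASA_H", "h_pKb", "Dipole", "IC50")
  m <- fit_mlr(tr)
  expect_equal(unname(m$coefficients), c(0.5, -0.2, 3, 1), tolerance = 1e-8)
})

test_that("validation recomputes diagnostics and LOO q-squared behaves", {
  # zero noise: perfect fit and perfect cross-validation
  m0 <- fit_mlr(gen_qsar_table(n = 30, noise_sd = 0, seed = 6))
  v0 <- validate_qsar(m0)
  expect_equal(v0$r_squared, 1, tolerance = 1e-8)
  expect_equal(v0$q_squared, 1, tolerance = 1e-8)
  # R^2 equals the squared Pearson correlation of fitted vs observed
  mn <- fit_mlr(gen_qsar_table(n = 50, noise_sd = 4, seed = 7))
  vn <- validate_qsar(mn)
  expect_equal(vn$r_squared,
               cor(mn$residuals$observed, mn$residuals$fitted)^2,
               tolerance = 1e-10)
  expect_equal(vn$r_squared, mn$r_squared, tolerance = 1e-10)
  # pure-noise response: cross-validated q^2 falls below R^2
  pure <- gen_qsar_table(n = 40, coefficients = c(asa_p = 0, asa_h = 0,
                                                  h_pkp = 0, dipole = 0),
                         intercept = 50, noise_sd = 10, seed = 12)
  mp <- fit_mlr(pure)
  vp <- validate_qsar(mp)
  expect_lt(vp$q_squared, vp$r_squared)
})

test_that("log10 response transform round-trips through prediction", {
  tr <- gen_qsar_table(n = 40,
                       coefficients = c(asa_p = 0.002, asa_h = -0.001,
                                        h_pkp = 0.05, dipole = 0.02),
                       intercept = 0.3, noise_sd = 0, seed = 13)
  tr$ic50 <- 10^tr$ic50           # activity strictly positive, log-linear
  m <- fit_mlr(tr, transform = "log10")
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  pr <- predict(m, tr)
  expect_equal(pr$pred_activity, tr$ic50, tolerance = 1e-6)
})

test_that("prediction is equivariant under descriptor column shifts", {
  tr <- gen_qsar_table(n = 40, noise_sd = 1, seed = 14)
  m1 <- fit_mlr(tr)
  sh <- dplyr::mutate(tr, asa_p = asa_p + 100)
  m2 <- fit_mlr(sh)
  expect_equal(m2$coefficients, m1$coefficients, tolerance = 1e-8)
  expect_equal(m2$intercept, m1$intercept - m1$coefficients[["asa_p"]] * 100,
               tolerance = 1e-8)
  expect_equal(predict(m2, sh)$pred_activity, predict(m1, tr)$pred_activity,
               tolerance = 1e-8)
})

test_that("coefficient estimates stay unbiased under response noise", {
  # noise sd set to 5 % of the noiseless response spread
  base <- gen_qsar_table(n = 100, noise_sd = 0, seed = 20)
  sdy <- sd(base$ic50)
  b_true <- c(asa_p = 0.5, asa_h = -0.2, h_pkp = 3, dipole = 1)
  reps <- 200
  est <- matrix(NA_real_, reps, 4, dimnames = list(NULL, names(b_true)))
  for (r in 1:reps) {
    m <- fit_mlr(gen_qsar_table(n = 100, noise_sd = 0.05 * sdy,
                                seed = 30000 + r))
    est[r, ] <- m$coefficients
  }
  for (d in names(b_true)) {
    se_mean <- sd(est[, d]) / sqrt(reps)
    expect_lt(abs(mean(est[, d]) - b_true[[d]]), 2 * se_mean + 1e-12)
  }
})
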