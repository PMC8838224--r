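test_that("noise-free titrations are recovered to machine precision", {
  for (k in c(5e5, 1.4e6, 8.33e5)) {
    tt <- gen_titration(true_k = k, noise_sd = 0)
    f <- benesi_hildebrand_fit(tt)
    expect_lt(abs(f$k_b - k) / k, 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
    expect_equal(f$epsilon_ratio, attr(tt, "epsilon_ratio"), tolerance = 1e-9)
  }
})

test_that("three collinear transformed points give a perfect line", {
  # construct absorbances whose transform is exactly y = 2 + 1e-6 x
  D <- c(1e-6, 2e-6, 5e-6)
  a0 <- 0.5
  y <- 2 + 1e-6 / D
  A <- a0 + a0 / y
  f <- benesi_hildebrand_fit(tibble::tibble(dna_M = D, absorbance = A), a0 = a0)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$k_b, 2 / 1e-6, tolerance = 1e-9)
})

test_that("degenerate titrations are rejected", {
  D <- 10^seq(-7, -5, length.out = 6)
  expect_error(
    benesi_hildebrand_fit(tibble::tibble(dna_M = D, absorbance = rep(0.6, 6)),
                          a0 = 0.6),
    class = "no_absorbance_change")
  expect_error(
    benesi_hildebrand_fit(tibble::tibble(dna_M = D[1:2], absorbance = c(.7, .8)),
                          a0 = 0.6),
    class = "insufficient_data")
  expect_error(
    benesi_hildebrand_fit(tibble::tibble(dna_M = rev(D), absorbance = runif(6)),
                          a0 = 0.6),
    class = "bad_concentration_grid")
})

test_that("points inside the exclusion floor are dropped and reported", {
  tt <- gen_titration(true_k = 1e6, noise_sd = 0)
  tt$absorbance[1] <- attr(tt, "a0") + 5e-4   # push below the 1e-3 floor
  f <- benesi_hildebrand_fit(tt)
  expect_equal(f$n_used, nrow(tt) - 1L)
  expect_false(f$data$used[1])
})

test_that("mixed chromism falls back to the majority sign with a warning", {
  tt <- gen_titration(true_k = 1e6, noise_sd = 0)
  tt$absorbance[2] <- attr(tt, "a0") - 0.05
  expect_warning(f <- benesi_hildebrand_fit(tt), "majority")
  expect_equal(f$chromism, "indeterminate")
  expect_equal(f$n_used, nrow(tt) - 1L)
})

test_that("the binding constant is invariant to rescaling all absorbances", {
  tt <- gen_titration(true_k = 7.7e5, noise_sd = 0.01, seed = 3)
  f1 <- benesi_hildebrand_fit(tt)
  tt2 <- tt
  tt2$absorbance <- tt2$absorbance * 4.2
  f2 <- benesi_hildebrand_fit(tt2, a0 = attr(tt, "a0") * 4.2)
  expect_equal(f2$k_b, f1$k_b, tolerance = 1e-9)
})

test_that("recovery stays within 5 percent median error across the binding range", {
  # each synthetic titration uses a DNA window bracketing 1/K, as an
  # absorption titration would be designed
  set.seed(202)
  ks <- 10^runif(200, 5, 7)
  errs <- vapply(seq_along(ks), function(i) {
    k <- ks[i]
    tt <- gen_titration(true_k = k,
                        dna_grid = 10^seq(log10(0.1 / k), log10(10 / k),
                                          length.out = 20),
                        noise_sd = 0.01, seed = 5000 + i)
    abs(benesi_hildebrand_fit(tt)$k_b - k) / k
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("the nonlinear cross-check agrees with the linear estimate on clean data", {
  tt <- gen_titration(true_k = 1.4e6, noise_sd = 0.005, seed = 9)
  f <- benesi_hildebrand_fit(tt, nonlinear_check = TRUE)
  expect_false(is.na(f$k_b_nls))
  expect_lt(abs(f$k_b_nls - f$k_b) / f$k_b, 0.2)
})

test_that("chromism classification matches the published behaviour patterns", {
  # hyperchromic, blue-shifted complex
  up <- tibble::tibble(dna_M = c(1e-6, 2e-6, 4e-6),
                       absorbance = c(0.62, 0.66, 0.71))
  c1 <- classify_chromism(up, a0 = 0.6, lambda_free = 265, lambda_bound = 259)
  expect_equal(c1$chromism, "hyperchromic")
  expect_equal(c1$shift, "blue")
  # hypochromic ligand
  dn <- tibble::tibble(dna_M = c(1e-6, 2e-6, 4e-6),
                       absorbance = c(0.58, 0.55, 0.51))
  c2 <- classify_chromism(dn, a0 = 0.6, lambda_free = 395, lambda_bound = 376)
  expect_equal(c2$chromism, "hypochromic")
  expect_equal(c2$shift, "blue")
  # flat series within threshold; unknown shift without a bound-form maximum
  fl <- tibble::tibble(dna_M = c(1e-6, 2e-6, 4e-6),
                       absorbance = c(0.601, 0.599, 0.602))
  c3 <- classify_chromism(fl, a0 = 0.6)
  expect_equal(c3$chromism, "indeterminate")
  expect_equal(c3$shift, "unknown")
  # equal maxima give no shift
  c4 <- classify_chromism(up, a0 = 0.6, lambda_free = 263, lambda_bound = 263)
  expect_equal(c4$shift, "none")
})

test_that("tidy and glance expose the fit in broom shape", {
  f <- benesi_hildebrand_fit(gen_titration(1e6, noise_sd = 0.01, seed = 1))
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(f)
  expect_true(all(c("k_b", "r_squared", "chromism", "shift") %in% names(gl)))
  expect_equal(gl$k_b, f$k_b)
})
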