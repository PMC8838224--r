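# Seeded generators producing synthetic inputs with the statistical
# structure each analysis stage assumes: 1:1 binding titrations, first-order
# non-isothermal thermograms, ideal molar-ratio series, and linear
# descriptor-activity tables. Every generator is a pure function of its
# arguments including the seed, and its zero-noise output is an exact fixed
# point of the corresponding estimator.

#' Generate a DNA absorption titration
#'
#' Inverts the 1:1 Benesi-Hildebrand isotherm to produce absorbances from a
#' known binding constant:
#' `A = a0 + a0 / (epsilon_ratio * (1 + 1/(K [DNA])))`,
#' then applies multiplicative Gaussian noise to `A`. At zero noise the
#' double-reciprocal transform of the output is an exact line and
#' [benesi_hildebrand_fit()] recovers `true_k` to machine precision.
#'
#' Defaults describe a strongly hyperchromic complex titrated over a
#' DNA window bracketing `1/K`: constant compound absorbance 0.6, twenty
#' additions log-spaced over `[1e-7, 1e-5]` M, and
#' `epsilon_ratio = epsG/(epsHG - epsG) = 0.4`. A negative `epsilon_ratio`
#' produces a hypochromic series.
#'
#' @param true_k Binding constant, M^-1.
#' @param a0 Absorbance of the compound alone.
#' @param epsilon_ratio Intercept of the double-reciprocal line,
#'   `epsG/(epsHG - epsG)`.
#' @param dna_grid Strictly increasing positive DNA concentrations, M.
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   noise on `A` (0.01 = 1 %).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param lambda_free,lambda_bound Band maxima (nm) carried as metadata.
#' @return A tibble with columns `dna_M`, `absorbance`, carrying `a0`,
#'   `lambda_free`, `lambda_bound`, `true_k`, `epsilon_ratio` attributes.
#' @examples
#' tt <- gen_titration(1.4e6, noise_sd = 0.01, seed = 42)
#' benesi_hildebrand_fit(tt)
#' @export
gen_titration <- function(true_k = 1.4e6, a0 = 0.6, epsilon_ratio = 0.4,
                          dna_grid = 10^seq(-7, -5, length.out = 20),
                          noise_sd = 0, seed = NULL,
                          lambda_free = 265, lambda_bound = 259) {
  if (true_k <= 0) stop_input("`true_k` must be positive.", "bad_generator_config")
  if (epsilon_ratio == 0) {
    stop_input("`epsilon_ratio` must be non-zero.", "bad_generator_config")
  }
  if (any(dna_grid <= 0) || any(diff(dna_grid) <= 0)) {
    stop_input("`dna_grid` must be strictly positive and increasing.",
               "bad_generator_config")
  }
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0.", "bad_generator_config")
  A <- a0 + a0 / (epsilon_ratio * (1 + 1 / (true_k * dna_grid)))
  if (any(A == a0)) {
    stop_input("Grid produced A identical to a0; choose a wider grid.",
               "bad_generator_config")
  }
  A <- run_seeded(seed, A * (1 + rnorm(length(A), 0, noise_sd)))
  out <- tibble::tibble(dna_M = dna_grid, absorbance = A)
  attr(out, "a0") <- a0
  attr(out, "lambda_free") <- lambda_free
  attr(out, "lambda_bound") <- lambda_bound
  attr(out, "true_k") <- true_k
  attr(out, "epsilon_ratio") <- epsilon_ratio
  out
}

#' Generate a first-order thermogram at constant heating rate
#'
#' Integrates the non-isothermal first-order rate law
#' `d(alpha)/dT = (A/beta) exp(-E_a/(R T)) (1 - alpha)` exactly (cumulative
#' trapezoid on the output grid) for each decomposition step and superposes
#' the steps on a remaining-mass curve starting at 100 %. Additive Gaussian
#' noise (mass-percent units) is then applied. Default steps mimic a
#' hydrated complex: a small low-temperature dehydration followed by a large
#' organic decomposition.
#'
#' @param steps List of steps, each a list/vector with elements `loss`
#'   (percent of initial mass), `e_a` (kJ mol^-1) and `a` (pre-exponential,
#'   min^-1). Losses must sum to < 100.
#' @param beta Heating rate, K min^-1.
#' @param t_range Temperature range, K.
#' @param t_step Grid spacing, K.
#' @param noise_sd Additive noise standard deviation, mass-percent units.
#' @param seed Integer seed.
#' @return A tibble with columns `temperature` (K) and `mass_percent`,
#'   carrying `beta` and `steps` attributes. A warning is raised when two
#'   steps overlap (both partially converted at the same temperature).
#' @examples
#' tg <- gen_thermogram(steps = list(list(loss = 9.44, e_a = 120, a = 1e10)))
#' segment_steps(tg)
#' @export
gen_thermogram <- function(steps = list(list(loss = 4.1, e_a = 80, a = 1e10),
                                        list(loss = 86.5, e_a = 200, a = 1e12)),
                           beta = 10, t_range = c(300, 1100), t_step = 0.5,
                           noise_sd = 0, seed = NULL) {
  losses <- vapply(steps, function(s) as.numeric(s[["loss"]]), numeric(1))
  eas <- vapply(steps, function(s) as.numeric(s[["e_a"]]), numeric(1)) * 1000
  as_ <- vapply(steps, function(s) as.numeric(s[["a"]]), numeric(1))
  if (length(steps) > 0L) {
    if (any(losses <= 0) || sum(losses) >= 100) {
      stop_input("Step losses must be positive and sum to < 100.",
                 "bad_generator_config")
    }
    if (any(eas <= 0) || any(as_ <= 0)) {
      stop_input("`e_a` and `a` must be positive.", "bad_generator_config")
    }
  }
  Tg <- seq(t_range[1], t_range[2], by = t_step)
  mass <- rep(100, length(Tg))
  alphas <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    k <- (as_[i] / beta) * exp(-eas[i] / (.const$r_gas * Tg))
    al <- 1 - exp(-cumtrapz(Tg, k))
    alphas[[i]] <- al
    mass <- mass - losses[i] * al
  }
  if (length(steps) > 1L) {
    for (i in seq_len(length(steps) - 1L)) {
      for (j in seq(i + 1L, length(steps))) {
        both <- alphas[[i]] > 0.01 & alphas[[i]] < 0.99 &
                alphas[[j]] > 0.01 & alphas[[j]] < 0.99
        if (any(both)) {
          rlang::warn(sprintf("Steps %d and %d overlap in temperature.", i, j))
        }
      }
    }
  }
  mass <- run_seeded(seed, mass + rnorm(length(mass), 0, noise_sd))
  out <- tibble::tibble(temperature = Tg, mass_percent = mass)
  attr(out, "beta") <- beta
  attr(out, "steps") <- steps
  out
}

#' Generate an ideal molar-ratio series
#'
#' Under effectively complete complex formation the absorbance of an ML_n
#' solution prepared at metal mole fraction `x = [M]/([M]+[L])` is
#' proportional to `min(x, (1-x)/n)`: it rises while metal is limiting and
#' falls once ligand is, with the break at `x = 1/(n+1)` (0.5 for 1:1, 1/3
#' for 1:2). The series is scaled so the theoretical peak equals `max_abs`,
#' then additive Gaussian noise with standard deviation
#' `noise_sd * max_abs` is applied.
#'
#' @param ratio `"1:1"` or `"1:2"` (metal:ligand).
#' @param max_abs Absorbance at the theoretical break.
#' @param fractions Strictly increasing mole-fraction grid in `[0, 1]`;
#'   default the seven-flask design `0, 1/6, ..., 1`.
#' @param noise_sd Noise standard deviation relative to `max_abs`.
#' @param seed Integer seed.
#' @return A tibble with columns `mole_fraction_metal`, `absorbance` and a
#'   `ratio` attribute.
#' @examples
#' fit_breakpoint(gen_molar_ratio("1:1", noise_sd = 0))
#' @export
gen_molar_ratio <- function(ratio = c("1:1", "1:2"), max_abs = 1,
                            fractions = (0:6) / 6, noise_sd = 0, seed = NULL) {
  ratio <- match.arg(ratio)
  n_lig <- if (ratio == "1:1") 1 else 2
  if (any(fractions < 0) || any(fractions > 1) || any(diff(fractions) <= 0)) {
    stop_input("`fractions` must be strictly increasing within [0, 1].",
               "bad_generator_config")
  }
  y <- pmin(fractions, (1 - fractions) / n_lig) * (n_lig + 1) * max_abs
  y <- run_seeded(seed, y + rnorm(length(y), 0, noise_sd * max_abs))
  out <- tibble::tibble(mole_fraction_metal = fractions, absorbance = y)
  attr(out, "ratio") <- ratio
  out
}

#' Generate a synthetic descriptor/activity table
#'
#' Draws descriptors uniformly from the given ranges and builds the response
#' as the exact linear model `Y = sum(b x) + C` plus additive Gaussian
#' noise. At zero noise [fit_mlr()] recovers the coefficients to machine
#' precision.
#'
#' @param n Number of compounds (> 5).
#' @param coefficients Named numeric vector of generating coefficients (names
#'   are the descriptor columns).
#' @param intercept Generating intercept.
#' @param descriptor_ranges Named list of `c(min, max)` ranges; a zero-width
#'   range yields a constant column with a warning.
#' @param noise_sd Additive response noise standard deviation (response
#'   units).
#' @param seed Integer seed.
#' @return A tibble with `compound_id`, one column per descriptor, and
#'   `ic50`.
#' @examples
#' fit_mlr(gen_qsar_table(n = 50, noise_sd = 0, seed = 7))
#' @export
gen_qsar_table <- function(n = 100,
                           coefficients = c(asa_p = 0.5, asa_h = -0.2,
                                            h_pkp = 3, dipole = 1),
                           intercept = 7,
                           descriptor_ranges = list(asa_p = c(20, 200),
                                                    asa_h = c(150, 600),
                                                    h_pkp = c(2, 12),
                                                    dipole = c(1, 10)),
                           noise_sd = 0, seed = NULL) {
  if (n <= 5L) stop_input("`n` must exceed 5.", "bad_generator_config")
  descs <- names(coefficients)
  if (is.null(descs) || !setequal(descs, names(descriptor_ranges))) {
    stop_input("`coefficients` and `descriptor_ranges` must share names.",
               "bad_generator_config")
  }
  run_seeded(seed, {
    X <- lapply(descs, function(d) {
      rg <- descriptor_ranges[[d]]
      if (diff(rg) == 0) {
        rlang::warn(sprintf("Descriptor '%s' has zero-width range; constant column.", d))
        rep(rg[1], n)
      } else {
        runif(n, rg[1], rg[2])
      }
    })
    names(X) <- descs
    X <- tibble::as_tibble(X)
    y <- as.numeric(as.matrix(X) %*% coefficients) + intercept +
      rnorm(n, 0, noise_sd)
    dplyr::bind_cols(tibble::tibble(compound_id = sprintf("cpd%03d", seq_len(n))),
                     X, tibble::tibble(ic50 = y))
  })
}

#' Write a labelled bundle of synthetic fixtures
#'
#' Emits one delimited-text file per analysis stage (titration, thermogram,
#' molar-ratio series for both stoichiometries, QSAR training and test
#' tables) plus a `manifest.json` recording every generator configuration,
#' so a whole pipeline run is reproducible from the manifest alone.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed; per-file seeds are derived from it.
#' @param noise Named list overriding the default noise levels
#'   (`titration`, `thermogram`, `molar_ratio`, `qsar`).
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_bundle <- function(dir, seed = 1,
                            noise = list(titration = 0.01, thermogram = 0.1,
                                         molar_ratio = 0.02, qsar = 2)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  cfg <- list(
    seed = seed,
    titration = list(true_k = 1.4e6, a0 = 0.6, epsilon_ratio = 0.4,
                     noise_sd = noise$titration, seed = seed + 1),
    thermogram = list(steps = list(list(loss = 4.1, e_a = 80, a = 1e10),
                                   list(loss = 86.5, e_a = 200, a = 1e12)),
                      beta = 10, noise_sd = noise$thermogram, seed = seed + 2),
    molar_ratio_11 = list(ratio = "1:1", noise_sd = noise$molar_ratio,
                          seed = seed + 3),
    molar_ratio_12 = list(ratio = "1:2", noise_sd = noise$molar_ratio,
                          seed = seed + 4),
    qsar_train = list(n = 100, noise_sd = noise$qsar, seed = seed + 5),
    qsar_test = list(n = 8, noise_sd = 0, seed = seed + 6)
  )
  tt <- gen_titration(true_k = cfg$titration$true_k, a0 = cfg$titration$a0,
                      epsilon_ratio = cfg$titration$epsilon_ratio,
                      noise_sd = cfg$titration$noise_sd,
                      seed = cfg$titration$seed)
  write_titration(tt, p("titration.csv"))
  tg <- gen_thermogram(steps = cfg$thermogram$steps, beta = cfg$thermogram$beta,
                       noise_sd = cfg$thermogram$noise_sd,
                       seed = cfg$thermogram$seed)
  write_thermogram(tg, p("thermogram.csv"))
  readr::write_csv(gen_molar_ratio("1:1", noise_sd = cfg$molar_ratio_11$noise_sd,
                                   seed = cfg$molar_ratio_11$seed),
                   p("molar_ratio_11.csv"))
  readr::write_csv(gen_molar_ratio("1:2", noise_sd = cfg$molar_ratio_12$noise_sd,
                                   seed = cfg$molar_ratio_12$seed),
                   p("molar_ratio_12.csv"))
  readr::write_csv(gen_qsar_table(n = cfg$qsar_train$n,
                                  noise_sd = cfg$qsar_train$noise_sd,
                                  seed = cfg$qsar_train$seed),
                   p("qsar_train.csv"))
  readr::write_csv(gen_qsar_table(n = cfg$qsar_test$n,
                                  noise_sd = cfg$qsar_test$noise_sd,
                                  seed = cfg$qsar_test$seed),
                   p("qsar_test.csv"))
  jsonlite::write_json(cfg, p("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(
    titration = p("titration.csv"), thermogram = p("thermogram.csv"),
    molar_ratio_11 = p("molar_ratio_11.csv"),
    molar_ratio_12 = p("molar_ratio_12.csv"),
    qsar_train = p("qsar_train.csv"), qsar_test = p("qsar_test.csv"),
    manifest = p("manifest.json")
  ))
}
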