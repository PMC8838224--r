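# Delimited-text readers and writers for the tables each stage consumes.
# Scalar metadata (a0, wavelengths, heating rate) travels in leading
# `# key: value` comment lines so one file is self-contained.

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) trimws(m[3]) else v
    }
  }
  meta
}

#' Read a compound table
#'
#' Comma-separated with header `id, formula, role, mass` (the `mass` column,
#' if present, is treated as the user-supplied nominal molar mass).
#'
#' @param path File path.
#' @return A tibble with columns `id`, `formula`, `role`, `nominal_mass`.
#' @export
read_compound_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  names(d) <- tolower(names(d))
  if ("mass" %in% names(d) && !"nominal_mass" %in% names(d)) {
    d <- dplyr::rename(d, nominal_mass = "mass")
  }
  d
}

#' Read an orbital-energy table
#'
#' Comma-separated with columns `id`, `e_homo_eV`, `e_lumo_eV` (the `_eV`
#' suffix is optional); any additional numeric columns (printed descriptor
#' values) are kept for [descriptor_consistency()].
#'
#' @param path File path.
#' @return A tibble with at least `id`, `e_homo`, `e_lumo`.
#' @export
read_orbital_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  names(d) <- sub("_ev$", "", tolower(names(d)))
  d
}

#' Read / write an absorption titration
#'
#' Data columns `dna_M, absorbance`; metadata (`a0`, `lambda_free`,
#' `lambda_bound`) in leading `# key: value` lines, restored as attributes.
#'
#' @param path File path.
#' @return A tibble with `dna_M`, `absorbance` and metadata attributes.
#' @export
read_titration <- function(path) {
  meta <- read_meta(path)
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  for (k in c("a0", "lambda_free", "lambda_bound", "true_k", "epsilon_ratio")) {
    if (!is.null(meta[[k]])) attr(d, k) <- meta[[k]]
  }
  d
}

#' @rdname read_titration
#' @param data Titration tibble (e.g. from [gen_titration()]).
#' @export
write_titration <- function(data, path) {
  keys <- c("a0", "lambda_free", "lambda_bound", "true_k", "epsilon_ratio")
  hdr <- character(0)
  for (k in keys) {
    v <- attr(data, k)
    if (!is.null(v)) hdr <- c(hdr, sprintf("# %s: %.15g", k, v))
  }
  writeLines(c(hdr, readr::format_csv(data)), path)
  invisible(path)
}

#' Read / write a thermogram
#'
#' Data columns `temperature_C` (or `temperature_K`) and `mass_percent`;
#' Celsius input is converted to kelvin. The heating rate travels as a
#' `# beta: <K/min>` header line, restored as the `beta` attribute.
#'
#' @param path File path.
#' @return A tibble with `temperature` (K) and `mass_percent`.
#' @export
read_thermogram <- function(path) {
  meta <- read_meta(path)
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  names(d) <- tolower(names(d))
  if ("temperature_c" %in% names(d)) {
    d$temperature <- d$temperature_c + 273.15
    d$temperature_c <- NULL
  } else if ("temperature_k" %in% names(d)) {
    d <- dplyr::rename(d, temperature = "temperature_k")
  }
  if (!all(c("temperature", "mass_percent") %in% names(d))) {
    stop_input("Thermogram needs `temperature_C` (or `_K`) and `mass_percent`.",
               "bad_thermogram")
  }
  if (!is.null(meta$beta)) attr(d, "beta") <- meta$beta
  d[c("temperature", "mass_percent")]
}

#' @rdname read_thermogram
#' @param data Thermogram tibble (temperature in K; e.g. from
#'   [gen_thermogram()]).
#' @export
write_thermogram <- function(data, path) {
  hdr <- character(0)
  if (!is.null(attr(data, "beta"))) {
    hdr <- sprintf("# beta: %.15g", attr(data, "beta"))
  }
  out <- tibble::tibble(temperature_K = data$temperature,
                        mass_percent = data$mass_percent)
  writeLines(c(hdr, readr::format_csv(out)), path)
  invisible(path)
}

#' Read a molar-ratio series
#'
#' Comma-separated with columns `mole_fraction_metal, absorbance`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_molar_ratio <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  names(d) <- tolower(names(d))
  d
}

#' Read a descriptor/activity table
#'
#' Comma-separated with header `compound_id, ASA_P, ASA_H, h_pkp, dipole,
#' IC50`; header spellings are normalized case-insensitively and `h_pkb` is
#' accepted for `h_pkp`.
#'
#' @param path File path.
#' @return A tibble with standardized lower-case names.
#' @export
read_descriptor_table <- function(path) {
  standardize_qsar_names(readr::read_csv(path, comment = "#",
                                         show_col_types = FALSE))
}
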