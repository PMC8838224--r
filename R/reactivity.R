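# Conceptual-DFT global reactivity descriptors from frontier-orbital
# energies, and the empirical correlation between the V=O stretching
# frequency and the V=O bond length.

#' Global reactivity descriptors from frontier orbital energies
#'
#' Computes the conceptual-DFT global descriptors from HOMO/LUMO energies
#' (eV): energy gap `delta_e = E_LUMO - E_HOMO`, absolute electronegativity
#' `chi = -(E_HOMO + E_LUMO)/2`, absolute hardness `eta = delta_e/2`,
#' chemical potential `mu = -chi`, global softness `softness_s = 1/(2 eta)`
#' (eV^-1), global electrophilicity `omega = mu^2/(2 eta)` (the Parr
#' electrophilicity index), and the maximum electronic charge the species can
#' accept, `dn_max = chi/eta`.
#'
#' @param data A data frame with one row per species containing the orbital
#'   energy columns; all other columns are carried through.
#' @param e_homo,e_lumo Column names (unquoted) holding the HOMO and LUMO
#'   energies in eV.
#' @return The input tibble with columns `delta_e`, `chi`, `eta`, `mu`,
#'   `softness_s`, `omega`, `dn_max` appended (full precision; round to two
#'   decimals for table-style reporting).
#' @examples
#' reactivity_descriptors(tibble::tibble(id = "CBZ", e_homo = -5.55, e_lumo = -1.00))
#' @export
reactivity_descriptors <- function(data, e_homo = e_homo, e_lumo = e_lumo) {
  data <- tibble::as_tibble(data)
  eh <- dplyr::pull(data, {{ e_homo }})
  el <- dplyr::pull(data, {{ e_lumo }})
  if (any(!is.finite(eh)) || any(!is.finite(el))) {
    stop_input("Orbital energies must be finite.", "bad_orbitals")
  }
  if (any(eh >= el)) {
    bad <- which(eh >= el)
    stop_input(sprintf(
      "Degenerate or inverted frontier gap (E_HOMO >= E_LUMO) in row(s) %s; hardness would be non-positive.",
      paste(bad, collapse = ", ")), "degenerate_gap")
  }
  dplyr::mutate(data,
    delta_e    = el - eh,
    chi        = -(eh + el) / 2,
    eta        = (el - eh) / 2,
    mu         = -.data$chi,
    softness_s = 1 / (2 * .data$eta),
    omega      = .data$mu^2 / (2 * .data$eta),
    dn_max     = .data$chi / .data$eta
  )
}

#' Consistency report for a published descriptor table
#'
#' Recomputes every global reactivity descriptor from the HOMO/LUMO columns
#' and compares against the printed descriptor columns supplied alongside
#' them, flagging cells that disagree beyond `tolerance`. Published tables of
#' this kind are not always internally consistent; this report makes the
#' deviations explicit instead of silently reproducing or correcting them.
#'
#' If both printed `chi` and `eta` columns are present, an additional
#' `dn_max_printed_pair` row per species checks the printed `dn_max` against
#' the quotient of the *printed* chi and eta (which can be consistent even
#' when chi itself is not reproducible from the orbitals).
#'
#' @param data A data frame with `e_homo` and `e_lumo` columns plus any of
#'   `delta_e`, `chi`, `eta`, `mu`, `softness_s`, `omega`, `dn_max` holding
#'   printed values, and an `id` column.
#' @param tolerance Absolute deviation (eV or unitless) below which a printed
#'   cell counts as consistent. The default 0.0105 accepts half-unit rounding
#'   of two-decimal tables while rejecting genuine disagreement.
#' @return A long tibble with columns `id`, `quantity`, `printed`,
#'   `computed`, `deviation`, `consistent`.
#' @export
descriptor_consistency <- function(data, tolerance = 0.0105) {
  data <- tibble::as_tibble(data)
  if (!all(c("e_homo", "e_lumo") %in% names(data))) {
    stop_input("`data` needs `e_homo` and `e_lumo` columns.", "bad_orbitals")
  }
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  comp <- reactivity_descriptors(data[c("id", "e_homo", "e_lumo")])
  quantities <- c("delta_e", "chi", "eta", "mu", "softness_s", "omega", "dn_max")
  rows <- list()
  for (q in intersect(quantities, names(data))) {
    rows[[q]] <- tibble::tibble(
      id = data$id, quantity = q,
      printed = as.numeric(data[[q]]),
      computed = comp[[q]]
    )
  }
  # Printed tables of this family often carry extra softness-like columns
  # (sigma, S) whose definitions conflict; compare each against the stated
  # S = 1/(2 eta) so disagreement is flagged explicitly.
  for (alias in intersect(c("sigma", "sigma1", "sigma2", "s"), names(data))) {
    rows[[paste0(alias, "_sft")]] <- tibble::tibble(
      id = data$id, quantity = paste0(alias, "_as_softness"),
      printed = as.numeric(data[[alias]]),
      computed = comp$softness_s
    )
  }
  if (all(c("chi", "eta", "dn_max") %in% names(data))) {
    rows[["dn_pair"]] <- tibble::tibble(
      id = data$id, quantity = "dn_max_printed_pair",
      printed = as.numeric(data$dn_max),
      computed = as.numeric(data$chi) / as.numeric(data$eta)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$deviation <- out$printed - out$computed
  out$consistent <- !is.na(out$deviation) & abs(out$deviation) <= tolerance
  out
}

#' V=O bond length from stretching frequency
#'
#' Inverts the empirical exponential correlation `nu = 21349 exp(-1.9176 R)`
#' between the V=O stretching frequency (cm^-1) and the V=O bond length
#' (angstrom): `R = ln(21349 / nu) / 1.9176`. Stretching frequency and bond
#' length are inversely related, so IR data alone locate the bond length.
#'
#' @param nu Stretching frequency or vector thereof, cm^-1; must lie in
#'   (0, 21349) for a positive length.
#' @return Bond length(s) in angstrom (full precision; report to 3 decimals).
#' @examples
#' bond_length_from_frequency(980)  # 1.607
#' @export
bond_length_from_frequency <- function(nu) {
  if (any(!is.finite(nu)) || any(nu <= 0) || any(nu >= .vo_corr$nu0)) {
    stop_input(sprintf(
      "Frequency must lie strictly between 0 and %d cm^-1.", .vo_corr$nu0),
      "frequency_out_of_range")
  }
  log(.vo_corr$nu0 / nu) / .vo_corr$b
}

#' V=O stretching frequency from bond length
#'
#' Forward form of the empirical correlation:
#' `nu = 21349 exp(-1.9176 R)`. Round-trips with
#' [bond_length_from_frequency()].
#'
#' @param r Bond length(s), angstrom; must be positive.
#' @return Frequency in cm^-1.
#' @examples
#' frequency_from_bond_length(1.607)  # ~980
#' @export
frequency_from_bond_length <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop_input("Bond length must be positive.", "length_out_of_range")
  }
  .vo_corr$nu0 * exp(-.vo_corr$b * r)
}

#' Tabulate V=O bond lengths from a frequency table
#'
#' Data-frame-first wrapper around [bond_length_from_frequency()]: appends a
#' `length` column (angstrom) computed from the stretching-frequency column.
#'
#' @param data A data frame with one row per complex.
#' @param frequency Unquoted column holding nu(V=O) in cm^-1.
#' @return The input tibble with a `length` column appended.
#' @export
vo_bond_table <- function(data, frequency = frequency) {
  data <- tibble::as_tibble(data)
  nu <- dplyr::pull(data, {{ frequency }})
  dplyr::mutate(data, length = bond_length_from_frequency(nu))
}
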