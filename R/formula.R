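# Molecular-formula parsing and mass arithmetic. These underpin the
# elemental-analysis checks and the assignment of thermogravimetric mass
# losses to departing fragments (hydrate water, ligand fragments, the VO2
# residue).

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings (`"C42H52Cl2N4O9V"`), parenthesised groups
#' (`"VO(SO4)2"`), and hydrate/adduct notation: an optional leading integer is
#' a multiplicity (`"2H2O"` means two water molecules), and segments may be
#' joined by a middle dot, an ASCII dot or whitespace
#' (`"VOSO4 . 5H2O"`). Typographic underscores and Unicode subscript digits
#' are stripped before parsing, so formulas copied out of typeset tables
#' (`"C_42_H_52_Cl_2_N_4_O_9_V"`) parse unchanged.
#'
#' A single-segment formula keeps its leading multiplicity (so `"8H2O"` has
#' unit composition H2O and multiplicity 8); multi-segment formulas are
#' expanded and merged into a single composition with multiplicity 1.
#'
#' @param text A formula string, or an existing `mol_formula` object
#'   (returned unchanged).
#' @return A `mol_formula` object: a named integer vector of element counts
#'   plus a `multiplicity` attribute.
#' @examples
#' parse_formula("C42H52Cl2N4O9V")
#' parse_formula("2H2O")
#' parse_formula("VO(SO4)(C7H10N2O2S) 8H2O")
#' @export
parse_formula <- function(text) {
  if (inherits(text, "mol_formula")) return(text)
  if (!is.character(text) || length(text) != 1L) {
    stop_input("`text` must be a single formula string.", "formula_parse_error")
  }
  raw <- text
  # strip typographic noise: underscores, unicode subscripts, brackets kept
  txt <- gsub("_", "", text)
  subs <- c("₀","₁","₂","₃","₄",
            "₅","₆","₇","₈","₉")
  for (i in seq_along(subs)) txt <- gsub(subs[i], as.character(i - 1L), txt)
  txt <- gsub("·", " ", txt)           # middle dot
  txt <- gsub("\\.", " ", txt)              # ASCII dot as adduct separator
  txt <- trimws(txt)
  if (!nzchar(txt)) {
    stop_input("Empty formula string.", "formula_parse_error")
  }
  segments <- strsplit(txt, "\\s+")[[1]]
  parsed <- lapply(segments, parse_segment, raw = raw)
  if (length(parsed) == 1L) {
    new_mol_formula(parsed[[1]]$counts, parsed[[1]]$multiplicity)
  } else {
    merged <- integer(0)
    for (p in parsed) {
      ex <- p$counts * p$multiplicity
      for (el in names(ex)) {
        merged[el] <- if (el %in% names(merged)) merged[[el]] + ex[[el]] else ex[[el]]
      }
    }
    new_mol_formula(merged, 1L)
  }
}

new_mol_formula <- function(counts, multiplicity = 1L) {
  counts <- as.integer(counts[order(hill_rank(names(counts)), names(counts))]) |>
    setNames(names(counts)[order(hill_rank(names(counts)), names(counts))])
  structure(counts, multiplicity = as.integer(multiplicity),
            class = "mol_formula")
}

# Hill convention: C first, then H, then alphabetical.
hill_rank <- function(els) {
  ifelse(els == "C", 0L, ifelse(els == "H", 1L, 2L))
}

parse_segment <- function(seg, raw) {
  mult <- 1L
  m <- regmatches(seg, regexpr("^[0-9]+", seg))
  if (length(m) == 1L && nzchar(m)) {
    mult <- as.integer(m)
    if (mult < 1L) {
      stop_input(sprintf("Zero multiplicity in '%s'.", raw), "formula_parse_error")
    }
    seg <- substring(seg, nchar(m) + 1L)
  }
  counts <- parse_group(seg, raw)
  if (length(counts) == 0L) {
    stop_input(sprintf("No elements found in '%s'.", raw), "formula_parse_error")
  }
  list(counts = counts, multiplicity = mult)
}

# Recursive-descent parse of one segment; returns a named integer vector.
parse_group <- function(s, raw) {
  counts <- integer(0)
  add <- function(el, n) {
    counts[el] <<- if (el %in% names(counts)) counts[[el]] + n else n
  }
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substring(s, i, i)
    if (ch %in% c("(", "[")) {
      close <- if (ch == "(") ")" else "]"
      depth <- 1L; j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) stop_input(sprintf("Unbalanced '%s' in '%s'.", ch, raw),
                              "formula_parse_error")
        cj <- substring(s, j, j)
        if (cj == ch) depth <- depth + 1L
        if (cj == close) depth <- depth - 1L
      }
      inner <- parse_group(substring(s, i + 1L, j - 1L), raw)
      rest <- substring(s, j + 1L)
      num <- regmatches(rest, regexpr("^[0-9]+", rest))
      k <- if (length(num) == 1L && nzchar(num)) as.integer(num) else 1L
      if (k < 1L) stop_input(sprintf("Zero group count in '%s'.", raw),
                             "formula_parse_error")
      for (el in names(inner)) add(el, inner[[el]] * k)
      i <- j + 1L + if (length(num) == 1L) nchar(num) else 0L
    } else if (grepl("^[A-Z]$", ch)) {
      # longest-match a known element symbol (case-sensitive), else report
      # the full candidate token
      two <- substring(s, i, min(i + 1L, n))
      el <- if (nchar(two) == 2L && two %in% names(.atomic_weights)) two
            else if (ch %in% names(.atomic_weights)) ch
            else NA_character_
      if (is.na(el)) {
        tok <- regmatches(substring(s, i), regexpr("^[A-Z][a-z]*", substring(s, i)))
        stop_input(sprintf("Unknown element symbol '%s' in '%s'.", tok, raw),
                   "formula_unknown_element")
      }
      rest <- substring(s, i + nchar(el))
      num <- regmatches(rest, regexpr("^[0-9]+", rest))
      k <- if (length(num) == 1L && nzchar(num)) as.integer(num) else 1L
      if (k < 1L) {
        stop_input(sprintf("Zero count for element '%s' in '%s'.", el, raw),
                   "formula_parse_error")
      }
      add(el, k)
      i <- i + nchar(el) + if (length(num) == 1L) nchar(num) else 0L
    } else {
      stop_input(sprintf("Unexpected character '%s' in '%s'.", ch, raw),
                 "formula_parse_error")
    }
  }
  counts
}

#' @export
format.mol_formula <- function(x, ...) {
  mult <- attr(x, "multiplicity")
  body <- paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
  if (mult > 1L) paste0(mult, body) else body
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format(x), "  (",
      format(round_half_up(molar_mass(x), 2), nsmall = 2), " g/mol)\n", sep = "")
  invisible(x)
}

# Full composition with the multiplicity expanded, as a named integer vector.
expand_counts <- function(f) {
  f <- parse_formula(f)
  setNames(as.integer(unclass(f)) * attr(f, "multiplicity"), names(f))
}

#' Molar mass of a formula
#'
#' Sum of count times standard atomic weight over all elements, times the
#' formula multiplicity. Weights come from the fixed table in
#' [atomic_weights()].
#'
#' @param f A formula string or `mol_formula`.
#' @return Molar mass in g mol^-1 (full precision; round for reporting).
#' @examples
#' molar_mass("VO2")             # 82.94
#' molar_mass("C42H52Cl2N4O9V")  # 878.74
#' @export
molar_mass <- function(f) {
  ex <- expand_counts(f)
  if (length(ex) == 0L) {
    stop_input("Formula has no elements.", "formula_empty")
  }
  sum(.atomic_weights[names(ex)] * ex)
}

#' Percent elemental composition
#'
#' Mass percentage of each element in a formula, as reported in elemental
#' (CHN) analyses. When `elements` is given, only those rows are returned but
#' the denominator is always the full molar mass; a requested element absent
#' from the formula is reported as zero.
#'
#' @param f A formula string or `mol_formula`.
#' @param elements Optional character vector of element symbols to report.
#' @return A tibble with columns `element`, `count`, `mass` (g mol^-1
#'   contribution) and `percent`. Percentages over all elements sum to 100.
#' @examples
#' percent_composition("C42H52Cl2N4O9V", c("C", "H", "N"))
#' @export
percent_composition <- function(f, elements = NULL) {
  ex <- expand_counts(f)
  total <- molar_mass(f)
  out <- tibble::tibble(
    element = names(ex),
    count = unname(ex),
    mass = unname(.atomic_weights[names(ex)] * ex)
  )
  out$percent <- 100 * out$mass / total
  if (!is.null(elements)) {
    missing <- setdiff(elements, out$element)
    out <- out[match(elements, out$element), ]
    out$element <- elements
    out$count[is.na(out$count)] <- 0L
    out$mass[is.na(out$mass)] <- 0
    out$percent[is.na(out$percent)] <- 0
    rownames(out) <- NULL
  }
  tibble::as_tibble(out)
}

#' Mass loss of a fragment relative to a parent formula
#'
#' The percentage of the parent's molar mass carried away by a departing
#' fragment, the quantity against which thermogravimetric step losses are
#' checked. The fragment must be a sub-multiset of the parent composition.
#'
#' @param fragment,parent Formula strings or `mol_formula` objects.
#' @return Mass-loss percentage (full precision).
#' @examples
#' mass_loss_percent("VO2", "C42H52Cl2N4O9V")   # 9.44
#' mass_loss_percent("2H2O", "C42H52Cl2N4O9V")  # 4.10
#' @export
mass_loss_percent <- function(fragment, parent) {
  exf <- expand_counts(fragment)
  exp_ <- expand_counts(parent)
  excess <- names(exf)[!(names(exf) %in% names(exp_)) |
                         exf > exp_[names(exf)]]
  excess <- excess[!is.na(excess)]
  if (length(excess) > 0L) {
    stop_input(sprintf(
      "Fragment is not contained in parent; exceeded element(s): %s.",
      paste(excess, collapse = ", ")), "fragment_not_subset")
  }
  100 * molar_mass(fragment) / molar_mass(parent)
}

#' Enumerate candidate fragments matching a mass-loss percentage
#'
#' Bounded exhaustive enumeration of all sub-multisets of the parent
#' composition (optionally restricted to an element pool) whose mass-loss
#' percentage lies within `tolerance` of `target_percent`. This automates the
#' assignment of thermogram steps to departing fragments.
#'
#' @param parent Formula string or `mol_formula`.
#' @param target_percent Target mass loss, percent of parent mass (0-100).
#' @param tolerance Acceptance half-width in percentage points.
#' @param element_pool Optional character vector restricting which elements
#'   may appear in candidates.
#' @param max_atoms Maximum total atom count of a candidate (bounds the
#'   enumeration).
#' @return A tibble with columns `formula`, `n_atoms`, `mass`, `percent` and
#'   `deviation`, sorted by absolute deviation, then fewer atoms, then
#'   formula string. Empty when nothing matches.
#' @examples
#' suggest_fragments("C42H52Cl2N4O9V", 9.44, tolerance = 0.05,
#'                   element_pool = c("V", "O"), max_atoms = 3)
#' @export
suggest_fragments <- function(parent, target_percent, tolerance = 0.5,
                              element_pool = NULL, max_atoms = 10L) {
  if (!is.numeric(target_percent) || target_percent <= 0 || target_percent > 100) {
    stop_input("`target_percent` must lie in (0, 100].", "bad_target")
  }
  exp_ <- expand_counts(parent)
  if (!is.null(element_pool)) {
    unknown <- setdiff(element_pool, names(exp_))
    exp_ <- exp_[names(exp_) %in% element_pool]
  }
  if (length(exp_) == 0L) {
    return(empty_fragment_tbl())
  }
  caps <- pmin(exp_, max_atoms)
  n_combo <- prod(caps + 1)
  if (n_combo > 2e6) {
    stop_input(paste0(
      "Enumeration too large (", format(n_combo, big.mark = ","),
      " combinations); restrict `element_pool` or lower `max_atoms`."),
      "enumeration_too_large")
  }
  grid <- as.matrix(expand.grid(lapply(caps, function(k) 0:k)))
  natoms <- rowSums(grid)
  keep <- natoms >= 1 & natoms <= max_atoms
  grid <- grid[keep, , drop = FALSE]
  natoms <- natoms[keep]
  w <- .atomic_weights[colnames(grid)]
  mass <- as.numeric(grid %*% w)
  pct <- 100 * mass / molar_mass(parent)
  dev <- pct - target_percent
  hit <- abs(dev) <= tolerance + 1e-12
  if (!any(hit)) return(empty_fragment_tbl())
  grid <- grid[hit, , drop = FALSE]
  fml <- apply(grid, 1L, function(r) {
    r <- r[r > 0]
    format(new_mol_formula(r))
  })
  out <- tibble::tibble(
    formula = fml,
    n_atoms = as.integer(natoms[hit]),
    mass = mass[hit],
    percent = pct[hit],
    deviation = dev[hit]
  )
  out[order(abs(out$deviation), out$n_atoms, out$formula), ]
}

empty_fragment_tbl <- function() {
  tibble::tibble(formula = character(), n_atoms = integer(),
                 mass = double(), percent = double(), deviation = double())
}

#' Recompute masses and compositions for a compound table
#'
#' Takes a table of compounds (one row per compound, with a formula string)
#' and returns the recomputed molar mass and elemental composition, flagging
#' rows whose user-supplied nominal mass deviates from the recomputed value.
#' Deviations are reported, never silently corrected.
#'
#' @param data A data frame with columns `id`, `formula`, and optionally
#'   `role` and `nominal_mass` (a column named `mass` is treated as
#'   `nominal_mass`).
#' @param elements Elements to report percentages for (default C, H, N, the
#'   usual combustion-analysis set).
#' @param flag_tol Absolute mass deviation (g mol^-1) beyond which a nominal
#'   mass is flagged.
#' @return A tibble with recomputed `mass`, one `pct_<element>` column per
#'   requested element, `mass_dev` and logical `flagged`.
#' @examples
#' compound_report(tibble::tibble(id = "VO-CTZ", formula = "C42H52Cl2N4O9V",
#'                                nominal_mass = 878.7))
#' @export
compound_report <- function(data, elements = c("C", "H", "N"), flag_tol = 0.2) {
  data <- tibble::as_tibble(data)
  if (!all(c("id", "formula") %in% names(data))) {
    stop_input("`data` needs columns `id` and `formula`.", "bad_compound_table")
  }
  if (!"nominal_mass" %in% names(data) && "mass" %in% names(data)) {
    data$nominal_mass <- data$mass
  }
  out <- data[intersect(c("id", "formula", "role", "nominal_mass"), names(data))]
  out$mass <- vapply(data$formula, function(f) molar_mass(f), numeric(1),
                     USE.NAMES = FALSE)
  for (el in elements) {
    out[[paste0("pct_", el)]] <- vapply(data$formula, function(f) {
      percent_composition(f, el)$percent
    }, numeric(1), USE.NAMES = FALSE)
  }
  if ("nominal_mass" %in% names(out)) {
    out$mass_dev <- out$mass - out$nominal_mass
    out$flagged <- !is.na(out$mass_dev) & abs(out$mass_dev) > flag_tol
  }
  out
}
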