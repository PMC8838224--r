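# Shared fixtures: the published characterization tables shipped as extdata.

ext <- function(f) system.file("extdata", f, package = "vanchar")

orbital_tbl <- function() read_orbital_table(ext("orbitals.csv"))
vo_bond_tbl <- function() readr::read_csv(ext("vo_bonds.csv"), show_col_types = FALSE)
compound_tbl <- function() read_compound_table(ext("compounds.csv"))

# Independent brute-force fragment enumerator used as the oracle for
# suggest_fragments(): recursive descent over elements, no shared code path.
brute_fragments <- function(parent, target, tol, max_atoms) {
  cnt <- sapply(strsplit(gsub("([A-Z][a-z]?)(\\d*)", "\\1:\\2;", parent), ";")[[1]],
                function(tok) {
                  kv <- strsplit(tok, ":")[[1]]
                  stats::setNames(ifelse(is.na(kv[2]) | kv[2] == "", 1L,
                                         as.integer(kv[2])), kv[1])
                })
  els <- sub(":.*$", "", names(cnt))
  names(cnt) <- els
  w <- with(atomic_weights(), stats::setNames(weight, element))
  pm <- sum(w[els] * cnt)
  out <- list()
  recurse <- function(i, pick) {
    if (i > length(els)) {
      if (sum(pick) == 0 || sum(pick) > max_atoms) return()
      pct <- 100 * sum(w[els] * pick) / pm
      if (abs(pct - target) <= tol + 1e-12) {
        out[[length(out) + 1L]] <<- stats::setNames(pick, els)
      }
      return()
    }
    for (k in 0:cnt[[i]]) recurse(i + 1L, c(pick, k))
  }
  recurse(1L, integer(0))
  out
}
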