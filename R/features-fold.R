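#' Folding energy per nucleotide
#'
#' Normalizes a total minimum free energy by the number of bases folded,
#' giving the secondary-structure score per base used throughout the
#' feature analyses.
#'
#' @param dg_total Total folding free energy (kcal/mol, <= 0).
#' @param n_bases Number of bases in the folded (sub)sequence (> 0).
#' @return `dg_total / n_bases`, vectorized.
#' @export
#' @examples
#' per_base_energy(-30, 100)  # -0.3
per_base_energy <- function(dg_total, n_bases) {
  if (any(n_bases <= 0)) abort("`n_bases` must be positive.")
  if (any(dg_total > 0, na.rm = TRUE)) abort("`dg_total` must be <= 0.")
  dg_total / n_bases
}

#' Minimum folding free energy of an RNA sequence
#'
#' The default `"stack"` backend is the package's documented
#' dynamic-programming proxy: a Nussinov-style search over nested pairings
#' scoring GC/AU/GU pairs with fixed energies plus a nearest-neighbor
#' stacking bonus (see `src/fold.cpp`). It preserves the ordering "more
#' pairable and more stacked is more stable" but makes no claim of
#' thermodynamic parity with mfold-class folders. The `"vienna"` backend
#' shells out to ViennaRNA's `RNAfold` when it is installed, for users who
#' need thermodynamic energies.
#'
#' @param seq RNA sequence (A/C/G/U; case-insensitive). Vectorized.
#' @param backend `"stack"` (built-in proxy) or `"vienna"` (`RNAfold`).
#' @return Numeric free energy value(s), <= 0 (kcal/mol for `"vienna"`;
#'   proxy units for `"stack"`).
#' @export
#' @examples
#' fold_energy("AAAAAAAA")      # 0: no pairs
#' fold_energy("GGGGAAAACCCC")  # < 0
fold_energy <- function(seq, backend = c("stack", "vienna")) {
  backend <- match.arg(backend)
  seq <- toupper(seq)
  bad <- gregexpr("[^ACGU]", seq)
  for (i in seq_along(seq)) {
    if (bad[[i]][1] != -1) {
      abort(sprintf("Sequence %d contains non-ACGU character(s) at position(s) %s.",
                    i, paste(bad[[i]], collapse = ", ")))
    }
  }
  if (backend == "stack") {
    return(vapply(seq, fold_energy_cpp, numeric(1), USE.NAMES = FALSE))
  }
  rnafold <- Sys.which("RNAfold")
  if (rnafold == "") abort("`RNAfold` not found on PATH; use backend = \"stack\".")
  vapply(seq, function(s) {
    out <- system2(rnafold, args = "--noPS", input = s, stdout = TRUE)
    mfe_line <- out[length(out)]
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", mfe_line))
  }, numeric(1), USE.NAMES = FALSE)
}
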