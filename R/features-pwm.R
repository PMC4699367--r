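#' Build a position weight matrix from aligned site sequences
#'
#' Column-wise base frequencies with a pseudocount, over the RNA alphabet.
#'
#' @param seqs Character vector of equal-length aligned sites (A/C/G/U).
#' @param pseudocount Added to every base count per position (default 0.5).
#' @return A 4 x width numeric matrix of frequencies (rows A, C, G, U;
#'   columns sum to 1), of class `tu_pwm`.
#' @export
build_pwm <- function(seqs, pseudocount = 0.5) {
  seqs <- toupper(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1) abort("All site sequences must have the same length.")
  bases <- c("A", "C", "G", "U")
  mat <- matrix(pseudocount, 4, w, dimnames = list(bases, NULL))
  chars <- do.call(rbind, strsplit(seqs, ""))
  if (!all(chars %in% bases)) abort("Site sequences must use the RNA alphabet (ACGU).")
  for (p in seq_len(w)) {
    tab <- table(factor(chars[, p], levels = bases))
    mat[, p] <- mat[, p] + as.numeric(tab)
  }
  mat <- sweep(mat, 2, colSums(mat), "/")
  class(mat) <- c("tu_pwm", class(mat))
  mat
}

#' Information-content score of a sequence window against a PWM
#'
#' Sums, over window positions, the log2 ratio of the PWM frequency of the
#' observed base to a uniform 0.25 background — the sequence-logo bit score
#' of the window. A uniform PWM scores 0 everywhere; the consensus sequence
#' attains the maximum.
#'
#' @param seq_window Sequence of exactly the PWM width (A/C/G/U).
#' @param pwm Matrix from [build_pwm()].
#' @param background Background base probability (default uniform 0.25).
#' @return Score in bits.
#' @export
site_score <- function(seq_window, pwm, background = 0.25) {
  seq_window <- toupper(seq_window)
  w <- ncol(pwm)
  if (nchar(seq_window) != w) {
    abort(sprintf("Window length (%d) must equal the PWM width (%d).",
                  nchar(seq_window), w))
  }
  chars <- strsplit(seq_window, "")[[1]]
  if (!all(chars %in% rownames(pwm))) {
    abort("Window must use the RNA alphabet (ACGU).")
  }
  sum(log2(pwm[cbind(match(chars, rownames(pwm)), seq_len(w))] / background))
}
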