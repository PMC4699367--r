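#' Simulate yeast-like intron sequences with annotated splice signals
#'
#' Builds RNA-alphabet intron sequences carrying the three core splicing
#' signals at known positions: the 5' splice-site consensus `GUAUGU` at the
#' intron start, the branch-point consensus `UACUAAC` (branch adenosine =
#' position 6 of the motif) ending 20-40 nt upstream of the 3' end, and a
#' `YAG` 3' splice site at the very end. All remaining positions are drawn
#' i.i.d. with `P(A) = au_bias * a_share`, `P(U) = au_bias * (1 - a_share)`
#' and `P(G) = P(C) = (1 - au_bias)/2`, so the expected A+U fraction of the
#' non-motif background equals `au_bias`.
#'
#' @param n Number of introns.
#' @param au_bias Background A+U fraction, in (0, 1).
#' @param a_share Share of the A+U mass given to adenosine (default 0.5;
#'   varying it at fixed `au_bias` emulates the A-rich vs U-rich trade-off
#'   of natural introns).
#' @param length Intron length in nt (single value or vector of length `n`);
#'   must be at least 46 so the motifs and spacers fit.
#' @param seed Integer seed.
#' @return Tibble with `intron_id`, `seq` (RNA alphabet), `length`,
#'   `bp_pos` (1-based position of the branch-point adenosine within the
#'   intron), `ss5_start = 1`, `ss3_end = length`.
#' @export
simulate_intron_sequences <- function(n, au_bias, a_share = 0.5,
                                      length = 150L, seed = 1L) {
  assert_scalar_number(n, "n", lower = 1)
  assert_scalar_number(au_bias, "au_bias", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  len <- rep_len(as.integer(length), n)
  ss5 <- "GUAUGU"
  bp <- "UACUAAC"
  min_len <- nchar(ss5) + nchar(bp) + 3L + 30L  # motifs + 3'ss + minimal spacers
  if (any(len < min_len)) {
    abort(sprintf("Intron length must be at least %d nt to fit the splice signals.", min_len))
  }
  assert_scalar_number(a_share, "a_share", lower = 0, upper = 1)
  probs <- c(A = au_bias * a_share, U = au_bias * (1 - a_share),
             G = (1 - au_bias) / 2, C = (1 - au_bias) / 2)
  with_seed(derive_seed(seed, 303L), {
    rows <- lapply(seq_len(n), function(i) {
      L <- len[i]
      base <- sample(names(probs), L, replace = TRUE, prob = probs)
      base[1:6] <- strsplit(ss5, "")[[1]]
      # BP motif ends 20-40 nt upstream of the 3' end
      bp_end <- L - 3L - sample(20:40, 1)
      bp_start <- bp_end - 6L
      base[bp_start:bp_end] <- strsplit(bp, "")[[1]]
      base[L - 2L] <- sample(c("U", "C"), 1)  # Y of YAG
      base[(L - 1L):L] <- c("A", "G")
      tibble(
        intron_id = sprintf("I%04d", i),
        seq = paste(base, collapse = ""),
        length = L,
        bp_pos = bp_start + 5L,  # the branch adenosine (6th motif base)
        ss5_start = 1L, ss3_end = L
      )
    })
    bind_rows(rows)
  })
}

#' Simulate a labeled transcript feature table with tunable class separation
#'
#' Generates the two structural features that discriminate fast- from
#' slow-degrading non-coding transcripts — folding energy per nucleotide and
#' transcript length — for a balanced two-class sample. `class_separation`
#' is the per-feature shift, in within-class standard deviations, between
#' the `fast` and `slow` decay classes: 0 gives indistinguishable classes,
#' large values perfectly separable ones, and the default 0.52 places a
#' Gaussian naive Bayes classifier on the two features in the
#' 0.65-0.75 cross-validated AUC regime. The slow class is shifted toward
#' more negative (more structured) energies and greater lengths.
#'
#' @param n Total number of transcripts (split evenly between classes).
#' @param class_separation Per-feature shift in SD units (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `transcript_id`, `decay_class` (`fast`/`slow`),
#'   `dg_per_nt` (kcal/mol/nt, <= 0) and `length_nt`.
#' @export
simulate_feature_table <- function(n = 400L, class_separation = 0.52, seed = 1L) {
  assert_scalar_number(n, "n", lower = 2)
  assert_scalar_number(class_separation, "class_separation", lower = 0)
  n_fast <- ceiling(n / 2)
  n_slow <- n - n_fast
  d <- class_separation
  with_seed(derive_seed(seed, 404L), {
    tibble(
      transcript_id = sprintf("T%04d", seq_len(n)),
      decay_class = rep(c("fast", "slow"), c(n_fast, n_slow)),
      dg_per_nt = pmin(0, c(rnorm(n_fast, -0.25, 0.05),
                            rnorm(n_slow, -0.25 - d * 0.05, 0.05))),
      length_nt = pmax(50, round(c(
        exp(rnorm(n_fast, 5.85, 0.35)),
        exp(rnorm(n_slow, 5.85 + d * 0.35, 0.35))
      )))
    )[sample(n), ]
  })
}
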