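#' Transcript classes known to the simulator
#'
#' The class labels mirror the transcript categories of a yeast 4tU-seq
#' experiment: intron-containing ribosomal-protein (RP) and non-RP mRNAs,
#' the three long non-coding classes (CUT, SUT, XUT), snoRNAs, and a
#' catch-all "other" for intronless mRNAs.
#'
#' @export
transcript_classes <- function() {
  c("RP-intronic", "non-RP-intronic", "CUT", "SUT", "XUT", "snoRNA", "other")
}

default_length_params <- function() {
  list(
    # Intron-containing genes: lognormal lengths for exon1 / intron / exon2.
    # Yeast RP introns are characteristically long (~400 nt) with a short
    # first exon; non-RP introns are shorter.
    `RP-intronic`     = list(exon1 = c(3.7, 0.3), intron = c(6.0, 0.25), exon2 = c(6.2, 0.4)),
    `non-RP-intronic` = list(exon1 = c(4.0, 0.4), intron = c(5.0, 0.40), exon2 = c(6.3, 0.5)),
    # Intronless classes: a single lognormal transcript length. SUTs are
    # longer than CUTs, XUTs longer still; snoRNAs are short.
    CUT    = list(length = c(5.85, 0.35)),
    SUT    = list(length = c(6.40, 0.40)),
    XUT    = list(length = c(6.70, 0.40)),
    snoRNA = list(length = c(4.80, 0.25)),
    other  = list(length = c(7.00, 0.45))
  )
}

#' Simulate a transcript annotation with known structure
#'
#' Generates `n_genes` non-overlapping transcript models on a single synthetic
#' chromosome. Intron-containing classes get exactly one intron (two exons);
#' all other classes are single-exon. Lengths are drawn from per-class
#' lognormal distributions; strands are assigned at random. Coordinates are
#' 0-based half-open genomic intervals; the `exon1` fields always refer to the
#' first exon in transcription order.
#'
#' @param n_genes Number of genes to simulate (>= 1).
#' @param class_mix Named numeric vector of class proportions summing to 1.
#'   Names must be among [transcript_classes()].
#' @param length_params Optional per-class length parameters; a named list
#'   whose entries are lists with elements `exon1`, `intron`, `exon2` (for the
#'   intronic classes) or `length` (for intronless classes), each a
#'   `c(meanlog, sdlog)` pair. Missing classes fall back to the defaults.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param gap Intergenic gap in nucleotides between consecutive genes.
#'
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `class`, genomic `tx_start`/`tx_end`, `exon1_start`/`exon1_end`,
#'   `intron_start`/`intron_end`, `exon2_start`/`exon2_end` (NA for
#'   single-exon genes), and the transcription-order lengths `exon1_len`,
#'   `intron_len`, `exon2_len`, `tx_len`.
#' @export
#' @examples
#' simulate_annotation(5, c(`RP-intronic` = 0.5, CUT = 0.5), seed = 1)
simulate_annotation <- function(n_genes, class_mix, length_params = NULL,
                                seed = 1L, gap = 200L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  if (is.null(names(class_mix)) || any(names(class_mix) == "")) {
    abort("`class_mix` must be a fully named numeric vector.")
  }
  unknown <- setdiff(names(class_mix), transcript_classes())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown transcript class(es): %s.", paste(unknown, collapse = ", ")))
  }
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8) {
    abort("`class_mix` proportions must be non-negative and sum to 1.")
  }
  lp <- utils::modifyList(default_length_params(), length_params %||% list())

  with_seed(derive_seed(seed, 101L), {
    classes <- sample(names(class_mix), n_genes, replace = TRUE, prob = class_mix)
    rows <- vector("list", n_genes)
    cursor <- 1000L
    for (i in seq_len(n_genes)) {
      cls <- classes[i]
      p <- lp[[cls]]
      intronic <- !is.null(p$intron)
      if (intronic) {
        e1 <- max(30L, round(stats::rlnorm(1, p$exon1[1], p$exon1[2])))
        in_len <- max(60L, round(stats::rlnorm(1, p$intron[1], p$intron[2])))
        e2 <- max(60L, round(stats::rlnorm(1, p$exon2[1], p$exon2[2])))
      } else {
        e1 <- max(80L, round(stats::rlnorm(1, p$length[1], p$length[2])))
        in_len <- 0L
        e2 <- 0L
      }
      tx_len <- e1 + in_len + e2
      strand <- sample(c("+", "-"), 1)
      tx_start <- cursor
      tx_end <- tx_start + tx_len
      cursor <- tx_end + gap
      # genomic placement of the transcription-order parts
      if (intronic) {
        if (strand == "+") {
          coords <- c(tx_start, tx_start + e1, tx_start + e1 + in_len, tx_end)
          exon1 <- c(coords[1], coords[2]); intr <- c(coords[2], coords[3]); exon2 <- c(coords[3], coords[4])
        } else {
          exon1 <- c(tx_end - e1, tx_end)
          intr <- c(tx_end - e1 - in_len, tx_end - e1)
          exon2 <- c(tx_start, tx_start + e2)
        }
      } else {
        exon1 <- c(tx_start, tx_end); intr <- c(NA_integer_, NA_integer_); exon2 <- c(NA_integer_, NA_integer_)
      }
      rows[[i]] <- tibble(
        gene_id = sprintf("G%04d", i), chrom = "chrS", strand = strand, class = cls,
        tx_start = tx_start, tx_end = tx_end,
        exon1_start = exon1[1], exon1_end = exon1[2],
        intron_start = intr[1], intron_end = intr[2],
        exon2_start = exon2[1], exon2_end = exon2[2],
        exon1_len = e1, intron_len = in_len, exon2_len = e2, tx_len = tx_len
      )
    }
    bind_rows(rows)
  })
}

has_intron <- function(models) models$intron_len > 0
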