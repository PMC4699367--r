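#' Overlapping k-mer frequencies of a sequence
#'
#' Counts the overlapping k-mers of `seq` and normalizes by the number of
#' windows (`length - k + 1`), so frequencies sum to 1.
#'
#' @param seq RNA sequence (A/C/G/U).
#' @param k Word size (>= 1; `length(seq)` must be >= k).
#' @return Named numeric vector over all 4^k k-mers.
#' @export
#' @examples
#' kmer_frequencies("AUAU", 2)  # AU = 2/3, UA = 1/3
kmer_frequencies <- function(seq, k) {
  seq <- toupper(seq)
  if (nchar(seq) < k) abort("Sequence shorter than `k`.")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::RNAString(seq), width = k)
  counts / (nchar(seq) - k + 1)
}

#' Extract the unspliced transcript sequence of a gene model from a genome
#'
#' Minus-strand genes are reverse-complemented so the returned sequence runs
#' 5' to 3' in transcription orientation; DNA is transcribed to the RNA
#' alphabet.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` keyed
#'   by chromosome.
#' @param model One-row annotation tibble.
#' @return RNA sequence string of length `tx_len`.
#' @export
transcript_sequence <- function(genome, model) {
  chrom_seq <- if (is.character(genome)) genome[[model$chrom]] else
    as.character(genome[[model$chrom]])
  if (is.null(chrom_seq)) abort(sprintf("Chromosome %s absent from genome.", model$chrom))
  s <- substr(chrom_seq, model$tx_start + 1L, model$tx_end)
  d <- Biostrings::DNAString(gsub("U", "T", toupper(s)))
  if (model$strand == "-") d <- Biostrings::reverseComplement(d)
  as.character(Biostrings::RNAString(d))
}

window_around <- function(seq, center, half_width) {
  lo <- max(1L, center - half_width)
  hi <- min(nchar(seq), center + half_width)
  list(seq = substr(seq, lo, hi),
       truncated = lo > center - half_width || hi < center + half_width)
}

# terminal windows: the first/last (2 * half_width + 1) nt of the transcript
# (a +/- window around position 1 has no upstream context within the
# transcript, so the terminal windows are anchored inside it)
window_terminal <- function(seq, half_width, end = FALSE) {
  w <- 2L * half_width + 1L
  n <- nchar(seq)
  s <- if (end) substr(seq, max(1L, n - w + 1L), n) else substr(seq, 1L, min(w, n))
  list(seq = s, truncated = n < w)
}

#' Extract intron and transcript features for kinetic association analyses
#'
#' Populates, per intron-containing gene, the features associated with
#' splicing and decay kinetics: folding energy per nucleotide of the whole
#' intron and of the 5'ss-to-branch-point region (intron positions
#' 1..`bp_pos`, with `bp_pos` the 1-based position of the branch adenosine
#' within the intron), folding energies of the terminal `2*window + 1` nt
#' windows at the transcript start and end and of the +/-`window` nt window
#' around the 3' splice site, PWM bit scores
#' of the 5'ss (first 6 intron nt), branch point (7-mer ending one base
#' after the branch A) and 3'ss (last 3 intron nt) — the PWMs are built from
#' the supplied annotation set itself — region lengths, and overlapping
#' k-mer frequencies of the intron (columns `kmer_<word>`).
#'
#' @param models Annotation tibble (intronless rows are dropped).
#' @param sequences Named character vector of unspliced transcript sequences
#'   in transcription orientation (RNA or DNA alphabet), names = `gene_id`;
#'   see [transcript_sequence()].
#' @param bp_positions Tibble `gene_id`, `bp_pos` (1-based branch-A offset
#'   within the intron), or a named numeric vector.
#' @param window Half-width of the start/stop/3'ss windows (default 15 nt).
#' @param kmer_k Word sizes for intron k-mer frequencies (default 1:2;
#'   extendable to 3).
#' @param fold_backend Backend for [fold_energy()].
#' @param energies Optional precomputed total folding energies: a tibble
#'   with `gene_id` and any of `dg_intron`, `dg_5ss_bp` (total kcal/mol for
#'   those regions; normalized per nucleotide here); supplied values
#'   override the folding backend.
#' @return A feature tibble, one row per gene, with a logical
#'   `window_truncated` flag for transcripts shorter than a full window.
#' @export
extract_intron_features <- function(models, sequences, bp_positions,
                                    window = 15L, kmer_k = 1:2,
                                    fold_backend = "stack", energies = NULL) {
  models <- models[models$intron_len > 0, , drop = FALSE]
  if (nrow(models) == 0) abort("No intron-containing genes in `models`.")
  if (!is.null(dim(bp_positions)) || is.data.frame(bp_positions)) {
    bp <- setNames(bp_positions$bp_pos, bp_positions$gene_id)
  } else {
    bp <- bp_positions
  }
  seqs <- toupper(chartr("T", "U", unlist(sequences)))
  missing_seq <- setdiff(models$gene_id, names(seqs))
  if (length(missing_seq) > 0) {
    abort(sprintf("Missing sequence(s) for: %s.", paste(missing_seq, collapse = ", ")))
  }

  intron_seq <- character(nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    intron_seq[i] <- substr(seqs[[m$gene_id]], m$exon1_len + 1L,
                            m$exon1_len + m$intron_len)
  }
  bp_pos <- as.integer(bp[models$gene_id])
  if (anyNA(bp_pos)) abort("`bp_positions` must cover every intron-containing gene.")
  if (any(bp_pos < 1 | bp_pos > models$intron_len)) {
    abort("Branch-point position outside the intron.")
  }
  if (any(bp_pos < 6 | bp_pos + 1L > models$intron_len)) {
    abort("Branch-point position leaves no room for the 7-mer branch-point window.")
  }

  pwm_5ss <- build_pwm(substr(intron_seq, 1, 6))
  pwm_bp <- build_pwm(substr(intron_seq, bp_pos - 5L, bp_pos + 1L))
  pwm_3ss <- build_pwm(substr(intron_seq, models$intron_len - 2L, models$intron_len))

  rows <- vector("list", nrow(models))
  pre <- function(gid, col) {
    if (is.null(energies) || !col %in% names(energies)) return(NA_real_)
    v <- energies[[col]][match(gid, energies$gene_id)]
    if (length(v) == 0) NA_real_ else v
  }
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    tx <- seqs[[m$gene_id]]
    iseq <- intron_seq[i]
    dg_intron <- pre(m$gene_id, "dg_intron")
    if (is.na(dg_intron)) dg_intron <- fold_energy(iseq, backend = fold_backend)
    ss_bp_seq <- substr(iseq, 1, bp_pos[i])
    dg_5ss_bp <- pre(m$gene_id, "dg_5ss_bp")
    if (is.na(dg_5ss_bp)) dg_5ss_bp <- fold_energy(ss_bp_seq, backend = fold_backend)
    w_start <- window_terminal(tx, window)
    w_stop <- window_terminal(tx, window, end = TRUE)
    w_3ss <- window_around(tx, m$exon1_len + m$intron_len, window)
    row <- tibble(
      gene_id = m$gene_id, class = m$class,
      dg_per_nt_intron = per_base_energy(dg_intron, nchar(iseq)),
      dg_per_nt_5ss_bp = per_base_energy(dg_5ss_bp, nchar(ss_bp_seq)),
      dg_window_start = fold_energy(w_start$seq, backend = fold_backend),
      dg_window_stop = fold_energy(w_stop$seq, backend = fold_backend),
      dg_window_3ss = fold_energy(w_3ss$seq, backend = fold_backend),
      score_5ss = site_score(substr(iseq, 1, 6), pwm_5ss),
      score_bp = site_score(substr(iseq, bp_pos[i] - 5L, bp_pos[i] + 1L), pwm_bp),
      score_3ss = site_score(substr(iseq, nchar(iseq) - 2L, nchar(iseq)), pwm_3ss),
      intron_length = m$intron_len, exon2_length = m$exon2_len,
      transcript_length = m$tx_len,
      bp_pos = bp_pos[i],
      window_truncated = w_start$truncated || w_stop$truncated || w_3ss$truncated
    )
    for (k in kmer_k) {
      kf <- kmer_frequencies(iseq, k)
      names(kf) <- paste0("kmer_", names(kf))
      row <- bind_cols(row, as_tibble(as.list(kf)))
    }
    rows[[i]] <- row
  }
  bind_rows(rows)
}
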