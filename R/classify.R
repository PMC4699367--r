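# Vectorized classification of aligned fragments against a single-intron gene
# model. Blocks are 0-based half-open intervals in unspliced (pre-mRNA)
# transcript-local coordinates; a fragment has one block (contiguous on the
# pre-mRNA) or two blocks (a spliced fragment that skips the intron).

region_levels <- c("exon1", "intron", "exon2", "junction",
                   "boundary_5ss", "boundary_3ss")

classify_blocks_impl <- function(e1, ilen, s1, b1e, s2, b2e, min_anchor) {
  n <- length(s1)
  category <- character(n)
  identity <- rep("ambiguous", n)
  two <- !is.na(s2)
  i_start <- e1
  i_end <- e1 + ilen

  # spliced (two-block) fragments: mature iff the gap is exactly the intron
  gap_ok <- two & (b1e == i_start) & (s2 == i_end)
  identity[gap_ok] <- "mature"
  a1 <- b1e - s1
  a2 <- b2e - s2
  jx <- gap_ok & a1 >= min_anchor & a2 >= min_anchor
  category[jx] <- "junction"
  weak <- two & !jx
  category[weak] <- ifelse(a1[weak] >= a2[weak], "exon1", "exon2")

  # contiguous fragments
  one <- !two
  o1 <- pmax(0, pmin(b1e, i_start) - s1)
  oi <- pmax(0, pmin(b1e, i_end) - pmax(s1, i_start))
  o2 <- pmax(0, b1e - pmax(s1, i_end))
  intronic <- one & oi > 0 & ilen > 0
  identity[intronic] <- "precursor"
  b5 <- intronic & (i_start - s1) >= min_anchor & (b1e - i_start) >= min_anchor
  b3 <- intronic & !b5 & (i_end - s1) >= min_anchor & (b1e - i_end) >= min_anchor
  inn <- intronic & !b5 & !b3 & o1 == 0 & o2 == 0
  category[b5] <- "boundary_5ss"
  category[b3] <- "boundary_3ss"
  category[inn] <- "intron"
  weak1 <- intronic & !b5 & !b3 & !inn
  if (any(weak1)) {
    pick <- max.col(cbind(o1[weak1], oi[weak1], o2[weak1]), ties.method = "first")
    category[weak1] <- c("exon1", "intron", "exon2")[pick]
  }
  exonic <- one & !intronic
  category[exonic] <- ifelse(o2[exonic] > 0 & o1[exonic] == 0, "exon2", "exon1")
  identity[one & ilen == 0] <- NA_character_  # intronless gene: no latent identity

  list(category = category, identity = identity)
}

#' Classify reads as precursor, mature or ambiguous
#'
#' Assigns every read a compatibility verdict against its gene model:
#' junction-spanning (two blocks skipping exactly the intron) reads are
#' unambiguously mature; reads overlapping any intronic position are
#' unambiguously precursor; exon-only reads are compatible with both isoforms
#' and stay ambiguous. A region `category` is also assigned (one region per
#' read): `junction` and `boundary_5ss`/`boundary_3ss` require at least
#' `min_anchor` nucleotides on each side of the junction/border, otherwise
#' the read falls back to its majority region.
#'
#' @param reads Tibble with columns `gene_id`, `start1`, `end1`, `start2`,
#'   `end2` (block coordinates, 0-based half-open, transcript-local; the
#'   second block NA for contiguous fragments).
#' @param models Annotation tibble from [simulate_annotation()] or
#'   [read_annotation()].
#' @param min_anchor Minimum overhang (nt) for junction/boundary calls.
#' @return `reads` with `category` and `identity` columns (re)computed.
#' @export
classify_reads <- function(reads, models, min_anchor = 5L) {
  assert_columns(reads, c("gene_id", "start1", "end1"), "reads")
  assert_columns(models, c("gene_id", "exon1_len", "intron_len", "tx_len"), "models")
  if (!"start2" %in% names(reads)) reads$start2 <- NA_integer_
  if (!"end2" %in% names(reads)) reads$end2 <- NA_integer_
  idx <- match(reads$gene_id, models$gene_id)
  if (anyNA(idx)) {
    abort(sprintf("Reads reference unknown gene(s): %s.",
                  paste(unique(reads$gene_id[is.na(idx)]), collapse = ", ")))
  }
  tx_len <- models$tx_len[idx]
  last_end <- ifelse(is.na(reads$end2), reads$end1, reads$end2)
  if (any(reads$start1 < 0 | last_end > tx_len)) {
    abort("Some reads fall outside their gene bounds.")
  }
  cl <- classify_blocks_impl(models$exon1_len[idx], models$intron_len[idx],
                             reads$start1, reads$end1, reads$start2, reads$end2,
                             min_anchor)
  reads$category <- cl$category
  reads$identity <- cl$identity
  reads
}
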