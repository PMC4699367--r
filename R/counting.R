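#' Count fragments per gene region
#'
#' Tallies fragments per gene into the six regions used by the splicing
#' estimators: `exon1`, `intron`, `exon2`, `junction` (blocks skipping the
#' whole intron with >= `min_anchor` nt in both exons), and
#' `boundary_5ss`/`boundary_3ss` (a block covering an exon/intron border with
#' >= `min_anchor` nt on each side). Every fragment is assigned to exactly
#' one region (junction/boundary calls take precedence; fragments failing
#' the anchor rule fall back to their majority region), so region counts sum
#' to the number of fragments assigned to the gene. If `reads` carries a
#' `time` column, counts are produced per gene and time point.
#'
#' @param reads Read tibble.
#' @param models Annotation tibble.
#' @param min_anchor Minimum overhang in nt (default 5).
#' In addition to the fragment counts, per-nucleotide coverage totals of the
#' intron and the exons (`intron_cov_nt`, `exon_cov_nt`: summed overlap
#' lengths of all fragments with the region) are reported, together with the
#' region lengths they refer to (`intron_cov_len`, `exon_cov_len`); these
#' feed the density-based intron/exon estimator. Exon coverage excludes the
#' first and last `end_trim` nucleotides of the transcript, where coverage
#' is limited by fragment-start availability rather than by abundance — the
#' intron, sitting in the transcript interior, needs no such trim.
#'
#' @param end_trim Nucleotides trimmed from each transcript end for the exon
#'   coverage density (default: the mean fragment length attached to
#'   `reads`, minus one; else the median observed fragment span minus one).
#' @return Tibble with one row per gene (x time), columns `gene_id`,
#'   optionally `time`, the six region counts, `n_reads`, and the coverage
#'   totals and lengths.
#' @export
count_regions <- function(reads, models, min_anchor = 5L, end_trim = NULL) {
  by_time <- "time" %in% names(reads) && !all(is.na(reads$time))
  if (nrow(reads) == 0) {
    empty <- tibble(gene_id = models$gene_id)
    for (r in region_levels) empty[[r]] <- 0L
    empty$n_reads <- 0L
    empty$intron_cov_nt <- 0
    empty$exon_cov_nt <- 0
    empty$intron_cov_len <- models$intron_len
    empty$exon_cov_len <- as.numeric(models$exon1_len + models$exon2_len)
    return(empty)
  }
  end_trim <- end_trim %||% {
    fl <- attr(reads, "frag_len_mean") %||%
      median(ifelse(is.na(reads$end2), reads$end1 - reads$start1,
                    (reads$end1 - reads$start1) + (reads$end2 - reads$start2)),
             na.rm = TRUE)
    max(0L, as.integer(round(fl)) - 1L)
  }
  reads <- classify_reads(reads, models, min_anchor = min_anchor)
  idx <- match(reads$gene_id, models$gene_id)
  i_start <- models$exon1_len[idx]
  i_end <- i_start + models$intron_len[idx]
  tx_len <- models$tx_len[idx]
  e1_lo <- pmin(end_trim, i_start)           # trimmed exon1 = [e1_lo, i_start)
  e2_hi <- pmax(i_end, tx_len - end_trim)    # trimmed exon2 = [i_end, e2_hi)
  ov <- function(s, e, lo, hi) pmax(0, pmin(e, hi) - pmax(s, lo))
  blk2 <- !is.na(reads$start2)
  s2 <- ifelse(blk2, reads$start2, 0L)
  e2 <- ifelse(blk2, reads$end2, 0L)
  reads$.i_cov <- ov(reads$start1, reads$end1, i_start, i_end) +
    ov(s2, e2, i_start, i_end)
  reads$.e_cov <- ov(reads$start1, reads$end1, e1_lo, i_start) +
    ov(s2, e2, e1_lo, i_start) +
    ov(reads$start1, reads$end1, i_end, e2_hi) +
    ov(s2, e2, i_end, e2_hi)
  keys <- if (by_time) c("gene_id", "time") else "gene_id"
  counts <- reads |>
    dplyr::count(across(all_of(keys)), .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (r in region_levels) {
    if (!r %in% names(counts)) counts[[r]] <- 0L
  }
  # zero rows for annotated genes with no reads
  frame <- if (by_time) {
    tidyr::expand_grid(gene_id = models$gene_id,
                       time = sort(unique(reads$time)))
  } else {
    tibble(gene_id = models$gene_id)
  }
  cov <- reads |>
    group_by(across(all_of(keys))) |>
    summarise(intron_cov_nt = sum(.data$.i_cov),
              exon_cov_nt = sum(.data$.e_cov), .groups = "drop")
  counts <- left_join(frame, counts, by = keys)
  counts <- left_join(counts, cov, by = keys)
  counts <- mutate(counts,
                   across(all_of(region_levels), ~ tidyr::replace_na(.x, 0L)),
                   across(c("intron_cov_nt", "exon_cov_nt"),
                          ~ tidyr::replace_na(.x, 0)))
  counts$n_reads <- rowSums(counts[, region_levels])
  midx <- match(counts$gene_id, models$gene_id)
  m_e1 <- models$exon1_len[midx]
  m_tx <- models$tx_len[midx]
  m_iend <- m_e1 + models$intron_len[midx]
  counts$intron_cov_len <- models$intron_len[midx]
  counts$exon_cov_len <- (m_e1 - pmin(end_trim, m_e1)) +
    (pmax(m_iend, m_tx - end_trim) - m_iend)
  select(counts, all_of(keys), all_of(region_levels), "n_reads",
         "intron_cov_nt", "exon_cov_nt", "intron_cov_len", "exon_cov_len")
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = 1e9 * count / (length * total)`: fragment counts normalized by
#' feature length (nt) and sequencing depth (total mapped fragments).
#'
#' @param count Fragment count(s) (>= 0).
#' @param region_length_nt Feature length(s) in nucleotides (> 0).
#' @param total_mapped_fragments Total mapped fragments in the sample (> 0).
#' @return Numeric FPKM value(s).
#' @export
#' @examples
#' fpkm(200, 2000, 1e7)  # 10
fpkm <- function(count, region_length_nt, total_mapped_fragments) {
  if (any(region_length_nt <= 0)) abort("`region_length_nt` must be positive.")
  if (any(total_mapped_fragments <= 0)) abort("`total_mapped_fragments` must be positive.")
  if (any(count < 0)) abort("`count` must be non-negative.")
  1e9 * count / (region_length_nt * total_mapped_fragments)
}

#' Per-gene FPKM table from a read table
#'
#' Computes whole-gene FPKM per sample (time point), with the per-sample
#' total mapped fragments taken as the number of reads in that sample.
#'
#' @param reads Read tibble with a `time` column.
#' @param models Annotation tibble.
#' @return Tibble `gene_id`, `time`, `count`, `fpkm`.
#' @export
fpkm_table <- function(reads, models) {
  assert_columns(reads, c("gene_id", "time"), "reads")
  totals <- dplyr::count(reads, .data$time, name = "total")
  frame <- tidyr::expand_grid(gene_id = models$gene_id,
                              time = sort(unique(reads$time)))
  counts <- dplyr::count(reads, .data$gene_id, .data$time, name = "count")
  out <- frame |>
    left_join(counts, by = c("gene_id", "time")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    left_join(totals, by = "time") |>
    left_join(select(models, "gene_id", "tx_len"), by = "gene_id")
  out$fpkm <- fpkm(out$count, out$tx_len, out$total)
  select(out, "gene_id", "time", "count", "fpkm")
}
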