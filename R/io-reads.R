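# Read-table TSV format (bit-exact specification)
# ------------------------------------------------
# Tab-separated, header line, one row per aligned fragment:
#   read_id      character
#   gene_id      character
#   time         numeric labeling time in minutes; Inf = steady state
#   origin       "signal" or "background" (simulator ground truth; "." if unknown)
#   block_starts comma-joined 0-based half-open block starts, transcript-local
#   block_ends   comma-joined block ends, same order
#   category     region category (exon1|intron|exon2|junction|boundary_5ss|boundary_3ss)
#   identity     precursor|mature|ambiguous|NA
# Blocks are on the unspliced transcript in transcription orientation.

#' Write a read table TSV
#'
#' @param reads Read tibble ([simulate_reads()] / [load_reads()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(reads, path) {
  assert_columns(reads, c("read_id", "gene_id", "start1", "end1"), "reads")
  starts <- ifelse(is.na(reads$start2), as.character(reads$start1),
                   paste(reads$start1, reads$start2, sep = ","))
  ends <- ifelse(is.na(reads$end2), as.character(reads$end1),
                 paste(reads$end1, reads$end2, sep = ","))
  out <- tibble(
    read_id = reads$read_id, gene_id = reads$gene_id,
    time = reads$time %||% NA_real_,
    origin = reads$origin %||% ".",
    block_starts = starts, block_ends = ends,
    category = reads$category %||% NA_character_,
    identity = reads$identity %||% NA_character_
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Load aligned reads from a read-table TSV or SAM/BAM file
#'
#' TSV input follows the documented read-table format (see
#' [write_read_table()]). SAM/BAM input is read with Rsamtools /
#' GenomicAlignments; each alignment is assigned to the transcript model
#' whose span contains it, its blocks are converted from genomic to
#' transcript-local coordinates (reverse-complement orientation for
#' minus-strand genes), and categories/identities are (re)computed with
#' [classify_reads()].
#'
#' @param path Input file (`.tsv`, `.sam` or `.bam`).
#' @param models Annotation tibble.
#' @param format `"auto"` (by extension), `"tsv"`, or `"sam"`.
#' @param min_anchor Anchor rule for classification.
#' @return A read tibble with the same columns as [simulate_reads()].
#' @export
load_reads <- function(path, models, format = c("auto", "tsv", "sam"),
                       min_anchor = 5L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  reads <- if (format == "tsv") read_read_table_tsv(path) else read_sam(path, models)
  classify_reads(reads, models, min_anchor = min_anchor)
}

read_read_table_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          block_starts = readr::col_character(),
                          block_ends = readr::col_character()
                        ))
  assert_columns(df, c("read_id", "gene_id", "block_starts", "block_ends"), "read table")
  starts <- unpack_blocks(df$block_starts)
  ends <- unpack_blocks(df$block_ends)
  nb <- lengths(starts)
  if (any(nb != lengths(ends)) || any(nb < 1 | nb > 2)) {
    abort("Read table blocks must have 1 or 2 matched start/end entries.")
  }
  tibble(
    read_id = df$read_id, gene_id = df$gene_id,
    time = if ("time" %in% names(df)) df$time else NA_real_,
    origin = if ("origin" %in% names(df)) df$origin else ".",
    start1 = vapply(starts, `[`, integer(1), 1),
    end1 = vapply(ends, `[`, integer(1), 1),
    start2 = vapply(starts, function(v) if (length(v) > 1) v[2] else NA_integer_, integer(1)),
    end2 = vapply(ends, function(v) if (length(v) > 1) v[2] else NA_integer_, integer(1)),
    frag_len = NA_integer_
  )
}

read_sam <- function(path, models) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  aln <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE, param = Rsamtools::ScanBamParam(what = "flag")
  )
  if (length(aln) == 0) abort(sprintf("No alignments in '%s'.", path))
  blocks <- GenomicAlignments::grglist(aln)  # genomic blocks per read
  gene_gr <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$tx_start + 1L, models$tx_end)
  )
  hits <- GenomicRanges::findOverlaps(range(blocks), gene_gr, type = "within",
                                      ignore.strand = TRUE)
  if (length(hits) == 0) abort("No alignments fall within an annotated gene span.")
  qi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(qi), function(k) {
    b <- blocks[[qi[k]]]
    m <- models[gi[k], ]
    gs <- GenomicRanges::start(b) - 1L  # 0-based half-open genomic
    ge <- GenomicRanges::end(b)
    if (m$strand == "+") {
      ls <- gs - m$tx_start; le <- ge - m$tx_start
    } else {
      ls <- m$tx_end - ge; le <- m$tx_end - gs
      ord <- order(ls); ls <- ls[ord]; le <- le[ord]
    }
    tibble(
      read_id = names(aln)[qi[k]] %||% sprintf("aln%06d", qi[k]),
      gene_id = m$gene_id,
      start1 = as.integer(ls[1]), end1 = as.integer(le[1]),
      start2 = if (length(ls) > 1) as.integer(ls[2]) else NA_integer_,
      end2 = if (length(ls) > 1) as.integer(le[2]) else NA_integer_
    )
  })
  out <- bind_rows(rows)
  out$time <- NA_real_
  out$origin <- "."
  out$frag_len <- NA_integer_
  out
}

#' Write reads as a minimal SAM file
#'
#' Converts transcript-local blocks back to genomic coordinates against
#' `models` and writes single-end SAM records (CIGAR `M`/`N`, mapped strand
#' taken from the gene, sequence omitted). Useful for interoperating with
#' samtools-based tooling and for round-trip testing of [load_reads()].
#'
#' @param reads Read tibble.
#' @param models Annotation tibble.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, models, path) {
  assert_columns(reads, c("read_id", "gene_id", "start1", "end1"), "reads")
  idx <- match(reads$gene_id, models$gene_id)
  if (anyNA(idx)) abort("Reads reference genes absent from `models`.")
  m <- models[idx, ]
  two <- !is.na(reads$start2)
  # genomic forward-strand blocks
  g1s <- g1e <- g2s <- g2e <- integer(nrow(reads))
  plus <- m$strand == "+"
  g1s[plus] <- m$tx_start[plus] + reads$start1[plus]
  g1e[plus] <- m$tx_start[plus] + reads$end1[plus]
  g2s[plus] <- m$tx_start[plus] + ifelse(two[plus], reads$start2[plus], NA_integer_)
  g2e[plus] <- m$tx_start[plus] + ifelse(two[plus], reads$end2[plus], NA_integer_)
  mn <- !plus
  last_end <- ifelse(two, reads$end2, reads$end1)
  # minus strand: local block [s,e) maps to genomic [tx_end - e, tx_end - s)
  g1s[mn] <- m$tx_end[mn] - ifelse(two[mn], reads$end2[mn], reads$end1[mn])
  g1e[mn] <- m$tx_end[mn] - ifelse(two[mn], reads$start2[mn], reads$start1[mn])
  g2s[mn] <- ifelse(two[mn], m$tx_end[mn] - reads$end1[mn], NA_integer_)
  g2e[mn] <- ifelse(two[mn], m$tx_end[mn] - reads$start1[mn], NA_integer_)
  cigar <- ifelse(two,
                  sprintf("%dM%dN%dM", g1e - g1s, g2s - g1e, g2e - g2s),
                  sprintf("%dM", g1e - g1s))
  flag <- ifelse(m$strand == "-", 16L, 0L)
  chroms <- unique(models$chrom)
  chrom_len <- vapply(chroms, function(ch) {
    max(models$tx_end[models$chrom == ch]) + 1000L
  }, numeric(1))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(chrom_len)))
  records <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                     reads$read_id, flag, m$chrom, g1s + 1L, cigar)
  writeLines(c(header, records), path)
  invisible(path)
}
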