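#' Write a transcript annotation to GTF or BED
#'
#' GTF output uses the ENSEMBL-style dialect (1-based inclusive coordinates,
#' `gene_id`/`transcript_id`/`gene_biotype` attributes) with one `exon`
#' feature per exon. BED6 output records one line per transcript span only
#' (exon/intron structure is not representable in BED6 and is dropped).
#'
#' @param models Annotation tibble ([simulate_annotation()]).
#' @param path Output file.
#' @param format `"gtf"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  assert_columns(models, c("gene_id", "chrom", "strand", "class",
                           "tx_start", "tx_end"), "models")
  if (format == "bed") {
    bed <- tibble(
      chrom = models$chrom, start = models$tx_start, end = models$tx_end,
      name = models$gene_id, score = 0L, strand = models$strand
    )
    readr::write_tsv(bed, path, col_names = FALSE)
    return(invisible(path))
  }
  gr <- annotation_to_granges(models)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

annotation_to_granges <- function(models) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    exons <- if (!is.na(m$intron_start)) {
      # exon order in the file is genomic; exon_number follows transcription
      if (m$strand == "+") {
        data.frame(start = c(m$exon1_start, m$exon2_start),
                   end = c(m$exon1_end, m$exon2_end), number = c(1L, 2L))
      } else {
        data.frame(start = c(m$exon2_start, m$exon1_start),
                   end = c(m$exon2_end, m$exon1_end), number = c(2L, 1L))
      }
    } else {
      data.frame(start = m$exon1_start, end = m$exon1_end, number = 1L)
    }
    rows[[i]] <- GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
      strand = m$strand,
      type = "exon", source = "tukinetics",
      gene_id = m$gene_id, transcript_id = paste0(m$gene_id, ".1"),
      gene_biotype = m$class, exon_number = exons$number
    )
  }
  do.call(c, rows)
}

#' Read a transcript annotation (GTF or BED6)
#'
#' GTF input is interpreted with the standard 1-based inclusive convention
#' and converted to the package's internal 0-based half-open coordinates;
#' for two-exon transcripts the single intron is inferred between the exons
#' and exon order follows the direction of transcription. BED6 input yields
#' single-exon models. Malformed lines fail with the offending line number.
#'
#' @param path Annotation file.
#' @param dialect `"gtf"` or `"bed"` (default: guessed from the extension).
#' @return An annotation tibble with the same schema as
#'   [simulate_annotation()].
#' @export
read_annotation <- function(path, dialect = NULL) {
  dialect <- dialect %||%
    (if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf")
  dialect <- match.arg(dialect, c("gtf", "bed"))
  if (dialect == "bed") {
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                               "score", "strand"),
                           show_col_types = FALSE)
    return(dplyr::transmute(bed,
      gene_id = .data$name, chrom = .data$chrom, strand = .data$strand,
      class = "other", tx_start = .data$start, tx_end = .data$end,
      exon1_start = .data$start, exon1_end = .data$end,
      intron_start = NA_integer_, intron_end = NA_integer_,
      exon2_start = NA_integer_, exon2_end = NA_integer_,
      exon1_len = .data$end - .data$start, intron_len = 0L, exon2_len = 0L,
      tx_len = .data$end - .data$start
    ))
  }
  check_gtf_lines(path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) abort(sprintf("Malformed GTF '%s': %s", path, conditionMessage(e))))
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0) abort(sprintf("No exon features found in '%s'.", path))
  split_rows <- split(df, df$gene_id)
  out <- lapply(names(split_rows), function(gid) {
    ex <- split_rows[[gid]]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 2) {
      abort(sprintf("Gene %s has %d exons; at most one intron is supported.", gid, nrow(ex)))
    }
    strand <- as.character(ex$strand[1])
    cls <- if ("gene_biotype" %in% names(ex) && !is.na(ex$gene_biotype[1])) {
      ex$gene_biotype[1]
    } else "other"
    s0 <- ex$start - 1L  # to 0-based half-open
    e0 <- ex$end
    tx_start <- min(s0); tx_end <- max(e0)
    if (nrow(ex) == 2) {
      # first exon in transcription order
      first <- if (strand == "-") 2L else 1L
      second <- 3L - first
      tibble(
        gene_id = gid, chrom = as.character(ex$seqnames[1]), strand = strand,
        class = cls, tx_start = tx_start, tx_end = tx_end,
        exon1_start = s0[first], exon1_end = e0[first],
        intron_start = e0[1], intron_end = s0[2],
        exon2_start = s0[second], exon2_end = e0[second],
        exon1_len = e0[first] - s0[first],
        intron_len = s0[2] - e0[1],
        exon2_len = e0[second] - s0[second],
        tx_len = tx_end - tx_start
      )
    } else {
      tibble(
        gene_id = gid, chrom = as.character(ex$seqnames[1]), strand = strand,
        class = cls, tx_start = tx_start, tx_end = tx_end,
        exon1_start = s0[1], exon1_end = e0[1],
        intron_start = NA_integer_, intron_end = NA_integer_,
        exon2_start = NA_integer_, exon2_end = NA_integer_,
        exon1_len = e0[1] - s0[1], intron_len = 0L, exon2_len = 0L,
        tx_len = tx_end - tx_start
      )
    }
  })
  arrange(bind_rows(out), .data$gene_id)
}

check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfields <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nfields < 9]
  if (length(bad) > 0) {
    abort(sprintf("Malformed GTF '%s': line %d has fewer than 9 tab-separated fields.",
                  path, bad[1]))
  }
  invisible(TRUE)
}
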