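#' Direct splicing-ratio estimate from junction and boundary reads
#'
#' The simplest unambiguous-read estimator: `R = J / (J + B)` where `J` is
#' the splice-junction count and `B` summarizes the intron-boundary counts —
#' by default the mean of the 5'ss and 3'ss boundary counts; `boundary =
#' "5ss"` uses the 5' boundary alone (mirroring an RT-qPCR design that
#' amplifies across the 5' splice site). Genes with `J + B = 0` are flagged
#' inestimable (`ratio = NA`).
#'
#' @param counts Region-count tibble from [count_regions()].
#' @param boundary `"both"` (mean of the two boundaries) or `"5ss"`.
#' @return A tibble with `gene_id` (and `time` if present), `n_reads`,
#'   `ratio`, `inestimable`, `estimator = "junction"`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g", junction = 6,
#'                          boundary_5ss = 2, boundary_3ss = 2)
#' direct_ratio_junction(counts)  # 6/8 = 0.75
direct_ratio_junction <- function(counts, boundary = c("both", "5ss")) {
  boundary <- match.arg(boundary)
  assert_columns(counts, c("gene_id", "junction", "boundary_5ss", "boundary_3ss"),
                 "counts")
  b <- if (boundary == "both") {
    (counts$boundary_5ss + counts$boundary_3ss) / 2
  } else {
    counts$boundary_5ss
  }
  j <- counts$junction
  denom <- j + b
  keys <- intersect(c("gene_id", "time"), names(counts))
  out <- counts[, keys, drop = FALSE]
  out$n_reads <- counts$junction + counts$boundary_5ss + counts$boundary_3ss
  out$ratio <- ifelse(denom > 0, j / denom, NA_real_)
  out$inestimable <- denom == 0
  out$estimator <- "junction"
  as_tibble(out)
}

#' Direct splicing-ratio estimate from intron and exon read densities
#'
#' With intron read density `d_i` and exon read density `d_e` (covered
#' nucleotides per nucleotide of region), the intron is present only in the
#' precursor while exons are present in both isoforms, so
#' `R = 1 - d_i / d_e`, clamped to `[0, 1]`. The densities are computed from
#' the per-nucleotide coverage totals of [count_regions()] rather than
#' whole-fragment counts, which would be distorted by boundary-straddling
#' fragments. Genes with zero exon density are flagged inestimable; genes
#' whose raw ratio falls outside `[0, 1]` are clamped and flagged
#' (`clamped`).
#'
#' @param counts Region-count tibble from [count_regions()] (with the
#'   coverage columns).
#' @param models Annotation tibble providing region lengths.
#' @return A tibble with `gene_id` (and `time`), `n_reads`, `d_intron`,
#'   `d_exon`, `ratio`, `inestimable`, `clamped`,
#'   `estimator = "intron_exon"`.
#' @export
direct_ratio_intron_exon <- function(counts, models) {
  assert_columns(counts, c("gene_id", "intron_cov_nt", "exon_cov_nt",
                           "intron_cov_len", "exon_cov_len"), "counts")
  idx <- match(counts$gene_id, models$gene_id)
  intron_len <- models$intron_len[idx]
  d_i <- counts$intron_cov_nt / pmax(counts$intron_cov_len, 1)
  d_e <- counts$exon_cov_nt / pmax(counts$exon_cov_len, 1)
  direct_ratio_from_densities(d_i, d_e, counts, intron_len)
}

#' @rdname direct_ratio_intron_exon
#' @param d_i,d_e Intron and exon per-nucleotide densities (for use with
#'   externally computed densities).
#' @export
#' @examples
#' direct_ratio_from_densities(1, 4)$ratio  # 0.75
direct_ratio_from_densities <- function(d_i, d_e, counts = NULL,
                                        intron_len = NULL) {
  raw <- 1 - d_i / d_e
  keys <- intersect(c("gene_id", "time"), names(counts))
  out <- if (is.null(counts)) tibble(.rows = length(d_i)) else
    as_tibble(counts[, keys, drop = FALSE])
  out$n_reads <- if (is.null(counts)) NA_integer_ else counts$n_reads
  out$d_intron <- d_i
  out$d_exon <- d_e
  out$inestimable <- d_e == 0 |
    (if (is.null(intron_len)) FALSE else intron_len == 0)
  out$ratio <- ifelse(out$inestimable, NA_real_, pmin(pmax(raw, 0), 1))
  out$clamped <- !out$inestimable & (raw < 0 | raw > 1)
  out$estimator <- "intron_exon"
  out
}

#' Filter splicing estimates by credible-interval width
#'
#' Retains only genes whose 95% credible interval on the splicing ratio is
#' strictly narrower than `max_width` at every nascent (finite) time point —
#' the principled noise filter enabled by the posterior estimator; genes
#' failing it are typically low-coverage.
#'
#' @param estimates Tibble from [posterior_ratio()] (needs `gene_id`,
#'   `ci_width`, and optionally `time`).
#' @param max_width Maximum allowed interval width (default 0.3; the
#'   retention rule is `ci_width < max_width`, strict).
#' @return The rows of `estimates` belonging to retained genes.
#' @export
ci_filter <- function(estimates, max_width = 0.3) {
  if (nrow(estimates) == 0) return(estimates)
  assert_columns(estimates, c("gene_id", "ci_width"), "estimates")
  nascent <- if ("time" %in% names(estimates)) {
    filter(estimates, is.finite(.data$time))
  } else {
    estimates
  }
  keep <- nascent |>
    group_by(.data$gene_id) |>
    summarise(ok = all(.data$ci_width < max_width), .groups = "drop") |>
    filter(.data$ok)
  filter(estimates, .data$gene_id %in% keep$gene_id)
}
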