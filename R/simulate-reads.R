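#' Simulate aligned 4tU-seq fragments from known abundances
#'
#' Draws sequencing fragments for every sample (time point) present in
#' `truth`. Within a sample, a fragment picks an isoform with probability
#' proportional to abundance times effective length, gets a truncated-normal
#' fragment length, and a start position uniform over the valid positions of
#' that isoform — then its blocks are laid out on the unspliced transcript
#' and classified with [classify_reads()]. Nascent samples (finite `time`)
#' are contaminated with a `background_fraction` of unlabeled fragments drawn
#' from the steady-state (`time = Inf`, mostly spliced) composition,
#' emulating RNA that binds the purification beads non-specifically.
#'
#' @param truth Abundance tibble from [simulate_labeled_abundances()]
#'   (columns `gene_id`, `time`, `precursor`, `mature`, `total`). A
#'   `time = Inf` steady-state block is required when
#'   `background_fraction > 0`.
#' @param models Annotation tibble ([simulate_annotation()]).
#' @param n_fragments Fragments per sample.
#' @param read_len Minimum observable fragment length (nt).
#' @param frag_len_mean,frag_len_sd Fragment-length distribution (normal,
#'   truncated to `[read_len, isoform length]`).
#' @param background_fraction Fraction of fragments in nascent samples drawn
#'   from steady-state composition; in `[0, 1)`.
#' @param min_anchor Anchor rule passed to [classify_reads()].
#' @param seed Integer seed; the returned table is identical across reruns.
#' @return A tibble of reads: `read_id`, `gene_id`, `time`, `origin`
#'   (signal/background), block columns `start1`, `end1`, `start2`, `end2`,
#'   `frag_len`, `category`, `identity`. The fragment-length mean used is
#'   attached as attribute `frag_len_mean` (consumed as the default effective
#'   length by the estimators).
#' @export
simulate_reads <- function(truth, models, n_fragments = 10000L, read_len = 50L,
                           frag_len_mean = 80, frag_len_sd = 10,
                           background_fraction = 0, min_anchor = 5L, seed = 1L) {
  assert_columns(truth, c("gene_id", "time", "precursor", "mature", "total"), "truth")
  assert_scalar_number(background_fraction, "background_fraction",
                       lower = 0, upper = 1, strict_upper = TRUE)
  assert_scalar_number(n_fragments, "n_fragments", lower = 1)
  times <- sort(unique(truth$time))
  if (background_fraction > 0 && !any(is.infinite(times))) {
    abort("`background_fraction > 0` requires steady-state (time = Inf) rows in `truth`.")
  }

  iso <- isoform_table(truth, models, frag_len_mean, read_len)
  out <- vector("list", length(times))
  with_seed(derive_seed(seed, 202L), {
    for (k in seq_along(times)) {
      t <- times[k]
      sig <- iso[iso$time == t & iso$weight > 0, ]
      if (nrow(sig) == 0) {
        warn(sprintf("No positive-abundance isoforms at time %s; sample skipped.", format(t)))
        next
      }
      n_bg <- if (is.finite(t) && background_fraction > 0) {
        rbinom(1L, as.integer(n_fragments), background_fraction)
      } else 0L
      n_sig <- as.integer(n_fragments) - n_bg
      draw_sig <- draw_fragments(sig, n_sig, read_len, frag_len_mean, frag_len_sd)
      draw_sig$origin <- "signal"
      if (n_bg > 0) {
        bg <- iso[is.infinite(iso$time) & iso$weight > 0, ]
        draw_bg <- draw_fragments(bg, n_bg, read_len, frag_len_mean, frag_len_sd)
        draw_bg$origin <- "background"
        draw_sig <- bind_rows(draw_sig, draw_bg)
      }
      draw_sig$time <- t
      draw_sig$read_id <- sprintf("r_%s_%06d",
                                  ifelse(is.finite(t), format(t), "ss"),
                                  seq_len(nrow(draw_sig)))
      out[[k]] <- draw_sig
    }
  })
  reads <- bind_rows(out)
  reads <- classify_reads(reads, models, min_anchor = min_anchor)
  reads <- reads[, c("read_id", "gene_id", "time", "origin", "start1", "end1",
                     "start2", "end2", "frag_len", "category", "identity")]
  attr(reads, "frag_len_mean") <- frag_len_mean
  reads
}

# One row per gene x isoform x time with sampling weight = abundance x
# effective length. Isoforms shorter than the minimum fragment are dropped
# with a warning.
isoform_table <- function(truth, models, frag_len_mean, read_len) {
  assert_columns(models, c("gene_id", "exon1_len", "intron_len", "exon2_len",
                           "tx_len"), "models")
  m <- models[match(truth$gene_id, models$gene_id), ]
  if (anyNA(m$gene_id)) abort("`truth` references genes absent from `models`.")
  intronic <- m$intron_len > 0
  pre <- tibble(
    gene_id = truth$gene_id, time = truth$time, isoform = "precursor",
    iso_len = m$tx_len, exon1_len = m$exon1_len, intron_len = m$intron_len,
    abundance = ifelse(intronic, truth$precursor, truth$total)
  )
  mat <- tibble(
    gene_id = truth$gene_id[intronic], time = truth$time[intronic],
    isoform = "mature", iso_len = m$exon1_len[intronic] + m$exon2_len[intronic],
    exon1_len = m$exon1_len[intronic], intron_len = m$intron_len[intronic],
    abundance = truth$mature[intronic]
  )
  iso <- bind_rows(pre, mat)
  too_short <- iso$iso_len < read_len
  if (any(too_short & iso$abundance > 0)) {
    bad <- unique(iso$gene_id[too_short])
    warn(sprintf("Isoform(s) shorter than the minimum fragment skipped for: %s.",
                 paste(bad, collapse = ", ")))
  }
  eff <- pmax(iso$iso_len - frag_len_mean + 1, 0)
  eff[too_short] <- 0
  iso$weight <- iso$abundance * eff
  iso
}

draw_fragments <- function(iso, n, read_len, frag_len_mean, frag_len_sd) {
  if (n == 0) {
    return(tibble(gene_id = character(), isoform = character(),
                  start1 = integer(), end1 = integer(),
                  start2 = integer(), end2 = integer(), frag_len = integer()))
  }
  pick <- sample.int(nrow(iso), n, replace = TRUE, prob = iso$weight)
  iso_len <- iso$iso_len[pick]
  f <- round(rnorm(n, frag_len_mean, frag_len_sd))
  for (i in 1:50) {  # truncation by resampling
    bad <- f < read_len | f > iso_len
    if (!any(bad)) break
    f[bad] <- round(rnorm(sum(bad), frag_len_mean, frag_len_sd))
  }
  f <- pmin(pmax(f, read_len), iso_len)
  s <- floor(runif(n) * (iso_len - f + 1))
  e1 <- iso$exon1_len[pick]
  ilen <- iso$intron_len[pick]
  mat <- iso$isoform[pick] == "mature"
  spans <- mat & s < e1 & (s + f) > e1
  # precursor / non-spanning fragments: one contiguous block (mature
  # exon2-only fragments are shifted past the intron)
  shift <- ifelse(mat & s >= e1, ilen, 0L)
  start1 <- as.integer(s + ifelse(spans, 0L, shift))
  end1 <- as.integer(ifelse(spans, e1, s + f + shift))
  start2 <- ifelse(spans, e1 + ilen, NA_integer_)
  end2 <- ifelse(spans, s + f + ilen, NA_integer_)
  tibble(
    gene_id = iso$gene_id[pick], isoform = iso$isoform[pick],
    start1 = start1, end1 = end1,
    start2 = as.integer(start2), end2 = as.integer(end2),
    frag_len = as.integer(f)
  )
}
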