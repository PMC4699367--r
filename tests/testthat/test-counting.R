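test_that("region counts match exhaustive enumeration on a toy gene", {
  # exon 50 / intron 40 / exon 50; every possible 30-nt contiguous read
  model <- test_gene_model(exon1_len = 50L, intron_len = 40L, exon2_len = 50L)
  starts <- 0:110
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", starts), gene_id = "G0001",
    start1 = starts, end1 = starts + 30L,
    start2 = NA_integer_, end2 = NA_integer_
  )
  counts <- count_regions(reads, model, min_anchor = 5, end_trim = 0)

  # independent brute-force expectation from interval arithmetic
  exp_counts <- c(exon1 = 0, intron = 0, exon2 = 0, junction = 0,
                  boundary_5ss = 0, boundary_3ss = 0)
  for (s in starts) {
    e <- s + 30
    o1 <- max(0, min(e, 50) - s)
    oi <- max(0, min(e, 90) - max(s, 50))
    o2 <- max(0, e - max(s, 90))
    lab <- if (s <= 45 && e >= 55) "boundary_5ss"
    else if (s <= 85 && e >= 95) "boundary_3ss"
    else if (o1 == 0 && o2 == 0 && oi > 0) "intron"
    else c("exon1", "intron", "exon2")[which.max(c(o1, oi, o2))]
    exp_counts[lab] <- exp_counts[lab] + 1
  }
  for (r in names(exp_counts)) {
    expect_equal(counts[[r]], unname(exp_counts[r]), label = r)
  }
  # conservation: every read counted exactly once across regions
  expect_equal(counts$n_reads, length(starts))
})

test_that("junction and intron reads are counted per the anchor rule", {
  model <- test_gene_model()
  jx <- tibble::tibble(read_id = "j", gene_id = "G0001",
                       start1 = 190L, end1 = 200L, start2 = 350L, end2 = 360L)
  counts <- count_regions(jx, model, min_anchor = 5)
  expect_equal(counts$junction, 1L)
  counts10 <- count_regions(jx, model, min_anchor = 11)
  expect_equal(counts10$junction, 0L)
  inside <- tibble::tibble(read_id = "i", gene_id = "G0001",
                           start1 = 250L, end1 = 290L,
                           start2 = NA_integer_, end2 = NA_integer_)
  ci <- count_regions(inside, model)
  expect_equal(ci$intron, 1L)
  expect_equal(ci$boundary_5ss + ci$boundary_3ss, 0L)
})

test_that("coverage totals accumulate overlap lengths", {
  model <- test_gene_model()  # intron [200, 350)
  reads <- tibble::tibble(
    read_id = c("a", "b"), gene_id = "G0001",
    start1 = c(180L, 250L), end1 = c(260L, 290L),
    start2 = NA_integer_, end2 = NA_integer_
  )
  counts <- count_regions(reads, model, end_trim = 0)
  expect_equal(counts$intron_cov_nt, 60 + 40)
  expect_equal(counts$exon_cov_nt, 20)
  expect_equal(counts$exon_cov_len, 400)
  trimmed <- count_regions(reads, model, end_trim = 79)
  expect_equal(trimmed$exon_cov_len, 400 - 2 * 79)
  expect_equal(trimmed$intron_cov_len, 150)
})

test_that("FPKM follows its definition and scaling", {
  expect_equal(fpkm(200, 2000, 1e7), 10)
  expect_equal(fpkm(0, 500, 1e6), 0)
  expect_equal(fpkm(100, 1000, 2e6), fpkm(100, 1000, 1e6) / 2)
  expect_error(fpkm(10, 0, 1e6), "positive")
  expect_error(fpkm(10, 100, 0), "positive")
  expect_error(fpkm(-1, 100, 1e6), "non-negative")
})

test_that("per-gene FPKM table uses sample totals and gene lengths", {
  models <- dplyr::bind_rows(
    test_gene_model(gene_id = "A"),
    test_gene_model(gene_id = "B", exon1_len = 400L))
  truth <- dplyr::bind_rows(one_gene_truth(0.5, gene_id = "A"),
                            one_gene_truth(0.5, gene_id = "B"))
  reads <- simulate_reads(truth, models, n_fragments = 1000, seed = 4)
  fp <- fpkm_table(reads, models)
  expect_equal(sum(fp$count), 1000)
  manual <- fpkm(fp$count[fp$gene_id == "A"], models$tx_len[1], 1000)
  expect_equal(fp$fpkm[fp$gene_id == "A"], manual)
})
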