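test_that("read simulation is deterministic for a fixed seed", {
  r1 <- sim_gene_reads(0.5, 500, seed = 11)
  r2 <- sim_gene_reads(0.5, 500, seed = 11)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_read_table(r1, f1); write_read_table(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- sim_gene_reads(0.5, 500, seed = 12)
  expect_false(identical(r1$start1, r3$start1))
})

test_that("a fully spliced gene yields no intron-overlapping reads", {
  reads <- sim_gene_reads(1, 2000, seed = 5)
  expect_equal(sum(reads$identity == "precursor"), 0)
  expect_equal(sum(reads$category %in% c("intron", "boundary_5ss", "boundary_3ss")), 0)
})

test_that("unambiguous identity counts match the binomial expectation", {
  # fixed fragment length makes the expectation exactly computable:
  # a fragment is drawn from the mature isoform with probability
  # q = R l_m / (R l_m + (1-R) l_p); given mature, it spans the junction
  # (f-1 of l_m starts); given precursor, it overlaps the intron
  # (i + f - 1 of l_p starts)
  f <- 80; e1 <- 200; i <- 150; e2 <- 200; n <- 10000
  l_m <- e1 + e2 - f + 1; l_p <- e1 + i + e2 - f + 1
  q <- 0.5 * l_m / (0.5 * l_m + 0.5 * l_p)
  reads <- sim_gene_reads(0.5, n, seed = 42, frag_len_sd = 0)
  p_mat <- q * (f - 1) / l_m
  p_pre <- (1 - q) * (i + f - 1) / l_p
  n_mat <- sum(reads$identity == "mature")
  n_pre <- sum(reads$identity == "precursor")
  expect_gte(n_mat, qbinom(5e-4, n, p_mat))
  expect_lte(n_mat, qbinom(1 - 5e-4, n, p_mat))
  expect_gte(n_pre, qbinom(5e-4, n, p_pre))
  expect_lte(n_pre, qbinom(1 - 5e-4, n, p_pre))
})

test_that("isoforms shorter than the minimum fragment are skipped with a warning", {
  model <- test_gene_model(exon1_len = 30L, intron_len = 150L, exon2_len = 10L)
  expect_warning(
    reads <- simulate_reads(one_gene_truth(0.5), model, n_fragments = 200,
                            seed = 1),
    "shorter than the minimum fragment"
  )
  # only precursor-compatible fragments remain
  expect_equal(sum(reads$identity == "mature"), 0)
})

test_that("background contamination requires steady-state rows and draws from them", {
  truth <- one_gene_truth(0.2)
  expect_error(
    simulate_reads(truth, test_gene_model(), background_fraction = 0.3, seed = 1),
    "steady-state"
  )
  truth_ss <- dplyr::bind_rows(truth, dplyr::tibble(
    gene_id = "G0001", time = Inf, precursor = 0.02, mature = 0.98, total = 1))
  reads <- simulate_reads(truth_ss, test_gene_model(), n_fragments = 4000,
                          background_fraction = 0.3, seed = 2)
  nascent <- reads[is.finite(reads$time), ]
  bg <- nascent[nascent$origin == "background", ]
  expect_gt(nrow(bg), 0.2 * nrow(nascent))
  # background is drawn from the (mostly spliced) steady state
  expect_lt(mean(bg$identity == "precursor"),
            mean(nascent$identity[nascent$origin == "signal"] == "precursor"))
})
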