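test_that("per-base energy is a simple normalization with validation", {
  expect_equal(per_base_energy(-30, 100), -0.3)
  expect_equal(per_base_energy(0, 50), 0)
  expect_equal(per_base_energy(-12.4, 62), -0.2)
  expect_error(per_base_energy(-10, 0), "positive")
  expect_error(per_base_energy(3, 10), "<= 0")
})

test_that("the folding proxy matches exhaustive enumeration on short sequences", {
  expect_equal(fold_energy("AAAAAAAA"), 0)
  seqs <- c("GGGGAAAACCCC", "GCGCAAAAGCGC", "AUAUGCAAAAAU", "GGCAUAAAUGCC")
  for (s in seqs) {
    expect_equal(fold_energy(s), oracle_fold_energy(s), label = s)
  }
  expect_lt(fold_energy("GGGGAAAACCCC"), 0)
})

test_that("a perfect stem scores as more stable than its shuffles", {
  stem <- "GGGGGGGAAAACCCCCCC"
  dg <- fold_energy(stem)
  set.seed(8)
  shuffled <- vapply(1:100, function(i) {
    fold_energy(paste(sample(strsplit(stem, "")[[1]]), collapse = ""))
  }, numeric(1))
  expect_lte(dg, min(shuffled))
  expect_lt(dg, mean(shuffled) - 2)
})

test_that("non-RNA characters are rejected with their positions", {
  expect_error(fold_energy("ACGTACGU"), "position\\(s\\) 4")
  expect_error(fold_energy("ACGXXCGU"), "4, 5")
})

test_that("the ViennaRNA backend parses RNAfold output", {
  dg <- fold_energy("GGGGGGGAAAACCCCCCC", backend = "vienna")
  expect_lt(dg, -5)
  expect_equal(fold_energy("AAAAAAAAAA", backend = "vienna"), 0)
})

test_that("PWM site scores behave as information content", {
  # uniform PWM scores zero everywhere
  uni <- build_pwm(c("AAAA", "CCCC", "GGGG", "UUUU"), pseudocount = 0)
  expect_equal(site_score("ACGU", uni), 0)
  expect_equal(site_score("GGGG", uni), 0)
  # hand example: two positions with f = (0.5, 0.25, 0.125, 0.125)
  pwm <- matrix(rep(c(0.5, 0.25, 0.125, 0.125), 2), nrow = 4,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  expect_equal(site_score("AA", pwm), 2)
  expect_equal(site_score("AC", pwm), log2(2) + log2(1))
  # consensus maximizes the score over all windows
  sites <- c("GUAUGU", "GUAUGU", "GUACGU", "GCAUGU", "GUAUGA")
  pwm2 <- build_pwm(sites)
  all_windows <- apply(expand.grid(rep(list(c("A", "C", "G", "U")), 2)), 1,
                       function(x) paste0("GUAU", x[1], x[2]))
  scores <- vapply(all_windows, site_score, numeric(1), pwm = pwm2)
  expect_equal(names(which.max(scores)), "GUAUGU")
  expect_error(site_score("GUA", pwm2), "width")
})

test_that("k-mer frequencies count overlapping words", {
  expect_equal(kmer_frequencies("AUAU", 1)[c("A", "U")], c(A = 0.5, U = 0.5))
  k2 <- kmer_frequencies("AUAU", 2)
  expect_equal(unname(k2["AU"]), 2 / 3)
  expect_equal(unname(k2["UA"]), 1 / 3)
  expect_equal(sum(k2), 1)
  expect_error(kmer_frequencies("AU", 3), "shorter")
})

test_that("simulated introns carry the splice signals at their annotated positions", {
  introns <- simulate_intron_sequences(50, au_bias = 0.6, length = 120, seed = 2)
  expect_identical(introns,
                   simulate_intron_sequences(50, au_bias = 0.6, length = 120, seed = 2))
  expect_true(all(substr(introns$seq, 1, 6) == "GUAUGU"))
  expect_true(all(substr(introns$seq, introns$bp_pos - 5, introns$bp_pos + 1) ==
                    "UACUAAC"))
  expect_true(all(substr(introns$seq, introns$bp_pos, introns$bp_pos) == "A"))
  expect_true(all(grepl("[UC]AG$", introns$seq)))
  expect_error(simulate_intron_sequences(5, 0.5, length = 30), "at least")
})

test_that("intron base composition tracks the A/U bias", {
  introns <- simulate_intron_sequences(200, au_bias = 0.5, length = 200, seed = 3)
  # non-motif background only (the splice signals themselves are A/U-rich)
  au <- vapply(introns$seq, function(s) {
    f <- kmer_frequencies(substr(s, 7, nchar(s) - 50), 1)
    unname(f["A"] + f["U"])
  }, numeric(1))
  expect_equal(mean(au), 0.5, tolerance = 0.02)
})

test_that("varying the A share at fixed A+U content anticorrelates A and U", {
  shares <- seq(0.2, 0.8, length.out = 60)
  freqs <- t(vapply(seq_along(shares), function(i) {
    s <- simulate_intron_sequences(1, au_bias = 0.65, a_share = shares[i],
                                   length = 300, seed = 400 + i)$seq
    kmer_frequencies(s, 1)[c("A", "U")]
  }, numeric(2)))
  expect_lt(cor(freqs[, 1], freqs[, 2]), -0.75)
})

test_that("feature extraction populates the full vector and respects the BP convention", {
  introns <- simulate_intron_sequences(12, au_bias = 0.6, length = 150, seed = 9)
  e1 <- 60L; e2 <- 90L
  models <- dplyr::bind_rows(lapply(1:12, function(i) {
    dplyr::mutate(test_gene_model(exon1_len = e1, intron_len = 150L,
                                  exon2_len = e2,
                                  gene_id = sprintf("G%04d", i)),
                  tx_start = 1000L + (i - 1L) * 500L,
                  tx_end = tx_start + tx_len)
  }))
  seqs <- setNames(paste0(strrep("C", e1), introns$seq, strrep("G", e2)),
                   models$gene_id)
  bp <- tibble::tibble(gene_id = models$gene_id, bp_pos = introns$bp_pos)
  fv <- extract_intron_features(models, seqs, bp)
  expect_equal(nrow(fv), 12)
  expect_true(all(fv$dg_per_nt_intron <= 0))
  expect_true(all(fv$intron_length == 150))
  expect_true(all(fv$exon2_length == 90))
  expect_true(all(fv$transcript_length == 300))
  expect_false(any(fv$window_truncated))
  # 5'ss-to-BP region is intron positions 1..bp_pos
  g1 <- introns$seq[1]
  expect_equal(fv$dg_per_nt_5ss_bp[1],
               fold_energy(substr(g1, 1, introns$bp_pos[1])) / introns$bp_pos[1])
  # k = 1 frequencies match direct computation on the intron
  expect_equal(fv$kmer_A[1], unname(kmer_frequencies(g1, 1)["A"]))
  # BP outside the intron is rejected
  bad <- dplyr::mutate(bp, bp_pos = 200L)
  expect_error(extract_intron_features(models, seqs, bad), "outside")
  # precomputed energies override the folding backend
  pre <- tibble::tibble(gene_id = models$gene_id[1], dg_intron = -75)
  fv2 <- extract_intron_features(models[1, ], seqs[1], bp[1, ], energies = pre)
  expect_equal(fv2$dg_per_nt_intron, -75 / 150)
  expect_equal(fv2$dg_per_nt_5ss_bp, fv$dg_per_nt_5ss_bp[1])
})

test_that("feature extraction is strand-symmetric", {
  intron <- simulate_intron_sequences(1, au_bias = 0.6, length = 100, seed = 31)
  tx_rna <- paste0(strrep("A", 40), intron$seq, strrep("G", 50))
  tx_dna <- gsub("U", "T", tx_rna)
  plus <- dplyr::mutate(test_gene_model(40L, 100L, 50L, gene_id = "Gp",
                                        strand = "+"))
  minus <- test_gene_model(40L, 100L, 50L, gene_id = "Gm", strand = "-")
  genome_plus <- setNames(list(paste0(strrep("T", 1000), tx_dna)), "chrS")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_dna)))
  genome_minus <- setNames(list(paste0(strrep("T", 1000), rc)), "chrS")
  sp <- transcript_sequence(genome_plus, plus)
  sm <- transcript_sequence(genome_minus, minus)
  expect_equal(sp, tx_rna)
  expect_equal(sm, tx_rna)
  bp <- intron$bp_pos
  fp <- extract_intron_features(plus, setNames(sp, "Gp"),
                                tibble::tibble(gene_id = "Gp", bp_pos = bp))
  fm <- extract_intron_features(minus, setNames(sm, "Gm"),
                                tibble::tibble(gene_id = "Gm", bp_pos = bp))
  expect_equal(dplyr::select(fp, -gene_id), dplyr::select(fm, -gene_id))
})

test_that("windows at transcript ends are truncated and flagged", {
  intron <- simulate_intron_sequences(1, au_bias = 0.5, length = 50, seed = 5)
  model <- test_gene_model(exon1_len = 5L, intron_len = 50L, exon2_len = 6L,
                           gene_id = "Gshort")
  seqs <- setNames(paste0("CCCCC", intron$seq, "GGGGGG"), "Gshort")
  fv <- extract_intron_features(model, seqs,
                                tibble::tibble(gene_id = "Gshort",
                                               bp_pos = intron$bp_pos))
  expect_true(fv$window_truncated)
})
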