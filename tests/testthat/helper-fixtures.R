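# Shared fixtures built in code.

# One-gene truth table at a single nascent time with a given molar ratio.
one_gene_truth <- function(ratio, time = 1, gene_id = "G0001") {
  tibble::tibble(gene_id = gene_id, time = time,
                 precursor = 1 - ratio, mature = ratio, total = 1)
}

# Reads for one synthetic gene with known molar splicing ratio.
sim_gene_reads <- function(ratio, n, seed, model = test_gene_model(),
                           frag_len_sd = 10) {
  simulate_reads(one_gene_truth(ratio), model, n_fragments = n,
                 frag_len_sd = frag_len_sd, seed = seed)
}

# Unambiguous-only read tables built directly from block coordinates on the
# default test gene (exon 200 / intron 150 / exon 200): junction reads are
# mature, 5'ss boundary reads precursor.
manual_reads <- function(n_mature, n_precursor, n_ambiguous = 0) {
  mk <- function(n, s1, e1, s2 = NA_integer_, e2 = NA_integer_) {
    if (n == 0) return(NULL)
    tibble::tibble(read_id = sprintf("m%04d", seq_len(n)), gene_id = "G0001",
                   time = 1, start1 = s1, end1 = e1, start2 = s2, end2 = e2)
  }
  dplyr::bind_rows(
    mk(n_mature, 160L, 200L, 350L, 390L),      # junction, 40 nt anchors
    mk(n_precursor, 180L, 260L),               # 5'ss boundary
    mk(n_ambiguous, 10L, 90L)                  # exon1-only
  )
}
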