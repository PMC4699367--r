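# Independent oracles used to freeze expected values.

# Exhaustive enumeration of all nested pairings of a short RNA, scored with
# the same constants as the folding proxy (GC -2, AU -1.1, GU -0.6, stacking
# -1, minimum hairpin loop 3), implemented independently of the dynamic
# program: structures are generated explicitly and scored as whole objects.
oracle_fold_energy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  pair_e <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = , CG = -2, AU = , UA = -1.1, GU = , UG = -0.6, NA_real_)
  }
  # all structures (lists of pairs) on [i, j]
  structures <- function(i, j) {
    if (j - i < 4) return(list(list()))
    out <- structures(i + 1, j)  # i unpaired
    for (k in seq(i + 4, j)) {
      if (!is.na(pair_e(chars[i], chars[k]))) {
        inner <- structures(i + 1, k - 1)
        rest <- if (k + 1 <= j) structures(k + 1, j) else list(list())
        for (a in inner) for (b in rest) {
          out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
        }
      }
    }
    out
  }
  score <- function(st) {
    if (length(st) == 0) return(0)
    pairs <- do.call(rbind, st)
    e <- sum(mapply(function(p, q) pair_e(chars[p], chars[q]),
                    pairs[, 1], pairs[, 2]))
    key <- paste(pairs[, 1], pairs[, 2])
    stacks <- sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key)
    e - 1 * stacks
  }
  min(vapply(structures(1, n), score, numeric(1)))
}

# Numerical ODE oracle for the labeling chain, via deSolve.
oracle_chain_ode <- function(k_syn, k_splice, k_decay, n_steps, times) {
  r <- n_steps * k_splice
  rhs <- function(t, y, parms) {
    dp <- numeric(n_steps + 1)
    dp[1] <- k_syn - r * y[1]
    if (n_steps > 1) {
      for (j in 2:n_steps) dp[j] <- r * y[j - 1] - r * y[j]
    }
    dp[n_steps + 1] <- r * y[n_steps] - k_decay * y[n_steps + 1]
    list(dp)
  }
  sol <- deSolve::ode(y = rep(0, n_steps + 1), times = c(0, times), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  sol <- sol[-1, -1, drop = FALSE]
  cbind(precursor = rowSums(sol[, seq_len(n_steps), drop = FALSE]),
        mature = sol[, n_steps + 1])
}
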