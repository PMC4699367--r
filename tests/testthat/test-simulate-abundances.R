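test_that("labeled abundances follow the first-order closed form", {
  p <- kinetic_params(10, 2, 1, label_offset = 0)
  tr <- simulate_labeled_abundances(p, c(1e-9, 1, 2, 4))
  # zero labeled material at t ~ 0
  expect_lt(tr$precursor[1], 1e-6)
  expect_lt(tr$mature[1], 1e-6)
  # P(t) = (k_syn/k_splice) (1 - exp(-k_splice t))
  expect_equal(tr$precursor[2:4], 5 * (1 - exp(-2 * c(1, 2, 4))), tolerance = 1e-8)
  # steady state: R_ss = k_splice / (k_splice + k_decay)
  ss <- tr[is.infinite(tr$time), ]
  expect_equal(ss$ratio, 2 / 3, tolerance = 1e-12)
  expect_equal(ss$precursor, 5, tolerance = 1e-10)
  expect_equal(ss$mature, 10, tolerance = 1e-10)
})

test_that("label incorporation delay shifts the effective time", {
  p <- kinetic_params(10, 2, 1, label_offset = 0.5)
  tr <- simulate_labeled_abundances(p, c(0.25, 0.5, 1.5), include_steady_state = FALSE)
  expect_equal(tr$precursor[1:2], c(0, 0))
  expect_equal(tr$mature[1:2], c(0, 0))
  expect_true(is.na(tr$ratio[1]))
  p0 <- kinetic_params(10, 2, 1, label_offset = 0)
  tr0 <- simulate_labeled_abundances(p0, 1, include_steady_state = FALSE)
  expect_equal(unname(tr$precursor[3]), unname(tr0$precursor), tolerance = 1e-10)
})

test_that("closed form matches a numerical ODE integrator across a grid", {
  grid <- expand.grid(k_syn = c(2, 10), k_splice = c(0.3, 1, 2),
                      k_decay = c(0.3, 1), n = c(1L, 3L))
  times <- c(0.5, 1.5, 2.5, 5, 20)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- kinetic_params(g$k_syn, g$k_splice, g$k_decay, g$n, label_offset = 0)
    tr <- simulate_labeled_abundances(p, times, include_steady_state = FALSE)
    ode <- oracle_chain_ode(g$k_syn, g$k_splice, g$k_decay, g$n, times)
    expect_equal(tr$precursor, unname(ode[, "precursor"]), tolerance = 1e-6)
    expect_equal(tr$mature, unname(ode[, "mature"]), tolerance = 1e-6)
  }
  # the degenerate k_splice == k_decay case is handled without special-casing
  p <- kinetic_params(5, 1, 1, label_offset = 0)
  tr <- simulate_labeled_abundances(p, times, include_steady_state = FALSE)
  ode <- oracle_chain_ode(5, 1, 1, 1L, times)
  expect_equal(tr$mature, unname(ode[, "mature"]), tolerance = 1e-6)
  expect_true(all(is.finite(tr$mature)))
})

test_that("multi-step maturation produces the early plateau; one step is first order", {
  times <- c(1.5, 2.5, 5)
  # a delayed multi-step unstable transcript and a background population of
  # stable first-order mRNAs; relative (depth-normalized) abundance is the
  # FPKM analogue
  cut <- simulate_labeled_abundances(
    kinetic_params(3, 0.3, 1.5, n_maturation_steps = 4, gene_id = "cut"),
    times, include_steady_state = FALSE)
  mrna <- simulate_labeled_abundances(
    kinetic_params(10, 5, 0.1, gene_id = "mrna"), times,
    include_steady_state = FALSE)
  fast1 <- simulate_labeled_abundances(
    kinetic_params(3, 5, 1.5, n_maturation_steps = 1, gene_id = "fast"),
    times, include_steady_state = FALSE)
  depth <- cut$total + mrna$total + fast1$total
  rel_cut <- cut$total / depth
  rel_fast <- fast1$total / depth
  # delayed transcript: flat within 25% across 1.5-5 min
  expect_lt(max(rel_cut) / min(rel_cut), 1.25)
  # first-order fast-decay transcript: clearly declining in relative terms
  expect_gt(rel_fast[1] / rel_fast[3], 1.5)
  # and the n = 1 trajectory is exactly first order (recovered by the fit)
  tr <- simulate_labeled_abundances(kinetic_params(8, 1e6, 0.4), c(1, 2, 4, 8, 16),
                                    include_steady_state = FALSE)
  fit <- first_order_check(pmax(0, tr$time - 0.5), tr$total)
  expect_equal(unname(fit$k), 0.4, tolerance = 0.05)
  expect_false(fit$flagged)
})

test_that("parameter validation rejects bad rates and times", {
  expect_error(kinetic_params(0, 1, 1), "k_syn")
  expect_error(kinetic_params(1, 1, 1, n_maturation_steps = 0), "n_maturation_steps")
  expect_error(kinetic_params(1, 1, 1, label_offset = -1), "label_offset")
  p <- kinetic_params(1, 1, 1)
  expect_error(simulate_labeled_abundances(p, c(2, 1)), "increasing")
})
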