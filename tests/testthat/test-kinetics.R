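test_that("splicing-speed AUC normalizes to one at steady state and is monotone", {
  for (r in c(0.1, 0.5, 0.9)) {
    expect_equal(splicing_speed_auc(r, r, r, r), 1)
  }
  expect_equal(splicing_speed_auc(0.2, 0.5, 0.8, 1.0),
               (0.35 + 1.625) / 3.5, tolerance = 1e-12)
  base <- splicing_speed_auc(0.3, 0.4, 0.5, 0.8)
  expect_gt(splicing_speed_auc(0.35, 0.4, 0.5, 0.8), base)
  expect_gt(splicing_speed_auc(0.3, 0.45, 0.5, 0.8), base)
  expect_gt(splicing_speed_auc(0.3, 0.4, 0.55, 0.8), base)
  expect_lt(splicing_speed_auc(0.3, 0.4, 0.5, 0.9), base)
  expect_error(splicing_speed_auc(0.3, 0.4, 0.5, 0), "r_ss")
  expect_error(splicing_speed_auc(-0.1, 0.4, 0.5, 1), "\\[0, 1\\]")
})

test_that("splicing_speed pivots an estimate table to per-gene AUCs", {
  est <- tibble::tibble(
    gene_id = rep("g1", 4),
    time = c(1.5, 2.5, 5, Inf),
    ratio = c(0.2, 0.5, 0.8, 1.0)
  )
  out <- splicing_speed(est)
  expect_equal(out$auc, 1.975 / 3.5)
  expect_error(splicing_speed(est[1:2, ]), "lack time point")
})

test_that("the decay proxy is the log2 weighted nascent/steady-state ratio", {
  expect_equal(decay_rate_proxy(8, 8, 8, 2), 2)
  expect_equal(decay_rate_proxy(3, 3, 3, 3), 0)
  expect_equal(decay_rate_proxy(4, 8, 16, 2, weights = "uniform"),
               log2((28 / 3) / 2), tolerance = 1e-12)
  # trapezoid default weights (0.5, 1.75, 1.25)/3.5
  expect_equal(decay_rate_proxy(4, 8, 16, 2),
               log2(((4 * 0.5 + 8 * 1.75 + 16 * 1.25) / 3.5) / 2), tolerance = 1e-12)
  expect_true(is.na(decay_rate_proxy(0, 8, 8, 2)))
  expect_true(is.na(decay_rate_proxy(8, 8, 8, 0)))
  expect_error(decay_rate_proxy(1, 1, 1, 1, weights = c(1, 2)), "3 non-negative")
})

test_that("the background bound reproduces the mass-balance formula", {
  bg <- background_bound(0.075, 0.461, 0.5)
  expect_equal(bg$m_over_n, 0.039 / 0.386, tolerance = 1e-10)
  expect_equal(bg$fraction_bound, 0.0918, tolerance = 1e-3)
  expect_equal(background_bound(0.1, 0.3, 0.5)$m_over_n, 1.0)
  expect_equal(background_bound(0.1, 0.3, 0.5)$fraction_bound, 0.5)
  expect_equal(background_bound(0.1, 0.5, 0.5)$fraction_bound, 0)
  expect_error(background_bound(0.3, 0.2), "alpha1")
  expect_error(background_bound(0.1, 0.6, 0.5), "beta")
})

test_that("the background bound is monotone in its inputs and below one", {
  a1 <- seq(0.2, 0.49, by = 0.01)
  fb <- vapply(a1, function(a) background_bound(0.075, a)$fraction_bound,
               numeric(1))
  expect_true(all(diff(fb) < 0))        # decreasing in alpha1
  betas <- seq(0.47, 0.9, by = 0.01)
  fb2 <- vapply(betas, function(b) background_bound(0.075, 0.46, b)$fraction_bound,
                numeric(1))
  expect_true(all(diff(fb2) > 0))       # increasing in beta
  expect_true(all(c(fb, fb2) < 1))
})

test_that("class decrease medians and tests behave under known shifts", {
  set.seed(11)
  n <- 60
  base <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:n),
    f1.5 = 2^rnorm(n, 5, 0.5), f2.5 = 2^rnorm(n, 4.8, 0.5),
    f5 = 2^rnorm(n, 4.5, 0.5), fss = 2^rnorm(n, 2, 0.5)
  )
  long <- function(df, cls, ss_shift = 0) {
    tidyr::pivot_longer(df, -transcript_id) |>
      dplyr::mutate(
        class = cls,
        transcript_id = paste0(cls, transcript_id),
        time = dplyr::recode(name, f1.5 = 1.5, f2.5 = 2.5, f5 = 5, fss = Inf),
        fpkm = value * ifelse(name == "fss", 2^ss_shift, 1)
      ) |>
      dplyr::select(transcript_id, class, time, fpkm)
  }
  # identical class matrices: equal medians, p ~ 1
  same <- dplyr::bind_rows(long(base, "A"), long(base, "B"))
  tab <- class_decrease_table(same)
  expect_equal(tab$median_A, tab$median_B)
  expect_true(all(tab$p_value > 0.99))
  # class B shifted by +c in log2 at steady state only
  shifted <- dplyr::bind_rows(long(base, "A"), long(base, "B", ss_shift = 1.5))
  tab2 <- class_decrease_table(shifted)
  ss_row <- tab2[is.infinite(tab2$t2), ]
  expect_equal(ss_row$median_A - ss_row$median_B, 1.5, tolerance = 1e-10)
  other <- tab2[is.finite(tab2$t2), ]
  expect_equal(other$median_A, other$median_B)
})

test_that("simulated class decreases at published medians are recovered", {
  # CUT-like and SUT-like steady-state decreases centred on 3.41 and 2.86
  set.seed(42)
  mk <- function(cls, n, med) {
    d <- rnorm(n, med, 0.8)
    tibble::tibble(
      transcript_id = rep(sprintf("%s%04d", cls, 1:n), 2), class = cls,
      time = rep(c(1.5, Inf), each = n),
      fpkm = c(2^d, rep(1, n))
    )
  }
  fpkms <- dplyr::bind_rows(mk("CUT", 900, 3.41), mk("SUT", 850, 2.86))
  tab <- class_decrease_table(fpkms, time_pairs = list(c(1.5, Inf)))
  expect_equal(tab$median_CUT, 3.41, tolerance = 0.1)
  expect_equal(tab$median_SUT, 2.86, tolerance = 0.1)
  expect_lt(tab$p_value, 1e-6)
})

test_that("class enrichment fractions use a strict threshold and report empty classes as missing", {
  de <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:10),
    class = "CUT",
    padj = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.2, 0.4, 0.6, 0.8, 1)
  )
  out <- class_enrichment_summary(de)
  expect_equal(out$fraction, 0.4)  # p = 0.05 itself is not counted
  out2 <- class_enrichment_summary(de, all_classes = c("CUT", "SUT"))
  expect_true(is.na(out2$fraction[out2$class == "SUT"]))
})

test_that("first-order fits recover rates and flag plateau trajectories", {
  times <- c(1, 2, 4, 8, 16)
  vals <- 10 * (1 - exp(-0.5 * times))
  fit <- first_order_check(times, vals)
  expect_equal(fit$k, 0.5, tolerance = 0.01)
  expect_equal(fit$a_ss, 10, tolerance = 0.01)
  expect_false(fit$flagged)
  expect_equal(glance(fit)$k, fit$k)
  # early plateau far above the eventual steady state
  plateau <- first_order_check(c(1.5, 2.5, 5, 60), c(5, 5, 5, 1))
  expect_true(plateau$flagged)
  expect_gt(plateau$relative_rmse, 0.1)
  expect_error(first_order_check(c(1, 2), c(1, 2)), "3 time points")
})
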