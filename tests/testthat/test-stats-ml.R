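test_that("thirds splits use the floor rule and stable tie-breaking", {
  df9 <- tibble::tibble(id = sprintf("t%02d", 1:9), score = 9:1)
  s9 <- thirds_split(df9, id, score)
  expect_equal(table(s9$third)[c("fastest", "middle", "slowest")],
               table(factor(rep(c("fastest", "middle", "slowest"), 3)))[
                 c("fastest", "middle", "slowest")])
  expect_setequal(s9$id[s9$third == "fastest"], c("t01", "t02", "t03"))
  df10 <- tibble::tibble(id = sprintf("t%02d", 1:10), score = runif(10))
  s10 <- thirds_split(df10, id, score)
  expect_equal(sum(s10$third == "fastest"), 3)
  expect_equal(sum(s10$third == "slowest"), 3)
  expect_equal(sum(s10$third == "middle"), 4)
  # all-equal scores: the split is determined by id order alone
  ties <- tibble::tibble(id = sprintf("t%02d", 10:1), score = 1)
  st <- thirds_split(ties, id, score)
  expect_setequal(st$id[st$third == "fastest"], c("t01", "t02", "t03"))
  expect_setequal(st$id[st$third == "slowest"], c("t08", "t09", "t10"))
})

test_that("rank-sum comparisons give exact small-sample p-values", {
  df <- tibble::tibble(id = sprintf("t%02d", 1:15), score = 15:1,
                       feature = seq(15, 1))   # distinct, fully separated
  split <- thirds_split(df, id, score)
  out <- wilcoxon_thirds(split, feature)
  # completely separated groups of 5: exact two-sided p = 2 / choose(10, 5)
  expect_equal(out$p_value, 2 / choose(10, 5), tolerance = 1e-10)
  expect_equal(out$n_fastest, 5)
  # identical groups: p ~ 1
  same <- dplyr::mutate(split, feature = rep(c(1, 2, 3, 4, 5), 3))
  expect_gt(wilcoxon_thirds(same, feature)$p_value, 0.9)
})

test_that("a calibrated structural shift reaches the reported significance regime", {
  # 27 vs 27, feature shifted by 1.5 within-group SDs
  set.seed(15)
  df <- tibble::tibble(
    id = sprintf("t%02d", 1:81), score = 81:1,
    dg = c(rnorm(27, -0.35, 0.05), rnorm(27, -0.3, 0.05), rnorm(27, -0.275, 0.05))
  )
  out <- wilcoxon_thirds(thirds_split(df, id, score), dg)
  expect_lt(out$p_value, 3e-4)
})

test_that("feature-score correlations flag perfect, null and degenerate features", {
  set.seed(21)
  n <- 80
  speed <- rnorm(n)
  df <- tibble::tibble(
    speed = speed,
    exact = speed,
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
    constant = 1
  )
  out <- feature_speed_correlations(df, speed)
  expect_equal(out$r[out$feature == "exact"], 1, tolerance = 1e-12)
  expect_lt(out$p_value[out$feature == "exact"], 1e-20)
  expect_true(is.na(out$r[out$feature == "constant"]))
  noise <- out[grepl("noise", out$feature), ]
  expect_true(all(abs(noise$r) < 0.35))
  # BH adjustment is monotone in the raw p-values
  ok <- out[!is.na(out$p_value), ]
  ord <- order(ok$p_value)
  expect_true(all(diff(ok$p_adj[ord]) >= -1e-12))
  # per-group subsets are reported alongside the pooled analysis
  df$grp <- rep(c("RP", "non-RP"), each = n / 2)
  out2 <- feature_speed_correlations(df, speed, group = "grp")
  expect_setequal(unique(out2$subset), c("all", "RP", "non-RP"))
})

test_that("naive Bayes cross-validation separates signal from null", {
  set.seed(31)
  n <- 400
  sep <- tibble::tibble(
    label = rep(c("fast", "slow"), each = n / 2),
    f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 8)),
    f2 = c(rnorm(n / 2, 0), rnorm(n / 2, -8))
  )
  fit <- nb_classifier_cv(sep, label, seed = 1)
  expect_equal(fit$auc, 1.0)
  expect_equal(glance(fit)$auc, 1.0)
  null <- dplyr::mutate(sep, f1 = rnorm(n), f2 = rnorm(n))
  fit0 <- nb_classifier_cv(null, label, seed = 2)
  expect_gt(fit0$auc, 0.4)
  expect_lt(fit0$auc, 0.6)
  roc <- tidy(fit)
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
})

test_that("duplicating features cannot inflate the cross-validated AUC on null labels", {
  set.seed(41)
  n <- 300
  df <- tibble::tibble(label = sample(rep(c("a", "b"), each = n / 2)),
                       f1 = rnorm(n), f2 = rnorm(n))
  dup <- df
  for (i in 1:8) dup[[paste0("copy", i)]] <- df$f1
  auc_dup <- nb_classifier_cv(dup, label, seed = 3)$auc
  expect_lt(auc_dup, 0.6)
})

test_that("classifier AUC rises monotonically with the generated class separation", {
  aucs <- vapply(c(0, 0.52, 3), function(sep) {
    tab <- simulate_feature_table(400, class_separation = sep, seed = 5)
    nb_classifier_cv(tab, decay_class, features = c("dg_per_nt", "length_nt"),
                     seed = 5)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(aucs[1], 0.6)
  expect_gt(aucs[3], 0.95)
})

test_that("random-forest regression recovers noiseless structure and rejects noise", {
  set.seed(51)
  n <- 150
  df <- tibble::tibble(
    x1 = runif(n), x2 = runif(n), junk1 = rnorm(n), junk2 = rnorm(n))
  df$speed <- 2 * df$x1 - 3 * df$x2
  fit <- rf_regression(df, speed, seed = 9)
  expect_gt(fit$r, 0.95)
  expect_true(all(c("x1", "x2") %in% fit$selected))
  fit_b <- rf_regression(df, speed, seed = 9)
  expect_identical(fit$predictions, fit_b$predictions)
  noise <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100),
                          speed = rnorm(100))
  fit0 <- rf_regression(noise, speed, seed = 10)
  expect_lt(abs(fit0$r), 0.15)
  expect_equal(nrow(tidy(fit)), 4)
})

test_that("K-S length comparisons behave at the extremes and in the CUT/SUT regime", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_lengths(x, x)
  expect_equal(same$d_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_lengths(1:5, 11:15)$d_statistic, 1)
  set.seed(61)
  cuts <- exp(rnorm(887, 5.85, 0.35))
  suts <- exp(rnorm(823, 6.40, 0.40))
  expect_lt(ks_lengths(cuts, suts)$p_value, 0.05)
})
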