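#' Area-under-the-curve splicing speed
#'
#' Collapses the splicing-ratio trajectory over the 1.5, 2.5 and 5 minute
#' labeling points into a single speed statistic: the trapezoidal area under
#' the trajectory, normalized by the total interval (3.5 min) and by the
#' merged steady-state ratio:
#' \deqn{AUC = \frac{(R_{2.5}+R_{1.5})/2 + 2.5 (R_{5.0}+R_{2.5})/2}{3.5\, R_{SS}}}
#' The AUC equals 1 when all nascent ratios already sit at the steady-state
#' value, and the larger the AUC, the faster the splicing. All arguments are
#' vectorized.
#'
#' @param r_1.5,r_2.5,r_5.0 Splicing ratios at the nascent time points, in
#'   `[0, 1]`.
#' @param r_ss Merged steady-state splicing ratio, in (0, 1].
#' @return Numeric AUC value(s), >= 0.
#' @export
#' @examples
#' splicing_speed_auc(0.2, 0.5, 0.8, 1.0)  # 0.5643
splicing_speed_auc <- function(r_1.5, r_2.5, r_5.0, r_ss) {
  rs <- cbind(r_1.5, r_2.5, r_5.0)
  if (any(rs < 0 | rs > 1, na.rm = TRUE)) {
    abort("Nascent splicing ratios must lie in [0, 1].")
  }
  if (any(r_ss <= 0 | r_ss > 1, na.rm = TRUE)) {
    abort("`r_ss` must lie in (0, 1].")
  }
  ((r_2.5 + r_1.5) / 2 + 2.5 * (r_5.0 + r_2.5) / 2) / (3.5 * r_ss)
}

#' Per-gene splicing speed from an estimate table
#'
#' Pivots a per-gene x time estimate table (times 1.5, 2.5, 5 and Inf for
#' the steady state) and evaluates [splicing_speed_auc()].
#'
#' @param estimates Tibble with `gene_id`, `time`, `ratio`.
#' @return Tibble `gene_id`, `r_1.5`, `r_2.5`, `r_5.0`, `r_ss`, `auc`
#'   (genes missing any of the four points are dropped).
#' @export
splicing_speed <- function(estimates) {
  assert_columns(estimates, c("gene_id", "time", "ratio"), "estimates")
  wide <- estimates |>
    mutate(tp = dplyr::case_when(
      .data$time == 1.5 ~ "r_1.5",
      .data$time == 2.5 ~ "r_2.5",
      .data$time == 5 ~ "r_5.0",
      is.infinite(.data$time) ~ "r_ss",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$tp)) |>
    select("gene_id", "tp", "ratio") |>
    tidyr::pivot_wider(names_from = "tp", values_from = "ratio")
  need <- c("r_1.5", "r_2.5", "r_5.0", "r_ss")
  missing <- setdiff(need, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("Estimates lack time point(s): %s.", paste(missing, collapse = ", ")))
  }
  wide <- wide[complete.cases(wide[, need]) & wide$r_ss > 0, , drop = FALSE]
  wide$auc <- splicing_speed_auc(wide$`r_1.5`, wide$`r_2.5`, wide$`r_5.0`, wide$r_ss)
  wide
}

#' Decay-rate proxy from nascent over steady-state expression
#'
#' For transcripts whose early kinetics depart from first order (delayed
#' multi-step degradation), early labeled expression is effectively
#' proportional to the production rate while steady-state expression equals
#' production over decay, so the log-ratio of nascent over steady-state
#' expression is a relative decay rate: the higher the nascent/steady-state
#' ratio, the faster the degradation. Computed as
#' `log2(weighted mean of the nascent FPKMs / FPKM_ss)`; the default weights
#' are the trapezoid point weights of the splicing-speed AUC
#' ((0.5, 1.75, 1.25)/3.5 at 1.5/2.5/5 min), `weights = "uniform"` uses equal
#' weights. Transcripts with any non-positive FPKM are flagged and get `NA`.
#'
#' @param fpkm_1.5,fpkm_2.5,fpkm_5.0 Nascent FPKMs (vectorized).
#' @param fpkm_ss Steady-state FPKM.
#' @param weights `"trapezoid"`, `"uniform"`, or a numeric length-3 vector.
#' @return Numeric decay proxy (log2 scale); `NA` where flagged.
#' @export
#' @examples
#' decay_rate_proxy(8, 8, 8, 2)  # 2
decay_rate_proxy <- function(fpkm_1.5, fpkm_2.5, fpkm_5.0, fpkm_ss,
                             weights = c("trapezoid", "uniform")) {
  w <- if (is.numeric(weights)) {
    if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0) {
      abort("Numeric `weights` must be 3 non-negative values with a positive sum.")
    }
    weights / sum(weights)
  } else {
    switch(match.arg(weights),
           trapezoid = c(0.5, 1.75, 1.25) / 3.5,
           uniform = rep(1 / 3, 3))
  }
  nasc <- cbind(fpkm_1.5, fpkm_2.5, fpkm_5.0)
  ok <- rowSums(nasc <= 0 | is.na(nasc)) == 0 & fpkm_ss > 0 & !is.na(fpkm_ss)
  proxy <- as.vector(log2((nasc %*% w) / fpkm_ss))
  proxy[!ok] <- NA_real_
  proxy
}

#' Upper bound on unlabeled background contamination
#'
#' In a short-labeling sample, unlabeled background RNA is overwhelmingly
#' spliced, so it dilutes the intronic signal. Writing `alpha0` for the
#' measured intronic FPKM fraction of the background (0 min) sample,
#' `alpha1` for that of the labeled sample, and `beta` for the (unknown)
#' intronic fraction of the true signal, mass balance over background (`m`)
#' and signal (`n`) gives `m/n = (beta - alpha1) / (alpha1 - alpha0)`; with
#' the theoretical worst case `beta = 0.5` this bounds the background
#' fraction of the sample at `(m/n) / (1 + m/n)`.
#'
#' @param alpha0 Intronic FPKM fraction in the background sample, `[0, 1)`.
#' @param alpha1 Intronic FPKM fraction in the labeled sample; must exceed
#'   `alpha0`.
#' @param beta Worst-case intronic fraction of the signal (default 0.5,
#'   attained if spliced intronic RNA decayed as fast as mature mRNA); must
#'   be at least `alpha1`.
#' @return One-row tibble: `alpha0`, `alpha1`, `beta`, `m_over_n`,
#'   `fraction_bound` (in `[0, 1)`).
#' @export
#' @examples
#' background_bound(0.075, 0.461)  # fraction_bound ~ 0.092
background_bound <- function(alpha0, alpha1, beta = 0.5) {
  assert_scalar_number(alpha0, "alpha0", lower = 0, upper = 1, strict_upper = TRUE)
  assert_scalar_number(alpha1, "alpha1", lower = 0, upper = 1)
  assert_scalar_number(beta, "beta", lower = 0, upper = 1)
  if (alpha1 <= alpha0) {
    abort("`alpha1` must exceed `alpha0` (no labeling signal otherwise).")
  }
  if (beta < alpha1) {
    abort("`beta` must be at least `alpha1` for a non-negative bound.")
  }
  m_over_n <- (beta - alpha1) / (alpha1 - alpha0)
  tibble(
    alpha0 = alpha0, alpha1 = alpha1, beta = beta,
    m_over_n = m_over_n,
    fraction_bound = m_over_n / (1 + m_over_n)
  )
}

#' Median expression decreases between time points, by transcript class
#'
#' For each transcript class and each pair of time points, computes the
#' median over transcripts of `log2(FPKM at t1) - log2(FPKM at t2)` (the
#' "decrease" from the earlier to the later point), and a Welch two-sample
#' t-test comparing the per-transcript decreases between the two classes.
#'
#' @param fpkms Long tibble: `transcript_id`, `class`, `time` (numeric, Inf
#'   for steady state), `fpkm`.
#' @param time_pairs List of `c(t1, t2)` pairs (default the study design:
#'   1.5 vs 2.5, 1.5 vs 5, 1.5 vs steady state).
#' @param classes Character vector of exactly two classes to compare
#'   (default the two classes present).
#' @return Tibble: `t1`, `t2`, one `median_<class>` column per class,
#'   `t_statistic`, `p_value`.
#' @export
class_decrease_table <- function(fpkms,
                                 time_pairs = list(c(1.5, 2.5), c(1.5, 5), c(1.5, Inf)),
                                 classes = NULL) {
  assert_columns(fpkms, c("transcript_id", "class", "time", "fpkm"), "fpkms")
  classes <- classes %||% sort(unique(fpkms$class))
  if (length(classes) != 2) abort("Exactly two classes are compared.")
  rows <- lapply(time_pairs, function(pr) {
    wide <- fpkms |>
      filter(.data$time %in% pr, .data$class %in% classes, .data$fpkm > 0) |>
      mutate(which_t = ifelse(.data$time == pr[1], "t1", "t2")) |>
      select("transcript_id", "class", "which_t", "fpkm") |>
      tidyr::pivot_wider(names_from = "which_t", values_from = "fpkm")
    if (!all(c("t1", "t2") %in% names(wide))) {
      abort(sprintf("No data for time pair (%s, %s).", pr[1], pr[2]))
    }
    wide <- wide[complete.cases(wide), , drop = FALSE]
    wide$decrease <- log2(wide$t1) - log2(wide$t2)
    d1 <- wide$decrease[wide$class == classes[1]]
    d2 <- wide$decrease[wide$class == classes[2]]
    tt <- if (sd(c(d1, d2)) == 0) {
      list(statistic = c(t = 0), p.value = 1)
    } else {
      t.test(d1, d2)  # Welch
    }
    out <- tibble(t1 = pr[1], t2 = pr[2])
    out[[paste0("median_", classes[1])]] <- median(d1)
    out[[paste0("median_", classes[2])]] <- median(d2)
    out$t_statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
    out
  })
  bind_rows(rows)
}

#' Fraction of each transcript class called enriched
#'
#' Given per-transcript adjusted p-values from an external differential
#' caller, counts the transcripts of each class with `padj < p_thresh`
#' (strict) and divides by the class size. Classes with no transcripts are
#' reported with `NA` fraction, not zero.
#'
#' @param de Tibble: `transcript_id`, `class`, `padj`.
#' @param p_thresh Adjusted p-value threshold (default 0.05).
#' @param all_classes Optional class universe to report (defaults to the
#'   classes present).
#' @return Tibble `class`, `n_total`, `n_enriched`, `fraction`.
#' @export
class_enrichment_summary <- function(de, p_thresh = 0.05, all_classes = NULL) {
  assert_columns(de, c("transcript_id", "class", "padj"), "de")
  all_classes <- all_classes %||% sort(unique(de$class))
  counted <- de |>
    group_by(.data$class) |>
    summarise(n_total = n(),
              n_enriched = sum(.data$padj < p_thresh, na.rm = TRUE),
              .groups = "drop")
  out <- left_join(tibble(class = all_classes), counted, by = "class")
  out$n_total <- tidyr::replace_na(out$n_total, 0L)
  out$n_enriched <- tidyr::replace_na(out$n_enriched, 0L)
  out$fraction <- ifelse(out$n_total > 0, out$n_enriched / out$n_total, NA_real_)
  out
}

#' Goodness of fit of first-order labeled accumulation
#'
#' Fits the first-order labeling model `A(t) = A_ss (1 - exp(-k t))` to an
#' expression trajectory by nonlinear least squares and reports the rate,
#' the asymptote, and a residual statistic, so that trajectories
#' incompatible with first-order kinetics (e.g. an early plateau above the
#' steady state) can be flagged.
#'
#' @param times Labeling times in minutes (>= 3 points).
#' @param values Labeled abundance/FPKM at those times.
#' @param flag_threshold Relative RMSE above which the trajectory is flagged
#'   non-first-order (default 0.1).
#' @return An object of class `tu_first_order`: list with `k`, `a_ss`,
#'   `rmse`, `relative_rmse`, `flagged`, `fitted`, `times`, `values`.
#'   [tidy()] and [glance()] methods are available.
#' @export
first_order_check <- function(times, values, flag_threshold = 0.1) {
  if (length(times) != length(values)) abort("`times` and `values` must match.")
  if (length(times) < 3) {
    abort("At least 3 time points are needed to assess first-order kinetics.")
  }
  if (any(times <= 0)) abort("`times` must be positive.")
  a0 <- max(values)
  k0 <- 1 / stats::median(times)
  fit <- minpack.lm::nlsLM(
    values ~ a_ss * (1 - exp(-k * times)),
    start = list(a_ss = a0, k = k0),
    lower = c(a_ss = 1e-12, k = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  fitted <- est[["a_ss"]] * (1 - exp(-est[["k"]] * times))
  rmse <- sqrt(mean((values - fitted)^2))
  rel <- rmse / mean(abs(values))
  structure(
    list(k = est[["k"]], a_ss = est[["a_ss"]], rmse = rmse,
         relative_rmse = rel, flagged = rel > flag_threshold,
         fitted = fitted, times = times, values = values),
    class = "tu_first_order"
  )
}

#' @export
print.tu_first_order <- function(x, ...) {
  cat(sprintf(
    "First-order accumulation fit: k = %.4g /min, A_ss = %.4g, relative RMSE = %.3g%s\n",
    x$k, x$a_ss, x$relative_rmse,
    if (x$flagged) " [flagged: departs from first order]" else ""
  ))
  invisible(x)
}
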