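#' Split ranked transcripts into fastest/middle/slowest thirds
#'
#' Ranks by `score` (descending: highest score = "fastest") and labels the
#' top and bottom `floor(n/3)` as the fastest and slowest thirds. Ties are
#' broken by a stable sort on `id`, so the split is deterministic.
#'
#' @param df Data frame with an id column and a score column.
#' @param id,score Column names (tidy-eval) for the identifier and the
#'   ranking score.
#' @return `df` with an added `third` column (`fastest`/`middle`/`slowest`).
#' @export
thirds_split <- function(df, id, score) {
  id <- rlang::enquo(id); score <- rlang::enquo(score)
  ids <- dplyr::pull(df, !!id)
  sc <- dplyr::pull(df, !!score)
  ord <- order(-sc, ids)
  n <- nrow(df)
  k <- floor(n / 3)
  third <- rep("middle", n)
  third[ord[seq_len(k)]] <- "fastest"
  third[ord[seq(n - k + 1, n)]] <- "slowest"
  df$third <- third
  df
}

#' Rank-sum comparison of a feature between the extreme thirds
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of `feature` between the
#' fastest and slowest thirds of a [thirds_split()] table, exact for small
#' samples without ties.
#'
#' @param df Output of [thirds_split()].
#' @param feature Column name (tidy-eval) of the feature to compare.
#' @return One-row tibble: `statistic` (W), `p_value`, `n_fastest`,
#'   `n_slowest`, `median_fastest`, `median_slowest`.
#' @export
wilcoxon_thirds <- function(df, feature) {
  assert_columns(df, "third", "df")
  feature <- rlang::enquo(feature)
  x <- dplyr::pull(filter(df, .data$third == "fastest"), !!feature)
  y <- dplyr::pull(filter(df, .data$third == "slowest"), !!feature)
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_fastest = length(x), n_slowest = length(y),
    median_fastest = median(x), median_slowest = median(y)
  )
}

#' Pearson correlations of every feature with a kinetic score
#'
#' Correlates each feature column with the score column, overall and within
#' each level of an optional grouping column (e.g. RP vs non-RP), reporting
#' the Pearson r, the raw p-value, and a Benjamini-Hochberg adjusted
#' p-value per subset. Features with zero variance in a subset are reported
#' with `NA`.
#'
#' @param df Data frame containing the score, the features and optionally a
#'   grouping column.
#' @param score Column name (tidy-eval) of the kinetic score.
#' @param features Character vector of feature column names (default: all
#'   numeric columns except the score and group).
#' @param group Optional column name (character) defining subsets; the
#'   overall subset is always reported as `"all"`.
#' @return Tibble `subset`, `feature`, `n`, `r`, `p_value`, `p_adj`.
#' @export
feature_speed_correlations <- function(df, score, features = NULL, group = NULL) {
  score <- rlang::enquo(score)
  score_name <- rlang::as_name(score)
  if (is.null(features)) {
    numeric_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    features <- setdiff(numeric_cols, c(score_name, group))
  }
  subsets <- list(all = rep(TRUE, nrow(df)))
  if (!is.null(group)) {
    for (g in sort(unique(df[[group]]))) subsets[[g]] <- df[[group]] == g
  }
  rows <- list()
  for (s in names(subsets)) {
    sub <- df[subsets[[s]], , drop = FALSE]
    y <- dplyr::pull(sub, !!score)
    res <- lapply(features, function(f) {
      x <- sub[[f]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        return(tibble(subset = s, feature = f, n = sum(ok),
                      r = NA_real_, p_value = NA_real_))
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      tibble(subset = s, feature = f, n = sum(ok),
             r = unname(ct$estimate), p_value = ct$p.value)
    })
    res <- bind_rows(res)
    res$p_adj <- p.adjust(res$p_value, method = "BH")
    rows[[s]] <- res
  }
  bind_rows(rows)
}

#' Cross-validated Gaussian naive Bayes classification with ROC/AUC
#'
#' Stratified `folds`-fold cross-validation of a Gaussian naive Bayes
#' classifier on continuous features; out-of-fold posterior scores are
#' pooled into a single ROC curve and AUC, so no in-sample prediction ever
#' enters the performance estimate.
#'
#' @param df Data frame of features plus a binary label column.
#' @param label Column name (tidy-eval) of the binary class label.
#' @param features Character vector of feature columns (default: all
#'   numeric columns).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return Object of class `tu_nb_cv`: list with `auc`, `roc` (tibble of
#'   ROC points), `scores` (out-of-fold scores), `folds`, `n`, `features`.
#'   [tidy()] returns the ROC points, [glance()] the AUC.
#' @export
nb_classifier_cv <- function(df, label, features = NULL, folds = 10L, seed = 1L) {
  label <- rlang::enquo(label)
  y <- factor(dplyr::pull(df, !!label))
  if (nlevels(y) != 2) abort("`label` must have exactly two classes.")
  label_name <- rlang::as_name(label)
  if (is.null(features)) {
    features <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], label_name)
  }
  x <- as.data.frame(df[, features, drop = FALSE])
  fold_id <- stratified_folds(y, folds, seed)
  if (min(table(y, fold_id)) < 1) {
    abort("Each fold needs at least one sample of each class.")
  }
  pos <- levels(y)[2]
  score <- numeric(length(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- e1071::naiveBayes(x[!test, , drop = FALSE], y[!test])
    pr <- predict(fit, x[test, , drop = FALSE], type = "raw")
    score[test] <- pr[, pos]
  }
  roc_obj <- pROC::roc(response = y, predictor = score, levels = levels(y),
                       direction = "<", quiet = TRUE)
  structure(
    list(
      auc = as.numeric(pROC::auc(roc_obj)),
      roc = tibble(
        threshold = roc_obj$thresholds,
        fpr = 1 - roc_obj$specificities,
        tpr = roc_obj$sensitivities
      ),
      scores = tibble(label = y, score = score, fold = fold_id),
      folds = folds, n = length(y), features = features
    ),
    class = "tu_nb_cv"
  )
}

stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  with_seed(derive_seed(seed, 606L), {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

#' @export
print.tu_nb_cv <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes, %d-fold CV on %d samples: AUC = %.3f\n",
              x$folds, x$n, x$auc))
  invisible(x)
}

#' Random-forest regression of a kinetic score with feature selection
#'
#' Fits a random forest to the features, selects the features whose
#' permutation importance (%IncMSE) exceeds `importance_threshold`, refits
#' on the selected set, and reports out-of-bag predictions only — in-sample
#' predictions never enter the performance estimate. If no feature passes
#' the threshold the full model is kept and flagged.
#'
#' @param df Data frame of features plus the response column.
#' @param response Column name (tidy-eval) of the kinetic score.
#' @param features Character vector of feature columns (default: all other
#'   numeric columns).
#' @param n_trees Trees per forest (default 500).
#' @param importance_threshold %IncMSE cutoff for selection (default 2).
#' @param seed Integer seed.
#' @return Object of class `tu_rf`: list with `r` (Pearson r of observed vs
#'   out-of-bag predicted), `predictions` tibble, `selected` features,
#'   `importance` tibble, `selection_failed` flag. [tidy()] returns the
#'   importance table, [glance()] the fit summary.
#' @export
rf_regression <- function(df, response, features = NULL, n_trees = 500L,
                          importance_threshold = 2, seed = 1L) {
  response <- rlang::enquo(response)
  y <- dplyr::pull(df, !!response)
  response_name <- rlang::as_name(response)
  if (is.null(features)) {
    features <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], response_name)
  }
  x <- as.data.frame(df[, features, drop = FALSE])
  with_seed(derive_seed(seed, 707L), {
    fit0 <- randomForest::randomForest(x, y, ntree = n_trees, importance = TRUE)
    imp <- randomForest::importance(fit0, type = 1)  # %IncMSE
    selected <- rownames(imp)[imp[, 1] > importance_threshold]
    selection_failed <- length(selected) == 0
    if (selection_failed) selected <- features
    fit <- randomForest::randomForest(x[, selected, drop = FALSE], y,
                                      ntree = n_trees)
    oob <- predict(fit)  # OOB predictions
  })
  structure(
    list(
      r = suppressWarnings(cor(y, oob)),
      predictions = tibble(observed = y, predicted_oob = oob),
      selected = selected,
      importance = tibble(feature = rownames(imp), inc_mse = imp[, 1]),
      selection_failed = selection_failed,
      n_trees = n_trees, n = length(y)
    ),
    class = "tu_rf"
  )
}

#' @export
print.tu_rf <- function(x, ...) {
  cat(sprintf(
    "Random-forest regression (%d trees, %d samples): out-of-bag r = %.3f; selected: %s\n",
    x$n_trees, x$n, x$r, paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of two length distributions
#'
#' @param lengths_a,lengths_b Numeric samples (e.g. CUT and SUT transcript
#'   lengths).
#' @return One-row tibble: `d_statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_lengths <- function(lengths_a, lengths_b) {
  kt <- suppressWarnings(ks.test(lengths_a, lengths_b))
  tibble(d_statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(lengths_a), n_b = length(lengths_b))
}
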