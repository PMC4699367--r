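#' Tidy a cross-validated naive Bayes classifier
#'
#' @param x A `tu_nb_cv` object.
#' @param ... Unused.
#' @return The pooled out-of-fold ROC points as a tibble.
#' @export
tidy.tu_nb_cv <- function(x, ...) x$roc

#' @rdname tidy.tu_nb_cv
#' @return For `glance()`: a one-row tibble with `auc`, `folds`, `n`.
#' @export
glance.tu_nb_cv <- function(x, ...) {
  tibble(auc = x$auc, folds = x$folds, n = x$n)
}

#' Tidy a random-forest kinetic regression
#'
#' @param x A `tu_rf` object.
#' @param ... Unused.
#' @return Per-feature permutation importance with a `selected` flag.
#' @export
tidy.tu_rf <- function(x, ...) {
  mutate(x$importance, selected = .data$feature %in% x$selected)
}

#' @rdname tidy.tu_rf
#' @return For `glance()`: one-row tibble with the out-of-bag Pearson `r`,
#'   `n`, `n_trees`, `n_selected`, `selection_failed`.
#' @export
glance.tu_rf <- function(x, ...) {
  tibble(r = x$r, n = x$n, n_trees = x$n_trees,
         n_selected = length(x$selected),
         selection_failed = x$selection_failed)
}

#' Tidy a first-order accumulation fit
#'
#' @param x A `tu_first_order` object.
#' @param ... Unused.
#' @return Per-time observed and fitted values with residuals.
#' @export
tidy.tu_first_order <- function(x, ...) {
  tibble(time = x$times, observed = x$values, fitted = x$fitted,
         residual = x$values - x$fitted)
}

#' @rdname tidy.tu_first_order
#' @return For `glance()`: one-row tibble with `k`, `a_ss`, `rmse`,
#'   `relative_rmse`, `flagged`.
#' @export
glance.tu_first_order <- function(x, ...) {
  tibble(k = x$k, a_ss = x$a_ss, rmse = x$rmse,
         relative_rmse = x$relative_rmse, flagged = x$flagged)
}
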