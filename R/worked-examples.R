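#' Worked examples: the small in-text calculations of a 4tU yield experiment
#'
#' Reproduces three desk calculations from the published yield measurements
#' of an ultra-short 4tU labeling time course, using the package's own
#' statistics: (i) the ordinary-least-squares R-squared of recovered RNA
#' yield against labeling time, (ii) the fold enrichment of the 1.5-min
#' yield over the unlabeled (0-min) background, and (iii) the upper bound
#' on unlabeled background contamination from the measured intronic FPKM
#' fractions via [background_bound()].
#'
#' @param yield_minutes,yield_ug The yield time course: labeling times
#'   (min) and recovered RNA (micrograms). Defaults are the published
#'   measurements (average of two experiments) of the 600-ml cultures:
#'   0.50, 0.77, 1.16, 3.30 and 4.52 ug at 0, 1, 1.5, 5 and 10 min.
#' @param alpha0,alpha1 Measured intronic FPKM fractions of the background
#'   and 1.5-min samples (defaults: the published 7.5% and 46.1%).
#' @param beta Worst-case signal intronic fraction (default 0.5).
#' @return A tibble with one row per example: `quantity`, `value`, `units`,
#'   `detail`.
#' @export
#' @examples
#' worked_examples()
worked_examples <- function(yield_minutes = c(0, 1, 1.5, 5, 10),
                            yield_ug = c(0.50, 0.77, 1.16, 3.30, 4.52),
                            alpha0 = 0.075, alpha1 = 0.461, beta = 0.5) {
  if (length(yield_minutes) != length(yield_ug)) {
    abort("`yield_minutes` and `yield_ug` must have the same length.")
  }
  fit <- lm(yield_ug ~ yield_minutes)
  r2 <- summary(fit)$r.squared
  enrich <- yield_ug[yield_minutes == 1.5] / yield_ug[yield_minutes == 0]
  bg <- background_bound(alpha0, alpha1, beta)
  tibble(
    quantity = c("yield_fit_r_squared", "fold_enrichment_1.5min",
                 "background_bound_percent"),
    value = c(r2, enrich, 100 * bg$fraction_bound),
    units = c("R^2", "fold", "%"),
    detail = c(
      sprintf("OLS of yield (ug) on labeling time over %d points", length(yield_ug)),
      "1.5-min yield over 0-min (unlabeled background) yield",
      sprintf("m/n = (%.3g - %.3g)/(%.3g - %.3g) = %.4f; bound = (m/n)/(1 + m/n)",
              beta, alpha1, alpha1, alpha0, bg$m_over_n)
    )
  )
}
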