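#' Comparison-adjusted funnel-plot data
#'
#' Centers every contrast on the fixed-effect pooled direct estimate of its
#' own comparison, so that contrasts from different comparisons share a
#' common zero and small-study asymmetry can be inspected on one plot.
#' Within each comparison the inverse-variance weighted mean of the
#' centered effects is exactly zero; single-study comparisons center to 0.
#' Fixed-effect centering is used regardless of the heterogeneity rule: the
#' funnel asks about asymmetry around the common effect.
#'
#' @param dataset An [outcome_dataset()] with contrast evidence.
#' @param level Level for the pseudo-confidence guide lines.
#' @return A list with `points` (data frame: `study`, `treatment`,
#'   `reference`, `centered_effect`, `se`) and `guide` (data frame of
#'   `se`, `lower`, `upper` limits `0 +/- z * se`).
#' @export
funnel_points <- function(dataset, level = 0.95) {
  stopifnot(inherits(dataset, "outcome_dataset"))
  co <- dataset$contrasts
  if (is.null(co) || nrow(co) == 0)
    stop("funnel data need at least one contrast")
  key <- paste(co$treatment, co$reference, sep = " vs ")
  centered <- numeric(nrow(co))
  for (k in unique(key)) {
    idx <- which(key == k)
    pooled <- pool_fixed_iv(co[idx, , drop = FALSE])$estimate
    centered[idx] <- co$estimate[idx] - pooled
  }
  z <- stats::qnorm((1 + level) / 2)
  se_grid <- seq(0, max(co$std_err) * 1.05, length.out = 50)
  list(points = data.frame(study = co$study, treatment = co$treatment,
                           reference = co$reference,
                           centered_effect = centered, se = co$std_err),
       guide = data.frame(se = se_grid, lower = -z * se_grid,
                          upper = z * se_grid))
}
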