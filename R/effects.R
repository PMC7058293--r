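#' Log effect and standard error from a reported ratio and confidence interval
#'
#' Recovers a log hazard ratio (or log odds ratio) and its standard error from
#' a published point estimate with a symmetric-on-the-log-scale confidence
#' interval, the first of the standard summary-based extraction methods for
#' survival endpoints. The standard error is the log-scale interval width
#' divided by twice the two-sided normal quantile at the interval's level.
#'
#' @param point Point estimate on the natural (ratio) scale, > 0.
#' @param lower,upper Confidence bounds on the natural scale,
#'   `0 < lower <= point <= upper`.
#' @param level Confidence level of the interval, in (0, 1). Default 0.95,
#'   matching the 95% intervals reported throughout the trial literature.
#' @return A list with elements `estimate` (log scale) and `std_err`.
#' @examples
#' effect_from_ci(0.69, 0.55, 0.87)
#' @export
effect_from_ci <- function(point, lower, upper, level = 0.95) {
  stopifnot(length(point) == 1, length(lower) == 1, length(upper) == 1)
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1")
  if (!all(is.finite(c(point, lower, upper))) || lower <= 0)
    stop("ratio and confidence bounds must be finite and positive")
  if (!(lower <= point && point <= upper))
    stop("confidence bounds must satisfy lower <= point <= upper")
  if (lower == upper)
    stop("degenerate interval (lower == upper) carries no standard error")
  z <- stats::qnorm((1 + level) / 2)
  list(estimate = log(point), std_err = (log(upper) - log(lower)) / (2 * z))
}

#' Log effect and standard error from a log-rank p-value and event counts
#'
#' Reconstructs a log hazard ratio when only a two-sided log-rank p-value,
#' the total number of events and the arm sizes are reported. The variance of
#' the log hazard ratio is approximated by the inverse of
#' `V = events * n1 * n2 / (n1 + n2)^2` (the null log-rank variance), and the
#' estimate is the signed normal deviate of the p-value scaled by `1/sqrt(V)`.
#'
#' @param p_two_sided Two-sided p-value in (0, 1].
#' @param events_total Total observed events across both arms.
#' @param n1,n2 Numbers randomized per arm.
#' @param favours_treatment If `TRUE` (default) the observed effect favours
#'   the treatment arm and the log hazard ratio is negative.
#' @return A list with elements `estimate` and `std_err`.
#' @examples
#' effect_from_pvalue_events(0.05, 100, 200, 200)
#' @export
effect_from_pvalue_events <- function(p_two_sided, events_total, n1, n2,
                                      favours_treatment = TRUE) {
  if (!is.finite(p_two_sided) || p_two_sided <= 0 || p_two_sided > 1)
    stop("'p_two_sided' must lie in (0, 1]")
  if (events_total < 1) stop("'events_total' must be at least 1")
  if (n1 < 1 || n2 < 1) stop("arm sizes must be at least 1")
  v <- events_total * n1 * n2 / (n1 + n2)^2
  z <- stats::qnorm(1 - p_two_sided / 2)
  sgn <- if (isTRUE(favours_treatment)) -1 else 1
  list(estimate = sgn * z / sqrt(v), std_err = 1 / sqrt(v))
}

#' Tabulated Kaplan-Meier summary for one trial arm
#'
#' Container for an already-digitized survival curve: survival probabilities
#' on a time grid, with optional numbers at risk and an optional maximum
#' follow-up used for the censoring adjustment when numbers at risk are not
#' reported. `S(0) = 1` is implicit and must not be included in the grid.
#'
#' @param label Arm label.
#' @param time Increasing positive time grid (months).
#' @param surv Survival probabilities in (0, 1], non-increasing.
#' @param n_risk Optional numbers at risk at each grid time.
#' @param n_start Number of patients at time zero (required when `n_risk` is
#'   absent).
#' @param max_followup Optional maximum follow-up (months) for the
#'   uniform-accrual censoring adjustment used when `n_risk` is absent.
#' @return An object of class `km_summary`.
#' @export
km_summary <- function(label, time, surv, n_risk = NULL, n_start = NULL,
                       max_followup = NULL) {
  if (length(time) != length(surv) || length(time) < 1)
    stop("'time' and 'surv' must be non-empty and of equal length")
  if (any(diff(time) <= 0) || any(time <= 0))
    stop("'time' must be positive and strictly increasing")
  if (any(!is.finite(surv)) || any(surv <= 0) || any(surv > 1))
    stop("'surv' must lie in (0, 1]")
  if (any(diff(surv) > 1e-12)) stop("'surv' must be non-increasing")
  if (!is.null(n_risk) && length(n_risk) != length(time))
    stop("'n_risk' must match the time grid")
  if (is.null(n_risk) && is.null(n_start))
    stop("either 'n_risk' or 'n_start' is required")
  structure(list(label = label, time = time, surv = surv, n_risk = n_risk,
                 n_start = n_start, max_followup = max_followup),
            class = "km_summary")
}

#' @export
print.km_summary <- function(x, ...) {
  cat("Kaplan-Meier summary:", x$label, "-", length(x$time), "grid points,",
      "S(last) =", format(x$surv[length(x$surv)], digits = 3), "\n")
  invisible(x)
}

# Effective number at risk at interval start. Reported numbers at risk are
# used when present; otherwise n_start * S(t), deflated by the
# uniform-accrual censoring factor (1 - t / (2 * max_followup)) when a
# follow-up window is given.
km_effective_n <- function(km, idx, t0, s0) {
  if (!is.null(km$n_risk)) {
    if (idx == 0) if (!is.null(km$n_start)) return(km$n_start) else return(km$n_risk[1])
    return(km$n_risk[idx])
  }
  n <- km$n_start * s0
  if (!is.null(km$max_followup) && km$max_followup > 0)
    n <- n * max(0, 1 - t0 / (2 * km$max_followup))
  n
}

#' Log hazard ratio from paired Kaplan-Meier summaries
#'
#' Estimates a log hazard ratio from two tabulated survival curves sharing a
#' time grid, the curve-based member of the summary-extraction family. The
#' grid is cut into non-overlapping intervals; within each interval the
#' conditional survival drop gives an interval log hazard ratio
#' `log(log S_t(b)/S_t(a)) - log(log S_c(b)/S_c(a))` (equal under
#' proportional hazards to the common log hazard ratio), with variance
#' `1/e_c + 1/e_t` from the expected events
#' `e = n_eff * (S(a) - S(b)) / S(a)` in each arm. Intervals in which either
#' arm has fewer than one expected event, or no drop in survival, are
#' dropped; the remaining interval estimates are pooled by inverse variance.
#'
#' @param control,treated `km_summary` objects on a common time grid.
#' @return A list with `estimate`, `std_err`, and `n_intervals` used.
#' @export
effect_from_km <- function(control, treated) {
  stopifnot(inherits(control, "km_summary"), inherits(treated, "km_summary"))
  if (length(control$time) != length(treated$time) ||
      any(control$time != treated$time))
    stop("both curves must share one time grid")
  tt <- c(0, control$time)
  sc <- c(1, control$surv)
  st <- c(1, treated$surv)
  est <- var <- numeric(0)
  for (j in seq_along(control$time)) {
    a <- j; b <- j + 1L
    dc <- log(sc[b]) - log(sc[a])   # -(interval cumulative hazard), control
    dt <- log(st[b]) - log(st[a])
    if (dc >= 0 || dt >= 0) next    # no survival drop in one arm
    ec <- km_effective_n(control, j - 1L, tt[a], sc[a]) * (sc[a] - sc[b]) / sc[a]
    et <- km_effective_n(treated, j - 1L, tt[a], st[a]) * (st[a] - st[b]) / st[a]
    if (ec < 1 || et < 1) next
    est <- c(est, log(dt / dc))
    var <- c(var, 1 / ec + 1 / et)
  }
  if (length(est) < 1) stop("fewer than 1 usable interval between the curves")
  w <- 1 / var
  list(estimate = sum(w * est) / sum(w), std_err = 1 / sqrt(sum(w)),
       n_intervals = length(est))
}
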