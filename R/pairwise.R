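#' @title Direct pairwise meta-analysis
#' @description Classical head-to-head pooling of the contrasts observed for
#'   one comparison: inverse-variance fixed effect, DerSimonian-Laird random
#'   effects, Mantel-Haenszel odds-ratio pooling for 2x2 tables, Cochran's Q
#'   with Higgins' I-squared, and the heterogeneity-driven model choice rule
#'   (random effects when I-squared exceeds 50% and/or the Q test is
#'   significant at 0.05).
#' @name pairwise
NULL

check_effects <- function(effects, min_k = 1) {
  stopifnot(is.data.frame(effects))
  need <- c("estimate", "std_err")
  miss <- setdiff(need, names(effects))
  if (length(miss)) stop("effects lack columns: ", paste(miss, collapse = ", "))
  if (nrow(effects) < min_k)
    stop("at least ", min_k, " effects are required")
  if (all(c("treatment", "reference") %in% names(effects))) {
    cmp <- unique(paste(effects$treatment, effects$reference))
    if (length(cmp) > 1)
      stop("effects mix comparisons: ", paste(cmp, collapse = "; "))
  }
  invisible(effects)
}

pairwise_result <- function(effects, model, est, se, tau2, level) {
  z <- stats::qnorm((1 + level) / 2)
  q <- if (nrow(effects) >= 2) cochran_q(effects) else
    list(Q = NA_real_, df = NA_integer_, p = NA_real_, I2 = NA_real_)
  structure(list(
    treatment = if ("treatment" %in% names(effects)) effects$treatment[1] else NA,
    reference = if ("reference" %in% names(effects)) effects$reference[1] else NA,
    k = nrow(effects), model = model,
    estimate = est, std_err = se,
    ci_lower = est - z * se, ci_upper = est + z * se, level = level,
    Q = q$Q, df = q$df, p_Q = q$p, I2 = q$I2, tau2 = tau2),
    class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s, k = %d): %.3f [%.3f, %.3f] natural %.3f [%.3f, %.3f]\n",
              x$treatment, x$reference, x$model, x$k, x$estimate,
              x$ci_lower, x$ci_upper, exp(x$estimate), exp(x$ci_lower),
              exp(x$ci_upper)))
  if (!is.na(x$Q))
    cat(sprintf("  Q = %.3f (df %d, p = %.3f), I2 = %.1f%%, tau2 = %.4f\n",
                x$Q, x$df, x$p_Q, x$I2, if (is.na(x$tau2)) 0 else x$tau2))
  invisible(x)
}

#' Inverse-variance fixed-effect pooling
#'
#' @param effects Data frame of log-scale effects with columns `estimate`
#'   and `std_err` (optionally `treatment`/`reference`, which must then be
#'   constant).
#' @param level Confidence level for the pooled interval.
#' @return A `pairwise_result` with the pooled log estimate
#'   `sum(w * y) / sum(w)`, `w = 1/SE^2`, and standard error
#'   `sum(w)^(-1/2)`.
#' @rdname pairwise
#' @export
pool_fixed_iv <- function(effects, level = 0.95) {
  check_effects(effects, 1)
  w <- 1 / effects$std_err^2
  est <- sum(w * effects$estimate) / sum(w)
  pairwise_result(effects, "fixed", est, 1 / sqrt(sum(w)), NA_real_, level)
}

#' Cochran's Q heterogeneity test and Higgins' I-squared
#'
#' @return For `cochran_q`, a list with `Q`, `df`, `p` (upper-tail
#'   chi-squared) and `I2` in percent, `max(0, (Q - df)/Q) * 100`.
#' @rdname pairwise
#' @export
cochran_q <- function(effects) {
  check_effects(effects, 2)
  w <- 1 / effects$std_err^2
  yhat <- sum(w * effects$estimate) / sum(w)
  Q <- sum(w * (effects$estimate - yhat)^2)
  df <- nrow(effects) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0)
}

#' DerSimonian-Laird random-effects pooling
#'
#' The method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` re-weights the
#' inverse-variance pool with `w* = 1/(SE^2 + tau2)`.
#'
#' @rdname pairwise
#' @export
pool_random_dl <- function(effects, level = 0.95) {
  check_effects(effects, 2)
  w <- 1 / effects$std_err^2
  q <- cochran_q(effects)
  tau2 <- max(0, (q$Q - q$df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (effects$std_err^2 + tau2)
  est <- sum(ws * effects$estimate) / sum(ws)
  pairwise_result(effects, "random", est, 1 / sqrt(sum(ws)), tau2, level)
}

#' Mantel-Haenszel fixed-effect odds-ratio pooling
#'
#' Pools one 2x2 table per study for a single comparison. The variance of
#' the pooled log odds ratio uses the Robins-Breslow-Greenland estimator. A
#' 0.5 continuity correction is added to all four cells of a table only when
#' that table contains a zero cell; tables with zero events (or zero
#' non-events) in both arms are excluded.
#'
#' @param arms Data frame of binary arms (`study`, `treatment`, `events`,
#'   `total`) with exactly two arms per study, the same two treatments
#'   throughout.
#' @param treatment,reference Treatment ids defining the odds-ratio
#'   orientation (treatment vs reference); defaults to the two ids present.
#' @rdname pairwise
#' @export
pool_mh_or <- function(arms, treatment = NULL, reference = NULL, level = 0.95) {
  stopifnot(is.data.frame(arms))
  ids <- unique(arms$treatment)
  if (length(ids) != 2) stop("arms must contain exactly two treatments")
  if (is.null(treatment)) treatment <- ids[1]
  if (is.null(reference)) reference <- setdiff(ids, treatment)
  stopifnot(treatment %in% ids, reference %in% ids, treatment != reference)
  studies <- unique(arms$study)
  a <- b <- cc <- d <- numeric(0)
  for (s in studies) {
    rs <- arms[arms$study == s, ]
    if (nrow(rs) != 2 || !setequal(rs$treatment, ids))
      stop("study ", s, " does not contribute one 2x2 table")
    tr <- rs[rs$treatment == treatment, ]
    co <- rs[rs$treatment == reference, ]
    tab <- c(tr$events, tr$total - tr$events, co$events, co$total - co$events)
    if ((tab[1] == 0 && tab[3] == 0) || (tab[2] == 0 && tab[4] == 0))
      next  # double-zero margin: no information on the odds ratio
    if (any(tab == 0)) tab <- tab + 0.5
    a <- c(a, tab[1]); b <- c(b, tab[2]); cc <- c(cc, tab[3]); d <- c(d, tab[4])
  }
  if (!length(a)) stop("all tables have a zero margin; odds ratio undefined")
  n <- a + b + cc + d
  R <- a * d / n; S <- b * cc / n
  if (sum(S) == 0 || sum(R) == 0)
    stop("Mantel-Haenszel odds ratio is degenerate (zero margin overall)")
  or <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log OR_MH
  P <- (a + d) / n; Q <- (b + cc) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  eff <- data.frame(treatment = treatment, reference = reference,
                    estimate = rep(log(or), length(a)), std_err = sqrt(v))
  res <- pairwise_result(eff[1, , drop = FALSE], "fixed", log(or), sqrt(v),
                         NA_real_, level)
  res$k <- length(a)
  res
}

#' Heterogeneity-driven model choice
#'
#' @param p_Q P-value of Cochran's Q test.
#' @param I2 Higgins' I-squared, in percent.
#' @return `"random"` when `I2 > 50` and/or `p_Q < 0.05`, else `"fixed"`.
#' @rdname pairwise
#' @export
choose_model <- function(p_Q, I2) {
  stopifnot(is.finite(p_Q), is.finite(I2), I2 >= 0, I2 <= 100,
            p_Q >= 0, p_Q <= 1)
  if (I2 > 50 || p_Q < 0.05) "random" else "fixed"
}

#' Direct meta-analysis of every observed comparison
#'
#' Runs the direct pairwise pipeline over an [outcome_dataset()]: each
#' comparison with contrast evidence is pooled by inverse variance, with the
#' model picked by [choose_model()] when two or more studies contribute
#' (single-study comparisons report the study effect as a fixed effect);
#' comparisons observed as binary 2x2 tables are pooled by Mantel-Haenszel
#' (random effects via DerSimonian-Laird on the log odds ratios of the
#' tables when heterogeneity triggers the rule).
#'
#' @param dataset An [outcome_dataset()].
#' @param level Confidence level.
#' @return A data frame, one row per comparison, with the pooled natural
#'   scale estimate, interval, and heterogeneity statistics.
#' @export
direct_meta <- function(dataset, level = 0.95) {
  stopifnot(inherits(dataset, "outcome_dataset"))
  out <- NULL
  if (!is.null(dataset$contrasts)) {
    co <- dataset$contrasts
    key <- paste(co$treatment, co$reference, sep = " vs ")
    for (k in unique(key)) {
      eff <- co[key == k, ]
      res <- pool_fixed_iv(eff, level)
      if (nrow(eff) >= 2) {
        q <- cochran_q(eff)
        if (choose_model(q$p, q$I2) == "random") res <- pool_random_dl(eff, level)
      }
      out <- rbind(out, pairwise_row(res))
    }
  }
  if (!is.null(dataset$arms)) {
    ar <- dataset$arms
    # every unordered treatment pair observed together in at least one study
    pairs <- unique(do.call(rbind, lapply(split(ar$treatment, ar$study), function(tr) {
      if (length(tr) < 2) return(NULL)
      t(utils::combn(sort(tr), 2))
    })))
    for (i in seq_len(nrow(pairs))) {
      ids <- pairs[i, ]
      in_study <- tapply(ar$treatment, ar$study, function(tr) all(ids %in% tr))
      st <- names(in_study)[in_study]
      sub <- ar[ar$study %in% st & ar$treatment %in% ids, ]
      res <- pool_mh_or(sub, treatment = ids[2], reference = ids[1], level = level)
      if (length(st) >= 2) {
        eff <- do.call(rbind, lapply(st, function(s) {
          or1 <- crude_log_or(sub[sub$study == s, ], ids[2], ids[1])
          data.frame(treatment = ids[2], reference = ids[1],
                     estimate = or1$estimate, std_err = or1$std_err)
        }))
        q <- cochran_q(eff)
        if (choose_model(q$p, q$I2) == "random") res <- pool_random_dl(eff, level)
        res$Q <- q$Q; res$df <- q$df; res$p_Q <- q$p; res$I2 <- q$I2
      }
      out <- rbind(out, pairwise_row(res))
    }
  }
  rownames(out) <- NULL
  out
}

# crude log OR of a single 2x2 (0.5 correction when a zero cell is present)
crude_log_or <- function(rs, treatment, reference) {
  tr <- rs[rs$treatment == treatment, ]
  co <- rs[rs$treatment == reference, ]
  tab <- c(tr$events, tr$total - tr$events, co$events, co$total - co$events)
  if (any(tab == 0)) tab <- tab + 0.5
  list(estimate = log(tab[1] * tab[4] / (tab[2] * tab[3])),
       std_err = sqrt(sum(1 / tab)))
}

pairwise_row <- function(res) {
  data.frame(treatment = res$treatment, reference = res$reference,
             k_studies = res$k, model = res$model,
             estimate_natural = exp(res$estimate),
             ci_low = exp(res$ci_lower), ci_high = exp(res$ci_upper),
             Q = res$Q, p_Q = res$p_Q, I2 = res$I2,
             tau2 = if (is.na(res$tau2)) 0 else res$tau2)
}
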