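#' Rank probabilities from an NMA fit
#'
#' For each retained posterior draw the treatments are ordered by their
#' basic parameter (the reference's parameter is identically 0 and is
#' ranked with the rest): with `direction = "lower"` rank 1 is the smallest
#' log effect (best for hazard-ratio and adverse-event outcomes), with
#' `"higher"` the largest (best for response outcomes). Exact ties are
#' broken by treatment order, a measure-zero event for continuous
#' posteriors. Tallying over draws gives the rank-probability matrix
#' `P[k, j] = Pr(treatment k has rank j)`, which is doubly stochastic.
#'
#' @param fit An `nma_fit` with consistency structure.
#' @param direction `"lower"` or `"higher"` -- which end of the effect
#'   scale is best.
#' @return An object of class `rank_result`: the rank-probability matrix
#'   `prob`, per-treatment SUCRA, `p_best`, and the direction.
#' @export
rank_probabilities <- function(fit, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "nma_fit"))
  if (is.null(fit$d)) stop("ranking requires the consistency structure")
  d <- fit$d
  if (direction == "higher") d <- -d
  a <- ncol(d)
  counts <- matrix(0L, a, a, dimnames = list(fit$treatments, NULL))
  for (i in seq_len(nrow(d))) {
    rk <- rank(d[i, ], ties.method = "first")
    counts[cbind(seq_len(a), rk)] <- counts[cbind(seq_len(a), rk)] + 1L
  }
  prob <- counts / nrow(d)
  structure(list(treatments = fit$treatments, prob = prob,
                 sucra = sucra(prob), p_best = prob[, 1],
                 direction = direction, n_draws = nrow(d)),
            class = "rank_result")
}

#' Surface under the cumulative ranking curve
#'
#' `SUCRA_k = sum_{j=1}^{a-1} cum_kj / (a - 1)` where `cum` is the row-wise
#' cumulative rank-probability matrix. It is 1 for a treatment certain to
#' be best, 0 for one certain to be worst, and 0.5 for a completely
#' uninformative ranking; SUCRAs always sum to `a/2`.
#'
#' @param prob A doubly stochastic rank-probability matrix (rows =
#'   treatments, columns = ranks), or a `rank_result`.
#' @return Named numeric vector of SUCRA values in `[0, 1]`.
#' @export
sucra <- function(prob) {
  if (inherits(prob, "rank_result")) return(prob$sucra)
  prob <- as.matrix(prob)
  a <- nrow(prob)
  if (ncol(prob) != a) stop("rank matrix must be square")
  if (any(abs(rowSums(prob) - 1) > 1e-8))
    stop("rank-probability rows must sum to 1")
  if (a == 1) return(stats::setNames(1, rownames(prob)))
  cum <- t(apply(prob, 1, cumsum))
  s <- rowSums(cum[, seq_len(a - 1), drop = FALSE]) / (a - 1)
  stats::setNames(as.numeric(s), rownames(prob))
}

#' @export
print.rank_result <- function(x, ...) {
  cat("Treatment ranking (", x$direction, " is better; ", x$n_draws,
      " draws)\n", sep = "")
  ord <- order(-x$sucra)
  print(data.frame(treatment = x$treatments[ord],
                   sucra = round(x$sucra[ord], 3),
                   p_best = round(x$p_best[ord], 3), row.names = NULL))
  invisible(x)
}

#' Two-outcome clustered ranking data
#'
#' Pairs each treatment's SUCRA on a safety outcome (x) with its SUCRA on
#' an efficacy outcome (y) -- the clustered ranking plot used to read the
#' efficacy/safety trade-off. Treatments not dominated on both axes form
#' the non-dominated (Pareto) set; optional seeded k-means labels group the
#' points.
#'
#' @param sucra_safety,sucra_efficacy Named SUCRA vectors (or
#'   `rank_result`s) over the same treatment set.
#' @param k_clusters Optional number of k-means clusters (default `NULL` =
#'   no clustering; published clustered ranking plots typically use 3).
#' @param seed Seed for the k-means initialization.
#' @return A data frame with `treatment`, `sucra_safety`, `sucra_efficacy`,
#'   `dominated` flag, and `cluster` label when requested.
#' @export
cluster_plot_data <- function(sucra_safety, sucra_efficacy, k_clusters = NULL,
                              seed = 1) {
  if (inherits(sucra_safety, "rank_result")) sucra_safety <- sucra_safety$sucra
  if (inherits(sucra_efficacy, "rank_result")) sucra_efficacy <- sucra_efficacy$sucra
  if (!setequal(names(sucra_safety), names(sucra_efficacy)))
    stop("the two outcomes rank different treatment sets")
  trt <- names(sucra_safety)
  x <- as.numeric(sucra_safety[trt])
  y <- as.numeric(sucra_efficacy[trt])
  dominated <- vapply(seq_along(trt), function(i)
    any(x >= x[i] & y >= y[i] & (x > x[i] | y > y[i])), TRUE)
  out <- data.frame(treatment = trt, sucra_safety = x, sucra_efficacy = y,
                    dominated = dominated)
  if (!is.null(k_clusters)) {
    if (k_clusters < 1 || k_clusters > length(trt))
      stop("'k_clusters' must lie between 1 and the number of treatments")
    set.seed(seed)
    km <- stats::kmeans(cbind(x, y), centers = k_clusters, nstart = 10)
    out$cluster <- km$cluster
  }
  out
}
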