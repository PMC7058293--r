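#' Generating truth for a synthetic evidence network
#'
#' Defines a network design with known generating parameters, for
#' calibration and recovery studies. The default geometry mirrors the
#' first-line HCC evidence base: two hub treatments -- a placebo reference
#' (`Pla`) and an active standard (`Sor`) -- joined by head-to-head trials,
#' spoke drugs compared to a hub, exactly one closed triangle
#' (`Pla`-`Sor`-`D1`) so that node-splitting is exercised on one loop, and
#' one three-arm trial when the network is large enough. True basic
#' parameters are log effects against the reference (reference fixed at 0),
#' drawn once per seed on the scale seen in practice (hazard ratios roughly
#' 0.45-1.5) unless supplied.
#'
#' @param n_treat Number of treatments (>= 3; the first two are the hubs).
#' @param n_trials Number of trials (>= n_treat, so the network is
#'   connected with the default geometry).
#' @param sigma True between-trial standard deviation (default 0.15).
#' @param d Optional named vector of true basic parameters (log scale,
#'   reference first and 0).
#' @param events_range Range of per-arm event counts driving the contrast
#'   variances `V = 1/e1 + 1/e2`; a single value fixes all counts.
#' @param n_range Range of per-arm sample sizes for binary-outcome
#'   simulation.
#' @param include_multiarm Replace one trial by a three-arm trial when the
#'   network has at least four treatments (default TRUE).
#' @param seed Integer seed; the design and truth are reproducible given it.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(n_treat = 5, n_trials = 12, sigma = 0.15, d = NULL,
                      events_range = c(80, 250), n_range = c(150, 400),
                      include_multiarm = TRUE, seed = 1) {
  if (n_treat < 3) stop("at least 3 treatments are required")
  if (n_trials < n_treat) stop("need at least as many trials as treatments")
  if (sigma < 0) stop("'sigma' must be non-negative")
  treatments <- c("Pla", "Sor", paste0("D", seq_len(n_treat - 2)))
  set.seed(seed %% .Machine$integer.max)
  if (is.null(d)) {
    d <- c(0, round(stats::runif(n_treat - 1, -0.8, 0.4), 3))
  } else if (length(d) != n_treat || d[1] != 0) {
    stop("'d' must have one entry per treatment with the reference first and 0")
  }
  names(d) <- treatments

  # edge list: hub edge, the triangle closure, then spokes to Sor
  edges <- list(c("Pla", "Sor"), c("Pla", "D1"), c("Sor", "D1"))
  for (k in seq_len(n_treat - 3))
    edges <- c(edges, list(c("Sor", paste0("D", k + 1))))
  trials <- list()
  for (i in seq_len(n_trials)) {
    e <- edges[[(i - 1) %% length(edges) + 1]]
    trials[[sprintf("t%02d", i)]] <- list(arms = e)
  }
  if (include_multiarm && n_treat >= 4) {
    # last trial becomes three-arm: both dose-like variants vs the hub
    trials[[length(trials)]] <- list(arms = c("Sor", "D1", "D2"))
  }
  rng <- function(lo_hi, n) {
    if (length(lo_hi) == 1) rep(lo_hi, n)
    else round(stats::runif(n, lo_hi[1], lo_hi[2]))
  }
  for (i in seq_along(trials)) {
    k <- length(trials[[i]]$arms)
    trials[[i]]$events <- stats::setNames(rng(events_range, k), trials[[i]]$arms)
    trials[[i]]$n <- stats::setNames(rng(n_range, k), trials[[i]]$arms)
  }
  structure(list(treatments = treatments, d = d, sigma = sigma,
                 omega = 0, omega_edge = NULL, trials = trials, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic network truth:", length(x$treatments), "treatments,",
      length(x$trials), "trials, sigma =", x$sigma)
  if (x$omega != 0)
    cat(", omega =", x$omega, "on", paste(x$omega_edge, collapse = "-"))
  cat("\n  d:", paste(sprintf("%s=%.3f", names(x$d), x$d), collapse = ", "), "\n")
  invisible(x)
}

#' Inject an inconsistency offset on a loop edge
#'
#' Shifts the direct evidence on one comparison by `omega`, leaving all
#' other evidence unchanged -- the alternative hypothesis the
#' node-splitting test is meant to detect. The edge must lie on a loop,
#' otherwise the offset would be indistinguishable from a shifted basic
#' parameter.
#'
#' @param truth A `sim_truth`.
#' @param edge Length-2 treatment vector; the offset applies to the
#'   `edge[2]` vs `edge[1]` direction.
#' @param omega Offset on the log scale.
#' @return The modified `sim_truth`.
#' @export
inject_inconsistency <- function(truth, edge, omega) {
  stopifnot(inherits(truth, "sim_truth"), length(edge) == 2)
  edge <- as.character(edge)
  if (!all(edge %in% truth$treatments)) stop("unknown treatments in 'edge'")
  ed <- unique(do.call(rbind, lapply(truth$trials, function(tr) {
    pr <- utils::combn(sort(tr$arms), 2)
    data.frame(t1 = pr[1, ], t2 = pr[2, ])
  })))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = truth$treatments))
  has_direct <- any(ed$t1 == min(edge) & ed$t2 == max(edge))
  if (!has_direct) stop("edge has no direct evidence in the design")
  g2 <- igraph::delete_edges(g, igraph::E(g)[igraph::`%--%`(edge[1], edge[2])])
  if (igraph::distances(g2, v = edge[1], to = edge[2]) == Inf)
    stop("edge ", edge[1], "-", edge[2], " does not lie on a loop")
  truth$omega <- omega
  truth$omega_edge <- edge
  truth
}

# omega contribution for a contrast t2-vs-t1 given an oriented offset edge
omega_for <- function(truth, t1, t2) {
  e <- truth$omega_edge
  if (is.null(e) || truth$omega == 0) return(0)
  if (t1 == e[1] && t2 == e[2]) return(truth$omega)
  if (t1 == e[2] && t2 == e[1]) return(-truth$omega)
  0
}

#' Simulate a contrast-level evidence network
#'
#' Draws, for every trial of the design, trial-specific true effects
#' `delta ~ N(d_t2 - d_t1 + omega, sigma^2)` (contrasts of a three-arm
#' trial correlated with covariance `sigma^2/2`), then observed log effects
#' `y ~ N(delta, V)` with `V = 1/e_baseline + 1/e_arm` from the design's
#' event counts. Contrasts of one multi-arm trial share baseline events and
#' are therefore drawn with data-level covariance `1/e_baseline`, which is
#' also attached to the dataset.
#'
#' @param truth A `sim_truth`.
#' @param measure Effect scale label for the dataset (default `"hr"`).
#' @return A list with `dataset` (an [outcome_dataset()]) and `truth`.
#' @export
simulate_contrast_network <- function(truth, measure = "hr") {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed %% .Machine$integer.max)
  rows <- NULL
  macov <- list()
  for (s in names(truth$trials)) {
    tr <- truth$trials[[s]]
    base <- tr$arms[1]
    oth <- tr$arms[-1]
    k <- length(oth)
    m <- vapply(oth, function(t2)
      truth$d[t2] - truth$d[base] + omega_for(truth, base, t2), 0)
    C <- if (k == 1) matrix(1) else matrix(0.5, k, k) + diag(0.5, k)
    delta <- m + drop(crossprod(chol(C), stats::rnorm(k))) * truth$sigma
    vb <- 1 / tr$events[base]
    Vmat <- diag(1 / tr$events[oth], k) + vb
    y <- delta + drop(crossprod(chol(Vmat), stats::rnorm(k)))
    rows <- rbind(rows, data.frame(study = s, treatment = oth,
                                   reference = base, estimate = y,
                                   std_err = sqrt(diag(Vmat)),
                                   source = "arm_counts"))
    if (k > 1) {
      off <- matrix(vb, k, k); diag(off) <- 0
      macov[[s]] <- off
    }
  }
  rownames(rows) <- NULL
  dataset <- outcome_dataset(measure = measure, contrasts = rows,
                             multiarm_cov = if (length(macov)) macov else NULL)
  list(dataset = dataset, truth = truth)
}

#' Simulate an arm-level binary evidence network
#'
#' Trial baseline logits are drawn around `logit(p_baseline)`, true
#' log odds ratios follow the same hierarchy as
#' [simulate_contrast_network()], and arm events are binomial.
#'
#' @param truth A `sim_truth`.
#' @param p_baseline Expected baseline event probability, in (0, 1).
#' @param baseline_sd Standard deviation of trial baseline logits.
#' @return A list with `arms` (a validated arm table), `dataset` (an
#'   `"or"` [outcome_dataset()]) and `truth`.
#' @export
simulate_binary_network <- function(truth, p_baseline = 0.3,
                                    baseline_sd = 0.2) {
  stopifnot(inherits(truth, "sim_truth"))
  if (p_baseline <= 0 || p_baseline >= 1)
    stop("'p_baseline' must lie in (0, 1)")
  set.seed((truth$seed + 1L) %% .Machine$integer.max)
  rows <- NULL
  for (s in names(truth$trials)) {
    tr <- truth$trials[[s]]
    base <- tr$arms[1]
    oth <- tr$arms[-1]
    k <- length(oth)
    m <- vapply(oth, function(t2)
      truth$d[t2] - truth$d[base] + omega_for(truth, base, t2), 0)
    C <- if (k == 1) matrix(1) else matrix(0.5, k, k) + diag(0.5, k)
    delta <- m + drop(crossprod(chol(C), stats::rnorm(k))) * truth$sigma
    mu <- stats::rnorm(1, logit(p_baseline), baseline_sd)
    p <- invlogit(c(mu, mu + delta))
    n <- tr$n[tr$arms]
    ev <- stats::rbinom(k + 1, n, p)
    rows <- rbind(rows, data.frame(study = s, treatment = tr$arms,
                                   events = ev, total = as.integer(n)))
  }
  rownames(rows) <- NULL
  dataset <- outcome_dataset(measure = "or", arms = rows)
  list(arms = dataset$arms, dataset = dataset, truth = truth)
}

#' Simulate tabulated Kaplan-Meier curves under proportional hazards
#'
#' Exponential event times (control hazard `hazard`, treated hazard
#' `hazard * hr`) with uniform censoring over the follow-up window;
#' Kaplan-Meier estimates and numbers at risk are tabulated on a regular
#' grid. Used to validate the curve-based hazard-ratio extraction.
#'
#' @param hr True hazard ratio (treated vs control), > 0.
#' @param hazard Control hazard rate per month, > 0.
#' @param horizon Follow-up horizon in months.
#' @param grid_step Tabulation step in months.
#' @param n_per_arm Patients per arm.
#' @param seed Integer seed.
#' @return A list with `control` and `treated` ([km_summary()] objects on a
#'   common grid) and `truth` (the generating parameters and realized event
#'   counts).
#' @export
simulate_km_tables <- function(hr, hazard = 0.08, horizon = 36,
                               grid_step = 3, n_per_arm = 2000, seed = 1) {
  if (hr <= 0 || hazard <= 0) stop("'hr' and 'hazard' must be positive")
  if (horizon <= 0) stop("'horizon' must be positive")
  set.seed(seed %% .Machine$integer.max)
  sim_arm <- function(rate) {
    t_ev <- stats::rexp(n_per_arm, rate)
    cens <- stats::runif(n_per_arm, 0, horizon)
    data.frame(time = pmin(t_ev, cens), status = as.integer(t_ev <= cens))
  }
  ctl <- sim_arm(hazard)
  trt <- sim_arm(hazard * hr)
  grid <- seq(grid_step, horizon, by = grid_step)
  tab <- function(df) {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = df)
    sm <- summary(fit, times = grid, extend = TRUE)
    list(surv = sm$surv, n_risk = sm$n.risk)
  }
  a <- tab(ctl); b <- tab(trt)
  ok <- a$surv > 0 & b$surv > 0 & a$n_risk >= 1 & b$n_risk >= 1
  use <- seq_len(max(which(ok)))
  list(control = km_summary("control", grid[use], a$surv[use],
                            n_risk = a$n_risk[use], n_start = n_per_arm,
                            max_followup = horizon),
       treated = km_summary("treated", grid[use], b$surv[use],
                            n_risk = b$n_risk[use], n_start = n_per_arm,
                            max_followup = horizon),
       truth = list(hr = hr, log_hr = log(hr), hazard = hazard,
                    events_control = sum(ctl$status),
                    events_treated = sum(trt$status), seed = seed))
}
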