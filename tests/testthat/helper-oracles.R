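# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the GLS solver works from the raw contrast data
# frame by weighted normal equations, and connectivity uses union-find.

# Generalized-least-squares solution of a fixed-effect contrast network
# with an optional vague prior ridge; returns named basic parameters.
gls_solve <- function(dataset, reference, prior_sd = NULL) {
  co <- dataset$contrasts
  trt <- setdiff(sort(unique(c(co$treatment, co$reference))), reference)
  X <- matrix(0, nrow(co), length(trt), dimnames = list(NULL, trt))
  for (i in seq_len(nrow(co))) {
    if (co$treatment[i] %in% trt) X[i, co$treatment[i]] <- 1
    if (co$reference[i] %in% trt) X[i, co$reference[i]] <- -1
  }
  V <- diag(co$std_err^2, nrow(co))
  for (s in names(dataset$multiarm_cov)) {
    idx <- which(co$study == s)
    V[idx, idx] <- V[idx, idx] + dataset$multiarm_cov[[s]]
  }
  W <- solve(V)
  A <- t(X) %*% W %*% X
  if (!is.null(prior_sd)) A <- A + diag(1 / prior_sd^2, ncol(X))
  drop(solve(A, t(X) %*% W %*% co$estimate))
}

# union-find connectivity over an edge list (two-column matrix of labels)
uf_connected <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges)))
    parent[[find(edges[i, 1])]] <- find(edges[i, 2])
  length(unique(vapply(nodes, find, ""))) == 1
}

# union-find reachability of a and b over an edge list
uf_reachable <- function(a, b, nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges)))
    parent[[find(edges[i, 1])]] <- find(edges[i, 2])
  identical(find(a), find(b))
}

# quick contrast dataset from vectors
make_contrasts <- function(study, treatment, reference, estimate, std_err,
                           measure = "hr") {
  outcome_dataset(measure, contrasts = data.frame(
    study = study, treatment = treatment, reference = reference,
    estimate = estimate, std_err = std_err))
}

# short MCMC configurations for tests
cfg_fast <- function(seed = 1, effects = "fixed", ...)
  nma_config(chains = 2, iterations = 3000, burn_in = 1000, thin = 1,
             seed = seed, effects = effects, ...)

cfg_mini <- function(seed = 1, effects = "fixed", ...)
  nma_config(chains = 2, iterations = 1500, burn_in = 500, thin = 1,
             seed = seed, effects = effects, ...)
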