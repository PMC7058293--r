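#' MCMC configuration for the Bayesian NMA
#'
#' Defaults follow common practice for these models: four chains of 100,000
#' iterations each including 50,000 burn-in, thinned by 10, which retains
#' 20,000 draws in total. Tests and simulation studies use far shorter runs.
#'
#' @param chains Number of chains (>= 2).
#' @param iterations Iterations per chain, including burn-in.
#' @param burn_in Burn-in iterations per chain (`burn_in < iterations`).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer seed; every random draw of the fit derives from it.
#' @param prior_sd_d Prior standard deviation of the basic parameters
#'   `d_k ~ N(0, prior_sd_d^2)`. Default `NULL` resolves at fit time to
#'   `15 * max(1, max |observed log effect|)`, vague relative to the log
#'   hazard-ratio range seen in practice.
#' @param sigma_upper Upper bound of the uniform prior on the between-trial
#'   standard deviation sigma (default 5).
#' @param effects `"random"` (hierarchical, the primary analysis) or
#'   `"fixed"`.
#' @param structure `"consistency"` (basic parameters linked by the
#'   consistency relations) or `"ume"` (unrelated mean effects: one free
#'   parameter per observed comparison, the saturated inconsistency model).
#' @return A list of class `nma_config`.
#' @export
nma_config <- function(chains = 4, iterations = 100000, burn_in = 50000,
                       thin = 10, seed = 1, prior_sd_d = NULL,
                       sigma_upper = 5, effects = c("random", "fixed"),
                       structure = c("consistency", "ume")) {
  effects <- match.arg(effects)
  structure <- match.arg(structure)
  if (chains < 2) stop("at least 2 chains are required")
  if (thin < 1) stop("'thin' must be at least 1")
  if (burn_in >= iterations) stop("'burn_in' must be smaller than 'iterations'")
  if (!is.null(prior_sd_d) && prior_sd_d <= 0) stop("'prior_sd_d' must be positive")
  if (sigma_upper <= 0) stop("'sigma_upper' must be positive")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), prior_sd_d = prior_sd_d,
                 sigma_upper = sigma_upper, effects = effects,
                 structure = structure),
            class = "nma_config")
}

# inverse of the multi-arm random-effect correlation (1 on the diagonal,
# 1/2 off-diagonal): contrasts of one trial against a common baseline
marm_corr_inv <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  solve(matrix(0.5, k, k) + diag(0.5, k))
}

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

# Assemble the sampler's view of the data. `split` (a length-2 treatment
# vector, orientation split[2] vs split[1]) decouples the direct evidence on
# that comparison into an extra parameter "d_direct" (node-splitting).
prepare_model <- function(dataset, reference, structure, split = NULL) {
  trt <- dataset$treatments$id
  if (is.null(reference)) reference <- trt[1]
  if (!reference %in% trt) stop("unknown reference treatment: ", reference)
  trt <- c(reference, setdiff(trt, reference))

  if (structure == "consistency") {
    params <- paste0("d.", trt[-1])
    col_of <- stats::setNames(seq_along(params), trt[-1])
    row_design <- function(t1, t2) {  # effect of t2 vs t1
      x <- numeric(length(params))
      if (t2 != reference) x[col_of[[t2]]] <- x[col_of[[t2]]] + 1
      if (t1 != reference) x[col_of[[t1]]] <- x[col_of[[t1]]] - 1
      x
    }
  } else {
    cmp <- NULL
    if (!is.null(dataset$contrasts))
      cmp <- rbind(cmp, cbind(pmin(dataset$contrasts$reference,
                                   dataset$contrasts$treatment),
                              pmax(dataset$contrasts$reference,
                                   dataset$contrasts$treatment)))
    if (!is.null(dataset$arms)) {
      for (s in unique(dataset$arms$study)) {
        tr <- dataset$arms$treatment[dataset$arms$study == s]
        base <- bin_baseline(tr, reference)
        oth <- setdiff(tr, base)
        cmp <- rbind(cmp, cbind(pmin(base, oth), pmax(base, oth)))
      }
    }
    cmp <- unique(cmp)
    params <- paste0("d.", cmp[, 2], ".vs.", cmp[, 1])
    ume_key <- stats::setNames(seq_len(nrow(cmp)), paste(cmp[, 1], cmp[, 2]))
    row_design <- function(t1, t2) {
      x <- numeric(length(params))
      j <- ume_key[[paste(min(t1, t2), max(t1, t2))]]
      x[j] <- if (t2 > t1) 1 else -1
      x
    }
  }

  split_col <- NULL
  if (!is.null(split)) {
    if (structure != "consistency")
      stop("node-splitting applies to the consistency structure")
    params <- c(params, "d.direct")
    split_col <- length(params)
  }
  P <- length(params)

  studies <- list()
  if (!is.null(dataset$contrasts)) {
    co <- dataset$contrasts
    for (s in unique(co$study)) {
      rows <- which(co$study == s)
      k <- length(rows)
      X <- matrix(0, k, P)
      direct <- logical(k)
      for (j in seq_len(k)) {
        t1 <- co$reference[rows[j]]; t2 <- co$treatment[rows[j]]
        if (!is.null(split) && setequal(c(t1, t2), split)) {
          direct[j] <- TRUE
          X[j, split_col] <- if (t2 == split[2]) 1 else -1
        } else {
          X[j, seq_len(P - !is.null(split))] <-
            row_design(t1, t2)[seq_len(P - !is.null(split))]
        }
      }
      V <- diag(co$std_err[rows]^2, k)
      if (!is.null(dataset$multiarm_cov) && s %in% names(dataset$multiarm_cov))
        V <- V + dataset$multiarm_cov[[s]]
      studies[[s]] <- list(y = co$estimate[rows], Vinv = solve(V),
                           X = X, k = k, Cinv = marm_corr_inv(k),
                           rows = rows, direct = direct)
    }
  }

  binstudies <- list()
  if (!is.null(dataset$arms)) {
    ar <- dataset$arms
    for (s in unique(ar$study)) {
      rows <- which(ar$study == s)
      tr <- ar$treatment[rows]
      base <- bin_baseline(tr, reference)
      oth <- setdiff(tr, base)
      k <- length(oth)
      X <- matrix(0, k, P)
      for (j in seq_len(k)) {
        if (!is.null(split) && setequal(c(base, oth[j]), split)) {
          X[j, split_col] <- if (oth[j] == split[2]) 1 else -1
        } else {
          X[j, seq_len(P - !is.null(split))] <-
            row_design(base, oth[j])[seq_len(P - !is.null(split))]
        }
      }
      ord <- rows[match(c(base, oth), tr)]
      binstudies[[s]] <- list(r = ar$events[ord], n = ar$total[ord],
                              treatments = c(base, oth), X = X, k = k,
                              Cinv = marm_corr_inv(k), rows = ord)
    }
  }

  n_delta <- sum(vapply(studies, `[[`, 0L, "k")) +
    sum(vapply(binstudies, `[[`, 0L, "k"))
  n_data <- sum(vapply(studies, `[[`, 0L, "k")) +
    sum(vapply(binstudies, function(b) b$k + 1L, 0L))

  # vectorized view: all single-contrast studies stacked (the bulk of the
  # data); multi-contrast blocks kept as a short list
  is_multi <- vapply(studies, function(s) s$k > 1, TRUE)
  uni_names <- names(studies)[!is_multi]
  uni <- NULL
  if (length(uni_names)) {
    uni <- list(
      y = vapply(studies[uni_names], function(s) s$y, 0),
      vinv = vapply(studies[uni_names], function(s) as.numeric(s$Vinv), 0),
      X = do.call(rbind, lapply(studies[uni_names], `[[`, "X")))
  }
  multi <- studies[names(studies)[is_multi]]

  list(treatments = trt, reference = reference, params = params, P = P,
       studies = studies, uni = uni, multi = multi,
       binstudies = binstudies, split = split,
       split_col = split_col, n_delta = n_delta, n_data = n_data)
}

# baseline arm of a binary study: the network reference when present,
# otherwise the alphabetically first arm
bin_baseline <- function(arms, reference) {
  if (reference %in% arms) reference else sort(arms)[1]
}

draw_mvn <- function(prec, b) {
  R <- chol(prec)
  mu <- backsolve(R, forwardsolve(t(R), b))
  mu + backsolve(R, stats::rnorm(length(b)))
}

# sigma | delta, d under the flat prior U(0, sigma_upper): 1/sigma^2 is
# gamma-distributed, truncated below at 1/sigma_upper^2
draw_sigma <- function(q, n_delta, sigma_upper) {
  shape <- (n_delta - 1) / 2
  rate <- max(q, 1e-300) / 2
  lo <- stats::pgamma(sigma_upper^-2, shape, rate)
  u <- stats::runif(1, lo, 1)
  phi <- stats::qgamma(min(u, 1 - 1e-16), shape, rate)
  if (!is.finite(phi) || phi <= 0) phi <- sigma_upper^-2
  1 / sqrt(max(phi, sigma_upper^-2))
}

#' Fit a hierarchical Bayesian network meta-analysis
#'
#' Contrast-based NMA in the standard hierarchical formulation. Observed
#' log effects are normal about trial-specific true effects,
#' `y_i ~ N(delta_i, V_i)`; under random effects the
#' `delta_i ~ N(d_t2 - d_t1, sigma^2)` with covariance `sigma^2/2` between
#' contrasts of one multi-arm trial, under fixed effects
#' `delta_i = d_t2 - d_t1`. Binary arm data enter through a binomial
#' likelihood `r ~ Bin(n, p)`, `logit p = mu_study + delta` with the same
#' hierarchy on delta and vague normal priors on the trial baselines. Basic
#' parameters carry vague normal priors (`d_reference = 0`), sigma a uniform
#' prior on `(0, sigma_upper)`. The unrelated-mean-effects structure
#' replaces the consistency relations with one free mean per observed
#' comparison.
#'
#' Sampling is by Gibbs: `delta` and `d` have closed-form normal
#' conditionals under the normal likelihood (multi-arm blocks drawn jointly
#' from their small multivariate-normal conditional), `1/sigma^2` a
#' truncated-gamma conditional, and binomial-logit parameters use
#' random-walk Metropolis steps tuned during burn-in. With fixed effects
#' and purely contrast data the posterior of `d` is multivariate normal and
#' is sampled exactly. Chains are seeded deterministically from
#' `config$seed` and pooled after burn-in and thinning.
#'
#' @param dataset An [outcome_dataset()] with a connected evidence network.
#' @param config An [nma_config()].
#' @param reference Reference treatment (basic parameter fixed at 0);
#'   defaults to the first treatment id.
#' @param .split Internal (used by [node_split()]): a length-2 treatment
#'   vector whose direct evidence is decoupled into a `d.direct` parameter.
#' @return An object of class `nma_fit` carrying pooled posterior draws of
#'   the basic parameters (matrix `d`, one column per treatment, reference
#'   identically 0), `sigma` draws (random effects), the residual-deviance
#'   trace, `Dbar`, `pD`, `DIC`, and per-parameter convergence diagnostics.
#' @examples
#' ds <- outcome_dataset("hr", contrasts = data.frame(
#'   study = c("s1", "s2"), treatment = c("B", "C"),
#'   reference = c("A", "B"), estimate = c(0.3, 0.2),
#'   std_err = c(0.1, 0.1)))
#' fit <- fit_nma(ds, nma_config(chains = 2, iterations = 2000,
#'                               burn_in = 500, thin = 1, effects = "fixed"))
#' fit
#' @export
fit_nma <- function(dataset, config = nma_config(), reference = NULL,
                    .split = NULL) {
  stopifnot(inherits(dataset, "outcome_dataset"),
            inherits(config, "nma_config"))
  build_network(dataset)  # errors if disconnected
  model <- prepare_model(dataset, reference, config$structure, .split)
  if (config$effects == "random" && model$n_delta < 2)
    stop("random effects need at least 2 contrasts")

  scale_obs <- 1
  if (!is.null(dataset$contrasts))
    scale_obs <- max(scale_obs, max(abs(dataset$contrasts$estimate)))
  prior_sd <- if (is.null(config$prior_sd_d)) 15 * scale_obs else config$prior_sd_d

  n_keep <- (config$iterations - config$burn_in) %/% config$thin
  if (n_keep < 2) stop("configuration retains fewer than 2 draws per chain")

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed((config$seed * 10007L + ch * 97L) %% .Machine$integer.max)
    chains[[ch]] <- run_chain(model, config, prior_sd, ch, n_keep)
  }

  pool <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  d_pool <- pool("d")
  colnames(d_pool) <- model$params
  sigma_pool <- if (config$effects == "random") as.vector(pool("sigma")) else NULL
  dev_pool <- as.vector(pool("dev"))

  # pD from the deviance at the posterior-mean fitted values
  fitted_mean <- Reduce(`+`, lapply(chains, `[[`, "fitted_sum")) /
    (n_keep * config$chains)
  Dbar <- mean(dev_pool)
  Dhat <- deviance_at(model, fitted_mean)
  pD <- Dbar - Dhat
  DIC <- Dbar + pD

  # basic-parameter draws for all treatments (reference column = 0)
  keep <- seq_len(model$P - !is.null(.split))
  if (config$structure == "consistency") {
    d_trt <- cbind(0, d_pool[, setdiff(keep, model$split_col), drop = FALSE])
    colnames(d_trt) <- model$treatments
  } else d_trt <- NULL

  diag_in <- lapply(chains, function(cc) {
    m <- cc$d
    colnames(m) <- model$params
    if (!is.null(cc$sigma)) m <- cbind(m, sigma = as.vector(cc$sigma))
    m
  })
  diagn <- convergence_diagnostics(diag_in, max_lag = 50)
  if (any(is.finite(diagn$psrf) & diagn$psrf > 1.05))
    warning("split-chain PSRF above 1.05 for: ",
            paste(names(diagn$psrf)[is.finite(diagn$psrf) & diagn$psrf > 1.05],
                  collapse = ", "),
            "; consider longer chains", call. = FALSE)

  structure(list(
    treatments = model$treatments, reference = model$reference,
    params = model$params, structure = config$structure,
    effects = config$effects, measure = dataset$measure,
    d = d_trt, d_params = d_pool, sigma = sigma_pool,
    d_direct = if (!is.null(.split)) d_pool[, model$split_col] else NULL,
    split = .split,
    deviance = dev_pool, Dbar = Dbar, pD = pD, DIC = DIC,
    n_data = model$n_data, n_draws = nrow(d_pool),
    psrf = diagn$psrf, ess = diagn$ess, diagnostics = diagn,
    prior_sd_d = prior_sd, config = config),
    class = "nma_fit")
}

# One MCMC chain. Returns retained draws and running sums of fitted values.
run_chain <- function(model, config, prior_sd, chain_id, n_keep) {
  P <- model$P
  random <- config$effects == "random"
  has_bin <- length(model$binstudies) > 0
  uni <- model$uni
  multi <- model$multi

  # constant pieces of the conditional of d
  prior_prec <- diag(1 / prior_sd^2, P)
  if (!random) {
    A_fix <- prior_prec
    b_fix <- numeric(P)
    for (s in model$studies) {
      A_fix <- A_fix + t(s$X) %*% s$Vinv %*% s$X
      b_fix <- b_fix + as.vector(t(s$X) %*% s$Vinv %*% s$y)
    }
    if (!has_bin) {
      R_fix <- chol(A_fix)
      mu_fix <- backsolve(R_fix, forwardsolve(t(R_fix), b_fix))
    }
  } else {
    M <- matrix(0, P, P)
    if (!is.null(uni)) M <- M + crossprod(uni$X)
    for (s in multi) M <- M + t(s$X) %*% s$Cinv %*% s$X
    for (s in model$binstudies) M <- M + t(s$X) %*% s$Cinv %*% s$X
    multi_CinvX <- lapply(multi, function(s) s$Cinv %*% s$X)
    multi_Vinvy <- lapply(multi, function(s) as.vector(s$Vinv %*% s$y))
  }

  # initial values: dispersed d, delta at the observed effects, sigma at
  # prior quantiles -- all deterministic given the chain index
  offs <- c(0, 0.5, -0.5, 1)[((chain_id - 1) %% 4) + 1]
  d <- rep(offs * 0.1 * prior_sd / 15, P)
  sigma <- config$sigma_upper * chain_id / (config$chains + 1)
  delta_u <- if (!is.null(uni)) uni$y else numeric(0)
  delta_m <- lapply(multi, `[[`, "y")
  bdelta <- lapply(model$binstudies, function(s) {
    p <- pmin(pmax((s$r + 0.5) / (s$n + 1), 0.01), 0.99)
    logit(p[-1]) - logit(p[1])
  })
  bmu <- lapply(model$binstudies, function(s)
    logit(pmin(pmax((s$r[1] + 0.5) / (s$n[1] + 1), 0.01), 0.99)))
  prop_sd <- list(mu = lapply(model$binstudies, function(s) 0.3),
                  delta = lapply(model$binstudies, function(s) rep(0.3, s$k)))
  acc <- list(mu = lapply(model$binstudies, function(s) 0),
              delta = lapply(model$binstudies, function(s) rep(0, s$k)))
  # fixed effects with binomial data: random-walk steps on d
  d_prop_sd <- rep(0.1, P)
  d_acc <- rep(0, P)

  keep_d <- matrix(NA_real_, n_keep, P)
  keep_sigma <- if (random) numeric(n_keep) else NULL
  keep_dev <- numeric(n_keep)
  fitted_sum <- numeric(model$n_data)
  kept <- 0L
  adapt_every <- 50L

  for (it in seq_len(config$iterations)) {
    if (random) {
      inv_s2 <- 1 / sigma^2
      # delta | d, sigma, y  (single-contrast studies: vectorized conjugate
      # normal; multi-arm blocks: joint small multivariate-normal draw)
      if (!is.null(uni)) {
        mu_u <- as.vector(uni$X %*% d)
        prec <- uni$vinv + inv_s2
        mean_u <- (uni$vinv * uni$y + mu_u * inv_s2) / prec
        delta_u <- mean_u + stats::rnorm(length(prec)) / sqrt(prec)
      }
      for (nm in names(multi)) {
        s <- multi[[nm]]
        prec <- s$Vinv + s$Cinv * inv_s2
        b <- multi_Vinvy[[nm]] + as.vector(multi_CinvX[[nm]] %*% d) * inv_s2
        delta_m[[nm]] <- draw_mvn(prec, b)
      }
      # delta, mu | ... (binary studies: random-walk Metropolis)
      for (nm in names(model$binstudies)) {
        s <- model$binstudies[[nm]]
        mu_s <- as.vector(s$X %*% d)
        st <- bin_mh_update(s, bmu[[nm]], bdelta[[nm]], mu_s, sigma,
                            prop_sd$mu[[nm]], prop_sd$delta[[nm]])
        bmu[[nm]] <- st$mu; bdelta[[nm]] <- st$delta
        acc$mu[[nm]] <- acc$mu[[nm]] + st$acc_mu
        acc$delta[[nm]] <- acc$delta[[nm]] + st$acc_delta
      }
      # d | delta, sigma
      b <- numeric(P)
      if (!is.null(uni)) b <- b + as.vector(crossprod(uni$X, delta_u))
      for (nm in names(multi))
        b <- b + as.vector(crossprod(multi_CinvX[[nm]], delta_m[[nm]]))
      for (nm in names(model$binstudies))
        b <- b + as.vector(t(model$binstudies[[nm]]$X) %*%
                             model$binstudies[[nm]]$Cinv %*% bdelta[[nm]])
      d <- draw_mvn(M * inv_s2 + prior_prec, b * inv_s2)
      # sigma | delta, d
      q <- 0
      if (!is.null(uni)) q <- q + sum((delta_u - as.vector(uni$X %*% d))^2)
      for (nm in names(multi)) {
        r <- delta_m[[nm]] - as.vector(multi[[nm]]$X %*% d)
        q <- q + sum(r * (multi[[nm]]$Cinv %*% r))
      }
      for (nm in names(model$binstudies)) {
        r <- bdelta[[nm]] - as.vector(model$binstudies[[nm]]$X %*% d)
        q <- q + sum(r * (model$binstudies[[nm]]$Cinv %*% r))
      }
      sigma <- draw_sigma(q, model$n_delta, config$sigma_upper)
    } else {
      if (!has_bin) {
        d <- mu_fix + backsolve(R_fix, stats::rnorm(P))
      } else {
        # random-walk Metropolis on each basic parameter; contrast data
        # enter through their gaussian likelihood
        for (p in seq_len(P)) {
          prop <- d
          prop[p] <- d[p] + stats::rnorm(1, 0, d_prop_sd[p])
          lr <- fixed_loglik(model, prop, bmu) - fixed_loglik(model, d, bmu) +
            stats::dnorm(prop[p], 0, prior_sd, log = TRUE) -
            stats::dnorm(d[p], 0, prior_sd, log = TRUE)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            d <- prop
            d_acc[p] <- d_acc[p] + 1
          }
        }
        for (nm in names(model$binstudies)) {
          s <- model$binstudies[[nm]]
          mu_s <- as.vector(s$X %*% d)
          st <- bin_mh_update(s, bmu[[nm]], mu_s, mu_s, 0,
                              prop_sd$mu[[nm]], NULL)
          bmu[[nm]] <- st$mu
          acc$mu[[nm]] <- acc$mu[[nm]] + st$acc_mu
        }
      }
    }

    # adapt proposal scales during burn-in
    if (has_bin && it <= config$burn_in && it %% adapt_every == 0) {
      for (nm in names(model$binstudies)) {
        rate <- acc$mu[[nm]] / adapt_every
        prop_sd$mu[[nm]] <- clamp(prop_sd$mu[[nm]] * exp(rate - 0.44), 0.01, 5)
        acc$mu[[nm]] <- 0
        if (random) {
          rate <- acc$delta[[nm]] / adapt_every
          prop_sd$delta[[nm]] <- clamp(prop_sd$delta[[nm]] * exp(rate - 0.44),
                                       0.01, 5)
          acc$delta[[nm]] <- rep(0, model$binstudies[[nm]]$k)
        }
      }
      if (!random && has_bin) {
        d_prop_sd <- clamp(d_prop_sd * exp(d_acc / adapt_every - 0.44), 0.01, 5)
        d_acc[] <- 0
      }
    }

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
      kept <- kept + 1L
      keep_d[kept, ] <- d
      if (random) keep_sigma[kept] <- sigma
      fv <- fitted_values(model, d, random,
                          delta_u, delta_m, bdelta, bmu)
      keep_dev[kept] <- deviance_at(model, fv)
      fitted_sum <- fitted_sum + fv
    }
  }

  list(d = keep_d, sigma = keep_sigma, dev = keep_dev, fitted_sum = fitted_sum)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Metropolis update of a binary study's baseline logit and (optionally) its
# delta block. `sigma = 0` marks fixed effects: delta stays at prior_mean.
bin_mh_update <- function(s, mu, delta, prior_mean, sigma, sd_mu, sd_delta) {
  loglik <- function(mu, delta) {
    eta <- c(mu, mu + delta)
    sum(stats::dbinom(s$r, s$n, invlogit(eta), log = TRUE))
  }
  acc_mu <- 0
  prop <- mu + stats::rnorm(1, 0, sd_mu)
  lr <- loglik(prop, delta) - loglik(mu, delta) +
    stats::dnorm(prop, 0, 15, log = TRUE) - stats::dnorm(mu, 0, 15, log = TRUE)
  if (is.finite(lr) && log(stats::runif(1)) < lr) {
    mu <- prop; acc_mu <- 1
  }
  acc_delta <- rep(0, s$k)
  if (!is.null(sd_delta) && sigma > 0) {
    Cprec <- s$Cinv / sigma^2
    for (j in seq_len(s$k)) {
      prop <- delta
      prop[j] <- delta[j] + stats::rnorm(1, 0, sd_delta[j])
      dpr <- -0.5 * (t(prop - prior_mean) %*% Cprec %*% (prop - prior_mean) -
                       t(delta - prior_mean) %*% Cprec %*% (delta - prior_mean))
      lr <- loglik(mu, prop) - loglik(mu, delta) + as.numeric(dpr)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        delta <- prop; acc_delta[j] <- 1
      }
    }
  }
  list(mu = mu, delta = delta, acc_mu = acc_mu, acc_delta = acc_delta)
}

# log-likelihood of all data at fixed-effect parameters d (binary studies
# profiled at current mu)
fixed_loglik <- function(model, d, bmu) {
  ll <- 0
  for (s in model$studies) {
    r <- s$y - as.vector(s$X %*% d)
    ll <- ll - 0.5 * sum(r * (s$Vinv %*% r))
  }
  for (nm in names(model$binstudies)) {
    s <- model$binstudies[[nm]]
    eta <- c(bmu[[nm]], bmu[[nm]] + as.vector(s$X %*% d))
    ll <- ll + sum(stats::dbinom(s$r, s$n, invlogit(eta), log = TRUE))
  }
  ll
}

# per-datum fitted values (order: single-contrast studies, multi-arm
# blocks, binary arms with baseline first): normal data -> fitted mean of
# y; binary data -> fitted event probability per arm
fitted_values <- function(model, d, random, delta_u, delta_m, bdelta, bmu) {
  fv <- numeric(0)
  if (!is.null(model$uni))
    fv <- if (random) delta_u else as.vector(model$uni$X %*% d)
  for (nm in names(model$multi)) {
    s <- model$multi[[nm]]
    th <- if (random) delta_m[[nm]] else as.vector(s$X %*% d)
    fv <- c(fv, th)
  }
  for (nm in names(model$binstudies)) {
    s <- model$binstudies[[nm]]
    del <- if (random) bdelta[[nm]] else as.vector(s$X %*% d)
    fv <- c(fv, invlogit(c(bmu[[nm]], bmu[[nm]] + del)))
  }
  fv
}

# residual deviance at given fitted values: (y - theta)' Vinv (y - theta)
# per normal block, the saturated binomial deviance per arm
deviance_at <- function(model, fitted) {
  dev <- 0
  i <- 0L
  if (!is.null(model$uni)) {
    n_u <- length(model$uni$y)
    th <- fitted[seq_len(n_u)]
    i <- n_u
    dev <- dev + sum(model$uni$vinv * (model$uni$y - th)^2)
  }
  for (nm in names(model$multi)) {
    s <- model$multi[[nm]]
    th <- fitted[i + seq_len(s$k)]
    i <- i + s$k
    r <- s$y - th
    dev <- dev + sum(r * (s$Vinv %*% r))
  }
  for (nm in names(model$binstudies)) {
    s <- model$binstudies[[nm]]
    p <- fitted[i + seq_len(s$k + 1L)]
    i <- i + s$k + 1L
    rhat <- s$n * p
    t1 <- ifelse(s$r > 0, s$r * log(s$r / rhat), 0)
    t2 <- ifelse(s$r < s$n, (s$n - s$r) * log((s$n - s$r) / (s$n - rhat)), 0)
    dev <- dev + 2 * sum(t1 + t2)
  }
  dev
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("Bayesian NMA fit (", x$structure, ", ", x$effects, " effects, ",
      toupper(x$measure), " scale)\n", sep = "")
  cat("  treatments:", paste(x$treatments, collapse = ", "),
      " (reference:", x$reference, ")\n")
  cat(sprintf("  %d pooled draws; Dbar = %.2f, pD = %.2f, DIC = %.2f (n = %d data points)\n",
              x$n_draws, x$Dbar, x$pD, x$DIC, x$n_data))
  if (!is.null(x$sigma))
    cat(sprintf("  sigma posterior median %.3f (95%% CrI %.3f-%.3f)\n",
                stats::median(x$sigma),
                stats::quantile(x$sigma, 0.025),
                stats::quantile(x$sigma, 0.975)))
  cat(sprintf("  max split-chain PSRF %.3f\n", max(x$psrf, na.rm = TRUE)))
  invisible(x)
}

#' Deviance summaries of a fit
#'
#' @param fit An `nma_fit`.
#' @return A list with `Dbar` (posterior mean residual deviance), `pD`
#'   (effective number of parameters, `Dbar` minus the deviance at the
#'   posterior-mean fitted values) and `DIC = Dbar + pD`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  list(Dbar = fit$Dbar, pD = fit$pD, DIC = fit$DIC, n_data = fit$n_data)
}

#' League table of all pairwise relative effects
#'
#' Summarizes the posterior of every pairwise contrast on the natural
#' (ratio) scale. Cell `[r, c]` is the effect of the column treatment
#' relative to the row treatment: the posterior median and equal-tailed 95%
#' credible interval of `exp(d_col - d_row)`. Medians and interval bounds
#' are computed on the log-scale samples and exponentiated, so the
#' reciprocity `cell[r, c] * cell[c, r] = 1` holds exactly.
#'
#' @param fit An `nma_fit` with consistency structure.
#' @param order Optional treatment ordering for rows/columns.
#' @param level Credible level (default 0.95).
#' @return An object of class `league_table` with matrices `median`,
#'   `lower`, `upper` and a formatted character matrix.
#' @export
league_table <- function(fit, order = NULL, level = 0.95) {
  stopifnot(inherits(fit, "nma_fit"))
  if (is.null(fit$d)) stop("league tables require the consistency structure")
  trt <- fit$treatments
  if (is.null(order)) order <- trt
  if (!all(order %in% trt))
    stop("unknown treatment in 'order': ",
         paste(setdiff(order, trt), collapse = ", "))
  a <- length(order)
  med <- lo <- hi <- matrix(NA_real_, a, a, dimnames = list(order, order))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  for (r in seq_len(a)) for (cl in seq_len(a)) {
    if (r == cl) next
    x <- fit$d[, order[cl]] - fit$d[, order[r]]
    qq <- stats::quantile(x, pr, names = FALSE)
    med[r, cl] <- exp(stats::median(x))
    lo[r, cl] <- exp(qq[1]); hi[r, cl] <- exp(qq[2])
  }
  fmt <- matrix(sprintf("%.2f (%.2f, %.2f)", med, lo, hi), a, a,
                dimnames = list(order, order))
  diag(fmt) <- order
  structure(list(treatments = order, median = med, lower = lo, upper = hi,
                 formatted = fmt, level = level,
                 orientation = "cell[r,c] = column vs row"),
            class = "league_table")
}

#' @export
print.league_table <- function(x, ...) {
  cat("League table (", x$orientation, ", ", x$level * 100, "% CrI):\n", sep = "")
  print(x$formatted, quote = FALSE)
  invisible(x)
}

#' Long-format league table
#'
#' @param lt A `league_table`.
#' @return A data frame with one row per ordered treatment pair:
#'   `treatment`, `reference`, `median`, `cri_low`, `cri_high`.
#' @export
league_long <- function(lt) {
  stopifnot(inherits(lt, "league_table"))
  trt <- lt$treatments
  out <- NULL
  for (r in seq_along(trt)) for (cl in seq_along(trt)) {
    if (r == cl) next
    out <- rbind(out, data.frame(treatment = trt[cl], reference = trt[r],
                                 median = lt$median[r, cl],
                                 cri_low = lt$lower[r, cl],
                                 cri_high = lt$upper[r, cl]))
  }
  rownames(out) <- NULL
  out
}

#' MCMC convergence diagnostics
#'
#' Split-chain potential scale reduction factors (Gelman-Rubin),
#' within-chain autocorrelation, and effective sample sizes. Accepts either
#' an `nma_fit` or a list of per-chain draw matrices (rows = iterations,
#' columns = parameters).
#'
#' @param x An `nma_fit`, or a list of numeric matrices with identical
#'   dimensions and column names.
#' @param max_lag Largest autocorrelation lag reported (default 50).
#' @return A list with `psrf` (named vector; `NA` with one chain),
#'   `autocorr` (lags x parameters matrix of chain-averaged
#'   autocorrelations) and `ess`.
#' @export
convergence_diagnostics <- function(x, max_lag = 50) {
  if (inherits(x, "nma_fit")) return(x$diagnostics)
  stopifnot(is.list(x), length(x) >= 1)
  chains <- lapply(x, as.matrix)
  n <- nrow(chains[[1]])
  pn <- colnames(chains[[1]])
  if (is.null(pn)) pn <- paste0("par", seq_len(ncol(chains[[1]])))
  npar <- ncol(chains[[1]])

  # split each chain in half for the PSRF
  psrf <- rep(NA_real_, npar)
  if (length(chains) >= 2 || n >= 4) {
    half <- n %/% 2
    subs <- unlist(lapply(chains, function(m)
      list(m[seq_len(half), , drop = FALSE],
           m[(n - half + 1):n, , drop = FALSE])), recursive = FALSE)
    m <- length(subs)
    for (p in seq_len(npar)) {
      means <- vapply(subs, function(s) mean(s[, p]), 0)
      vars <- vapply(subs, function(s) stats::var(s[, p]), 0)
      W <- mean(vars)
      B <- half * stats::var(means)
      if (W <= 0) {
        psrf[p] <- if (B > 0) Inf else 1
      } else {
        psrf[p] <- sqrt(((half - 1) / half * W + B / half) / W)
      }
    }
  }

  lags <- seq_len(max_lag)
  auto <- matrix(NA_real_, max_lag, npar, dimnames = list(lags, pn))
  ess <- numeric(npar)
  for (p in seq_len(npar)) {
    acfs <- vapply(chains, function(m) {
      if (stats::var(m[, p]) <= 0) return(rep(0, max_lag))
      stats::acf(m[, p], lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf[-1]
    }, numeric(max_lag))
    rho <- rowMeans(acfs)
    auto[, p] <- rho
    # initial positive sequence truncation
    pos <- which(rho <= 0)
    upto <- if (length(pos)) pos[1] - 1L else max_lag
    tau <- 1 + 2 * sum(rho[seq_len(upto)])
    ess[p] <- n * length(chains) / max(tau, 1e-8)
  }
  names(psrf) <- pn
  names(ess) <- pn
  list(psrf = psrf, autocorr = auto, ess = ess)
}

#' Posterior summary of the heterogeneity standard deviation
#'
#' @param fit A random-effects `nma_fit`.
#' @param level Credible level.
#' @return Named vector: median and credible bounds of sigma.
#' @export
sigma_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nma_fit"))
  if (is.null(fit$sigma)) stop("fixed-effect fit carries no sigma")
  q <- stats::quantile(fit$sigma, c(0.5, (1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(median = q[1], lower = q[2], upper = q[3])
}
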