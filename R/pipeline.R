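#' Run the full analysis pipeline for one outcome
#'
#' Reproduces the analysis shape used for each endpoint: direct pairwise
#' meta-analysis, evidence-network summary, node-splitting on every loop
#' comparison, the hierarchical NMA with its heterogeneity posterior and
#' league table, the unrelated-mean-effects refit with DIC comparison,
#' SUCRA ranking, and comparison-adjusted funnel data. All artifacts are
#' written as headed CSV/JSON files plus a run log.
#'
#' @param dataset An [outcome_dataset()] or a path to a contrast CSV
#'   readable by [read_contrast_table()].
#' @param out_dir Output directory (created if missing).
#' @param config An [nma_config()].
#' @param direction `"lower"` or `"higher"`: which end of the effect scale
#'   is clinically better for this outcome.
#' @param diagnostics Character subset of
#'   `c("nodesplit", "ume", "funnel", "ranking")`.
#' @param effects Effect models to fit: first entry is the primary model
#'   whose league table and ranking are reported; all entries contribute a
#'   fit summary with DIC.
#' @return (Invisibly) a list with every computed object and the paths of
#'   the written artifacts.
#' @export
run_outcome <- function(dataset, out_dir, config = nma_config(),
                        direction = c("lower", "higher"),
                        diagnostics = c("nodesplit", "ume", "funnel", "ranking"),
                        effects = config$effects) {
  direction <- match.arg(direction)
  diagnostics <- match.arg(diagnostics, several.ok = TRUE)
  if (is.character(dataset)) dataset <- read_contrast_table(dataset)
  stopifnot(inherits(dataset, "outcome_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wcsv <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[file]] <<- p
    p
  }

  network <- stage("network", build_network(dataset))
  wcsv(network$edges, "network.csv")

  direct <- stage("direct_ma", direct_meta(dataset))
  wcsv(direct, "direct_ma.csv")

  fits <- list()
  for (eff in unique(effects)) {
    cfg <- config; cfg$effects <- eff
    fits[[eff]] <- stage(paste0("nma_", eff), fit_nma(dataset, cfg))
  }
  primary <- fits[[1]]

  lt <- stage("league", league_table(primary))
  utils::write.csv(lt$formatted, file.path(out_dir, "league.csv"))
  paths[["league.csv"]] <- file.path(out_dir, "league.csv")
  wcsv(league_long(lt), "league_long.csv")

  summaries <- list()
  for (eff in names(fits)) {
    f <- fits[[eff]]
    summaries[[eff]] <- list(
      effects = eff, structure = f$structure,
      Dbar = f$Dbar, pD = f$pD, DIC = f$DIC, n_data = f$n_data,
      psrf_max = max(f$psrf, na.rm = TRUE),
      sigma = if (!is.null(f$sigma)) as.list(sigma_summary(f)) else NULL)
  }
  if ("ume" %in% diagnostics) {
    cfg <- config; cfg$structure <- "ume"
    ume <- stage("ume", fit_nma(dataset, cfg))
    summaries[["ume"]] <- list(
      effects = cfg$effects, structure = "ume",
      Dbar = ume$Dbar, pD = ume$pD, DIC = ume$DIC, n_data = ume$n_data,
      psrf_max = max(ume$psrf, na.rm = TRUE),
      sigma = if (!is.null(ume$sigma)) as.list(sigma_summary(ume)) else NULL)
    fits[["ume"]] <- ume
  }
  paths[["fit_summary.json"]] <- file.path(out_dir, "fit_summary.json")
  jsonlite::write_json(summaries, paths[["fit_summary.json"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  nsplit <- NULL
  if ("nodesplit" %in% diagnostics) {
    nsplit <- stage("nodesplit", node_split_all(dataset, config))
    wcsv(nsplit, "nodesplit.csv")
  }

  ranking <- NULL
  if ("ranking" %in% diagnostics) {
    ranking <- stage("ranking", rank_probabilities(primary, direction))
    wcsv(data.frame(treatment = ranking$treatments,
                    sucra = as.numeric(ranking$sucra),
                    p_best = as.numeric(ranking$p_best)), "sucra.csv")
    rm_df <- as.data.frame(ranking$prob)
    names(rm_df) <- paste0("rank", seq_along(rm_df))
    wcsv(cbind(treatment = ranking$treatments, rm_df), "rank_matrix.csv")
  }

  funnel <- NULL
  if ("funnel" %in% diagnostics && !is.null(dataset$contrasts)) {
    funnel <- stage("funnel", funnel_points(dataset))
    wcsv(funnel$points, "funnel.csv")
  }

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    paste0("hccnma ", as.character(utils::packageVersion("hccnma"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("measure: ", dataset$measure, "  direction: ", direction),
    paste0("seed: ", config$seed),
    paste0("config: chains=", config$chains, " iterations=", config$iterations,
           " burn_in=", config$burn_in, " thin=", config$thin,
           " sigma_upper=", config$sigma_upper,
           " prior_sd_d=", if (is.null(config$prior_sd_d)) "auto" else config$prior_sd_d),
    paste0("effects: ", paste(unique(effects), collapse = ", "),
           "  diagnostics: ", paste(diagnostics, collapse = ", ")),
    paste0("artifacts: ", paste(names(paths), collapse = ", "))),
    log_path)
  paths[["run.log"]] <- log_path

  invisible(list(network = network, direct = direct, fits = fits,
                 league = lt, nodesplit = nsplit, ranking = ranking,
                 funnel = funnel, summaries = summaries, paths = paths))
}

#' Parameter-recovery and calibration study on synthetic networks
#'
#' Simulates `n_replicates` evidence networks with known truth, fits the
#' NMA to each, and reports per-parameter coverage of the 95% credible
#' intervals, mean bias and RMSE of the basic parameters; optionally, the
#' node-splitting rejection rate on the design's loop edge under a given
#' inconsistency offset.
#'
#' @param n_replicates Number of replicates (>= 2); replicate `i` uses seed
#'   `seed + i`.
#' @param truth_args List of arguments to [sim_truth()] shared by all
#'   replicates (the per-replicate seed is inserted automatically).
#' @param config An [nma_config()] for the fits (use a reduced run).
#' @param omega Inconsistency offset injected on the loop edge
#'   (`Pla`-`Sor`); `NULL` (default) skips node-splitting.
#' @param seed Base seed.
#' @return A list with `coverage`, `bias`, `rmse` (per basic parameter and
#'   overall), and `rejection_rate` (share of replicates with node-split
#'   `p < 0.05`) when `omega` is not `NULL`. Per-fit convergence warnings
#'   are folded into `psrf_max` rather than raised per replicate.
#' @export
run_recovery_study <- function(n_replicates, truth_args = list(),
                               config = nma_config(chains = 2,
                                                   iterations = 3000,
                                                   burn_in = 1000, thin = 1),
                               omega = NULL, seed = 0) {
  if (n_replicates < 2) stop("at least 2 replicates are required")
  cover <- bias <- NULL
  reject <- logical(0)
  psrf_max <- 0
  # per-fit convergence warnings are collected into psrf_max instead of
  # being raised n_replicates times
  note_psrf <- function(fit) psrf_max <<- max(psrf_max, fit$psrf, na.rm = TRUE)
  quiet_fit <- function(expr)
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("PSRF", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  for (i in seq_len(n_replicates)) {
    ta <- truth_args
    ta$seed <- seed + i
    truth <- do.call(sim_truth, ta)
    if (!is.null(omega) && omega != 0)
      truth <- inject_inconsistency(truth, c("Pla", "Sor"), omega)
    sim <- simulate_contrast_network(truth)
    cfg <- config
    cfg$seed <- seed + i
    if (is.null(omega)) {
      fit <- quiet_fit(fit_nma(sim$dataset, cfg, reference = names(truth$d)[1]))
      note_psrf(fit)
      est <- apply(fit$d, 2, stats::median)[names(truth$d)]
      lo <- apply(fit$d, 2, stats::quantile, 0.025)[names(truth$d)]
      hi <- apply(fit$d, 2, stats::quantile, 0.975)[names(truth$d)]
      nonref <- names(truth$d)[-1]
      cover <- rbind(cover, (lo <= truth$d & truth$d <= hi)[nonref])
      bias <- rbind(bias, (est - truth$d)[nonref])
    } else {
      ns <- quiet_fit(node_split(sim$dataset, c("Pla", "Sor"), cfg))
      note_psrf(ns$fit)
      reject <- c(reject, ns$p < 0.05)
    }
  }
  out <- list(n_replicates = n_replicates, config = config,
              psrf_max = psrf_max)
  if (is.null(omega)) {
    out$coverage <- colMeans(cover)
    out$coverage_overall <- mean(cover)
    out$bias <- colMeans(bias)
    out$bias_overall <- mean(bias)
    out$rmse <- sqrt(colMeans(bias^2))
    out$rmse_overall <- sqrt(mean(bias^2))
  } else {
    out$omega <- omega
    out$rejection_rate <- mean(reject)
  }
  out
}
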