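#' Constituent agents of a treatment label
#'
#' Splits a regimen label into its constituent drug names. Combination
#' regimens are split on `+`; dose qualifiers (e.g. `"Van 100mg"`,
#' `"Van100"`, `"Tig 2mg"`) are stripped so that dose variants of one drug
#' share a single agent name. Placebo (`"Pla"`, `"Placebo"`, case
#' insensitive) has an empty agent set: it is an ordinary network node that
#' contributes no drug.
#'
#' @param label Treatment id or label, e.g. `"Erl + Sor"`.
#' @return Character vector of agent names (possibly empty for placebo).
#' @examples
#' treatment_agents("Tig 2mg + Sor")
#' treatment_agents("Pla")
#' @export
treatment_agents <- function(label) {
  stopifnot(length(label) == 1, is.character(label))
  parts <- trimws(strsplit(label, "+", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  # strip trailing dose tokens: "Van 100mg", "Van100", "Tig 6 mg"
  parts <- sub("[ _]*[0-9.]+[ ]*(mg|g|mcg)?$", "", parts)
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  parts[!tolower(parts) %in% c("pla", "placebo")]
}

#' Treatment table for an evidence network
#'
#' @param id Unique short treatment codes.
#' @param label Optional free-text labels (defaults to `id`).
#' @return A data frame with columns `id`, `label` and a list column
#'   `agents` derived by [treatment_agents()].
#' @export
treatment_table <- function(id, label = id) {
  if (anyDuplicated(id)) stop("treatment ids must be unique")
  data.frame(id = as.character(id), label = as.character(label),
             agents = I(lapply(as.character(id), treatment_agents)))
}

#' Evidence network dataset for one outcome
#'
#' Bundles the evidence for a single endpoint (e.g. overall survival as log
#' hazard ratios, or objective response as log odds ratios): within-trial
#' contrasts `(y_i, SE_i)` on the log scale, and/or binary arm counts. A
#' study contributes either contrasts or binary arms, never both. Contrasts
#' from multi-arm trials share a reference arm; their data-level covariance
#' may be supplied per study via `multiarm_cov` (matrices ordered as the
#' study's contrast rows) and is otherwise taken as zero.
#'
#' @param measure `"hr"` (log hazard ratio) or `"or"` (log odds ratio).
#' @param contrasts Data frame with columns `study`, `treatment`,
#'   `reference`, `estimate` (log scale), `std_err`, and optionally `source`.
#' @param arms Data frame with columns `study`, `treatment`, `events`,
#'   `total`.
#' @param treatments Optional treatment table from [treatment_table()];
#'   derived from the evidence when omitted.
#' @param multiarm_cov Optional named list (by study) of data-level
#'   covariance matrices between that study's contrasts.
#' @return An object of class `outcome_dataset`.
#' @export
outcome_dataset <- function(measure = c("hr", "or"), contrasts = NULL,
                            arms = NULL, treatments = NULL,
                            multiarm_cov = NULL) {
  measure <- match.arg(measure)
  if (is.null(contrasts) && is.null(arms))
    stop("at least one of 'contrasts' or 'arms' is required")
  if (!is.null(contrasts)) {
    need <- c("study", "treatment", "reference", "estimate", "std_err")
    miss <- setdiff(need, names(contrasts))
    if (length(miss)) stop("contrasts lack columns: ", paste(miss, collapse = ", "))
    contrasts <- as.data.frame(contrasts)
    for (col in c("study", "treatment", "reference"))
      contrasts[[col]] <- as.character(contrasts[[col]])
    if (!"source" %in% names(contrasts)) contrasts$source <- "reported_ci"
    if (any(contrasts$treatment == contrasts$reference))
      stop("a contrast must compare two distinct treatments")
    if (any(!is.finite(contrasts$std_err)) || any(contrasts$std_err <= 0))
      stop("contrast standard errors must be finite and positive")
    key <- paste(contrasts$study, contrasts$treatment, contrasts$reference)
    if (anyDuplicated(key))
      stop("duplicate (study, treatment, reference) rows; keep one effect per comparison")
  }
  if (!is.null(arms)) {
    need <- c("study", "treatment", "events", "total")
    miss <- setdiff(need, names(arms))
    if (length(miss)) stop("arms lack columns: ", paste(miss, collapse = ", "))
    arms <- as.data.frame(arms)
    arms$study <- as.character(arms$study)
    arms$treatment <- as.character(arms$treatment)
    if (any(arms$total < 1)) stop("arm totals must be at least 1")
    if (any(arms$events < 0) || any(arms$events > arms$total))
      stop("arm events must satisfy 0 <= events <= total")
    narm <- table(arms$study)
    if (any(narm < 2))
      stop("studies with fewer than 2 arms: ",
           paste(names(narm)[narm < 2], collapse = ", "))
    if (anyDuplicated(paste(arms$study, arms$treatment)))
      stop("duplicate (study, treatment) arm rows")
  }
  if (!is.null(contrasts) && !is.null(arms)) {
    both <- intersect(unique(contrasts$study), unique(arms$study))
    if (length(both))
      stop("studies contributing both contrasts and arms: ",
           paste(both, collapse = ", "))
  }
  seen <- unique(c(contrasts$treatment, contrasts$reference, arms$treatment))
  if (is.null(treatments)) {
    treatments <- treatment_table(sort(seen))
  } else {
    unused <- setdiff(treatments$id, seen)
    if (length(unused))
      stop("treatments with no evidence: ", paste(unused, collapse = ", "))
    unknown <- setdiff(seen, treatments$id)
    if (length(unknown))
      stop("evidence for treatments missing from the table: ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(multiarm_cov)) {
    stopifnot(is.list(multiarm_cov), !is.null(names(multiarm_cov)))
    for (s in names(multiarm_cov)) {
      k <- sum(contrasts$study == s)
      m <- multiarm_cov[[s]]
      if (!is.matrix(m) || nrow(m) != k || ncol(m) != k)
        stop("multiarm_cov for study ", s, " must be a ", k, "x", k, " matrix")
    }
  }
  structure(list(measure = measure, treatments = treatments,
                 contrasts = contrasts, arms = arms,
                 multiarm_cov = multiarm_cov),
            class = "outcome_dataset")
}

#' @export
print.outcome_dataset <- function(x, ...) {
  cat("Evidence network (", toupper(x$measure), " scale): ",
      nrow(x$treatments), " treatments, ",
      if (is.null(x$contrasts)) 0L else nrow(x$contrasts), " contrasts, ",
      if (is.null(x$arms)) 0L else nrow(x$arms), " binary arms\n", sep = "")
  invisible(x)
}

#' Read a contrast-level effect table
#'
#' Reads a CSV of within-trial relative effects, one row per comparison,
#' with columns `study`, `treatment`, `reference`, `measure`, and either the
#' natural-scale triple `estimate`, `ci_lower`, `ci_upper` (converted through
#' [effect_from_ci()]) or the log-scale pair `log_estimate`, `std_err`
#' (stored verbatim). Empty cells are missing; each row must carry exactly
#' one complete parameterization.
#'
#' @param source Path to a CSV file, or a data frame already in that layout.
#' @param level Confidence level of reported intervals (default 0.95).
#' @return An [outcome_dataset()].
#' @export
read_contrast_table <- function(source, level = 0.95) {
  tab <- if (is.data.frame(source)) source else
    utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("study", "treatment", "reference", "measure")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  has_ci <- all(c("estimate", "ci_lower", "ci_upper") %in% names(tab))
  has_log <- all(c("log_estimate", "std_err") %in% names(tab))
  if (!has_ci && !has_log)
    stop("need columns (estimate, ci_lower, ci_upper) or (log_estimate, std_err)")
  measure <- unique(tolower(tab$measure))
  if (length(measure) != 1 || !measure %in% c("hr", "or"))
    stop("'measure' must be a single value, 'hr' or 'or'")
  n <- nrow(tab)
  est <- se <- rep(NA_real_, n)
  src <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    lg <- has_log && is.finite(suppressWarnings(as.numeric(tab$log_estimate[i]))) &&
      is.finite(suppressWarnings(as.numeric(tab$std_err[i])))
    ci <- has_ci && is.finite(suppressWarnings(as.numeric(tab$estimate[i])))
    if (lg) {
      est[i] <- as.numeric(tab$log_estimate[i])
      se[i] <- as.numeric(tab$std_err[i])
      src[i] <- "log_se"
    } else if (ci) {
      lo <- as.numeric(tab$ci_lower[i]); hi <- as.numeric(tab$ci_upper[i])
      pt <- as.numeric(tab$estimate[i])
      if (!is.finite(lo) || !is.finite(hi))
        stop("row ", i, ": natural-scale estimate without both CI bounds")
      if (lo > hi) stop("row ", i, ": ci_lower exceeds ci_upper")
      e <- effect_from_ci(pt, lo, hi, level = level)
      est[i] <- e$estimate; se[i] <- e$std_err
      src[i] <- "reported_ci"
    } else {
      stop("row ", i, ": neither a CI triple nor a (log_estimate, std_err) pair")
    }
  }
  outcome_dataset(measure = measure,
                  contrasts = data.frame(study = tab$study,
                                         treatment = tab$treatment,
                                         reference = tab$reference,
                                         estimate = est, std_err = se,
                                         source = src))
}

#' Read an arm-level binary outcome table
#'
#' Reads a CSV with columns `study`, `treatment`, `events`, `total` and
#' validates counts and study structure (at least two arms per study).
#'
#' @param source Path to a CSV file, or a data frame.
#' @return A validated data frame of binary arms.
#' @export
read_arm_table <- function(source) {
  tab <- if (is.data.frame(source)) source else
    utils::read.csv(source, stringsAsFactors = FALSE)
  ds <- outcome_dataset(measure = "or", arms = tab)
  ds$arms
}

#' Read a study-metadata table
#'
#' Reads the trial-characteristics table (one row per arm: `study`, `year`,
#' `treatment`, `n`, `median_age`; empty `median_age` = not reported). The
#' packaged transcription of the 22 first-line HCC trials is at
#' `system.file("extdata", "hcc_study_table.csv", package = "hccnma")`.
#'
#' @param source Path to a CSV file, or a data frame.
#' @return A data frame of class `study_meta`.
#' @export
read_study_table <- function(source) {
  tab <- if (is.data.frame(source)) source else
    utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("study", "year", "treatment", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"median_age" %in% names(tab)) tab$median_age <- NA_real_
  if (any(tab$n < 1)) stop("arm sizes must be at least 1")
  narm <- table(tab$study)
  if (any(narm < 2))
    stop("studies with fewer than 2 arms: ",
         paste(names(narm)[narm < 2], collapse = ", "))
  if (anyDuplicated(paste(tab$study, tab$treatment)))
    stop("duplicate (study, treatment) rows")
  class(tab) <- c("study_meta", "data.frame")
  tab
}

#' Curation summary of a set of trials
#'
#' Totals used to describe an evidence base: number of studies, total
#' randomized patients, the range of within-trial sample sizes, the range of
#' arm median ages (arms with unreported age are ignored), and the number of
#' distinct drugs. Drugs are counted as distinct agent names across all
#' treatment nodes: combination components count individually, dose variants
#' of one drug collapse to a single agent, and placebo contributes none.
#'
#' @param metas A `study_meta` data frame from [read_study_table()].
#' @return A list with `n_studies`, `total_patients`, `trial_size_min`,
#'   `trial_size_max`, `age_min`, `age_max`, `n_distinct_agents`, `agents`.
#' @examples
#' tab <- read_study_table(system.file("extdata", "hcc_study_table.csv",
#'                                     package = "hccnma"))
#' summarize_trials(tab)
#' @export
summarize_trials <- function(metas) {
  if (is.null(metas) || nrow(metas) == 0) stop("empty study list")
  sizes <- tapply(metas$n, metas$study, sum)
  ages <- metas$median_age[is.finite(metas$median_age)]
  agents <- sort(unique(unlist(lapply(unique(metas$treatment),
                                      treatment_agents))))
  structure(list(
    n_studies = length(unique(metas$study)),
    total_patients = sum(metas$n),
    trial_size_min = as.integer(min(sizes)),
    trial_size_max = as.integer(max(sizes)),
    age_min = if (length(ages)) min(ages) else NA_real_,
    age_max = if (length(ages)) max(ages) else NA_real_,
    n_distinct_agents = length(agents),
    agents = agents), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("Trials:", x$n_studies, "  patients:", x$total_patients,
      "\nTrial size:", x$trial_size_min, "-", x$trial_size_max,
      "  arm median age:", x$age_min, "-", x$age_max,
      "\nDistinct agents:", x$n_distinct_agents,
      paste0("(", paste(x$agents, collapse = ", "), ")"), "\n")
  invisible(x)
}
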