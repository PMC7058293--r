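test_that("contrast tables read from CSV convert natural-scale rows to log scale", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "study,treatment,reference,measure,estimate,ci_lower,ci_upper,log_estimate,std_err",
    "SHARP,Sor,Pla,hr,0.69,0.55,0.87,,",
    "AsiaPacific,Sor,Pla,hr,0.68,0.50,0.93,,",
    "verbatim,Sor,Pla,hr,,,,0.0,0.1"), f)
  ds <- read_contrast_table(f)
  expect_s3_class(ds, "outcome_dataset")
  expect_equal(nrow(ds$contrasts), 3)
  expect_equal(ds$contrasts$estimate[1:2], log(c(0.69, 0.68)))
  expect_equal(round(ds$contrasts$estimate[1:2], 3), c(-0.371, -0.386))
  # log rows pass through verbatim
  expect_equal(ds$contrasts$estimate[3], 0)
  expect_equal(ds$contrasts$std_err[3], 0.1)
})

test_that("malformed contrast rows are rejected", {
  base <- data.frame(study = "s", treatment = "B", reference = "A",
                     measure = "hr")
  expect_error(read_contrast_table(
    cbind(base, estimate = 0.7, ci_lower = 0.9, ci_upper = 0.8,
          log_estimate = NA, std_err = NA)), "ci_lower exceeds")
  expect_error(read_contrast_table(
    cbind(base, estimate = NA, ci_lower = NA, ci_upper = NA,
          log_estimate = NA, std_err = NA)), "neither")
  expect_error(read_contrast_table(data.frame(study = "s", treatment = "B")),
               "missing required columns")
  dup <- rbind(cbind(base, log_estimate = 0.1, std_err = 0.1),
               cbind(base, log_estimate = 0.2, std_err = 0.1))
  expect_error(read_contrast_table(dup), "duplicate")
  expect_error(read_contrast_table(
    cbind(base, estimate = -0.5, ci_lower = -0.6, ci_upper = 0.9,
          log_estimate = NA, std_err = NA)), "positive")
})

test_that("arm tables validate counts and study structure", {
  ok <- read_arm_table(data.frame(study = "s", treatment = c("A", "B"),
                                  events = c(10, 5), total = c(100, 100)))
  expect_equal(nrow(ok), 2)
  # an all-event arm is a legal boundary case
  allev <- read_arm_table(data.frame(study = "s", treatment = c("A", "B"),
                                     events = c(100, 5), total = c(100, 100)))
  expect_equal(allev$events[1], allev$total[1])
  expect_error(read_arm_table(data.frame(study = "s", treatment = c("A", "B"),
                                         events = c(1, 0), total = c(0, 10))),
               "at least 1")
  expect_error(read_arm_table(data.frame(study = "s", treatment = c("A", "B"),
                                         events = c(11, 0), total = c(10, 10))),
               "events")
  expect_error(read_arm_table(data.frame(study = "s", treatment = "A",
                                         events = 1, total = 10)),
               "fewer than 2 arms")
})

test_that("agents parse from regimen labels", {
  expect_equal(treatment_agents("Sor"), "Sor")
  expect_equal(treatment_agents("Bev + Erl"), c("Bev", "Erl"))
  expect_equal(treatment_agents("Tig 2mg + Sor"), c("Tig", "Sor"))
  expect_equal(treatment_agents("Van 100mg"), "Van")
  expect_equal(treatment_agents("Van100"), "Van")
  expect_length(treatment_agents("Pla"), 0)
  expect_length(treatment_agents("placebo"), 0)
})

test_that("network construction counts nodes/edges and enforces connectivity", {
  # hub-and-spoke geometry: drugs joined only through Sor and Pla
  spokes_sor <- c("Bri", "Erl+Sor", "Eve+Sor", "Len", "Lin", "Nin", "Sun",
                  "Tig 2mg + Sor", "Tig 6mg + Sor")
  spokes_pla <- c("Bri", "Ora")
  ds <- make_contrasts(
    study = c(paste0("s", seq_along(spokes_sor)),
              paste0("p", seq_along(spokes_pla)), "hub1", "hub2"),
    treatment = c(spokes_sor, spokes_pla, "Sor", "Sor"),
    reference = c(rep("Sor", length(spokes_sor)),
                  rep("Pla", length(spokes_pla)), "Pla", "Pla"),
    estimate = 0, std_err = 0.2)
  net <- build_network(ds)
  expect_equal(net$n_nodes, 12)
  expect_equal(net$n_studies, 13)
  # dropping every hub contrast disconnects the evidence
  keep <- !(ds$contrasts$reference %in% c("Sor", "Pla") |
              ds$contrasts$treatment %in% c("Sor", "Pla"))
  expect_error(
    build_network(outcome_dataset("hr", contrasts = ds$contrasts[keep, ])),
    "no evidence")
  split_ds <- make_contrasts(c("s1", "s2"), c("B", "D"), c("A", "C"),
                             0, 0.2)
  expect_error(build_network(split_ds), "disconnected")
  single <- make_contrasts("s1", "B", "A", -0.5, 0.1)
  net1 <- build_network(single)
  expect_equal(c(net1$n_nodes, net1$n_edges), c(2, 1))
})

test_that("connectivity agrees with a union-find oracle on random graphs", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    nodes <- LETTERS[seq_len(n)]
    m <- sample(2:14, 1)
    edges <- cbind(sample(nodes, m, replace = TRUE),
                   sample(nodes, m, replace = TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges) == 0) next
    used <- unique(c(edges))
    co <- data.frame(study = paste0("s", seq_len(nrow(edges))),
                     treatment = edges[, 1], reference = edges[, 2],
                     estimate = 0, std_err = 1)
    co <- co[!duplicated(paste(co$study, co$treatment, co$reference)), ]
    ds <- outcome_dataset("hr", contrasts = co,
                          treatments = treatment_table(used))
    oracle <- uf_connected(used, edges)
    if (oracle) {
      expect_silent(build_network(ds))
    } else {
      expect_error(build_network(ds), "disconnected")
    }
  }
})

test_that("curation totals on the transcribed study table match brute-force sums", {
  tab <- read_study_table(system.file("extdata", "hcc_study_table.csv",
                                      package = "hccnma"))
  s <- summarize_trials(tab)
  expect_equal(s$n_studies, length(unique(tab$study)))
  expect_equal(s$total_patients, sum(tab$n))
  sizes <- tapply(tab$n, tab$study, sum)
  expect_equal(s$trial_size_min, min(sizes))
  expect_equal(s$trial_size_max, max(sizes))
  expect_equal(s$age_min, min(tab$median_age, na.rm = TRUE))
  expect_equal(s$age_max, max(tab$median_age, na.rm = TRUE))
  # dose variants collapse, combinations split, placebo excluded
  expect_true(all(c("Van", "Tig", "Bev", "Erl") %in% s$agents))
  expect_false("Pla" %in% s$agents)
  expect_error(summarize_trials(tab[0, ]), "empty")
})

test_that("dataset validation enforces the evidence contract", {
  expect_error(outcome_dataset("hr"), "at least one")
  expect_error(make_contrasts("s", "A", "A", 0, 0.1), "distinct")
  expect_error(make_contrasts("s", "B", "A", 0, -1), "positive")
  # a study cannot contribute both contrasts and arms
  expect_error(outcome_dataset(
    "or",
    contrasts = data.frame(study = "s", treatment = "B", reference = "A",
                           estimate = 0, std_err = 0.1),
    arms = data.frame(study = "s", treatment = c("A", "B"),
                      events = c(1, 2), total = c(10, 10))),
    "both contrasts and arms")
  # a treatment with no evidence is rejected
  expect_error(outcome_dataset(
    "hr",
    contrasts = data.frame(study = "s", treatment = "B", reference = "A",
                           estimate = 0, std_err = 0.1),
    treatments = treatment_table(c("A", "B", "C"))), "no evidence")
})
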