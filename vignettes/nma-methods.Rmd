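---
title: "Methods: contrast-based Bayesian NMA for first-line HCC therapy networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-based Bayesian NMA for first-line HCC therapy networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccnma)
```

This vignette is the package's own account of the statistics it
implements: the models, the sampler, the numerical choices, what the
synthetic-data generator does and does not emulate, and the limitations a
user should keep in mind.

## Setting and data model

The evidence base the package is built around is the first-line systemic
therapy literature in advanced hepatocellular carcinoma: twenty-odd
randomized trials, each comparing a targeted agent (or combination, or
dose variant) against either sorafenib or placebo, with survival endpoints
summarized as hazard ratios and response/toxicity endpoints as odds
ratios. Structurally this is a two-hub network — almost every treatment is
connected only through `Sor` or `Pla` — with a single closed loop
(`Pla`–`Sor`–brivanib), and a couple of three-arm dose-ranging trials.

The unit of analysis is the within-trial contrast: a log hazard ratio or
log odds ratio `y_i` with standard error `SE_i` (`V_i = SE_i^2`). An
`outcome_dataset()` holds one endpoint's evidence: contrasts, and/or raw
binary arm counts for studies where only events/totals are published. A
study may contribute one kind of evidence, not both; duplicate
`(study, treatment, reference)` rows are rejected rather than resolved,
because choosing among effect estimates reported under different response
criteria is a curation decision, not a parsing one.

## Effect reconstruction

Three standard conversions recover `(y, SE)` from published summaries:

* **From a CI** — `y = ln(point)`, `SE = (ln U - ln L) / (2 z)` with `z`
  the two-sided normal quantile at the interval's level (default 0.95;
  configurable because some older trials report 90% intervals). Published
  bounds are rounded and therefore rarely exactly log-symmetric; the
  round-trip identity holds exactly only for log-symmetric triples.
* **From a log-rank p-value with event counts** — the null log-rank
  variance `V = E n1 n2 / (n1 + n2)^2` gives `SE = 1/sqrt(V)` and
  `y = ±z_p / sqrt(V)`, signed by which arm is favoured.
* **From tabulated Kaplan–Meier curves** — the time grid is cut into
  intervals; each interval's conditional survival drop yields an interval
  log hazard ratio `ln[ln S_t(b)/S_t(a)] - ln[ln S_c(b)/S_c(a)]` (constant
  under proportional hazards), with variance `1/e_c + 1/e_t` from expected
  events `e = n_eff (S(a) - S(b))/S(a)`. Effective numbers at risk come
  from the published risk table when available, else from
  `n_0 S(t)` deflated by a uniform-accrual censoring factor
  `1 - t/(2 F)` when a follow-up window `F` is known. Intervals with
  fewer than one expected event in either arm, or no survival drop, are
  dropped; the rest are pooled by inverse variance. Working with
  conditional (per-interval) drops rather than cumulative survival keeps
  the interval estimates approximately independent, which the
  inverse-variance pool assumes.

The curve-based route is validated against `simulate_km_tables()`, which
draws exponential event times under a known hazard ratio with uniform
censoring and tabulates true Kaplan–Meier output: across hazard ratios
0.5–2 with ≥ 500 events the absolute bias of the recovered log hazard
ratio stays below 0.05.

## Direct pairwise meta-analysis

Head-to-head comparisons are pooled with the classical toolkit:
inverse-variance fixed effect; DerSimonian–Laird random effects
(`tau^2 = max(0, (Q - df)/(sum w - sum w^2 / sum w))`); Cochran's Q with
`I^2 = max(0, (Q - df)/Q)`; and, for 2×2 tables, Mantel–Haenszel pooling
with the Robins–Breslow–Greenland variance. The model-choice rule is the
conventional screen: random effects when `I^2 > 50%` and/or `p_Q < 0.05`,
else fixed. Log-ratio contrasts are pooled by inverse variance rather than
Mantel–Haenszel, which is defined only for count tables. Continuity
handling: 0.5 is added to all four cells of a table only when that table
contains a zero cell, and double-zero tables are excluded — standard
practice, and the only place a data value is modified.

One caveat surfaced by testing: adding a study with (effectively) infinite
standard error leaves the fixed-effect pool and Q unchanged, but *not* the
DerSimonian–Laird estimate, because the method-of-moments denominator
counts studies through `df = k - 1`. This is inherent to DL (reference
implementations behave identically), so the no-op invariant is asserted
only for the fixed-effect quantities.

## The hierarchical NMA model

With treatments `k = 1..a` and a reference whose basic parameter is fixed
at zero, the consistency model is

* data: `y_i ~ N(delta_i, V_i)`, with any user-supplied data-level
  covariance between contrasts of one trial added to `V`;
* random effects: `delta_i ~ N(d_{t2(i)} - d_{t1(i)}, sigma^2)`, contrasts
  of one multi-arm trial correlated with covariance `sigma^2/2` (the
  exchangeable-arms structure); fixed effects replace this with the
  deterministic consistency relation;
* binary arms: `r ~ Bin(n, p)`, `logit p = mu_study + delta`, the same
  hierarchy on `delta`, `mu_study ~ N(0, 15^2)`;
* priors: `d_k ~ N(0, (15 s)^2)` where `s = max(1, max |y|)` — vague
  relative to the log-ratio scale of this literature, whose published
  relative effects span roughly 0.03 to 38 on the natural scale — and
  `sigma ~ U(0, 5)`. Both scales are arguments of `nma_config()`.

The unrelated-mean-effects (UME) structure swaps the consistency relation
for one free mean per observed comparison; comparing its DIC with the
consistency model's is the global inconsistency check.

### Sampler

All Gaussian conditionals are conjugate, so the sampler is Gibbs with
closed-form blocks: each trial's `delta` block is drawn jointly from its
(at most three-dimensional) multivariate-normal conditional; `d` is drawn
jointly from its multivariate-normal conditional; and under the flat
`U(0, sigma_upper)` prior the transformation `phi = 1/sigma^2` has a
truncated-gamma conditional, sampled exactly by inverse CDF. Binomial
likelihoods are the one non-conjugate piece: trial baselines and their
`delta` blocks take random-walk Metropolis steps whose proposal scales are
tuned toward 44% acceptance during burn-in (and frozen afterwards, keeping
the retained chain Markovian). With fixed effects and purely Gaussian
data no other blocks remain, so the "chain" is i.i.d. exact sampling from
the multivariate-normal posterior — which is also what makes the
GLS-oracle tests sharp.

Defaults mirror common practice for these models: 4 chains × 100,000
iterations including 50,000 burn-in, thinned by 10 (20,000 retained
draws). Chain `c` starts `d` at a dispersed offset
(`{0, +0.5, −0.5, +1} × 0.1` of the prior scale) and `sigma` at the
`c/(chains+1)` quantile of its prior; chain seeds derive deterministically
from the configuration seed, so fits are bit-reproducible. Tests and
simulation studies run 2 chains × 2,500–8,000 iterations, which the
oracle-equivalence checks show is ample for these small networks.

Diagnostics: split-chain PSRF (a warning, never a truncation, when any
parameter exceeds 1.05), autocorrelation to lag 50, and
initial-positive-sequence effective sample sizes. Residual deviance is
`(y - theta)' V^{-1} (y - theta)` per Gaussian block and the saturated
binomial deviance per arm; `pD = Dbar - D(posterior-mean fitted values)`
and `DIC = Dbar + pD`.

### League tables and ranking

League-table cells summarize `exp(d_col - d_row)` — the column treatment
versus the row treatment, the orientation used throughout the package's
outputs. Medians and credible bounds are computed on the log-scale draws
and then exponentiated, so the reciprocity
`cell[r,c] × cell[c,r] = 1` is exact, not approximate. Rank probabilities
order the draws (direction-aware: "lower better" for hazard-ratio and
adverse-event outcomes, "higher better" for response), with exact ties —
a measure-zero event for continuous posteriors — broken by treatment
order. SUCRA is the normalized sum of cumulative rank probabilities; the
identities `sum SUCRA = a/2` and `SUCRA -> 1 - SUCRA` under direction
reversal hold exactly and are asserted at machine precision. The
two-outcome clustered ranking pairs safety and efficacy SUCRAs, flags the
non-dominated (Pareto) set — the principled summary — and offers seeded
k-means labels as the optional, purely visual grouping.

## Node-splitting

A comparison is splittable when it has direct evidence lying on a loop:
removing the direct edge must leave its endpoints connected (checked by
graph search, and in the tests against a union-find oracle). The split
refit decouples the comparison into a free `d.direct` parameter informed
by the trials observing it head-to-head — a multi-arm trial containing
both endpoints contributes its explicit contrast on that comparison to the
direct parameter and its remaining contrasts to the network — while all
other evidence informs it indirectly through the basic parameters. The
reference for the refit is chosen off the split comparison so both
endpoints stay free. The two-sided Bayesian p-value
`2 min(Pr(diff > 0), Pr(diff < 0))` is floored at `2/n_draws`: a Monte
Carlo p-value of exactly zero would overstate the evidence.

Calibration is checked by simulation: under consistent generation the
rejection rate at 0.05 sits at its nominal level (and the p-values match
an analytic inverse-variance z-test oracle almost exactly), while an
inconsistency offset of 1.0 on a loop edge with contrast SEs of 0.1 is
detected essentially always.

## Comparison-adjusted funnel data

Each contrast is centered on the fixed-effect pooled direct estimate of
its own comparison — fixed-effect deliberately, regardless of the
heterogeneity rule, because the funnel asks about small-study asymmetry
around the common effect. Within each comparison the weighted mean of
centered effects is exactly zero, and single-study comparisons center to
zero. The calibration test uses a precision-weighted regression of
centered effect on SE with per-comparison intercepts (the intercepts
absorb the centering constraint): the plain unweighted slope t-statistic
is only nominally inside |t| < 2 about 92% of the time at the small
residual degrees of freedom these networks give, so the weighted,
comparison-adjusted form is both the statistically correct Egger-style
test and the one with a stable null.

## Synthetic-data generator

`sim_truth()` defines the study conditions the simulations run under, and
its defaults encode the HCC evidence base rather than a convenient test
case: two hubs (`Pla`, `Sor`) with spoke drugs, exactly one closed
triangle so node-splitting is exercised on one loop, one three-arm trial,
12 trials over 5 treatments, between-trial `sigma = 0.15` (the low end of
the heterogeneity posteriors seen in this literature, whose endpoint-level
medians run from about 0.15 to 1.0), true log effects drawn once per seed
on the hazard-ratio scale 0.45–1.5, and per-arm event counts of 80–250
(sample sizes 150–400 for binary outcomes) matching mid-sized phase
II/III trials. Observed contrasts get `V = 1/e1 + 1/e2` — the standard
log-ratio variance approximation, and the generator's stated assumption —
with the shared-baseline covariance `1/e_baseline` attached for multi-arm
trials. `inject_inconsistency()` shifts the direct evidence on a loop edge
by `omega`, which is exactly the alternative the node-splitting test
targets.

What the generator does *not* emulate: real extraction error (rounded
CIs, digitization noise), non-proportional hazards, correlated endpoints
within a trial, selective reporting, or covariate-driven intransitivity.
Passing the recovery and calibration suites therefore demonstrates that
the inference machinery is correct under its own assumptions, not that
those assumptions hold in any given literature.

## Simulation studies and problem sizes

`run_recovery_study()` is the harness for the two standing calibration
claims, at sizes chosen to keep a full run on one CPU within minutes:

* **Recovery** — 200 networks (5 treatments, 12 trials,
  `sigma = 0.15`), random-effects fits at 2 chains × 3,000 iterations:
  95% credible-interval coverage of the basic parameters in
  [0.90, 0.99] and mean bias below 0.03.
* **Node-split calibration** — 200 consistent triangles (contrast SE 0.1)
  for the type-I rate, 50 with `omega = 1` for power (≥ 0.80 observed;
  in practice ~1).

## Numerical choices and degenerate inputs

* `1/sigma^2` conditional: gamma rate floored at 1e-300 and the inverse
  CDF clamped away from 1, so a degenerate `q = 0` or an extreme
  truncation cannot produce `Inf`.
* Random effects require at least two contrasts (one contrast cannot
  identify `sigma`); a treatment with no evidence, a disconnected
  network, or a comparison without a loop (for node-splitting) are
  rejected with named errors.
* Single-study comparisons are allowed everywhere; they simply carry no
  heterogeneity information.
* Double-zero 2×2 tables are excluded from Mantel–Haenszel pooling;
  all-zero margins across every table are an error, not a silent 0/0.
* Medians/quantiles of reciprocal league cells use the same log-scale
  draws, making reciprocity exact by construction rather than a tested
  approximation.

## Known limitations

* The multi-arm data-level covariance is used only when supplied (the
  simulator supplies it; published league-table-style inputs usually
  cannot), otherwise contrasts of a multi-arm trial are independent at
  the data level — the `sigma^2/2` random-effect correlation is always
  applied. This mirrors what is actually estimable from published
  hazard ratios and is surfaced, not hidden.
* Contrast- and arm-based evidence can coexist in one network but a
  given study must be one or the other.
* No meta-regression, no arm-based (baseline-modelled) NMA, no P-score;
  ranking covers all nodes including placebo, and any filtering of
  non-drug nodes is left to reports.
* The node-splitting convention for multi-arm trials (explicit contrast
  to the direct parameter, the rest to the network) is one of several in
  use; with this literature's two-arm loops the choice is immaterial.
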