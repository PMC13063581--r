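---
title: "Methods: PrEP-uptake barrier analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PrEP-uptake barrier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepbarriers)
```

This vignette documents the statistical procedures the package
implements, the assumptions behind them, and the design choices made
where a procedure was genuinely underdetermined. It states no
empirical result that the test suite or `scripts/acceptance.R` do not
themselves compute.

## The problem

PrEP (pre-exposure prophylaxis) prevents HIV infection, but uptake
among eligible MSM is incomplete. Given categorical survey records —
demographics, income, sexual behaviour, STI history, drug use, PrEP
status, and (for non-users) self-reported reasons for not taking PrEP
— the analysis asks two questions: which characteristics are
associated with *not* using PrEP among those with a guideline
indication, and which barriers do non-users report, stratified by how
they qualified and by the density of HIV-specialist care where they
live.

## Eligibility and selection

A record has a **PrEP indication** if at least one criterion holds:

* sexualized drug use (SDU) in the last 6 months,
* a syphilis, gonorrhea, chlamydia or hepatitis-C diagnosis in the
  last 12 months, or
* ≥ 2 sex partners in the last 6 months together with low condom use
  (0–50 % of contacts).

For current PrEP users the condom clause is waived: condom behaviour
*under* PrEP does not speak to eligibility before starting it. Missing
behavioural fields never satisfy a clause — eligibility must be
demonstrated, not assumed — which means records with largely missing
behavioural data are excluded by the indication filter rather than
given the benefit of the doubt. Age ≥ 18 is a survey precondition and
is validated, not treated as a flow filter.

The selection flow applies six conjunctive record-level filters in a
fixed order (completion, cis-male, PrEP status specified and not a
former user, no repeat participation, HIV-negative confirmation for
non-users, indication) and records a ledger of counts at each step.
Because the filters are conjunctive, the final cohort — though not the
ledger — is invariant to their order; the test suite checks this
against an independently computed conjunction. Eligible participants
are partitioned into indication subgroups by which clause family
fired: `sdu_only`, `partners_sti_hcv` (the partner/condom and STI
clauses form one family, matching how the stratified reason tables are
laid out), or `both`. A non-user qualifying via partners+condoms *and*
an STI diagnosis stays in `partners_sti_hcv`; the two are not split
further.

## Derived covariates and encoding

**Equivalised income.** Monthly net equivalent income is the mean of
the reported household-income category divided by the square root of
household size. Category means are arithmetic midpoints of the
category bounds; the open-ended top category is valued at 6,260 €
(the population-weighted median household income above 5,000 €,
SOEP 2018). The exact questionnaire answer options are not public, so
the default schema uses a 500 €/1,000 € grid consistent with the six
reporting bands (< 1,000 € up to ≥ 5,000 €) and is user-overridable.

**HIV-specialist density.** Federal states enter the model only
through licensed HIV-care physicians per 10,000 estimated gay men,
banded into 0, 1–2, 3–5, 6–9 and 10–13. A state's real-valued density
is rounded to the nearest integer (half away from zero) and assigned
to the band containing it; rounding was chosen over flooring because
the three published city-state densities (10.27, 10.73, 12.73) land in
the top band under either rule, leaving the choice free, and rounding
is the less surprising default. Only those three densities are public;
the shipped map's other thirteen values are synthetic (the file is
named accordingly) and exist for simulation only.

**Missing values.** The answers "I do not know" and "Prefer not to
say" are recoded to a `missing` sentinel. The design matrix encodes
each grouped variable as one indicator per non-reference category; the
reference is the most frequent *observed* category (ties broken by the
grouping-spec order, for determinism). Missingness is handled in two
modes: `separate_category` (the primary analysis; missing gets its own
indicator) and `reference` (the sensitivity analysis; missing rows are
all-zero for that variable, i.e. folded into the reference). The
reference is chosen among observed categories even when `missing` is
the modal value — a separate-category indicator for missingness is
interpretable, a missing reference is not. Constant columns are
inestimable and dropped before modelling. In `separate_category` mode
the encoding is exactly invertible, which the tests verify by
round-trip.

## Model selection

The outcome is current PrEP use (1) vs never-use (0) among indicated
participants. The model is logistic regression with an elastic-net
penalty. Two conventions worth stating explicitly:

* **Naming.** The package says `mixing` for the L1 share (glmnet's
  `alpha`) and `strength` for the overall penalty (glmnet's `lambda`),
  everywhere, to prevent silent transposition.
* **No standardization.** All predictors are 0/1 indicators, so
  columns are penalized as-is.

Tuning is two-stage. For each mixing value on the fixed grid
0.1, …, 1.0, the strength is tuned by 15-fold outcome-stratified
cross-validation, repeated (default 5 repeats, configurable; the
shipped drivers and the validation experiment use 2, which at their
problem sizes already yields stable AUC means). AUC is computed per
validation fold by the rank (Mann–Whitney) formula and averaged over
folds × repeats — per-fold averaging rather than pooling, since folds
are the resampling unit. The **elbow** (best AUC at fewest non-zero
coefficients) is operationalized as the one-standard-error rule: the
largest strength whose mean AUC is within one SE of the best row's
AUC; no further knee-detection is attempted. One strength is selected
*per mixing* — the tuning text supports per-mixing selection, and it
keeps the second stage a fair comparison of ten candidates.

Each candidate is refitted on the full data at its selected strength.
The final model minimizes the number of non-zero coefficients, with
ties broken by AIC and remaining ties by the larger mixing (sparser
penalties preferred). AIC for a penalized fit is not standard; the
package defines it as `2(k) − 2ℓ` with `k = n_nonzero + 1` and `ℓ` the
*unpenalized* log-likelihood at the penalized estimates, following the
degrees-of-freedom result for the lasso.

## Bootstrap inference

The chosen model (hyperparameters fixed; no re-tuning inside the
loop) is refitted on B stratified resamples: sampling with replacement
within each outcome class, preserving class sizes exactly. The
stratification variable is the outcome — the only binary design
variable the cross-validation stratifies by. Per coefficient the
package reports the percentile interval (linear-interpolation
quantiles at (1−level)/2 and 1−(1−level)/2) and a one-sided bootstrap
p-value

\[
p = \frac{1 + \#\{\text{replicates with sign opposite to the point
estimate, or exactly } 0\}}{B + 1},
\]

with `p = 1` for a zero point estimate. Replicates shrunk exactly to
zero count *against* significance: penalized refits put genuine point
mass at zero, and apportioning it to the null side is the conservative
convention (it also makes a CI whose bound touches 0.00 compatible
with p just below 0.05, as seen in practice with percentile CIs of
penalized coefficients). The +1 smoothing is the standard resampling
convention preventing p = 0. Replicates that fail to converge are
dropped and counted; more than 1 % drops aborts. BCa or basic
intervals, and bootstrapping the tuning itself, are out of scope.

## Contingency analyses

Each of the eight multi-select reasons for non-use is tested in a 2×2
table (citing vs not) across two strata. For the indication
stratification the two *single-criterion* subgroups are compared
(`partners_sti_hcv` vs `sdu_only`); the `both` column is displayed but
excluded from the test — a three-group test does not reproduce the
published p-values, the two-group comparison does, which the package
verified against both variants before freezing the behaviour. For the
density stratification, low is bands 0 through 6–9 and high is band
10–13; non-users whose state (hence band) is unknown are excluded from
the dichotomy but remain in the all-participants column.

The default test is Pearson's chi-squared *with continuity
correction*: recomputing the five published p-values (0.002, 0.013,
0.021, 0.045, 0.043) from their printed counts matches the corrected
statistic at three decimals and not the uncorrected one, so the
corrected variant was frozen as the default; the acceptance tests keep
both facts pinned. Fisher's exact test (two-sided,
probability-mass definition — the variant that reproduces the printed
0.062) replaces it whenever any expected cell is below 5 ("low
frequencies" made precise). Raw p-values are BH-adjusted across the
eight-reason family, unrounded. Participation probabilities per state
use Wilson score intervals, the standard choice for small proportions.

## The synthetic generator

The generator emulates what the analysis needs and no more:

* **Marginals.** Each covariate is sampled independently from a
  configured categorical marginal. Defaults transcribe the published
  baseline distribution where available (age bands, origin, condom
  use, partners, SDU, per-state counts) and use plausible values for a
  German MSM online survey otherwise; observed-category marginals are
  renormalised since missingness is injected separately.
* **Outcome.** PrEP status is drawn from a logistic model on the
  sampled covariates (default effects point the reported directions of
  association), with fixed shares of former users (3.4 %) and of
  records not specifying PrEP status (1.7 %), mirroring the published
  flow proportions.
* **Reasons.** Each reason is an independent Bernoulli per non-user
  with the probability of the record's indication stratum (defaults:
  the published per-subgroup citation rates).
* **Missingness.** Independent per-field masking at per-field rates
  (defaults from the published missing shares, including the high
  ~40 % non-response of the STI-history items); PrEP status can never
  be masked. Masking is idempotent.
* **Determinism.** Every sampled quantity has its own RNG stream
  derived from the master seed and a stream name, so adding a variable
  never shifts another variable's draws, and identical configurations
  give byte-identical CSVs.

What it deliberately does **not** emulate: covariate correlation (the
published evidence is marginal distributions only, so independence is
a generator assumption, not a claim about the survey), recruitment-
channel or wave effects, informative missingness, and reason
co-occurrence. Consequently, passing tests on synthetic cohorts
demonstrate that the *procedures* are implemented correctly and behave
as advertised under known truth — not that the substantive published
estimates would be recovered from real microdata, which are not
public. For the same reason the pipeline makes no attempt to reproduce
the published regression coefficients or participant-flow counts.

## Validation experiment

`selection_recovery_experiment()` is the package's synthetic-truth
check of the modelling stages: cohorts of n = 2,000 with 13
independent binary covariates (prevalence 0.3), three carrying
log-odds effects of ±0.8 and ten pure noise, 50 replications, B = 500
bootstrap resamples, 2 CV repeats. It reports how often the chosen
model contains all three true effects with correct signs, how often
any given noise covariate is included, and how often noise covariates
get one-sided bootstrap p ≥ 0.05. The acceptance suite requires
≥ 90 % recovery, ≤ 30 % per-column null inclusion and ≥ 90 % null-p
coverage; these problem sizes keep the whole experiment to a few
minutes on one CPU while leaving the effects comfortably detectable.

## Numerical choices and edge cases

* glmnet coordinate descent runs at `thresh = 1e-9`; final fits read
  coefficients at a strength that is exactly on the fitted path, so no
  interpolation occurs. Single-column designs are padded with an
  all-zero column (whose coefficient is identically zero) to satisfy
  glmnet's two-column minimum.
* The default strength grid is 25 log-spaced points from the
  data-derived maximum `max|Xᵀ(y − ȳ)| / (n·α_min)` down by 10⁻⁴.
* Quantiles are type 7 (linear interpolation) everywhere.
* Degenerate 2×2 tables (a zero margin) are routed to Fisher and
  return p = 1; a zero margin under chi-squared is an error.
* Reference-category ties, fold assignment, resampling and the
  per-stage seeds derived from the master seed are all deterministic;
  reports serialize identically across reruns.

## Known limitations

Independence of covariates in the generator understates the
collinearity a real survey would show, so the null-inclusion rates
measured here are optimistic for correlated designs. The AIC
definition for penalized fits is a convention, as is the one-SE
operationalization of the elbow and the treatment of exactly-zero
replicates in the bootstrap p — all are stated defaults, chosen once,
and configurable where that is meaningful. The urban/rural field is
taken as a direct categorical answer; no postcode-based spatial
matching is attempted.
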