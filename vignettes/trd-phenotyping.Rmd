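---
title: "Defining MDD and treatment-resistant depression from primary-care records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining MDD and treatment-resistant depression from primary-care records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdpheno)
```

## The problem

Treatment-resistant depression (TRD) — major depressive disorder (MDD) that
fails to respond to successive antidepressant trials — is hard to study at
scale because structured treatment-response measures are rare. UK primary
care, where most depression is managed, produces two streams of routinely
coded data: dated clinical events (Read v2 or CTV3 codes) and dated drug
issues. `trdpheno` implements a rule-based phenotyping algorithm that turns
those two streams into per-patient MDD and TRD labels, together with the
statistical layer needed to characterise the resulting groups and a
synthetic-cohort generator that makes every stage testable without
access-controlled data.

## The phenotyping algorithm

**MDD.** A patient is a case when they have at least two depression
diagnostic codes on distinct dates and no code for bipolar, psychotic or
substance-use disorders; any such exclusion code makes them `EXCLUDED`.
Patients with no psychiatric code at all are clean controls. The two-code
rule guards against one-off miscoding; requiring distinct dates extends the
same logic to same-day duplicate entries. Patients in between — a single
depression code, or another psychiatric diagnosis — fit neither set, and we
label them `SUBTHRESHOLD` rather than force them into a three-way
classification they would distort. `min_depression_codes = 1` switches to
the broad definition used in sensitivity analyses, and
`control_screening = "mdd_only"` relaxes the control screen to depression
codes only.

**Episodes.** Antidepressant issues of the same drug are chained into
episodes wherever consecutive issues are at most 98 days (14 weeks) apart;
an episode's duration is last minus first issue date, so a lone
prescription has duration 0. Dose and quantity are not modelled — they are
not reliably present in these records — so duration is the only available
proxy for an adequate trial.

**Switches and TRD.** Qualifying episodes last at least 42 days (6 weeks:
long enough that a switch plausibly reflects inefficacy rather than early
side-effects). Walking the qualifying episodes in chronological order, each
adjacent pair of *different* drugs is a switch when the gap from one
episode's end to the next one's start is at most 98 days (treatment was not
simply suspended) and the two date ranges do not overlap by more than 30
days. A treated case with at least two switches is TRD. Three consequences
of this formulation are worth making explicit:

* A–B–A counts as two switches: the rule constrains adjacent drugs, not
  drug novelty. Returning to a drug within 98 days of its last issue
  instead re-chains into the original episode and is no switch at all.
* Pairs overlapping by more than 30 days are combinations, not switches —
  a switch implies discontinuation — and are flagged separately
  (`combination_flag`), as is augmentation of an antidepressant with an
  antipsychotic or mood stabilizer under the same >30-day overlap rule.
* The within-drug chaining gap reuses the 98-day between-drug limit. The
  published rule set leaves the within-drug gap open; using one constant
  for both keeps the episode construction single-parameter and symmetric.

All day thresholds surface in `phenotype_params()` (42, 98, 30 days, two
codes), with inclusive comparisons (`<=` gaps, `>=` durations, strict `>`
for overlap): a 98-day gap chains, a 42-day episode qualifies, a 30-day
overlap is not yet a combination.

**Adherence proxy.** `adequate_interval_proportion()` pools all of a
patient's antidepressant issues (any drug) and reports the fraction of
consecutive intervals at most 98 days. Because it pools same-drug
intervals, it is not circular with the switch rule, which only constrains
the interval between different drugs. It is `NA` below two prescriptions.

**Record density.** Counts of clinical and prescription records, overall
and on distinct dates, are divided by the observation span (last minus
first record, in years of 365.25 days) floored at one year, so single-day
histories do not produce infinite rates.

## The synthetic cohort

`generate_cohort()` emulates the structure the algorithm consumes, not real
primary care. Its defaults are the study conditions the package is
validated under: MDD prevalence 8.68% (the UK-biobank-scale primary-care
figure), 90% of cases treated, 13.2% of treated cases on a switcher
trajectory, 2% of the cohort given exclusion codes, a 28 ± 7 day
prescribing rhythm, 10% non-adherent, 8% combination and 5% augmentation
among the relevant treated groups.

Case status comes from a liability-threshold model: each simulated SNP
(unlinked, Hardy–Weinberg dosages with MAF uniform in the configured range)
receives a normal effect, the standardized genetic score contributes
`h2_liability` of the liability variance, and patients above the empirical
`1 - K` liability quantile are cases. Thresholding the *realized*
distribution pins the planted prevalence to `K` up to quantile granularity,
which keeps prevalence-recovery tests sharp. Exclusion-coded patients are
drawn from the non-case pool and given depression codes *plus* an exclusion
code: the exclusion rule is exercised while planted prevalence stays equal
to `K`.

Trajectory archetypes (`UNTREATED`, `SINGLE_DRUG`, `SWITCHER`,
`NONADHERENT`, `COMBINATION`) are allocated by deterministic rounded counts
rather than per-patient coin flips, so configured fractions are recovered
exactly in expectation-free tests. Each archetype plants the structure its
name promises by construction: switcher episodes satisfy the duration and
gap rules for any jitter allowed by the config (the constructor rejects
`interval_mean_days + interval_jitter_days > 98`), and switcher episodes
use a fixed script count so that with jitter 0 and a 21-day interval every
episode spans exactly 42 days — placing the planted structure on the rule
boundary, where a one-day change to `min_episode_days` must flip every TRD
label. Depression codes are placed before the first prescription,
mirroring diagnosis-then-treatment ordering without claiming to model
onset.

What the generator does **not** emulate: real Read-code vocabularies (its
codelist is a small synthetic stand-in), linkage disequilibrium,
comorbidity structure, calendar-time prescribing trends, dose changes, and
free-text or out-of-practice prescribing. Tests passing on this generator
therefore demonstrate that the rules are implemented as stated and are
recoverable under clean longitudinal structure — not that the phenotype is
valid in any particular health-care system.

## The statistical layer

* **Prevalence** is `100 * n_case / n_total` to two decimals.
* **Odds ratios** use `ad/bc` with the Woolf log-scale interval; any zero
  cell triggers the Haldane–Anscombe 0.5 correction on all cells, flagged
  in the output.
* **Polygenic scores** are thresholded weighted dosage sums, standardized
  across the cohort. The default grid is 11 p-value thresholds
  (5e-8 … 1.0); clumping is replaced by the simulation's independence
  assumption. Threshold selection maximizes incremental Nagelkerke
  R² — computed against the covariate-only model, the convention in the
  polygenic-score literature — with ties resolved to the smallest
  threshold (the first maximum in the increasing grid).
* **Liability conversions.** Observed-scale heritability converts as
  `h2_liab = h2_obs * K²(1-K)² / (z² P(1-P))`, with exact inverse;
  `rescale_h2_liability()` moves a published liability-scale estimate
  between assumed prevalences (the case proportion cancels). Score R²
  converts through the ascertainment-corrected transformation
  `C R² / (1 + C θ R²)`, which reduces to `K(1-K)/z²` when `P = K`; the
  test suite validates it against a closed-form liability-model oracle and
  an ascertained-sampling simulation.
* **Tails.** Two-sided normal p-values use the complementary upper-tail
  function with a log-scale fallback, staying positive to `|z| ≈ 38.5`,
  the edge of what IEEE doubles can represent; beyond that the true tail is
  smaller than the smallest subnormal double and the correctly rounded
  result is 0.

## The pipeline

`run_pipeline()` chains simulate → write → re-read → phenotype → report,
so the on-disk table layouts are exercised end to end, logs the selection
flow (patients in, excluded, cases, treated, TRD), and emits a plain-text
report plus delimited intermediate tables; every reported number is
recomputable from those tables. The polygenic-score block builds its
summary statistics by perturbing the generator's true SNP effects with
discovery-scale noise (`simulate_sumstats()`), standing in for an external
GWAS of the same architecture. A thin command-line wrapper
(`inst/cli/trdpheno`, subcommands `simulate`, `phenotype`, `run`) exposes
the same functions to shell users.

## Numerical and testing choices

Test and validation problem sizes are chosen to make sampling error small
relative to the tolerance being asserted: 2,000 patients for
planted-label recovery (recovery is exact, so size only needs to cover all
archetypes), 10,000 for prevalence convergence under a 99% binomial bound,
500 null replicates at n = 1,000 for type-I error, 200 replicates at
n = 5,000 for effect recovery (three Monte-Carlo standard errors), and
20,000 individuals × 500 SNPs for liability-R² recovery at 20% relative
tolerance — the Lee-style transformations are approximations, and their
residual error (a few percent here) is part of what that tolerance
absorbs. The episode/switch/TRD logic is additionally cross-checked
against a brute-force reference (union–find closure over all prescription
pairs) on 200 random mini-patients, and all printed-figure consistency
checks (cross-prevalence rescaling of published liability-scale
heritability) use a 2% relative band reflecting rounding of the published
prevalence values.

## Limitations

The phenotype inherits the limits of prescribing-record data: no dose
adequacy, no distinction between switches for inefficacy and late
side-effect switches beyond the 6-week rule, no hospital-diagnosis
integration, and sensitivity to incomplete historical records. The
codelists shipped with the package are illustrative; real analyses must
supply curated ones. The generator's independence assumptions (no LD, no
comorbidity, uniform calendar placement) mean calibration results here
bound implementation correctness, not real-world validity.
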