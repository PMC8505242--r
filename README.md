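# trdpheno

Phenotyping major depressive disorder (MDD) and treatment-resistant
depression (TRD) from primary-care electronic health records.

## What it does and for whom

UK primary-care extracts provide two streams of routinely coded data per
patient: dated clinical events (Read v2 / CTV3 codes) and dated drug
issues. For researchers who need depression phenotypes at biobank scale —
epidemiologists characterising TRD, genetic analysts building case-control
sets — `trdpheno` turns those streams into per-patient labels:

* **MDD case**: ≥ 2 depression diagnostic codes on distinct dates, with no
  bipolar, psychotic or substance-use code (any such code → `EXCLUDED`;
  patients with no psychiatric code are clean controls).
* **Drug episode**: a maximal run of same-drug antidepressant issues with
  consecutive gaps ≤ 98 days (14 weeks); duration = last − first issue
  date.
* **Switch**: two chronologically adjacent qualifying episodes (each ≥ 42
  days, i.e. 6 weeks) of *different* antidepressants with an inter-episode
  gap ≤ 98 days and date-range overlap ≤ 30 days (longer overlap is a
  *combination*, analysed separately).
* **TRD**: an MDD case with ≥ 1 antidepressant prescription and ≥ 2
  switches.

Around the core algorithm the package provides the adherence proxy
(proportion of antidepressant issue intervals ≤ 98 days),
combination/augmentation flags, record-density measures, annual
prescribing trends, and a statistical layer: prevalence, odds ratios with
Woolf intervals, polygenic-score construction and logistic association
with incremental Nagelkerke R², observed↔liability-scale conversions of
heritability and variance explained

```
h2_liab = h2_obs · K²(1−K)² / (z² · P(1−P)),
R2_liab = C·R2_obs / (1 + C·θ·R2_obs),   C = K(1−K)/z² · K(1−K)/(P(1−P)),
```

effect-comparison z-tests and Bonferroni correction. A synthetic-cohort
generator with a liability-threshold genetic model and configurable
prescribing trajectories (switcher, combination, non-adherent, …) makes
every stage testable with no access to controlled data.

## Worked example

```r
library(trdpheno)

cfg    <- cohort_config(n_patients = 2000, seed = 1)   # defaults: 8.68% MDD, 13.2% TRD of treated
gcfg   <- genetic_config(n_snps = 200, seed = 1)
cohort <- generate_cohort(cfg, gcfg)

phen <- phenotype_cohort(cohort$clinical, cohort$prescriptions,
                         patient_ids = cohort$truth$patient_id)
table(phen$mdd_status)
#>     CASE  CONTROL EXCLUDED
#>      174     1786       40

n_case  <- sum(phen$mdd_status == "CASE")
treated <- phen$mdd_status == "CASE" & phen$treated
prevalence_percent(n_case, nrow(phen))                      # 8.7  (% MDD)
prevalence_percent(sum(phen$trd_status == "TRD"), sum(treated))  # 13.38 (% TRD of treated)

m <- merge(phen, cohort$truth, by = "patient_id")
mean((m$trd_status == "TRD") == m$true_trd)                 # 1 — planted labels recovered
```

The 174 cases are the patients whose simulated liability crossed the
prevalence threshold; 40 patients carry an exclusion code; of the 157
treated cases, 21 follow a switcher trajectory and all 21 — and only
they — are labelled TRD. The statistical layer works the same way on real
numbers:

```r
h2_observed_to_liability(0.1, liability_params(0.023, 0.161))  # 0.1258987
rescale_h2_liability(0.2459, k_from = 0.023, k_to = 0.01)      # 0.1995058
p_from_z(7.07)                                                 # 1.549337e-12
odds_ratio(46, 54, 8, 92)$or                                   # 9.80 [4.30-22.30]
```

`run_pipeline(out_dir)` chains simulate → phenotype → report and writes a
plain-text report plus all intermediate tables;
`inst/cli/trdpheno simulate|phenotype|run` exposes the same functions from
a shell. See `vignette("trd-phenotyping")` for the methods.

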