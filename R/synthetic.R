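#' Synthetic cohort configuration
#'
#' Parameters of the synthetic primary-care cohort. Defaults mirror the
#' UK-population setting the algorithm was designed for: an MDD prevalence
#' of 8.68% among patients with primary-care records, roughly nine in ten
#' cases with at least one antidepressant prescription, and a 13.2% rate of
#' treatment resistance among treated cases. Prescribing intervals follow a
#' 28-day repeat-prescription rhythm with uniform jitter.
#'
#' @param n_patients cohort size.
#' @param mdd_prevalence proportion of patients with planted MDD; also the
#'   prevalence `K` of the liability-threshold model used to assign case
#'   status from simulated genotypes.
#' @param treated_fraction proportion of MDD patients with at least one
#'   antidepressant prescription.
#' @param trd_fraction proportion of treated MDD patients given a switcher
#'   trajectory (three qualifying episodes, two switches).
#' @param exclusion_rate proportion of the cohort given depression codes
#'   plus a bipolar/psychotic/substance-use code, so the exclusion rule has
#'   work to do; drawn from the non-MDD pool, keeping planted prevalence
#'   interpretable.
#' @param interval_mean_days,interval_jitter_days prescriptions are spaced
#'   `interval_mean_days` plus uniform noise in
#'   `[-interval_jitter_days, +interval_jitter_days]`, truncated at 1 day.
#'   `interval_mean_days + interval_jitter_days` must stay at or below 98 so
#'   that planted episodes chain, and the jitter must be smaller than the
#'   mean.
#' @param nonadherent_fraction proportion of treated non-switcher MDD
#'   patients given a >98-day gap inside their prescribing run.
#' @param combination_rate proportion of treated non-switcher MDD patients
#'   given two antidepressants overlapping by more than 30 days.
#' @param augmentation_rate proportion of treated MDD patients additionally
#'   given an antipsychotic or mood-stabilizer episode overlapping an
#'   antidepressant episode by more than 30 days.
#' @param start_year,end_year window in which index dates are placed.
#' @param seed master seed; all component simulations derive sub-seeds from
#'   it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2000L,
                          mdd_prevalence = 0.0868,
                          treated_fraction = 0.9,
                          trd_fraction = 0.132,
                          exclusion_rate = 0.02,
                          interval_mean_days = 28,
                          interval_jitter_days = 7,
                          nonadherent_fraction = 0.1,
                          combination_rate = 0.08,
                          augmentation_rate = 0.05,
                          start_year = 2000L,
                          end_year = 2010L,
                          seed = 1L) {
  props <- c(mdd_prevalence, treated_fraction, trd_fraction, exclusion_rate,
             nonadherent_fraction, combination_rate, augmentation_rate)
  stopifnot(n_patients >= 0, all(props >= 0), all(props <= 1),
            interval_mean_days > 0,
            interval_jitter_days >= 0,
            interval_jitter_days < interval_mean_days,
            start_year <= end_year)
  if (mdd_prevalence + exclusion_rate > 1)
    stop("mdd_prevalence + exclusion_rate must not exceed 1")
  if (interval_mean_days + interval_jitter_days > 98)
    stop("interval_mean_days + interval_jitter_days must be <= 98 ",
         "for planted episodes to chain")
  if (nonadherent_fraction + combination_rate > 1)
    stop("nonadherent_fraction + combination_rate must not exceed 1")
  structure(list(
    n_patients = as.integer(n_patients),
    mdd_prevalence = mdd_prevalence,
    treated_fraction = treated_fraction,
    trd_fraction = trd_fraction,
    exclusion_rate = exclusion_rate,
    interval_mean_days = interval_mean_days,
    interval_jitter_days = interval_jitter_days,
    nonadherent_fraction = nonadherent_fraction,
    combination_rate = combination_rate,
    augmentation_rate = augmentation_rate,
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Genetic simulation configuration
#'
#' @param n_snps number of independent SNPs (no linkage disequilibrium is
#'   simulated).
#' @param maf_range interval within (0, 0.5) from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param h2_liability proportion of liability variance explained by the
#'   genetic score, in `[0, 1)`.
#' @param prevalence_k population prevalence of the liability-threshold
#'   model.
#' @param seed integer seed.
#' @return list of class `genetic_config`.
#' @export
genetic_config <- function(n_snps = 500L,
                           maf_range = c(0.05, 0.5),
                           h2_liability = 0.2,
                           prevalence_k = 0.0868,
                           seed = 1L) {
  stopifnot(n_snps >= 0, length(maf_range) == 2L)
  if (!(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] < maf_range[2]))
    stop("maf_range must be a non-empty interval within (0, 0.5]")
  if (!(h2_liability >= 0 && h2_liability < 1))
    stop("h2_liability must be in [0, 1)")
  stopifnot(prevalence_k > 0, prevalence_k < 1)
  structure(list(
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    h2_liability = h2_liability,
    prevalence_k = prevalence_k,
    seed = as.integer(seed)
  ), class = "genetic_config")
}

#' Simulate unlinked genotype dosages
#'
#' Per-SNP allele frequencies are drawn uniformly from `maf_range` and
#' dosages (0/1/2) binomially under Hardy-Weinberg equilibrium,
#' independently across SNPs.
#'
#' @param n number of individuals.
#' @param config a [genetic_config].
#' @return list with `genotypes` (n x n_snps integer matrix) and `maf`
#'   (length n_snps).
#' @export
simulate_genotypes <- function(n, config) {
  stopifnot(inherits(config, "genetic_config"), n >= 0)
  set.seed(config$seed)
  m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  g <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  colnames(g) <- if (m > 0) sprintf("snp%04d", seq_len(m)) else NULL
  list(genotypes = g, maf = maf)
}

#' Simulate case-control status under the liability-threshold model
#'
#' Each SNP receives a normal effect; the standardized genetic score
#' contributes a share `h2_liability` of the liability variance, with
#' independent normal noise making up the rest. A patient is a case when
#' their liability exceeds the empirical `(1 - K)` quantile of the realized
#' liability distribution, so the realized case fraction matches the
#' configured prevalence up to quantile granularity.
#'
#' @param genotypes n x m dosage matrix (from [simulate_genotypes]).
#' @param config a [genetic_config].
#' @return list with logical `case`, numeric `liability`, per-SNP `weights`
#'   (the true effect sizes) and `genetic_value` (standardized score).
#' @export
simulate_liability_case_control <- function(genotypes, config) {
  stopifnot(inherits(config, "genetic_config"))
  if (config$h2_liability >= 1) stop("h2_liability must be < 1")
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  set.seed(config$seed + 1L)
  if (n == 0L) {
    return(list(case = logical(), liability = numeric(),
                weights = stats::rnorm(m), genetic_value = numeric()))
  }
  weights <- stats::rnorm(m)
  if (m > 0 && n > 1) {
    raw <- as.numeric(genotypes %*% weights)
    s <- stats::sd(raw)
    gv <- if (s > 0) (raw - mean(raw)) / s else rep(0, n)
  } else {
    gv <- rep(0, n)
  }
  liability <- sqrt(config$h2_liability) * gv +
    sqrt(1 - config$h2_liability) * stats::rnorm(n)
  thr <- stats::quantile(liability, 1 - config$prevalence_k, names = FALSE)
  list(
    case = liability > thr,
    liability = liability,
    weights = weights,
    genetic_value = gv
  )
}

AD_DRUGS <- c("citalopram", "sertraline", "fluoxetine", "paroxetine",
              "venlafaxine", "mirtazapine", "amitriptyline", "duloxetine")
AUG_DRUGS <- c(quetiapine = "ANTIPSYCHOTIC", olanzapine = "ANTIPSYCHOTIC",
               lithium = "MOOD_STABILIZER", valproate = "MOOD_STABILIZER")

draw_intervals <- function(k, config) {
  pmax(1, round(config$interval_mean_days +
                  stats::runif(k, -config$interval_jitter_days,
                               config$interval_jitter_days)))
}

# minimum number of prescriptions so the episode spans >= 42 days even at
# the shortest possible jittered interval
episode_n_scripts <- function(config, min_span = 42) {
  lo <- config$interval_mean_days - config$interval_jitter_days
  max(3L, as.integer(ceiling(min_span / lo)) + 1L)
}

one_episode <- function(patient_id, drug, start, n_scripts, config) {
  dates <- start + c(0, cumsum(draw_intervals(n_scripts - 1L, config)))
  data.frame(
    patient_id = patient_id,
    issue_date = dates,
    drug_id = drug,
    drug_class = "ANTIDEPRESSANT",
    raw_code = "",
    stringsAsFactors = FALSE
  )
}

#' Simulate one patient's prescribing history
#'
#' Emits the prescription events of one trajectory archetype, starting at
#' `start_date`:
#' \describe{
#'   \item{UNTREATED}{no prescriptions.}
#'   \item{SINGLE_DRUG}{one antidepressant episode spanning at least 42 days
#'     with all gaps at most 98 days.}
#'   \item{SWITCHER}{three such episodes of three different antidepressants
#'     with inter-drug gaps of at most 98 days — phenotyped as two switches.}
#'   \item{NONADHERENT}{a single-drug run broken by one gap of 120-180 days,
#'     so the adequate-interval proportion falls below 1 and the run splits
#'     into two episodes.}
#'   \item{COMBINATION}{two different antidepressants overlapping by more
#'     than 30 days.}
#' }
#'
#' @param patient_id identifier carried into the output rows.
#' @param archetype one of `"UNTREATED"`, `"SINGLE_DRUG"`, `"SWITCHER"`,
#'   `"NONADHERENT"`, `"COMBINATION"`.
#' @param config a [cohort_config] (interval model).
#' @param seed integer seed for this patient's draws.
#' @param start_date Date of the first prescription.
#' @return data.frame of prescription events (possibly zero rows).
#' @export
simulate_prescription_history <- function(patient_id, archetype, config,
                                          seed,
                                          start_date = as.Date("2005-01-01")) {
  archetype <- match.arg(archetype, c("UNTREATED", "SINGLE_DRUG", "SWITCHER",
                                      "NONADHERENT", "COMBINATION"))
  empty <- data.frame(
    patient_id = character(), issue_date = as.Date(character()),
    drug_id = character(), drug_class = character(), raw_code = character(),
    stringsAsFactors = FALSE
  )
  if (archetype == "UNTREATED") return(empty)
  set.seed(seed)
  n_scripts <- episode_n_scripts(config)
  extra <- function() sample(0:2, 1L)
  if (archetype == "SINGLE_DRUG") {
    drug <- sample(AD_DRUGS, 1L)
    return(one_episode(patient_id, drug, start_date, n_scripts + extra(), config))
  }
  if (archetype == "SWITCHER") {
    # fixed script count per episode: with jitter 0 every switcher episode
    # spans exactly (n_scripts - 1) * interval_mean_days, keeping the
    # planted structure on a known side of the duration rule
    drugs <- sample(AD_DRUGS, 3L)
    out <- list()
    start <- start_date
    for (d in drugs) {
      ep <- one_episode(patient_id, d, start, n_scripts, config)
      out[[d]] <- ep
      start <- max(ep$issue_date) + draw_intervals(1L, config)
    }
    rx <- do.call(rbind, out)
    rownames(rx) <- NULL
    return(rx)
  }
  if (archetype == "NONADHERENT") {
    drug <- sample(AD_DRUGS, 1L)
    ep1 <- one_episode(patient_id, drug, start_date, n_scripts, config)
    gap <- sample(120:180, 1L)
    ep2 <- one_episode(patient_id, drug, max(ep1$issue_date) + gap, 2L, config)
    rx <- rbind(ep1, ep2)
    rownames(rx) <- NULL
    return(rx)
  }
  # COMBINATION: second drug starts 1-7 days into the first episode, so the
  # two ranges (each >= 42 days) overlap by at least 35 days
  drugs <- sample(AD_DRUGS, 2L)
  ep1 <- one_episode(patient_id, drugs[1], start_date, n_scripts + extra(), config)
  ep2 <- one_episode(patient_id, drugs[2], start_date + sample(1:7, 1L),
                     n_scripts, config)
  rx <- rbind(ep1, ep2)
  rx <- rx[order(rx$issue_date, rx$drug_id), , drop = FALSE]
  rownames(rx) <- NULL
  rx
}

augmentation_episode <- function(patient_id, rx, config) {
  drug <- sample(names(AUG_DRUGS), 1L)
  start <- min(rx$issue_date) + sample(1:7, 1L)
  n <- episode_n_scripts(config)
  dates <- start + c(0, cumsum(draw_intervals(n - 1L, config)))
  data.frame(
    patient_id = patient_id,
    issue_date = dates,
    drug_id = drug,
    drug_class = unname(AUG_DRUGS[drug]),
    raw_code = "",
    stringsAsFactors = FALSE
  )
}

DEPRESSION_CODES <- c("E112.", "E113.", "Eu32.", "Eu33.")
EXCLUSION_CODES <- c("E11y.", "Eu31.", "Eu20.", "Eu10.")
NEUTRAL_CODES <- c("H33..", "G30..")

SYNTH_CODE_CATEGORY <- c(
  "E112." = "DEPRESSION", "E113." = "DEPRESSION",
  "Eu32." = "DEPRESSION", "Eu33." = "DEPRESSION",
  "E11y." = "BIPOLAR", "Eu31." = "BIPOLAR",
  "Eu20." = "PSYCHOTIC", "Eu10." = "SUBSTANCE_USE",
  "H33.." = "NON_PSYCHIATRIC", "G30.." = "NON_PSYCHIATRIC"
)

clinical_rows <- function(patient_id, dates, codes) {
  data.frame(
    patient_id = if (length(codes)) patient_id else character(),
    event_date = dates,
    code = codes,
    code_system = if (length(codes)) "READ2" else character(),
    category = unname(SYNTH_CODE_CATEGORY[codes]),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort
#'
#' Produces clinical-event and prescription tables, a genotype matrix and a
#' truth table with the planted labels. MDD status comes from the
#' liability-threshold model at prevalence `mdd_prevalence`; MDD patients
#' receive at least two depression codes on distinct dates before their
#' first prescription, excluded patients (drawn from the non-MDD pool)
#' receive depression codes plus an exclusion code, and everyone gets one or
#' two neutral clinical codes so the whole cohort has primary-care events.
#' Trajectory archetypes are allocated deterministically by rounded counts
#' from the configured fractions. Identical seeds give byte-identical
#' output.
#'
#' @param config a [cohort_config].
#' @param gconfig a [genetic_config]; its `prevalence_k` is overridden by
#'   `config$mdd_prevalence` so the genetic and phenotypic layers agree.
#' @return list with `clinical`, `prescriptions` (event data.frames in the
#'   reader layout), `genotypes`, `maf`, and `truth` (per patient:
#'   `true_mdd`, `true_trd`, `true_excluded`, `treated`,
#'   `trajectory_archetype`, `genetic_liability`, planted `combination` and
#'   `augmentation` flags).
#' @export
generate_cohort <- function(config = cohort_config(),
                            gconfig = genetic_config()) {
  stopifnot(inherits(config, "cohort_config"), inherits(gconfig, "genetic_config"))
  n <- config$n_patients
  ids <- if (n > 0) sprintf("P%06d", seq_len(n)) else character()

  gconfig$prevalence_k <- config$mdd_prevalence
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 2L, 6L)
  gconfig$seed <- sub[1L]

  geno <- simulate_genotypes(n, gconfig)
  lia <- simulate_liability_case_control(geno$genotypes, gconfig)
  true_mdd <- if (n > 0) lia$case else logical()

  set.seed(sub[2L])
  non_mdd <- which(!true_mdd)
  n_excl <- min(length(non_mdd), round(n * config$exclusion_rate))
  excluded <- rep(FALSE, n)
  excluded[sample_fixed(non_mdd, n_excl)] <- TRUE

  mdd_idx <- which(true_mdd)
  n_treated <- round(length(mdd_idx) * config$treated_fraction)
  treated_idx <- sample_fixed(mdd_idx, n_treated)
  n_sw <- round(n_treated * config$trd_fraction)
  sw_idx <- sample_fixed(treated_idx, n_sw)
  rest <- setdiff(treated_idx, sw_idx)
  n_comb <- min(length(rest), round(length(rest) * config$combination_rate))
  comb_idx <- sample_fixed(rest, n_comb)
  rest2 <- setdiff(rest, comb_idx)
  n_nonadh <- min(length(rest2), round(length(rest) * config$nonadherent_fraction))
  nonadh_idx <- sample_fixed(rest2, n_nonadh)
  n_aug <- round(n_treated * config$augmentation_rate)
  aug_idx <- sample_fixed(treated_idx, n_aug)

  archetype <- rep("UNTREATED", n)
  archetype[sw_idx] <- "SWITCHER"
  archetype[comb_idx] <- "COMBINATION"
  archetype[nonadh_idx] <- "NONADHERENT"
  archetype[setdiff(rest2, nonadh_idx)] <- "SINGLE_DRUG"
  treated <- rep(FALSE, n)
  treated[treated_idx] <- TRUE
  augmented <- rep(FALSE, n)
  augmented[aug_idx] <- TRUE

  window_start <- as.Date(sprintf("%d-01-01", config$start_year))
  window_days <- as.numeric(as.Date(sprintf("%d-12-31", config$end_year)) -
                              window_start)
  index_date <- window_start + floor(stats::runif(n, 0, max(1, window_days - 400)))

  set.seed(sub[3L])
  patient_seeds <- sample.int(.Machine$integer.max - 2L, max(n, 1L))

  clin_list <- vector("list", n)
  rx_list <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(patient_seeds[i])
    dates <- index_date[i]
    codes <- character()
    dates_out <- as.Date(character())
    # neutral codes for everyone: the cohort is "patients with >= 1 event"
    k_neutral <- sample(1:2, 1L)
    codes <- c(codes, sample(NEUTRAL_CODES, k_neutral, replace = TRUE))
    dates_out <- c(dates_out, index_date[i] + sample(0:700, k_neutral))
    if (true_mdd[i] || excluded[i]) {
      k_dep <- sample(2:3, 1L)
      dep_dates <- index_date[i] + c(0, sort(sample(20:360, k_dep - 1L)))
      codes <- c(codes, sample(DEPRESSION_CODES, k_dep, replace = TRUE))
      dates_out <- c(dates_out, dep_dates)
    }
    if (excluded[i]) {
      codes <- c(codes, sample(EXCLUSION_CODES, 1L))
      dates_out <- c(dates_out, index_date[i] + sample(30:400, 1L))
    }
    clin_list[[i]] <- clinical_rows(ids[i], dates_out, codes)
    if (treated[i]) {
      rx_start <- index_date[i] + sample(380:420, 1L)
      rx <- simulate_prescription_history(ids[i], archetype[i], config,
                                          seed = patient_seeds[i] %% 1000000L + 7L,
                                          start_date = rx_start)
      if (augmented[i]) rx <- rbind(rx, augmentation_episode(ids[i], rx, config))
      rx_list[[i]] <- rx
    }
  }
  clinical <- do.call(rbind, clin_list)
  prescriptions <- do.call(rbind, rx_list)
  if (is.null(clinical)) clinical <- clinical_rows(character(), as.Date(character()), character())
  if (is.null(prescriptions)) prescriptions <- simulate_prescription_history("x", "UNTREATED", config, 1L)
  clinical <- clinical[order(clinical$patient_id, clinical$event_date,
                             clinical$code), , drop = FALSE]
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$issue_date,
                                       prescriptions$drug_id), , drop = FALSE]
  rownames(clinical) <- rownames(prescriptions) <- NULL

  truth <- data.frame(
    patient_id = ids,
    true_mdd = true_mdd,
    true_trd = true_mdd & archetype == "SWITCHER",
    true_excluded = excluded,
    treated = treated,
    trajectory_archetype = archetype,
    genetic_liability = if (n > 0) lia$liability else numeric(),
    combination = archetype == "COMBINATION",
    augmentation = augmented,
    stringsAsFactors = FALSE
  )
  rownames(geno$genotypes) <- ids
  list(clinical = clinical, prescriptions = prescriptions,
       genotypes = geno$genotypes, maf = geno$maf,
       snp_weights = lia$weights, truth = truth,
       config = config, genetic_config = gconfig)
}

# sample() with the size-1 surprise removed and a fixed empty case
sample_fixed <- function(x, size) {
  size <- min(length(x), size)
  if (size == 0L) return(integer())
  if (length(x) == 1L) return(x)
  sample(x, size)
}

#' Write a synthetic cohort to a directory of delimited files
#'
#' Emits `clinical.tsv` and `scripts.tsv` in the reader layouts,
#' `genotypes.tsv` (patient id plus one dosage column per SNP) and
#' `truth.tsv`.
#'
#' @param cohort result of [generate_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_prescription_table(cohort$prescriptions, file.path(dir, "scripts.tsv"))
  g <- as.data.frame(cohort$genotypes)
  g <- cbind(patient_id = rownames(cohort$genotypes), g)
  utils::write.table(g, file.path(dir, "genotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tr <- cohort$truth
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
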