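#' Simulate external GWAS summary statistics for the planted SNP effects
#'
#' Emulates a discovery genome-wide association study of the simulated
#' architecture: each SNP's estimated effect is its true planted effect plus
#' sampling noise of standard error `1/sqrt(n_discovery)`, with the matching
#' Wald p-value. These play the role of the external summary statistics a
#' polygenic score is built from.
#'
#' @param true_weights per-SNP true effects (from [generate_cohort]).
#' @param n_discovery effective discovery sample size controlling the noise.
#' @param seed integer seed.
#' @return data.frame with `snp`, `beta`, `se`, `p`.
#' @export
simulate_sumstats <- function(true_weights, n_discovery = 50000, seed = 1L) {
  stopifnot(n_discovery > 0)
  set.seed(seed)
  se <- 1 / sqrt(n_discovery)
  beta <- true_weights + stats::rnorm(length(true_weights), 0, se)
  data.frame(
    snp = sprintf("snp%04d", seq_along(true_weights)),
    beta = beta,
    se = se,
    p = p_from_z(beta / se),
    stringsAsFactors = FALSE
  )
}

#' Per-variable missingness compared between two groups
#'
#' For each variable, the proportion of missing values in each group and a
#' 2x2 comparison (missing vs observed by group) through the odds-ratio
#' machinery. Degenerate tables (no missingness, or an empty group) are
#' flagged rather than tested.
#'
#' @param data data.frame of per-patient variables (any types; `NA` counts
#'   as missing).
#' @param group vector of two group labels aligned with `data` rows.
#' @return data.frame with one row per variable: missing proportions by
#'   group, `or`, `ci_lower`, `ci_upper`, `p`, `degenerate`.
#' @export
missingness_comparison <- function(data, group) {
  stopifnot(is.data.frame(data), nrow(data) == length(group))
  group <- as.character(group)
  levels <- sort(unique(group[!is.na(group)]))
  if (length(levels) != 2)
    stop("group must have exactly two levels, got: ",
         paste(levels, collapse = ", "))
  g1 <- group == levels[1]
  g2 <- group == levels[2]
  rows <- lapply(names(data), function(v) {
    miss <- is.na(data[[v]])
    n1 <- sum(g1); n2 <- sum(g2)
    m1 <- sum(miss & g1); m2 <- sum(miss & g2)
    rate1 <- if (n1 > 0) m1 / n1 else NA_real_
    rate2 <- if (n2 > 0) m2 / n2 else NA_real_
    degenerate <- n1 == 0 || n2 == 0 || (m1 + m2) == 0 || (m1 + m2) == n1 + n2
    if (degenerate) {
      or <- list(or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                 p = NA_real_)
    } else {
      or <- odds_ratio(m1, n1 - m1, m2, n2 - m2)
    }
    data.frame(
      variable = v,
      group1 = levels[1], missing_rate1 = rate1,
      group2 = levels[2], missing_rate2 = rate2,
      or = or$or, ci_lower = or$ci_lower, ci_upper = or$ci_upper,
      p = or$p, degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

compare_binary <- function(flag, trd) {
  a <- sum(flag & trd); b <- sum(!flag & trd)
  c <- sum(flag & !trd); d <- sum(!flag & !trd)
  degenerate <- (a + c) == 0 || (b + d) == 0 || sum(trd) == 0 || sum(!trd) == 0
  if (degenerate)
    return(list(effect = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                p = NA_real_, degenerate = TRUE))
  or <- odds_ratio(a, b, c, d)
  list(effect = or$or, ci_lower = or$ci_lower, ci_upper = or$ci_upper,
       p = or$p, degenerate = FALSE)
}

compare_continuous <- function(x, trd) {
  x1 <- x[trd & !is.na(x)]; x2 <- x[!trd & !is.na(x)]
  if (length(x1) < 2 || length(x2) < 2 || (stats::sd(x1) == 0 && stats::sd(x2) == 0))
    return(list(effect = mean(x1) - mean(x2), ci_lower = NA_real_,
                ci_upper = NA_real_, p = NA_real_, degenerate = TRUE))
  tt <- stats::t.test(x1, x2)
  list(effect = unname(tt$estimate[1] - tt$estimate[2]),
       ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
       p = tt$p.value, degenerate = FALSE)
}

fmt <- function(x, d = 3) ifelse(is.na(x), "NA", formatC(x, digits = d, format = "fg"))

#' Run the full simulate-phenotype-report pipeline
#'
#' Generates a synthetic cohort, writes its tables, re-reads them through
#' the package readers (so the on-disk layout is exercised end to end),
#' phenotypes every patient, and assembles a plain-text report: the
#' selection flow (patients in, excluded, cases, treated, TRD), prevalence
#' block, TRD vs non-TRD comparison table with Bonferroni-adjusted
#' p-values, missingness comparison, annual prescribing trends and — when
#' genetics are enabled — a polygenic-score association block with
#' threshold selection and liability-scale variance explained. Everything
#' is deterministic under the configured seed, and every reported number
#' comes from an intermediate table written to `out_dir`.
#'
#' @param out_dir output directory.
#' @param config a [cohort_config].
#' @param gconfig a [genetic_config].
#' @param params a [phenotype_params].
#' @param alpha family-wise error rate for the comparison table.
#' @param with_genetics run the polygenic-score block.
#' @return invisibly, a list with `phenotypes`, `truth`, `counts`,
#'   `prevalence`, `comparisons`, `missingness`, `trends`, `prs` and
#'   `report_path`.
#' @export
run_pipeline <- function(out_dir,
                         config = cohort_config(),
                         gconfig = genetic_config(),
                         params = phenotype_params(),
                         alpha = 0.05,
                         with_genetics = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, gconfig)
  write_cohort(cohort, out_dir)

  cl <- example_codelists()
  clinical <- read_clinical_table(file.path(out_dir, "clinical.tsv"), cl)
  prescriptions <- read_prescription_table(file.path(out_dir, "scripts.tsv"), cl)

  phen <- phenotype_cohort(clinical, prescriptions, params,
                           patient_ids = cohort$truth$patient_id)
  utils::write.table(phen, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  n <- nrow(phen)
  n_excluded <- sum(phen$mdd_status == "EXCLUDED")
  n_case <- sum(phen$mdd_status == "CASE")
  treated_case <- phen$mdd_status == "CASE" & phen$treated
  n_treated <- sum(treated_case)
  n_trd <- sum(phen$trd_status == "TRD")
  counts <- c(patients_in = n, excluded = n_excluded, mdd_cases = n_case,
              treated_cases = n_treated, trd = n_trd)
  prevalence <- list(
    mdd_percent = if (n > 0) prevalence_percent(n_case, n) else NA_real_,
    trd_percent_of_treated = if (n_treated > 0)
      prevalence_percent(n_trd, n_treated) else NA_real_
  )

  # TRD vs non-TRD comparison among treated cases
  sub <- phen[treated_case, , drop = FALSE]
  trd <- sub$trd_status == "TRD"
  comp_list <- list(
    combination = c(list(variable = "combination_flag",
                         trd_summary = mean(sub$combination_flag[trd]),
                         non_trd_summary = mean(sub$combination_flag[!trd])),
                    compare_binary(sub$combination_flag, trd)),
    augmentation = c(list(variable = "augmentation_flag",
                          trd_summary = mean(sub$augmentation_flag[trd]),
                          non_trd_summary = mean(sub$augmentation_flag[!trd])),
                     compare_binary(sub$augmentation_flag, trd)),
    adequate = c(list(variable = "adequate_interval_proportion",
                      trd_summary = mean(sub$adequate_interval_proportion[trd],
                                         na.rm = TRUE),
                      non_trd_summary = mean(sub$adequate_interval_proportion[!trd],
                                             na.rm = TRUE)),
                 compare_continuous(sub$adequate_interval_proportion, trd)),
    density = c(list(variable = "records_per_year",
                     trd_summary = mean(sub$records_per_year[trd]),
                     non_trd_summary = mean(sub$records_per_year[!trd])),
                compare_continuous(sub$records_per_year, trd))
  )
  comparisons <- do.call(rbind, lapply(comp_list, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  rownames(comparisons) <- NULL
  comparisons$p_adjusted <- pmin(1, comparisons$p * nrow(comparisons))
  comparisons$alpha_bonferroni <- bonferroni_threshold(alpha, nrow(comparisons))
  utils::write.table(comparisons, file.path(out_dir, "trd_comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  missingness <- if (n_treated > 0 && n_trd > 0 && n_trd < n_treated) {
    missingness_comparison(
      sub[, c("adequate_interval_proportion"), drop = FALSE],
      ifelse(trd, "TRD", "non-TRD"))
  } else NULL

  trends <- annual_trends(prescriptions)
  utils::write.table(trends$by_drug, file.path(out_dir, "trends_by_drug.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(trends$by_class, file.path(out_dir, "trends_by_class.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  prs <- NULL
  if (with_genetics && n_case > 0 && gconfig$n_snps > 0) {
    set.seed(config$seed + 1L)
    sumstats <- simulate_sumstats(cohort$snp_weights, seed = config$seed + 1L)
    model <- prs_model(sumstats$beta, sumstats$p)
    analysed <- phen$mdd_status %in% c("CASE", "CONTROL")
    y <- phen$mdd_status[analysed] == "CASE"
    g <- cohort$genotypes[match(phen$patient_id[analysed],
                                rownames(cohort$genotypes)), , drop = FALSE]
    sel <- select_best_threshold(y, g, model)
    score <- suppressWarnings(prs_score(g, model, sel$threshold))
    assoc <- suppressWarnings(prs_association(y, score))
    r2_obs <- stats::cor(as.numeric(y), score)^2
    lp <- liability_params(config$mdd_prevalence, mean(y))
    prs <- list(selected_threshold = sel$threshold,
                threshold_results = sel$results,
                beta = assoc$beta, se = assoc$se, p = assoc$p,
                r2_nagelkerke = assoc$r2_nagelkerke,
                r2_liability = r2_observed_to_liability(r2_obs, lp),
                n_case = sum(y), n_control = sum(!y))
    utils::write.table(sel$results, file.path(out_dir, "prs_thresholds.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  report_path <- file.path(out_dir, "report.md")
  lines <- c(
    "# Synthetic cohort phenotyping report", "",
    "## Selection flow",
    sprintf("- patients with records: %d", counts["patients_in"]),
    sprintf("- excluded (bipolar/psychotic/substance-use code): %d",
            counts["excluded"]),
    sprintf("- MDD cases: %d", counts["mdd_cases"]),
    sprintf("- MDD cases with antidepressant prescription: %d",
            counts["treated_cases"]),
    sprintf("- TRD (>= 2 switches): %d", counts["trd"]), "",
    "## Prevalence",
    sprintf("- MDD prevalence: %s%%", fmt(prevalence$mdd_percent, 4)),
    sprintf("- TRD prevalence among treated MDD: %s%%",
            fmt(prevalence$trd_percent_of_treated, 4)), "",
    "## TRD vs non-TRD (treated MDD cases)",
    "variable | TRD | non-TRD | effect | 95% CI | p | p(adj)",
    "--- | --- | --- | --- | --- | --- | ---",
    apply(comparisons, 1, function(r)
      paste(r[["variable"]], fmt(as.numeric(r[["trd_summary"]])),
            fmt(as.numeric(r[["non_trd_summary"]])),
            fmt(as.numeric(r[["effect"]])),
            paste0("[", fmt(as.numeric(r[["ci_lower"]])), ", ",
                   fmt(as.numeric(r[["ci_upper"]])), "]"),
            fmt(as.numeric(r[["p"]])), fmt(as.numeric(r[["p_adjusted"]])),
            sep = " | ")),
    ""
  )
  if (!is.null(missingness)) {
    lines <- c(lines, "## Missingness (TRD vs non-TRD)",
               sprintf("- %s: %.3f vs %.3f (p = %s)",
                       missingness$variable, missingness$missing_rate1,
                       missingness$missing_rate2, fmt(missingness$p)), "")
  }
  if (!is.null(prs)) {
    lines <- c(lines, "## Polygenic score association (MDD case vs control)",
               sprintf("- selected p-value threshold: %g", prs$selected_threshold),
               sprintf("- beta per SD = %s (SE %s), p = %s",
                       fmt(prs$beta), fmt(prs$se), fmt(prs$p)),
               sprintf("- Nagelkerke R2 (incremental): %s", fmt(prs$r2_nagelkerke)),
               sprintf("- liability-scale R2 (K = %.3f): %s",
                       config$mdd_prevalence, fmt(prs$r2_liability)), "")
  }
  writeLines(lines, report_path)

  invisible(list(phenotypes = phen, truth = cohort$truth, counts = counts,
                 prevalence = prevalence, comparisons = comparisons,
                 missingness = missingness, trends = trends, prs = prs,
                 report_path = report_path))
}
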