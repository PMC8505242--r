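#' Prevalence as a percentage
#'
#' @param n_case number of cases.
#' @param n_total denominator (must be positive).
#' @param digits decimal places for reporting (default 2, the convention
#'   for prevalence figures).
#' @return percentage, rounded to `digits`.
#' @export
prevalence_percent <- function(n_case, n_total, digits = 2) {
  stopifnot(n_case >= 0, n_case <= n_total)
  if (n_total <= 0) stop("n_total must be positive")
  round(100 * n_case / n_total, digits)
}

#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' Counts are exposed-case `a`, exposed-noncase `b`, unexposed-case `c`,
#' unexposed-noncase `d`. The interval comes from the normal approximation
#' on the log scale with standard error `sqrt(1/a + 1/b + 1/c + 1/d)`. Any
#' zero cell triggers the Haldane-Anscombe correction (0.5 added to every
#' cell), flagged in the output.
#'
#' @param a,b,c,d non-negative counts.
#' @param conf_level confidence level (default 0.95).
#' @return list with `or`, `ci_lower`, `ci_upper`, `log_or`, `se_log_or`,
#'   `p` (two-sided Wald), `corrected` (logical).
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    or = exp(log_or),
    ci_lower = exp(log_or - zq * se),
    ci_upper = exp(log_or + zq * se),
    log_or = log_or,
    se_log_or = se,
    p = p_from_z(log_or / se),
    corrected = corrected
  )
}

#' Polygenic score model
#'
#' Bundles per-SNP effect sizes and p-values from external GWAS summary
#' statistics with the ordered p-value thresholds at which scores are
#' built. The default grid has 11 thresholds, from genome-wide significance
#' up to all SNPs.
#'
#' @param weights numeric per-SNP effect sizes (log odds ratios or betas).
#' @param pvalues per-SNP association p-values, same length.
#' @param thresholds strictly increasing p-value cutoffs in (0, 1].
#' @return list of class `prs_model`.
#' @export
prs_model <- function(weights, pvalues,
                      thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                     0.1, 0.2, 0.3, 0.5, 1.0)) {
  stopifnot(length(weights) == length(pvalues),
            all(pvalues >= 0), all(pvalues <= 1),
            all(thresholds > 0), all(thresholds <= 1),
            all(diff(thresholds) > 0))
  structure(list(weights = as.numeric(weights),
                 pvalues = as.numeric(pvalues),
                 thresholds = as.numeric(thresholds)),
            class = "prs_model")
}

#' Compute a standardized polygenic score at one threshold
#'
#' Sum of dosage times weight over SNPs whose p-value is at or below the
#' threshold, standardized to mean 0 and variance 1 across the cohort.
#' SNPs are treated as independent (no clumping); if no SNP passes, or the
#' raw score is constant, a zero score is returned with a warning.
#'
#' @param genotypes n x m dosage matrix.
#' @param model a [prs_model].
#' @param threshold p-value cutoff; SNPs with `p <= threshold` contribute.
#' @return numeric vector of length n (standardized; attribute `n_snps`
#'   records how many SNPs contributed).
#' @export
prs_score <- function(genotypes, model, threshold) {
  stopifnot(inherits(model, "prs_model"),
            ncol(genotypes) == length(model$weights))
  sel <- model$pvalues <= threshold
  n <- nrow(genotypes)
  if (!any(sel)) {
    warning("no SNP passes threshold ", threshold, "; returning zero scores")
    return(structure(rep(0, n), n_snps = 0L))
  }
  raw <- as.numeric(genotypes[, sel, drop = FALSE] %*% model$weights[sel])
  s <- stats::sd(raw)
  if (is.na(s) || s == 0) {
    warning("polygenic score is constant; returning zero scores")
    return(structure(rep(0, n), n_snps = sum(sel)))
  }
  structure((raw - mean(raw)) / s, n_snps = sum(sel))
}

nagelkerke_r2 <- function(fit_full, fit_base, n) {
  ll1 <- as.numeric(stats::logLik(fit_full))
  ll0 <- as.numeric(stats::logLik(fit_base))
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_max <- 1 - exp(2 * ll0 / n)
  if (r2_max <= 0) return(0)
  r2_cs / r2_max
}

#' Logistic association between a phenotype and a polygenic score
#'
#' Maximum-likelihood logistic regression of case status on the score plus
#' covariates. Variance explained is reported as incremental Nagelkerke
#' R-squared against the covariate-only model, the convention in the
#' polygenic-score literature.
#'
#' @param case_status logical or 0/1 vector.
#' @param score numeric score (typically standardized, so `beta` is per SD).
#' @param covariates optional data.frame or matrix of adjustment covariates
#'   (e.g. genetic ancestry principal components).
#' @return list with `beta`, `se`, `z`, `p`, `r2_nagelkerke`, `n`,
#'   `degenerate` (constant score), `separation` (fitted probabilities at
#'   the boundary or non-convergence; estimates reported with a warning).
#' @export
prs_association <- function(case_status, score, covariates = NULL) {
  y <- as.integer(case_status)
  stopifnot(length(y) == length(score), all(y %in% c(0L, 1L)))
  df <- data.frame(y = y, score = score)
  base_formula <- "y ~ 1"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    names(covariates) <- make.names(names(covariates), unique = TRUE)
    df <- cbind(df, covariates)
    base_formula <- paste("y ~", paste(names(covariates), collapse = " + "))
  }
  full_formula <- paste(base_formula, "+ score")
  if (stats::sd(score) == 0) {
    warning("score is constant; association is degenerate")
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                r2_nagelkerke = 0, n = length(y), degenerate = TRUE,
                separation = FALSE))
  }
  fit_full <- stats::glm(stats::as.formula(full_formula), data = df,
                         family = stats::binomial())
  fit_base <- stats::glm(stats::as.formula(base_formula), data = df,
                         family = stats::binomial())
  co <- summary(fit_full)$coefficients["score", ]
  eps <- 1e-8
  separation <- !fit_full$converged ||
    any(fit_full$fitted.values < eps | fit_full$fitted.values > 1 - eps)
  if (separation)
    warning("possible separation in logistic fit; estimates may be unstable")
  list(
    beta = unname(co[1]),
    se = unname(co[2]),
    z = unname(co[3]),
    p = p_from_z(unname(co[3])),
    r2_nagelkerke = nagelkerke_r2(fit_full, fit_base, length(y)),
    n = length(y),
    degenerate = FALSE,
    separation = separation
  )
}

#' Select the most predictive p-value threshold
#'
#' Builds the score at every threshold of the model, fits the logistic
#' association, and returns the threshold maximizing incremental Nagelkerke
#' R-squared. Ties (including the all-null case, where every threshold
#' explains nothing) resolve to the smallest threshold.
#'
#' @inheritParams prs_association
#' @param genotypes n x m dosage matrix.
#' @param model a [prs_model].
#' @return list with `threshold` (the selected cutoff), `r2` (its
#'   Nagelkerke R-squared) and `results` (data.frame over all thresholds:
#'   `threshold`, `n_snps`, `beta`, `se`, `p`, `r2`).
#' @export
select_best_threshold <- function(case_status, genotypes, model,
                                  covariates = NULL) {
  stopifnot(inherits(model, "prs_model"), length(model$thresholds) >= 1)
  rows <- lapply(model$thresholds, function(pt) {
    score <- suppressWarnings(prs_score(genotypes, model, pt))
    fit <- suppressWarnings(prs_association(case_status, score, covariates))
    data.frame(threshold = pt, n_snps = attr(score, "n_snps"),
               beta = fit$beta, se = fit$se, p = fit$p,
               r2 = fit$r2_nagelkerke)
  })
  results <- do.call(rbind, rows)
  best <- which.max(results$r2)  # first maximum = smallest threshold on ties
  list(threshold = results$threshold[best], r2 = results$r2[best],
       results = results)
}

#' Compare two effect estimates with a z-test
#'
#' Tests equality of two independent effect sizes (e.g. a polygenic score's
#' log odds ratio in two cohorts):
#' `z = (beta1 - beta2) / sqrt(se1^2 + se2^2)`, with a two-sided normal
#' p-value.
#'
#' @param beta1,se1 first estimate and standard error.
#' @param beta2,se2 second estimate and standard error.
#' @return list with `z` and `p`.
#' @export
z_compare_effects <- function(beta1, se1, beta2, se2) {
  if (!(se1 > 0 && se2 > 0)) stop("standard errors must be positive")
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  list(z = z, p = p_from_z(z))
}

#' Two-sided normal p-value from a z statistic
#'
#' Evaluated through the upper-tail complementary function, with a
#' log-scale fallback for extreme statistics, so p-values stay positive out
#' to the edge of what IEEE doubles can represent (around `|z| = 38.5`;
#' beyond that the true tail is smaller than the smallest subnormal double
#' and rounds to zero).
#'
#' @param z z statistic (finite).
#' @return two-sided p-value.
#' @export
p_from_z <- function(z) {
  stopifnot(all(is.finite(z)))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  under <- p == 0 & abs(z) > 0
  if (any(under)) {
    p[under] <- exp(log(2) +
                      stats::pnorm(abs(z[under]), lower.tail = FALSE,
                                   log.p = TRUE))
  }
  p
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (at least 1), e.g. traits times p-value
#'   thresholds.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Overlap between two binary measures
#'
#' Percentage of patients positive on measure `a` who are also positive on
#' measure `b` (e.g. primary-care MDD vs a questionnaire definition).
#' Pairs with a missing value on either measure are excluded, with counts
#' reported.
#'
#' @param a,b logical vectors over the same patients (`NA` allowed).
#' @return list with `percent` (`NA` if no complete a-positive exists),
#'   `n_a_positive`, `n_both`, `n_missing_excluded`.
#' @export
measure_overlap <- function(a, b) {
  stopifnot(length(a) == length(b))
  complete <- !is.na(a) & !is.na(b)
  n_missing <- sum(!complete)
  a <- a[complete]; b <- b[complete]
  n_a <- sum(a)
  n_both <- sum(a & b)
  list(
    percent = if (n_a == 0) NA_real_ else 100 * n_both / n_a,
    n_a_positive = n_a,
    n_both = n_both,
    n_missing_excluded = n_missing
  )
}
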