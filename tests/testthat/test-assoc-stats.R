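test_that("prevalence percentages come out to two decimals", {
  expect_equal(prevalence_percent(0, 100), 0)
  expect_equal(prevalence_percent(1, 3), 33.33)
  expect_error(prevalence_percent(1, 0))
  expect_error(prevalence_percent(5, 3))
})

test_that("odds ratios match the closed form and the logistic-fit oracle", {
  expect_equal(odds_ratio(10, 10, 10, 10)$or, 1)
  or <- odds_ratio(20, 10, 10, 20)
  expect_equal(or$or, 4)
  expect_false(or$corrected)
  # zero cell: continuity correction applied and flagged
  or0 <- odds_ratio(5, 0, 3, 7)
  expect_true(or0$corrected)
  expect_true(is.finite(or0$or))
  # oracle: exp(beta) from a logistic fit on the expanded binary data
  for (counts in list(c(20, 10, 10, 20), c(7, 13, 2, 31), c(4, 9, 16, 3))) {
    a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
    y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
    x <- c(rep(1, a + b), rep(0, c + d))
    fit <- stats::glm(y ~ x, family = stats::binomial())
    expect_equal(odds_ratio(a, b, c, d)$or,
                 unname(exp(stats::coef(fit)[2])), tolerance = 1e-6)
  }
})

test_that("polygenic scores threshold, weight and standardize correctly", {
  g <- matrix(c(2, 1, 0, 0, 1, 2), nrow = 3)
  m <- prs_model(weights = c(0.5, 0), pvalues = c(0.01, 0.5),
                 thresholds = c(0.05, 1))
  # only SNP 1 passes at 0.05; raw scores 1.0, 0.5, 0.0 -> standardized
  s <- prs_score(g, m, 0.05)
  expect_equal(attr(s, "n_snps"), 1L)
  expect_equal(as.numeric(s), as.numeric(scale(c(1, 0.5, 0))))
  expect_equal(mean(s), 0)
  expect_equal(stats::sd(s), 1)
  # at threshold 1 both pass, but SNP 2 has weight 0
  s2 <- prs_score(g, m, 1)
  expect_equal(attr(s2, "n_snps"), 2L)
  expect_equal(as.numeric(s2), as.numeric(s))
  # all weights zero -> constant score, warned
  m0 <- prs_model(weights = c(0, 0), pvalues = c(0.01, 0.5))
  expect_warning(s0 <- prs_score(g, m0, 1), "constant")
  expect_equal(as.numeric(s0), c(0, 0, 0))
  # nothing passes a tiny threshold
  expect_warning(sn <- prs_score(g, m, 1e-10), "no SNP")
  expect_equal(as.numeric(sn), c(0, 0, 0))
})

test_that("logistic association recovers a planted per-SD effect", {
  set.seed(42)
  n <- 4000
  score <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 0.4 * score))
  fit <- prs_association(y, score)
  expect_lt(abs(fit$beta - 0.4), 4 * fit$se)
  expect_lt(fit$p, 1e-10)
  expect_gt(fit$r2_nagelkerke, 0)
  # covariate adjustment keeps the score estimate sane
  cov <- data.frame(pc1 = stats::rnorm(n))
  fit2 <- prs_association(y, score, cov)
  expect_lt(abs(fit2$beta - fit$beta), 0.05)
  # constant score is degenerate
  expect_warning(d <- prs_association(y, rep(1, n)), "constant")
  expect_true(d$degenerate)
})

test_that("association p-values are uniform under the null", {
  set.seed(7)
  n_reps <- 1000
  pvals <- replicate(n_reps, {
    y <- stats::rbinom(300, 1, 0.3)
    s <- stats::rnorm(300)
    suppressWarnings(prs_association(y, s)$p)
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("threshold selection maximizes incremental Nagelkerke R2", {
  m1 <- prs_model(weights = 0.3, pvalues = 0.01, thresholds = 0.05)
  g <- matrix(stats::rbinom(200, 2, 0.3), ncol = 1)
  y <- stats::rbinom(100, 1, 0.5)
  sel <- select_best_threshold(y, g[1:100, , drop = FALSE], m1)
  expect_equal(sel$threshold, 0.05)

  # planted causal stratum: causal SNPs have tiny p, null SNPs large p
  set.seed(12)
  n <- 2500; m_causal <- 30; m_null <- 70
  maf <- stats::runif(m_causal + m_null, 0.1, 0.5)
  g <- sapply(maf, function(f) stats::rbinom(n, 2, f))
  w_true <- c(stats::rnorm(m_causal, 0, 0.25), rep(0, m_null))
  eta <- -0.5 + g %*% w_true
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  model <- prs_model(
    weights = w_true + stats::rnorm(m_causal + m_null, 0, 0.02),
    pvalues = c(stats::runif(m_causal, 0, 1e-5), stats::runif(m_null, 0.1, 1)),
    thresholds = c(1e-4, 0.05, 1)
  )
  sel <- select_best_threshold(y, g, model)
  # the causal-only threshold should beat all-SNPs; either of the two
  # causal-capturing cutoffs is acceptable, never the degenerate smallest R2
  expect_equal(sel$r2, max(sel$results$r2))
  expect_true(sel$results$r2[sel$results$threshold == 1e-4] >
                0.5 * max(sel$results$r2))
})

test_that("liability conversions round-trip and match the hand-derived oracle", {
  # oracle value derived by evaluating t and z numerically for
  # K = 0.023, P = 0.161: h2_liab = 0.1 * K^2(1-K)^2 / (z^2 P(1-P))
  lp <- liability_params(0.023, 0.161)
  expect_equal(h2_observed_to_liability(0.1, lp), 0.1258987, tolerance = 1e-6)
  expect_equal(h2_observed_to_liability(0, lp), 0)
  # round trip to 1e-10 relative
  for (K in c(0.01, 0.1, 0.3)) {
    for (P in c(0.05, 0.3, 0.5)) {
      lp <- liability_params(K, P)
      h <- h2_liability_to_observed(h2_observed_to_liability(0.37, lp), lp)
      expect_equal(h, 0.37, tolerance = 1e-10)
    }
  }
  # strictly increasing in h2_obs, continuous in K
  lp <- liability_params(0.1, 0.3)
  h2s <- h2_observed_to_liability(seq(0, 0.5, by = 0.05), lp)
  expect_true(all(diff(h2s) > 0))
  ks <- seq(0.02, 0.98, by = 0.02)
  hs <- vapply(ks, function(k)
    h2_observed_to_liability(0.1, liability_params(k, 0.3)), numeric(1))
  expect_true(all(is.finite(hs)))
  expect_lt(max(abs(diff(hs))), 0.2)  # no jumps on a fine grid
  expect_error(liability_params(0, 0.3))
  expect_error(liability_params(0.1, 1))
})

test_that("R2 conversion reduces to the simple rescaling when P = K", {
  for (K in c(0.05, 0.108, 0.3)) {
    lp <- liability_params(K)
    z <- stats::dnorm(stats::qnorm(1 - K))
    simple <- 0.04 * K * (1 - K) / z^2
    expect_equal(r2_observed_to_liability(0.04, lp), simple, tolerance = 1e-12)
  }
  expect_equal(r2_observed_to_liability(0, liability_params(0.1, 0.4)), 0)
})

test_that("ascertained R2 conversion recovers a planted liability variance share", {
  # simulation oracle: a population under the liability model, sampled to a
  # 50/50 case-control design, must transform back to the planted share
  set.seed(17)
  h2 <- 0.3; K <- 0.1
  n <- 150000
  s <- stats::rnorm(n)
  lia <- sqrt(h2) * s + sqrt(1 - h2) * stats::rnorm(n)
  case <- lia > stats::qnorm(1 - K)
  idx <- c(sample(which(case), 8000), sample(which(!case), 8000))
  r2_obs <- stats::cor(as.numeric(case[idx]), s[idx])^2
  r2_liab <- r2_observed_to_liability(r2_obs, liability_params(K, 0.5))
  expect_equal(r2_liab, h2, tolerance = 0.05)
})

test_that("effect-comparison z-test behaves and tails stay positive", {
  expect_equal(z_compare_effects(0.3, 0.1, 0.3, 0.2)$z, 0)
  expect_equal(z_compare_effects(0.3, 0.1, 0.3, 0.2)$p, 1)
  zt <- z_compare_effects(0.3, 0.05, 0.1, 0.05)
  expect_equal(zt$z, 0.2 / sqrt(0.005), tolerance = 1e-12)
  expect_equal(zt$z, 2.8284271, tolerance = 1e-6)
  # antisymmetry
  zt2 <- z_compare_effects(0.1, 0.05, 0.3, 0.05)
  expect_equal(zt2$z, -zt$z)
  expect_equal(zt2$p, zt$p)
  expect_error(z_compare_effects(0.3, 0, 0.1, 0.05), "positive")

  expect_equal(p_from_z(0), 1)
  expect_equal(p_from_z(1.96), 0.05, tolerance = 1e-3)
  # stable tails: positive out to the edge of subnormal doubles (a naive
  # 1 - pnorm(z) hits zero already near z = 8.3)
  expect_gt(p_from_z(38), 0)
  expect_gt(p_from_z(8.3), 0)
})

test_that("Bonferroni correction divides and stays monotone", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 88), 0.05 / 88)
  ns <- 1:20
  expect_true(all(diff(vapply(ns, bonferroni_threshold, numeric(1),
                              alpha = 0.05)) < 0))
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("binary-measure overlap counts a-positives found in b", {
  a <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  b <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(measure_overlap(a, b)$percent, 75)
  expect_equal(measure_overlap(a, a)$percent, 100)
  expect_equal(measure_overlap(a, !a)$percent, 0)
  expect_true(is.na(measure_overlap(c(FALSE, FALSE), c(TRUE, TRUE))$percent))
  # pairwise deletion of missing values, with the count reported
  ov <- measure_overlap(c(TRUE, NA, TRUE), c(TRUE, TRUE, NA))
  expect_equal(ov$percent, 100)
  expect_equal(ov$n_missing_excluded, 2L)
})
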