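test_that("same-drug prescriptions chain into episodes at the 98-day gap", {
  # 0, 28, 56: one run spanning 56 days
  eps <- build_drug_episodes(rx(c(0, 28, 56), "a"))
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$duration_days, 56)
  expect_equal(eps$n_prescriptions, 3L)
  # 0, 28, 200: the 172-day gap splits the run
  eps <- build_drug_episodes(rx(c(0, 28, 200), "a"))
  expect_equal(nrow(eps), 2L)
  expect_equal(eps$duration_days, c(28, 0))
  # a 98-day gap still chains (inclusive rule)
  eps <- build_drug_episodes(rx(c(0, 98), "a"))
  expect_equal(nrow(eps), 1L)
  # a 99-day gap does not
  eps <- build_drug_episodes(rx(c(0, 99), "a"))
  expect_equal(nrow(eps), 2L)
  # no prescriptions
  expect_equal(nrow(build_drug_episodes(no_rx())), 0L)
})

test_that("switches require qualifying episodes, a close gap and no combination", {
  # A 0-56, B 70-126, C 140-196: two switches, gaps 14 and 14
  p <- rx_bind(rx(c(0, 28, 56), "a"), rx(c(70, 98, 126), "b"),
               rx(c(140, 168, 196), "c"))
  sw <- detect_switches(build_drug_episodes(p))
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$gap_days, c(14, 14))
  expect_equal(sw$from_drug, c("a", "b"))
  expect_equal(sw$to_drug, c("b", "c"))

  # gap 144 > 98: no switch
  p <- rx_bind(rx(c(0, 28, 56), "a"), rx(c(200, 228, 256), "b"))
  expect_equal(nrow(detect_switches(build_drug_episodes(p))), 0L)

  # an episode below 42 days never qualifies
  p <- rx_bind(rx(c(0, 28), "a"), rx(c(60, 88, 116), "b"))
  expect_equal(nrow(detect_switches(build_drug_episodes(p))), 0L)

  # overlap beyond 30 days is a combination, not a switch
  p <- rx_bind(rx(c(0, 50, 100), "a"), rx(c(30, 80, 120), "b"))
  expect_equal(nrow(detect_switches(build_drug_episodes(p))), 0L)
  flags <- detect_combination_augmentation(p)
  expect_true(flags$combination)

  # single episode
  expect_equal(nrow(detect_switches(build_drug_episodes(rx(c(0, 28, 56), "a")))), 0L)

  # A -> B -> A counts as two switches: only adjacent drugs must differ.
  # The return to A starts 104 days after A's last issue, so the two A runs
  # stay separate episodes.
  p <- rx_bind(rx(c(0, 28, 56), "a"), rx(c(70, 98, 126), "b"),
               rx(c(160, 188, 216), "a"))
  expect_equal(nrow(detect_switches(build_drug_episodes(p))), 2L)
})

test_that("non-antidepressant episodes are invisible to switch detection", {
  p <- rx_bind(rx(c(0, 28, 56), "a"), rx(c(70, 98, 126), "q", "ANTIPSYCHOTIC"),
               rx(c(140, 168, 196), "b"))
  sw <- detect_switches(build_drug_episodes(p))
  # a -> b with gap 84 (<= 98): the antipsychotic in between neither counts
  # nor breaks adjacency
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$from_drug, "a")
  expect_equal(sw$to_drug, "b")
})

test_that("MDD classification follows the two-code and exclusion rules", {
  # two depression codes on distinct dates, nothing else
  expect_equal(classify_mdd(dx_bind(dx(0, "DEPRESSION"), dx(800, "DEPRESSION"))),
               "CASE")
  # one code only: neither case nor clean control
  expect_equal(classify_mdd(dx(0, "DEPRESSION")), "SUBTHRESHOLD")
  # two codes on the same date guard against duplicate coding
  expect_equal(classify_mdd(dx_bind(dx(0, "DEPRESSION"), dx(0, "DEPRESSION"))),
               "SUBTHRESHOLD")
  # exclusion code trumps depression codes
  expect_equal(classify_mdd(dx_bind(dx(0, "DEPRESSION"), dx(100, "DEPRESSION"),
                                    dx(50, "BIPOLAR"))), "EXCLUDED")
  expect_equal(classify_mdd(dx(0, "SUBSTANCE_USE")), "EXCLUDED")
  # no events, or only non-psychiatric events: control
  expect_equal(classify_mdd(no_dx()), "CONTROL")
  expect_equal(classify_mdd(dx(0, "NON_PSYCHIATRIC")), "CONTROL")
  # other psychiatric codes spoil the screened control set
  expect_equal(classify_mdd(dx(0, "OTHER_PSYCHIATRIC")), "SUBTHRESHOLD")
  # ... but not under MDD-only screening
  expect_equal(classify_mdd(dx(0, "OTHER_PSYCHIATRIC"),
                            phenotype_params(control_screening = "mdd_only")),
               "CONTROL")
  # relaxed one-code definition
  expect_equal(classify_mdd(dx(0, "DEPRESSION"),
                            phenotype_params(min_depression_codes = 1)),
               "CASE")
})

test_that("TRD status is gated on case status and treatment", {
  expect_equal(classify_trd("CASE", TRUE, 2L), "TRD")
  expect_equal(classify_trd("CASE", TRUE, 1L), "NON_TRD")
  expect_equal(classify_trd("CASE", FALSE, 2L), "NOT_APPLICABLE")
  expect_equal(classify_trd("CONTROL", TRUE, 2L), "NOT_APPLICABLE")
  expect_equal(classify_trd("EXCLUDED", TRUE, 5L), "NOT_APPLICABLE")
})

test_that("adequate-interval proportion pools all antidepressants", {
  expect_equal(adequate_interval_proportion(rx(c(0, 50, 200), "a")), 0.5)
  expect_equal(adequate_interval_proportion(rx(c(0, 28, 56), "a")), 1.0)
  expect_true(is.na(adequate_interval_proportion(rx(0, "a"))))
  expect_true(is.na(adequate_interval_proportion(no_rx())))
  # intervals pool across drugs: a@0, b@50, a@200 -> gaps 50 and 150
  p <- rx_bind(rx(c(0, 200), "a"), rx(50, "b"))
  expect_equal(adequate_interval_proportion(p), 0.5)
  # non-antidepressants are ignored
  p <- rx_bind(rx(c(0, 50), "a"), rx(25, "q", "ANTIPSYCHOTIC"))
  expect_equal(adequate_interval_proportion(p), 1.0)
})

test_that("combination and augmentation need more than 30 days of overlap", {
  # 70-day overlap of two antidepressants
  p <- rx_bind(rx(c(0, 50, 100), "a"), rx(c(30, 80, 120), "b"))
  flags <- detect_combination_augmentation(p)
  expect_true(flags$combination)
  expect_false(flags$augmentation)
  # 15-day antipsychotic overlap is not augmentation
  p <- rx_bind(rx(c(0, 50, 100), "a"), rx(c(80, 95), "q", "ANTIPSYCHOTIC"))
  expect_false(detect_combination_augmentation(p)$augmentation)
  # 40-day overlap is
  p <- rx_bind(rx(c(0, 50, 100), "a"), rx(c(60, 100), "q", "ANTIPSYCHOTIC"))
  flags <- detect_combination_augmentation(p)
  expect_true(flags$augmentation)
  expect_false(flags$combination)
  # exactly 30 days is not enough (strict rule)
  p <- rx_bind(rx(c(0, 50, 100), "a"), rx(c(70, 100), "q", "ANTIPSYCHOTIC"))
  expect_false(detect_combination_augmentation(p)$augmentation)
  # single drug
  flags <- detect_combination_augmentation(rx(c(0, 28, 56), "a"))
  expect_false(flags$combination)
  expect_false(flags$augmentation)
  # same drug in two separated episodes is never a combination
  p <- rx(c(0, 28, 200, 228), "a")
  expect_false(detect_combination_augmentation(p)$combination)
})

test_that("record density counts distinct dates against a floored span", {
  # 10 records on 5 distinct dates over exactly 2 years (730.5 days)
  ev <- dx(c(0, 0, 182, 182, 364), "NON_PSYCHIATRIC")
  p <- rx(c(364, 547, 547, 730.5, 730.5), "a")
  d <- record_density(ev, p)
  expect_equal(d$n_clinical_records, 5L)
  expect_equal(d$n_prescription_records, 5L)
  expect_equal(d$span_years, 2)
  expect_equal(d$records_per_year, 2.5)
  # all records on one date: span floored at one year
  d <- record_density(dx(c(0, 0), "NON_PSYCHIATRIC"), no_rx())
  expect_equal(d$span_years, 1)
  expect_equal(d$records_per_year, 1)
  # no records at all
  d <- record_density(no_dx(), no_rx())
  expect_equal(d$records_per_year, 0)
})

test_that("annual trends count prescriptions by year, drug and class", {
  expect_equal(nrow(annual_trends(no_rx())$by_drug), 0L)
  p <- rx_bind(
    rx(as.numeric(as.Date(c("2004-02-01", "2004-06-01", "2004-11-30")) - D0), "a"),
    rx(as.numeric(as.Date(c("2005-03-01", "2005-07-01")) - D0), "a")
  )
  tr <- annual_trends(p)
  expect_equal(tr$by_drug$n[tr$by_drug$year == 2004], 3L)
  expect_equal(tr$by_drug$n[tr$by_drug$year == 2005], 2L)
  # class totals conserve drug totals
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 2),
                        genetic_config(n_snps = 0, seed = 2))
  tr <- annual_trends(co$prescriptions)
  expect_equal(sum(tr$by_drug$n), sum(tr$by_class$n))
  expect_equal(sum(tr$by_drug$n), nrow(co$prescriptions))
})

test_that("phenotyping is invariant under permutation of input rows", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 42),
                        genetic_config(n_snps = 0, seed = 42))
  base <- phenotype_cohort(co$clinical, co$prescriptions,
                           patient_ids = co$truth$patient_id)
  set.seed(1)
  for (i in 1:3) {
    shuffled <- phenotype_cohort(
      co$clinical[sample(nrow(co$clinical)), , drop = FALSE],
      co$prescriptions[sample(nrow(co$prescriptions)), , drop = FALSE],
      patient_ids = co$truth$patient_id)
    expect_equal(shuffled, base)
  }
})

test_that("adding same-drug prescriptions never shortens an episode", {
  set.seed(99)
  for (i in 1:25) {
    p <- rx(sort(sample(0:500, sample(2:8, 1))), "a")
    eps <- build_drug_episodes(p)
    extra <- rx(sample(0:500, 1), "a")
    eps2 <- build_drug_episodes(rx_bind(p, extra))
    # every original episode lies inside some episode of the augmented set
    for (j in seq_len(nrow(eps))) {
      covered <- any(eps2$start_date <= eps$start_date[j] &
                       eps2$end_date >= eps$end_date[j])
      expect_true(covered)
    }
  }
})

test_that("every TRD patient is a treated case with >= 2 switches from >= 3 episodes", {
  co <- generate_cohort(cohort_config(n_patients = 400, trd_fraction = 0.3,
                                      seed = 8),
                        genetic_config(n_snps = 0, seed = 8))
  ph <- phenotype_cohort(co$clinical, co$prescriptions,
                         patient_ids = co$truth$patient_id)
  trd <- ph[ph$trd_status == "TRD", ]
  expect_gt(nrow(trd), 0)
  expect_true(all(trd$mdd_status == "CASE"))
  expect_true(all(trd$treated))
  expect_true(all(trd$n_switches >= 2))
  params <- phenotype_params()
  for (id in trd$patient_id) {
    p <- co$prescriptions[co$prescriptions$patient_id == id, , drop = FALSE]
    eps <- build_drug_episodes(p, params)
    q <- eps[eps$drug_class == "ANTIDEPRESSANT" &
               eps$duration_days >= params$min_episode_days, ]
    expect_gte(nrow(q), 3)
  }
})
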