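test_that("the corrected chi-squared reproduces published 2x2 p-values", {
  expect_equal(round(chi2_yates(51, 250, 23, 44), 3), 0.002)
  expect_equal(round(chi2_yates(172, 160, 55, 26), 3), 0.013)
  expect_equal(chi2_yates(10, 10, 10, 10), 1.0)
  expect_error(chi2_yates(0, 0, 5, 5), "zero margin")
})

test_that("the continuity correction is conservative on every table", {
  set.seed(12)
  for (i in 1:200) {
    tab <- rmultinom(1, sample(10:80, 1), prob = runif(4, 0.05, 1))
    m <- matrix(tab, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p_corr <- chi2_yates(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    p_raw <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value
    expect_gte(p_corr, p_raw - 1e-12)
  }
})

test_that("Fisher's exact test matches hand enumeration and published values", {
  # margins (5,5)x(5,5): only the two extreme tables are as improbable
  expect_equal(fisher_exact(0, 5, 5, 0), 2 / 252)  # the two extreme tables
  expect_equal(fisher_exact(1, 1, 1, 1), 1.0)
  expect_equal(round(fisher_exact(25, 276, 1, 66), 3), 0.062)
  expect_equal(fisher_exact(0, 0, 0, 0), 1)
})

test_that("Fisher p equals full margin-fixed enumeration on random tables", {
  set.seed(13)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    cells <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    ours <- do.call(fisher_exact, as.list(cells))
    oracle <- do.call(fisher_enum_oracle, as.list(cells))
    expect_equal(ours, oracle, tolerance = 1e-10,
                 label = paste("table", paste(cells, collapse = ",")))
  }
})

test_that("the test chooser applies the expected-count rule", {
  expect_equal(choose_test(51, 250, 23, 44), "chi_squared_yates")  # min E ~ 13.5
  expect_equal(choose_test(25, 276, 1, 66), "fisher_exact")        # min E ~ 4.7
  expect_equal(choose_test(0, 0, 0, 0), "fisher_exact")
})

test_that("Benjamini-Hochberg is step-up, monotone and idempotent", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))  # order-preserving
  expect_equal(bh_adjust(adj), adj)  # idempotent
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("Wilson intervals reproduce the published participation CIs", {
  berlin <- wilson_ci(282, 59394)
  expect_equal(round(100 * berlin, 2), c(low = 0.42, high = 0.53))
  bremen <- wilson_ci(9, 3930)
  expect_equal(round(100 * bremen, 2), c(low = 0.12, high = 0.43))
  expect_equal(wilson_ci(0, 10)[["low"]], 0)
  expect_error(wilson_ci(1, 0), "positive")
  expect_error(wilson_ci(5, 3), "\\[0, n\\]")
})

test_that("Wilson intervals bracket the point estimate and tighten with n", {
  set.seed(15)
  for (i in 1:50) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci["low"] >= 0 && ci["low"] <= k / n)
    expect_true(ci["high"] <= 1 && ci["high"] >= k / n)
    wider <- wilson_ci(k * 10, n * 10)
    expect_lt(diff(wider), diff(ci) + 1e-12)
  }
})

test_that("the published reason tables reproduce at three decimals", {
  ind <- reason_tests(survey_reason_counts("indication"))
  printed_raw <- c(risk_too_low = 0.239, no_prescriber = 0.746,
                   doctor_visit_effort = 0.043, discuss_sex_life = 0.333,
                   negative_reactions = 0.062, side_effects = 0.920,
                   daily_pill = 0.002, medical_reasons = 1.000)
  printed_adj <- c(risk_too_low = 0.478, no_prescriber = 0.994,
                   doctor_visit_effort = 0.164, discuss_sex_life = 0.532,
                   negative_reactions = 0.164, side_effects = 1.000,
                   daily_pill = 0.019, medical_reasons = 1.000)
  expect_equal(round(ind$p_raw, 3), unname(printed_raw[ind$reason]))
  expect_equal(round(ind$p_adjusted, 3), unname(printed_adj[ind$reason]))
  expect_equal(ind$test_used[ind$reason == "negative_reactions"], "fisher_exact")
  expect_equal(ind$test_used[ind$reason == "daily_pill"], "chi_squared_yates")

  den <- reason_tests(survey_reason_counts("density"))
  printed_raw_d <- c(risk_too_low = 0.045, no_prescriber = 0.266,
                     doctor_visit_effort = 0.200, discuss_sex_life = 0.021,
                     negative_reactions = 0.255, side_effects = 0.013,
                     daily_pill = 0.267, medical_reasons = 0.584)
  printed_adj_d <- c(risk_too_low = 0.121, no_prescriber = 0.306,
                     doctor_visit_effort = 0.306, discuss_sex_life = 0.083,
                     negative_reactions = 0.306, side_effects = 0.083,
                     daily_pill = 0.306, medical_reasons = 0.584)
  expect_equal(round(den$p_raw, 3), unname(printed_raw_d[den$reason]))
  expect_equal(round(den$p_adjusted, 3), unname(printed_adj_d[den$reason]))
})

test_that("cohort-level reason analysis counts citations per stratum", {
  rec <- make_records(
    make_record(prep_status = "never", sdu_6m = "yes",
                n_partners_6m_category = "1", sti_chlamydia_12m = "0"),
    make_record(prep_status = "never", sdu_6m = "no",
                sti_chlamydia_12m = "1", n_partners_6m_category = "1"),
    make_record(prep_status = "never", sdu_6m = "yes",
                sti_chlamydia_12m = "1", n_partners_6m_category = "1"),
    make_record(prep_status = "current")
  )
  for (r in c("risk_too_low", "side_effects")) {
    rec[[paste0("reason_", r)]] <- c(1L, 0L, 1L, 0L)
  }
  cohort <- apply_selection_flow(rec)
  an <- prepare_covariates(cohort$records)
  counts <- reason_counts(an, "indication")
  expect_equal(counts$n1, rep(1, 2))  # partners_sti_hcv stratum
  expect_equal(counts$n2, rep(1, 2))  # sdu_only stratum
  expect_equal(counts$n_both, rep(1, 2))
  expect_equal(counts$k1, rep(0, 2))
  expect_equal(counts$k2, rep(1, 2))
  res <- build_reason_analysis(an, "indication")
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_adjusted >= res$p_raw))
})

test_that("identical reason rates across strata produce no discovery", {
  cfg <- cohort_config(4000, seed = 42,
                       reason_probs = lapply(default_reason_probs(), function(p) {
                         p[] <- mean(p); p
                       }))
  rec <- generate_cohort(cfg)
  an <- prepare_covariates(apply_selection_flow(rec)$records)
  for (strat in c("indication", "density")) {
    res <- build_reason_analysis(an, strat)
    expect_gt(min(res$p_adjusted), 0.05)
  }
})

test_that("density stratification drops non-users with unknown state", {
  rec <- make_records(
    make_record(prep_status = "never", sdu_6m = "yes", federal_state = "Berlin"),
    make_record(prep_status = "never", sdu_6m = "yes", federal_state = "missing"),
    make_record(prep_status = "never", sdu_6m = "yes", federal_state = "Saxony")
  )
  rec$reason_side_effects <- c(1L, 1L, 0L)
  an <- prepare_covariates(apply_selection_flow(rec)$records)
  counts <- reason_counts(an, "density")
  expect_equal(counts$n1 + counts$n2, 2)  # the unknown-state record is excluded
  expect_equal(counts$n_all, 3)
})

test_that("user proportions and participation probabilities match print", {
  states <- survey_state_counts()
  props <- user_proportion(states)
  expect_equal(props$proportion[props$state == "Mecklenburg Western Pomerania"],
               0.74)  # 14 of 19
  expect_equal(props$proportion[props$state == "Bremen"], 0.89)  # 8 of 9
  expect_equal(user_proportion(data.frame(state = "A", n_participants = 5,
                                          n_users = 0))$proportion, 0)
  part <- participation_table(states)
  berlin <- part[part$state == "Berlin", ]
  expect_equal(round(100 * berlin$probability, 2), 0.47)
  sh <- part[part$state == "Schleswig-Holstein", ]
  expect_equal(round(100 * sh$probability, 2), 0.12)
})
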