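test_that("the indication predicate follows the criteria per role", {
  # non-user: SDU alone suffices, regardless of partners/condoms
  r <- make_record(prep_status = "never", sdu_6m = "yes",
                   n_partners_6m_category = "1", condom_use_category = ">95%",
                   sti_chlamydia_12m = "0")
  expect_true(has_indication(r, "prep_non_user"))
  # non-user: several partners but 75% condom use does not qualify
  r <- make_record(prep_status = "never", sdu_6m = "no",
                   n_partners_6m_category = "4-5", condom_use_category = "75%",
                   sti_chlamydia_12m = "0")
  expect_false(has_indication(r, "prep_non_user"))
  # user: the low-condom-use requirement is waived
  r <- make_record(prep_status = "current", sdu_6m = "no",
                   n_partners_6m_category = "2-3", condom_use_category = ">95%",
                   sti_chlamydia_12m = "0")
  expect_true(has_indication(r, "prep_user"))
  expect_false(has_indication(r, "prep_non_user"))
  expect_error(has_indication(r, "observer"), "arg")
})

test_that("missing behavioral fields never satisfy a clause", {
  r <- make_record(prep_status = "never", sdu_6m = "missing",
                   n_partners_6m_category = "missing",
                   condom_use_category = "missing",
                   sti_syphilis_12m = "missing", sti_gonorrhea_12m = "missing",
                   sti_chlamydia_12m = "missing", sti_hcv_12m = "missing")
  expect_false(has_indication(r, "prep_non_user"))
  expect_false(has_indication(r, "prep_user"))
})

test_that("subgroup classification partitions by clause family", {
  sdu_only <- make_record(prep_status = "never", sdu_6m = "yes",
                          n_partners_6m_category = "1",
                          sti_chlamydia_12m = "0")
  partners <- make_record(prep_status = "never", sdu_6m = "no",
                          n_partners_6m_category = "1",
                          sti_chlamydia_12m = "1")
  both <- make_record(prep_status = "never", sdu_6m = "yes",
                      n_partners_6m_category = "1",
                      sti_gonorrhea_12m = "1", sti_chlamydia_12m = "0")
  expect_equal(classify_subgroup(sdu_only), "sdu_only")
  expect_equal(classify_subgroup(partners), "partners_sti_hcv")
  expect_equal(classify_subgroup(both), "both")
  none <- make_record(prep_status = "never", sdu_6m = "no",
                      n_partners_6m_category = "0", sti_chlamydia_12m = "0")
  expect_error(classify_subgroup(none), "without indication")
})

test_that("empty input yields an empty cohort with a zeroed ledger", {
  cohort <- apply_selection_flow(make_record()[0, ])
  expect_equal(nrow(cohort$records), 0)
  expect_true(all(cohort$ledger$n_before == 0))
  expect_true(all(cohort$ledger$n_after == 0))
})

test_that("the flow removes records at the matching steps", {
  rec <- make_records(
    make_record(prep_status = "former"),
    make_record(prep_status = "never",
                hiv_status_confirmed_negative = "FALSE", sdu_6m = "yes"),
    make_record(prep_status = "current")  # eligible via chlamydia diagnosis
  )
  cohort <- apply_selection_flow(rec)
  expect_equal(nrow(cohort$records), 1)
  expect_equal(cohort$records$role, "prep_user")
  led <- cohort$ledger
  expect_equal(led$n_removed[led$filter_name == "prep_status_known_not_former"], 1)
  expect_equal(led$n_removed[led$filter_name == "nonuser_hiv_negative_confirmed"], 1)
  expect_equal(led$n_after[nrow(led)], 1)
  # ledger bookkeeping holds at every step
  expect_equal(led$n_after, led$n_before - led$n_removed)
  expect_equal(led$n_before[-1], led$n_after[-nrow(led)])
})

test_that("with all-pass settings no record is removed", {
  cfg <- all_pass_config(400, seed = 6)
  rec <- generate_cohort(cfg)
  cohort <- apply_selection_flow(rec)
  expect_equal(cohort$ledger$n_after[nrow(cohort$ledger)], 400)
})

test_that("the filters are conjunctive: the final cohort is order-free", {
  cfg <- cohort_config(600, seed = 8)
  rec <- inject_missingness(generate_cohort(cfg), cfg$missing_rate, cfg$seed)
  cohort <- apply_selection_flow(rec)
  # independent route: evaluate every record-level predicate directly
  role <- ifelse(rec$prep_status == "current", "prep_user", "prep_non_user")
  ind <- logical(nrow(rec))
  for (rl in c("prep_user", "prep_non_user")) {
    sel <- role == rl
    ind[sel] <- has_indication(rec[sel, , drop = FALSE], rl)
  }
  keep <- rec$survey_completed == "TRUE" &
    rec$gender_identity == "male" & rec$sex_assigned_at_birth == "male" &
    rec$prep_status %in% c("current", "never") &
    rec$prior_wave_participation == "FALSE" &
    (rec$prep_status == "current" | rec$hiv_status_confirmed_negative == "TRUE") &
    ind
  expect_setequal(cohort$records$participant_id, rec$participant_id[keep])
})

test_that("adding a record never decreases any post-filter count", {
  cfg <- cohort_config(200, seed = 10)
  rec <- generate_cohort(cfg)
  small <- apply_selection_flow(rec)$ledger
  extra <- make_record(participant_id = 9999L)
  grown <- apply_selection_flow(rbind(rec[names(extra)], extra))$ledger
  expect_true(all(grown$n_after >= small$n_after))
})

test_that("subgroups partition the retained non-users", {
  cfg <- cohort_config(1500, seed = 12)
  rec <- inject_missingness(generate_cohort(cfg), cfg$missing_rate, cfg$seed)
  cohort <- apply_selection_flow(rec)
  nonusers <- cohort$records[cohort$records$role == "prep_non_user", ]
  expect_gt(nrow(nonusers), 0)
  tab <- table(factor(nonusers$indication_subgroup,
                      levels = c("both", "partners_sti_hcv", "sdu_only")))
  expect_equal(sum(tab), nrow(nonusers))
  expect_false(any(is.na(nonusers$indication_subgroup)))
})
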