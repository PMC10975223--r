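test_that("starting-dose rule follows the risk-stratified algorithm", {
  expect_equal(recommend_starting_dose(
    patient_state("high", "none_detected", "MR3",
                  switch_reason = "resistance"))$action, "start_15")
  expect_equal(recommend_starting_dose(
    patient_state("very_high", current_mr = "MR2"))$action, "start_30")
  expect_equal(recommend_starting_dose(
    patient_state("low", "T315I", "BELOW_MR2",
                  switch_reason = "resistance"))$action, "start_45")
  expect_equal(recommend_starting_dose(
    patient_state("moderate", "none_detected", "MR2",
                  switch_reason = "intolerance"))$action, "start_30")
  # DMR counts as at least MR3
  expect_equal(recommend_starting_dose(
    patient_state("high", current_mr = "DMR"))$action, "start_15")
  # T315I at high risk: capped at 30 with a warning flag by default
  rec <- recommend_starting_dose(patient_state("very_high", "T315I", "MR2"))
  expect_equal(rec$action, "start_30")
  expect_true(length(rec$flags) > 0)
  expect_equal(recommend_starting_dose(
    patient_state("very_high", "T315I", "MR2"),
    allow_45_high_risk_mutation = TRUE)$action, "start_45")
  # missing risk: never a guess
  rec_na <- recommend_starting_dose(patient_state(NA))
  expect_equal(rec_na$action, "insufficient_information")
  expect_error(recommend_starting_dose(
    patient_state("low", current_dose_mg = 30)), "no ponatinib dose")
})

test_that("adjustment rule fires in the documented order", {
  expect_equal(recommend_adjustment(
    patient_state("high", "none_detected", "MR3", 6, 30, 12.0, 0))$action,
    "reduce_to_15")
  expect_true(recommend_adjustment(
    patient_state("high", "none_detected", "MR3", 6, 30, 12.0, 0))$strict_molecular_monitoring)
  expect_equal(recommend_adjustment(
    patient_state("low", "none_detected", "MR3", 8, 30, 15.0, 0))$action,
    "reduce_to_15")
  # no plasma level: reduction rules disabled
  expect_equal(recommend_adjustment(
    patient_state("low", "none_detected", "MR3", 8, 30, NA, 0))$action,
    "maintain")
  # grade >= 3 adverse event dominates everything
  rec <- recommend_adjustment(
    patient_state("low", "T315I", "DMR", 12, 45, 50, 3))
  expect_equal(rec$action, "interrupt_then_restart_reduced")
  expect_equal(rec$restart_dose_mg, 30)
  expect_equal(recommend_adjustment(
    patient_state("high", worst_active_ae_grade = 4,
                  current_dose_mg = 15))$restart_dose_mg, 15)
  # threshold is strict: a trough exactly at 10.7 does not trigger reduction
  expect_equal(recommend_adjustment(
    patient_state("low", "none_detected", "MR3", 8, 30, 10.7, 0))$action,
    "maintain")
  # low trough on 15 mg: maintained, flagged, no invented escalation
  rec15 <- recommend_adjustment(
    patient_state("low", "none_detected", "MR3", 8, 15, 8.0, 0))
  expect_equal(rec15$action, "maintain")
  expect_true("below_threshold_no_escalation_rule" %in% rec15$flags)
  expect_error(recommend_adjustment(patient_state("low")), "active dose")
})

starting_lattice <- function() {
  expand.grid(cv_risk = c("low", "moderate", "high", "very_high"),
              mutation = c("none_detected", "T315I", "compound"),
              current_mr = MR_BANDS, stringsAsFactors = FALSE)
}

test_that("starting rule is total, deterministic and risk-monotone over the lattice", {
  lat <- starting_lattice()
  expect_equal(nrow(lat), 48)
  act <- function(row) recommend_starting_dose(
    patient_state(row$cv_risk, row$mutation, row$current_mr))$action
  a1 <- vapply(seq_len(nrow(lat)), function(i) act(lat[i, ]), character(1))
  a2 <- vapply(seq_len(nrow(lat)), function(i) act(lat[i, ]), character(1))
  expect_identical(a1, a2)
  expect_false(any(a1 == "insufficient_information"))
  # higher risk never yields a higher starting dose, all else fixed
  dose_of <- c(start_15 = 15, start_30 = 30, start_45 = 45)
  risk_rank <- c(low = 1, moderate = 2, high = 3, very_high = 4)
  for (mut in unique(lat$mutation)) for (mr in unique(lat$current_mr)) {
    sel <- lat$mutation == mut & lat$current_mr == mr
    ord <- order(risk_rank[lat$cv_risk[sel]])
    expect_true(all(diff(dose_of[a1[sel][ord]]) <= 0))
  }
})

test_that("adjustment rule is total and deterministic over the categorical lattice", {
  lat <- expand.grid(cv_risk = c("low", "moderate", "high", "very_high"),
                     current_mr = MR_BANDS, dose = c("45", "30", "15"),
                     cmin = c(10.69, 10.7, 10.71), months = c(0, 6),
                     grade = c(0L, 3L), stringsAsFactors = FALSE)
  act <- function(row) recommend_adjustment(
    patient_state(row$cv_risk, current_mr = row$current_mr,
                  months_on_current_dose = row$months,
                  current_dose_mg = row$dose, cmin_ng_per_ml = row$cmin,
                  worst_active_ae_grade = row$grade))
  recs <- lapply(seq_len(nrow(lat)), function(i) act(lat[i, ]))
  acts <- vapply(recs, `[[`, character(1), "action")
  expect_true(all(acts %in% c("maintain", "reduce_to_15",
                              "interrupt_then_restart_reduced")))
  acts2 <- vapply(seq_len(nrow(lat)), function(i) act(lat[i, ])$action,
                  character(1))
  expect_identical(acts, acts2)
  # boundary behavior: strictly above 10.7 required
  red <- acts == "reduce_to_15"
  expect_true(all(lat$cmin[red] > 10.7))
})

# The rationale trace must suffice to re-derive the action: the final rule id
# determines it uniquely.
rule_to_action <- c(
  cv_risk_missing = "insufficient_information",
  high_risk_mutation_dose_capped_at_30 = "start_30",
  mutation_requires_full_dose = "start_45",
  mr_at_least_mr3 = "start_15", mr_below_mr3 = "start_30",
  low_moderate_risk_default_30 = "start_30",
  interrupt_until_recovery = "interrupt_then_restart_reduced",
  six_months_on_30_with_mr3_and_level = "reduce_to_15",
  low_moderate_risk_mr3_and_level = "reduce_to_15",
  no_reduction_rule_fired = "maintain")

test_that("the rationale trace alone re-derives the action", {
  lat <- starting_lattice()
  for (i in seq_len(nrow(lat))) {
    rec <- recommend_starting_dose(
      patient_state(lat$cv_risk[i], lat$mutation[i], lat$current_mr[i]))
    expect_equal(unname(rule_to_action[rec$rationale[length(rec$rationale)]]),
                 rec$action)
  }
  adj_cases <- list(
    patient_state("high", "none_detected", "MR3", 6, 30, 12, 0),
    patient_state("low", "none_detected", "DMR", 2, 45, 20, 0),
    patient_state("low", "none_detected", "MR3", 8, 30, NA, 0),
    patient_state("high", "compound", "MR2", 1, 45, 5, 4))
  for (st in adj_cases) {
    rec <- recommend_adjustment(st)
    expect_equal(unname(rule_to_action[rec$rationale[length(rec$rationale)]]),
                 rec$action)
  }
})

test_that("cohort policy evaluation is row-wise, tallied, and error-collecting", {
  empty <- evaluate_policy_on_cohort(data.frame(cv_risk = character(0)))
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "summary")), 0)
  lat <- starting_lattice()
  lat$current_dose_mg <- "none"
  res <- evaluate_policy_on_cohort(lat)
  expect_equal(nrow(res), 48)
  expect_false(any(res$action == "insufficient_information"))
  expect_equal(sum(attr(res, "summary")), 48)
  # invalid rows are reported, not dropped
  bad <- lat[1:3, ]
  bad$cv_risk[2] <- "galactic"
  res2 <- evaluate_policy_on_cohort(bad)
  expect_equal(length(attr(res2, "errors")), 1)
  expect_true(is.na(res2$action[2]))
  expect_false(anyNA(res2$action[c(1, 3)]))
})
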