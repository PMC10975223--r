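CV_RISK_LEVELS <- c("low", "moderate", "high", "very_high")
MUTATION_LEVELS <- c("none_detected", "T315I", "compound")
DOSE_LEVELS <- c("45", "30", "15", "interrupted", "none")

#' Patient state for the dose-recommendation engine
#'
#' @param cv_risk cardiovascular risk category from SCORE2 / SCORE2-OP (or
#'   equivalent), one of `low`, `moderate`, `high`, `very_high`; `NA` if not
#'   assessed (the engine then refuses to guess a starting dose).
#' @param mutation BCR-ABL1 kinase-domain mutation status: `none_detected`,
#'   `T315I`, or `compound`.
#' @param current_mr current molecular-response band (see [MR_BANDS]).
#' @param months_on_current_dose months at the current dose (>= 0).
#' @param current_dose_mg one of `45`, `30`, `15`, `"interrupted"`, `"none"`.
#' @param cmin_ng_per_ml predicted steady-state trough, ng/mL, or `NA` when
#'   no plasma level is available.
#' @param worst_active_ae_grade worst active adverse-event grade (CTCAE 0-5).
#' @param switch_reason why ponatinib was (or is being) chosen:
#'   `"resistance"` or `"intolerance"`.
#' @return object of class `patient_state`.
#' @export
patient_state <- function(cv_risk = NA_character_,
                          mutation = "none_detected",
                          current_mr = "BELOW_MR2",
                          months_on_current_dose = 0,
                          current_dose_mg = "none",
                          cmin_ng_per_ml = NA_real_,
                          worst_active_ae_grade = 0L,
                          switch_reason = NA_character_) {
  if (!is.na(cv_risk)) cv_risk <- match.arg(cv_risk, CV_RISK_LEVELS)
  mutation <- match.arg(mutation, MUTATION_LEVELS)
  current_mr <- match.arg(as.character(current_mr), MR_BANDS)
  dose <- as.character(current_dose_mg)
  if (!dose %in% DOSE_LEVELS)
    stop("current_dose_mg must be one of: ", paste(DOSE_LEVELS, collapse = ", "),
         call. = FALSE)
  if (!(is.numeric(months_on_current_dose) && months_on_current_dose >= 0))
    stop("months_on_current_dose must be >= 0", call. = FALSE)
  if (!(worst_active_ae_grade %in% 0:5))
    stop("worst_active_ae_grade must be an integer in [0, 5]", call. = FALSE)
  if (!is.na(cmin_ng_per_ml) &&
      !(is.finite(cmin_ng_per_ml) && cmin_ng_per_ml >= 0))
    stop("cmin_ng_per_ml must be non-negative when present", call. = FALSE)
  if (!is.na(switch_reason))
    switch_reason <- match.arg(switch_reason, c("resistance", "intolerance"))
  structure(list(cv_risk = cv_risk, mutation = mutation,
                 current_mr = current_mr,
                 months_on_current_dose = months_on_current_dose,
                 current_dose_mg = dose, cmin_ng_per_ml = cmin_ng_per_ml,
                 worst_active_ae_grade = as.integer(worst_active_ae_grade),
                 switch_reason = switch_reason),
            class = "patient_state")
}

new_recommendation <- function(action, rationale, strict_monitoring = FALSE,
                               flags = character(), restart_dose_mg = NA_real_) {
  stopifnot(action %in% c("start_15", "start_30", "start_45", "reduce_to_15",
                          "maintain", "interrupt_then_restart_reduced",
                          "insufficient_information"))
  if (action != "insufficient_information" && length(rationale) == 0)
    stop("rationale must be non-empty", call. = FALSE)
  structure(list(action = action,
                 strict_molecular_monitoring = strict_monitoring,
                 rationale = rationale, flags = flags,
                 restart_dose_mg = restart_dose_mg),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat("Recommendation:", x$action,
      if (isTRUE(x$strict_molecular_monitoring)) "(strict molecular monitoring)",
      "\n")
  if (!is.na(x$restart_dose_mg))
    cat("  restart dose:", x$restart_dose_mg, "mg/day\n")
  cat("  rationale:", paste(x$rationale, collapse = " -> "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Recommend a ponatinib starting dose
#'
#' Cardiovascular-risk-stratified starting rule: high / very-high-risk
#' patients start at 15 mg/day when the molecular response is at least MR3
#' and at 30 mg/day otherwise; low / moderate-risk patients start at
#' 30 mg/day, or 45 mg/day with a demonstrated T315I or compound mutation.
#' A T315I/compound mutation in a high-risk patient is capped at 30 mg/day
#' with a warning flag by default (`allow_45_high_risk_mutation` lifts the
#' cap). A missing risk category yields `insufficient_information`, never a
#' guess. The rationale trace lists every condition evaluated, in order.
#'
#' @param state [patient_state()] with `current_dose_mg = "none"`.
#' @param cmin_threshold not used by the starting rule; kept for signature
#'   symmetry with [recommend_adjustment()].
#' @param allow_45_high_risk_mutation allow 45 mg/day for T315I/compound in
#'   high or very-high risk.
#' @return [dose_recommendation][recommend_adjustment] object.
#' @examples
#' recommend_starting_dose(patient_state("high", current_mr = "MR3"))
#' @export
recommend_starting_dose <- function(state, cmin_threshold = 10.7,
                                    allow_45_high_risk_mutation = FALSE) {
  stopifnot(inherits(state, "patient_state"))
  if (state$current_dose_mg != "none")
    stop("starting rule applies only when no ponatinib dose is active",
         call. = FALSE)
  if (is.na(state$cv_risk))
    return(new_recommendation("insufficient_information",
                              "cv_risk_missing",
                              flags = "cardiovascular_risk_not_assessed"))
  trace <- sprintf("cv_risk_%s", state$cv_risk)
  mutated <- state$mutation %in% c("T315I", "compound")
  trace <- c(trace, sprintf("mutation_%s", state$mutation))
  if (state$cv_risk %in% c("high", "very_high")) {
    if (mutated && !allow_45_high_risk_mutation)
      return(new_recommendation("start_30",
                                c(trace, "high_risk_mutation_dose_capped_at_30"),
                                flags = "t315i_exposure_vs_vascular_risk_tradeoff"))
    if (mutated && allow_45_high_risk_mutation)
      return(new_recommendation("start_45", c(trace, "mutation_requires_full_dose")))
    mr_ok <- mr_at_least(state$current_mr, "MR3")
    trace <- c(trace, if (mr_ok) "mr_at_least_mr3" else "mr_below_mr3")
    return(new_recommendation(if (mr_ok) "start_15" else "start_30", trace))
  }
  if (mutated)
    return(new_recommendation("start_45", c(trace, "mutation_requires_full_dose")))
  new_recommendation("start_30", c(trace, "low_moderate_risk_default_30"))
}

#' Recommend a dose adjustment on treatment
#'
#' First-match rule order:
#' 1. an active adverse event of grade >= 3 interrupts treatment with restart
#'    one step down the 45 -> 30 -> 15 mg ladder;
#' 2. on 30 mg/day for >= 6 months with at least MR3 and a trough strictly
#'    above `cmin_threshold` (10.7 ng/mL), reduce to 15 mg/day with strict
#'    molecular monitoring;
#' 3. at low/moderate cardiovascular risk on 45 or 30 mg/day with at least
#'    MR3 and a trough strictly above the threshold, reduce to 15 mg/day;
#' 4. otherwise maintain.
#' Rules 2-3 require a plasma level: an absent trough disables them. A
#' patient on 15 mg/day with a trough at or below the threshold is maintained
#' with a `below_threshold_no_escalation_rule` flag (no escalation rule is
#' defined).
#'
#' @param state [patient_state()] with an active numeric dose.
#' @param cmin_threshold trough threshold, ng/mL (strict `>`, as the decision
#'   rule is stated; classification banding elsewhere is inclusive).
#' @return `dose_recommendation` object: `action`, logical
#'   `strict_molecular_monitoring`, `rationale` (ordered fired-rule trace),
#'   `flags`, and `restart_dose_mg` for interruptions.
#' @examples
#' recommend_adjustment(patient_state("high", current_mr = "MR3",
#'   months_on_current_dose = 6, current_dose_mg = 30, cmin_ng_per_ml = 12))
#' @export
recommend_adjustment <- function(state, cmin_threshold = 10.7) {
  stopifnot(inherits(state, "patient_state"))
  if (!state$current_dose_mg %in% c("45", "30", "15"))
    stop("adjustment rule needs an active dose of 45, 30 or 15 mg/day",
         call. = FALSE)
  dose <- as.numeric(state$current_dose_mg)
  if (state$worst_active_ae_grade >= 3) {
    restart <- c("45" = 30, "30" = 15, "15" = 15)[[state$current_dose_mg]]
    return(new_recommendation("interrupt_then_restart_reduced",
                              c(sprintf("ae_grade_%d_ge_3",
                                        state$worst_active_ae_grade),
                                "interrupt_until_recovery"),
                              restart_dose_mg = restart))
  }
  have_cmin <- !is.na(state$cmin_ng_per_ml)
  cmin_ok <- have_cmin && state$cmin_ng_per_ml > cmin_threshold
  mr_ok <- mr_at_least(state$current_mr, "MR3")
  trace <- c(sprintf("dose_%s", state$current_dose_mg),
             if (mr_ok) "mr_at_least_mr3" else "mr_below_mr3",
             if (!have_cmin) "cmin_unavailable"
             else if (cmin_ok) "cmin_above_threshold" else "cmin_at_or_below_threshold")
  if (dose == 30 && state$months_on_current_dose >= 6 && mr_ok && cmin_ok)
    return(new_recommendation("reduce_to_15",
                              c(trace, "six_months_on_30_with_mr3_and_level"),
                              strict_monitoring = TRUE))
  if (!is.na(state$cv_risk) && state$cv_risk %in% c("low", "moderate") &&
      dose %in% c(45, 30) && mr_ok && cmin_ok)
    return(new_recommendation("reduce_to_15",
                              c(trace, "low_moderate_risk_mr3_and_level")))
  flags <- character()
  if (dose == 15 && have_cmin && !cmin_ok)
    flags <- "below_threshold_no_escalation_rule"
  new_recommendation("maintain", c(trace, "no_reduction_rule_fired"),
                     flags = flags)
}

#' Apply the recommendation rules to a cohort table
#'
#' Each row is converted to a [patient_state()]; rows with
#' `current_dose_mg == "none"` go through [recommend_starting_dose()], rows
#' with an active dose through [recommend_adjustment()]. Row-level validation
#' failures are collected (attribute `"errors"`), not silently dropped.
#'
#' @param states data.frame whose columns match the [patient_state()]
#'   arguments (missing columns take the defaults).
#' @param cmin_threshold trough threshold for the adjustment rule, ng/mL.
#' @return data.frame with `action`, `strict_molecular_monitoring`,
#'   `rationale` (rule ids joined by `;`), `flags`, `restart_dose_mg`;
#'   attribute `"summary"` holds the action frequency table and attribute
#'   `"errors"` any per-row failures.
#' @export
evaluate_policy_on_cohort <- function(states, cmin_threshold = 10.7) {
  stopifnot(is.data.frame(states))
  n <- nrow(states)
  out <- data.frame(action = character(n),
                    strict_molecular_monitoring = logical(n),
                    rationale = character(n), flags = character(n),
                    restart_dose_mg = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  errors <- list()
  arg_names <- names(formals(patient_state))
  for (i in seq_len(n)) {
    rec <- tryCatch({
      args <- as.list(states[i, intersect(names(states), arg_names),
                             drop = FALSE])
      st <- do.call(patient_state, args)
      if (st$current_dose_mg == "none")
        recommend_starting_dose(st, cmin_threshold)
      else recommend_adjustment(st, cmin_threshold)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <- list(row = i, message = conditionMessage(rec))
      out$action[i] <- NA_character_
      next
    }
    out$action[i] <- rec$action
    out$strict_molecular_monitoring[i] <- rec$strict_molecular_monitoring
    out$rationale[i] <- paste(rec$rationale, collapse = ";")
    out$flags[i] <- paste(rec$flags, collapse = ";")
    out$restart_dose_mg[i] <- rec$restart_dose_mg
  }
  attr(out, "summary") <- table(factor(out$action[!is.na(out$action)]))
  attr(out, "errors") <- errors
  out
}
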