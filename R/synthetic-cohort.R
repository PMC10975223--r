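#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the sampling design of a real-world ponatinib TDM
#' cohort: ~32 patients contributing ~38 dose-occasions across 45/30/15
#' mg/day, log-normal between-subject PK variability, one random-time plasma
#' sample per occasion with combined residual assay error and an LLOQ of
#' 5 ng/mL, molecular-response outcomes from a logistic model on log trough
#' (slope 0 by default — no dose/exposure-response association, mirroring a
#' null association), and Poisson adverse-event counts per occasion.
#'
#' @param n_patients number of patients.
#' @param dose_probs allocation probabilities over 45/30/15 mg/day (named,
#'   must sum to 1); default 9/38, 17/38, 12/38.
#' @param prior [population_prior()] generating true individual parameters
#'   and residual error.
#' @param sampling_time_range range (h) of the uniform random sampling time
#'   within the dosing interval.
#' @param repeat_prob probability that a patient contributes a second
#'   dose-occasion (redrawn dose, same individual PK); 6/32 by default so the
#'   expected occasion count matches 38.
#' @param mr3_intercept,mr3_slope logistic model for P(at least MR3):
#'   `plogis(intercept + slope * log(true C_min))`. The default slope is 0
#'   and the intercept matches an overall MR3 rate of 25/38.
#' @param dmr_intercept,dmr_slope logistic model for P(DMR | at least MR3);
#'   default slope 0, intercept matching 15/25.
#' @param ae_rate named expected number of adverse events per occasion at
#'   each dose; defaults 7/9, 4/17, 2/12.
#' @param ae_p_hematological probability an event is hematological (5/13).
#' @param ae_p_grade3plus probability an event is grade >= 3 (6/13).
#' @param lloq assay lower limit of quantitation, ng/mL.
#' @param calibration_target_cmin_45 expected mean steady-state trough at
#'   45 mg/day implied by the defaults (ng/mL); carried in the configuration
#'   so calibration checks are self-describing.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 32L,
                          dose_probs = c("45" = 9, "30" = 17, "15" = 12) / 38,
                          prior = population_prior(),
                          sampling_time_range = c(0, 24),
                          repeat_prob = 6 / 32,
                          mr3_intercept = stats::qlogis(25 / 38),
                          mr3_slope = 0,
                          dmr_intercept = stats::qlogis(15 / 25),
                          dmr_slope = 0,
                          ae_rate = c("45" = 7 / 9, "30" = 4 / 17, "15" = 2 / 12),
                          ae_p_hematological = 5 / 13,
                          ae_p_grade3plus = 6 / 13,
                          lloq = 5,
                          calibration_target_cmin_45 = 41.99) {
  problems <- character()
  if (!(is.numeric(n_patients) && n_patients >= 1))
    problems <- c(problems, "n_patients must be >= 1")
  if (is.null(names(dose_probs)) ||
      !setequal(names(dose_probs), c("45", "30", "15")))
    problems <- c(problems, "dose_probs must be named over 45/30/15")
  else if (any(dose_probs < 0) || abs(sum(dose_probs) - 1) > 1e-8)
    problems <- c(problems, "dose_probs must be non-negative and sum to 1")
  if (!inherits(prior, "population_prior"))
    problems <- c(problems, "prior must be a population_prior")
  if (!(length(sampling_time_range) == 2 && sampling_time_range[1] >= 0 &&
        diff(sampling_time_range) > 0))
    problems <- c(problems, "sampling_time_range must be an increasing pair >= 0")
  if (!(repeat_prob >= 0 && repeat_prob <= 1))
    problems <- c(problems, "repeat_prob must be in [0, 1]")
  for (p in c(ae_p_hematological, ae_p_grade3plus))
    if (!(p >= 0 && p <= 1))
      problems <- c(problems, "AE probabilities must be in [0, 1]")
  if (any(ae_rate < 0)) problems <- c(problems, "ae_rate must be >= 0")
  if (length(problems))
    stop("invalid cohort configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 dose_probs = dose_probs[c("45", "30", "15")], prior = prior,
                 sampling_time_range = sampling_time_range,
                 repeat_prob = repeat_prob,
                 mr3_intercept = mr3_intercept, mr3_slope = mr3_slope,
                 dmr_intercept = dmr_intercept, dmr_slope = dmr_slope,
                 ae_rate = ae_rate, ae_p_hematological = ae_p_hematological,
                 ae_p_grade3plus = ae_p_grade3plus, lloq = lloq,
                 calibration_target_cmin_45 = calibration_target_cmin_45),
            class = "cohort_config")
}

draw_eta <- function(omega) {
  k <- ncol(omega)
  if (k == 0L) return(stats::setNames(numeric(0), character(0)))
  L <- chol(omega + diag(1e-12, k))
  stats::setNames(drop(stats::rnorm(k) %*% L), colnames(omega))
}

draw_is_percent <- function(band) {
  # log-uniform within the band's IS% range
  rng <- switch(band,
                DMR = c(0.001, 0.01), MR3 = c(0.011, 0.1),
                MR2 = c(0.11, 1), BELOW_MR2 = c(1.1, 50))
  exp(stats::runif(1, log(rng[1]), log(rng[2])))
}

#' Generate a stochastic synthetic cohort of dose-occasions
#'
#' Per patient: a dose is drawn, individual parameters are
#' `theta * exp(eta)` with `eta` from the prior's log-scale covariance, the
#' true steady-state trough is simulated from the PK model, a random-time
#' sample within the dosing interval receives combined residual error and
#' LLOQ flagging, and molecular-response and adverse-event outcomes are drawn
#' from the configured models. Fully reproducible from `seed`.
#'
#' @param config [cohort_config()].
#' @param seed integer seed.
#' @param predict also compute the MAP-predicted trough from the single
#'   sample for every occasion (slower; runs [predict_cmin_from_single_sample()]
#'   per row).
#' @return data.frame of assessments with columns `patient_id, dose_mg,
#'   t_since_dose_h, measured_conc, below_loq, true_cmin, predicted_cmin,
#'   is_percent, mr_band, ae_n_events, ae_grade, ae_category`.
#' @examples
#' head(generate_cohort(cohort_config(n_patients = 4), seed = 1))
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            predict = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  local_rng(seed, function() {
    prior <- config$prior
    rows <- list()
    for (pid in seq_len(config$n_patients)) {
      eta <- draw_eta(prior$omega)
      params <- apply_eta(prior$theta, eta)
      n_occ <- 1L + stats::rbinom(1, 1, config$repeat_prob)
      for (occ in seq_len(n_occ)) {
        dose <- as.numeric(sample(names(config$dose_probs), 1,
                                  prob = config$dose_probs))
        reg <- dosing_regimen(dose, 24)
        true_cmin <- steady_state_cmin(params, reg, max_doses = 1000L)
        t_s <- stats::runif(1, config$sampling_time_range[1],
                            min(config$sampling_time_range[2], reg$tau_h))
        f <- concentration_at(params, reg, t_s, max_doses = 1000L)
        meas <- max(0, f + stats::rnorm(1, 0, prior$sigma_add +
                                             prior$sigma_prop * f))
        p_mr3 <- stats::plogis(config$mr3_intercept +
                               config$mr3_slope * log(max(true_cmin, 1e-6)))
        mr3 <- stats::runif(1) < p_mr3
        band <- if (!mr3) "MR2" else {
          p_dmr <- stats::plogis(config$dmr_intercept +
                                 config$dmr_slope * log(max(true_cmin, 1e-6)))
          if (stats::runif(1) < p_dmr) "DMR" else "MR3"
        }
        n_ev <- stats::rpois(1, config$ae_rate[[as.character(dose)]])
        grades <- if (n_ev) ifelse(stats::runif(n_ev) < config$ae_p_grade3plus,
                                   3L, sample(1:2, n_ev, replace = TRUE)) else integer()
        cats <- if (n_ev) ifelse(stats::runif(n_ev) < config$ae_p_hematological,
                                 "hematological", "extra_hematological") else character()
        worst <- if (n_ev) max(grades) else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("S%03d", pid), dose_mg = dose,
          t_since_dose_h = t_s, measured_conc = meas,
          below_loq = meas < config$lloq, true_cmin = true_cmin,
          predicted_cmin = NA_real_,
          is_percent = draw_is_percent(band), mr_band = band,
          ae_n_events = n_ev, ae_grade = worst,
          ae_category = if (n_ev) cats[which.max(grades)] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, rows)
    d$mr_band <- factor(d$mr_band, levels = MR_BANDS, ordered = TRUE)
    if (predict) {
      d$predicted_cmin <- vapply(seq_len(nrow(d)), function(i) {
        s <- concentration_samples(d$t_since_dose_h[i], d$measured_conc[i],
                                   dose_mg = d$dose_mg[i], lloq = config$lloq)
        predict_cmin_from_single_sample(s, prior, lloq = config$lloq)
      }, numeric(1))
    }
    rownames(d) <- NULL
    d
  })
}

# Enumerate 3x3 tables with fixed row and column sums, in lexicographic
# (row-major) order of the flattened cell vector.
enum_3x3 <- function(rs, cs) {
  out <- list()
  for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[1] - a, cs[2])) {
    c3 <- rs[1] - a - b
    if (c3 < 0 || c3 > cs[3]) next
    for (d in 0:min(rs[2], cs[1] - a)) for (e in 0:min(rs[2] - d, cs[2] - b)) {
      f <- rs[2] - d - e
      if (f < 0 || f > cs[3] - c3) next
      g <- cs[1] - a - d; h <- cs[2] - b - e; i <- cs[3] - c3 - f
      if (g < 0 || h < 0 || i < 0 || g + h + i != rs[3]) next
      out[[length(out) + 1L]] <- matrix(c(a, b, c3, d, e, f, g, h, i),
                                        3, 3, byrow = TRUE)
    }
  }
  out
}

lex_less <- function(v, w) {
  i <- which(v != w)[1]
  !is.na(i) && v[i] < w[i]
}

# The published marginal and cross counts the fixture must reproduce.
fixture_constraints <- function() {
  list(
    dose_n = c("45" = 9, "30" = 17, "15" = 12),
    # per dose: occasions in trough band (<10.7, [10.7, 21.3), >=21.3)
    band = list("45" = c(1, 4, 4), "30" = c(3, 8, 6), "15" = c(7, 5, 0)),
    # per dose: occasions by response (<MR3, MR3 not DMR, DMR)
    mr = list("45" = c(6, 1, 2), "30" = c(5, 6, 6), "15" = c(2, 3, 7)),
    # global band x response cross table (rows: <10.7, mid, >=21.3)
    global = matrix(c(2, 4, 5,
                      7, 5, 5,
                      4, 1, 5), 3, 3, byrow = TRUE,
                    dimnames = list(c("lt10.7", "mid", "ge21.3"),
                                    c("below_mr3", "mr3_only", "dmr"))))
}

#' Deterministic counts-matched fixture (38 dose-occasions)
#'
#' Constructs a 38-row assessment table that simultaneously reproduces the
#' published per-dose group sizes (9/17/12 at 45/30/15 mg/day), per-dose
#' attainment of the 10.7 ng/mL (8/14/5) and 21.3 ng/mL (4/6/0) trough
#' thresholds, per-dose MR3 (3/12/10) and DMR (2/6/7) counts, and all
#' threshold-by-response cross counts (16/27 and 9/11 MR3, 10/27 and 5/11 DMR
#' at 10.7 ng/mL; 6/10 MR3, 5/10 DMR at 21.3 ng/mL), plus the adverse-event
#' tally (13 events in 9 patients, 7/4/2 by dose, 5 hematological and 8
#' extra-hematological, 6 of grade >= 3).
#'
#' The three-way dose x trough-band x response allocation is under-determined
#' by these margins; an exhaustive integer-feasibility search selects the
#' lexicographically smallest feasible allocation, so the fixture is unique
#' and stable. If the constraints were jointly infeasible the search would
#' fail loudly. Trough values are placed at band midpoints (5.35, 16.0 and
#' 25.0 ng/mL for the open top band) and IS% at band-representative values
#' (0.5 / 0.05 / 0.005); downstream statistics depend only on band
#' membership.
#'
#' @return data.frame of 38 assessments (same schema as [generate_cohort()]),
#'   with the adverse-event event list as attribute `"ae_events"`.
#' @examples
#' fx <- counts_matched_fixture()
#' table(fx$dose_mg)
#' @export
counts_matched_fixture <- function() {
  cn <- fixture_constraints()
  t45 <- enum_3x3(cn$band[["45"]], cn$mr[["45"]])
  t30 <- enum_3x3(cn$band[["30"]], cn$mr[["30"]])
  best <- NULL
  for (A in t45) for (B in t30) {
    C <- cn$global - A - B
    if (any(C < 0)) next
    if (!all(rowSums(C) == cn$band[["15"]]) ||
        !all(colSums(C) == cn$mr[["15"]])) next
    v <- c(t(A), t(B), t(C))
    if (is.null(best) || lex_less(v, best$v))
      best <- list(v = v, alloc = list("45" = A, "30" = B, "15" = C))
  }
  if (is.null(best))
    stop("published marginal and cross counts are jointly infeasible; ",
         "violated constraint set: per-dose band/MR margins vs global ",
         "band x MR cross table", call. = FALSE)
  cmin_vals <- c(5.35, 16.0, 25.0)            # band midpoints, top band 25.0
  is_vals <- c(0.5, 0.05, 0.005)              # MR2 / MR3 / DMR representatives
  band_names <- c("MR2", "MR3", "DMR")
  rows <- list()
  pid <- 0L
  for (dose in c("45", "30", "15")) {
    M <- best$alloc[[dose]]
    for (b in 1:3) for (m in 1:3) {
      k <- M[b, m]
      if (k == 0) next
      for (j in seq_len(k)) {
        pid <- pid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("F%02d", pid), dose_mg = as.numeric(dose),
          t_since_dose_h = 24, measured_conc = cmin_vals[b],
          below_loq = FALSE, true_cmin = cmin_vals[b],
          predicted_cmin = cmin_vals[b], is_percent = is_vals[m],
          mr_band = band_names[m], ae_n_events = 0L, ae_grade = 0L,
          ae_category = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  d <- do.call(rbind, rows)
  d$mr_band <- factor(d$mr_band, levels = MR_BANDS, ordered = TRUE)
  # 13 adverse events in 9 patients: 7/4/2 events by dose carried by 3/4/2
  # patients; the first 5 events are hematological, the rest
  # extra-hematological; the first 6 are grade 3, the rest grade 2.
  ev_dose <- rep(c("45", "30", "15"), times = c(7, 4, 2))
  carriers <- c(rep(1:3, length.out = 7),        # within-dose patient index
                rep(1:4, length.out = 4), rep(1:2, length.out = 2))
  events <- data.frame(dose_mg = as.numeric(ev_dose), carrier = carriers,
                       category = rep(c("hematological", "extra_hematological"),
                                      times = c(5, 8)),
                       grade = rep(c(3L, 2L), times = c(6, 7)),
                       stringsAsFactors = FALSE)
  events$patient_id <- vapply(seq_len(nrow(events)), function(i) {
    ids <- d$patient_id[d$dose_mg == events$dose_mg[i]]
    ids[events$carrier[i]]
  }, character(1))
  events$carrier <- NULL
  for (p in unique(events$patient_id)) {
    ev <- events[events$patient_id == p, ]
    i <- which(d$patient_id == p)
    d$ae_n_events[i] <- nrow(ev)
    d$ae_grade[i] <- max(ev$grade)
    d$ae_category[i] <- ev$category[which.max(ev$grade)]
  }
  rownames(d) <- NULL
  attr(d, "ae_events") <- events
  d
}
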