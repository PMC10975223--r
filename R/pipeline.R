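pick_conc <- function(assessments, conc = c("predicted_cmin", "true_cmin",
                                            "measured_conc")) {
  conc <- match.arg(conc)
  v <- assessments[[conc]]
  if (is.null(v)) stop("column ", conc, " not present", call. = FALSE)
  if (conc == "predicted_cmin" && all(is.na(v))) {
    # fall back to the raw measurement pathway when no MAP predictions exist
    v <- assessments[["measured_conc"]]
    if (is.null(v)) stop("neither predicted_cmin nor measured_conc available",
                         call. = FALSE)
  }
  if (any(is.na(v))) stop("concentration column contains NA", call. = FALSE)
  v
}

dose_factor <- function(dose_mg) {
  factor(as.character(dose_mg), levels = c("45", "30", "15"))
}

fraction_list <- function(num, den) {
  list(numerator = as.integer(num), denominator = as.integer(den),
       fraction = ifelse(den > 0, num / den, NA_real_),
       percent = ifelse(den > 0, round_half_up(100 * num / den, 1), NA_real_))
}

#' Threshold attainment by dose group
#'
#' Builds the dose x (attained, not attained) table at a trough threshold
#' (attainment inclusive, `>=`) and tests for a dose-group difference with
#' the Freeman-Halton exact test; the Pearson chi-squared p-value is reported
#' alongside, since published crosstab p-values do not always state their
#' convention.
#'
#' @param assessments assessment table ([generate_cohort()] /
#'   [counts_matched_fixture()] schema).
#' @param threshold trough threshold, ng/mL.
#' @param conc which concentration column to analyse; `predicted_cmin` falls
#'   back to `measured_conc` when no predictions are present.
#' @return list with the contingency `table`, per-dose `fractions`,
#'   `p_exact`, `p_pearson`, and `test` (`"freeman_halton"`, or
#'   `"not_applicable"` with a single dose group).
#' @examples
#' attainment_by_dose(counts_matched_fixture(), 10.7)
#' @export
attainment_by_dose <- function(assessments, threshold,
                               conc = c("predicted_cmin", "true_cmin",
                                        "measured_conc")) {
  v <- pick_conc(assessments, conc)
  g <- droplevels(dose_factor(assessments$dose_mg))
  att <- v >= threshold
  tab <- as.matrix(table(g, factor(att, levels = c(TRUE, FALSE),
                                   labels = c("attained", "not_attained"))))
  n <- as.vector(table(g))
  k <- as.vector(tapply(att, g, sum))
  fr <- fraction_list(k, n)
  fr$dose_mg <- levels(g)
  if (nlevels(g) < 2)
    return(list(table = tab, fractions = fr, p_exact = NA_real_,
                p_pearson = NA_real_, test = "not_applicable"))
  if (any(colSums(tab) == 0))  # degenerate column: all attain (or none)
    return(list(table = tab, fractions = fr, p_exact = 1, p_pearson = 1,
                test = "degenerate_all_one_column"))
  list(table = tab, fractions = fr,
       p_exact = freeman_halton_exact(tab),
       p_pearson = pearson_chi2(tab)$p,
       test = "freeman_halton")
}

#' Molecular response by threshold attainment (2x2)
#'
#' Cross-tabulates attainment of a trough threshold against reaching a
#' molecular-response level (MR3 or DMR, a deeper band counting as reaching
#' the level) and applies the two-sided Fisher exact test.
#'
#' @inheritParams attainment_by_dose
#' @param level `"MR3"` or `"DMR"`.
#' @return list with the 2x2 `table`, `fractions` (response rate on each side
#'   of the threshold), `p` (Fisher), `p_pearson`.
#' @examples
#' mr_by_threshold(counts_matched_fixture(), 10.7, "MR3")
#' @export
mr_by_threshold <- function(assessments, threshold, level = c("MR3", "DMR"),
                            conc = c("predicted_cmin", "true_cmin",
                                     "measured_conc")) {
  level <- match.arg(level)
  v <- pick_conc(assessments, conc)
  att <- factor(v >= threshold, levels = c(TRUE, FALSE),
                labels = c("attained", "not_attained"))
  if (any(table(att) == 0))
    stop("both sides of the threshold must be non-empty", call. = FALSE)
  hit <- factor(mr_at_least(assessments$mr_band, level),
                levels = c(TRUE, FALSE), labels = c("reached", "not_reached"))
  tab <- as.matrix(table(att, hit))
  n <- rowSums(tab)
  fr <- fraction_list(tab[, "reached"], n)
  fr$side <- rownames(tab)
  list(table = tab, fractions = fr, level = level,
       p = fisher_exact_two_sided(tab), p_pearson = pearson_chi2(tab)$p)
}

#' Molecular response by dose group
#'
#' Dose x (level reached, not) table with the Freeman-Halton exact test
#' (Pearson chi-squared alongside).
#'
#' @inheritParams mr_by_threshold
#' @return list as in [attainment_by_dose()].
#' @examples
#' mr_by_dose(counts_matched_fixture(), "MR3")
#' @export
mr_by_dose <- function(assessments, level = c("MR3", "DMR")) {
  level <- match.arg(level)
  g <- droplevels(dose_factor(assessments$dose_mg))
  hit <- mr_at_least(assessments$mr_band, level)
  tab <- as.matrix(table(g, factor(hit, levels = c(TRUE, FALSE),
                                   labels = c("reached", "not_reached"))))
  n <- as.vector(table(g))
  k <- as.vector(tapply(hit, g, sum))
  fr <- fraction_list(k, n)
  fr$dose_mg <- levels(g)
  if (nlevels(g) < 2)
    return(list(table = tab, fractions = fr, level = level,
                p_exact = NA_real_, p_pearson = NA_real_,
                test = "not_applicable"))
  if (any(colSums(tab) == 0))
    return(list(table = tab, fractions = fr, level = level, p_exact = 1,
                p_pearson = 1, test = "degenerate_all_one_column"))
  list(table = tab, fractions = fr, level = level,
       p_exact = freeman_halton_exact(tab), p_pearson = pearson_chi2(tab)$p,
       test = "freeman_halton")
}

summ_stats <- function(x) {
  list(n = length(x), mean = mean(x),
       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       sd_undefined = length(x) < 2,
       median = stats::median(x), min = min(x), max = max(x))
}

#' Cohort descriptives
#'
#' Occasion counts and percentages per dose group, concentration summaries
#' (mean, SD, median, range) per dose and overall, and adverse-event tallies
#' by grade and category (from the `"ae_events"` attribute when present,
#' otherwise from the per-row worst-event columns).
#'
#' @inheritParams attainment_by_dose
#' @return nested list of descriptives.
#' @export
summarize_cohort <- function(assessments,
                             conc = c("predicted_cmin", "true_cmin",
                                      "measured_conc")) {
  if (nrow(assessments) == 0) stop("empty assessment table", call. = FALSE)
  v <- pick_conc(assessments, conc)
  g <- droplevels(dose_factor(assessments$dose_mg))
  per_dose <- lapply(split(v, g), summ_stats)
  counts <- as.vector(table(g))
  ev <- attr(assessments, "ae_events")
  if (is.null(ev)) {
    has <- assessments$ae_grade > 0
    ae <- list(n_events = sum(assessments$ae_n_events),
               n_occasions_with_event = sum(has),
               by_grade = table(factor(assessments$ae_grade[has], levels = 1:5)),
               by_category = table(assessments$ae_category[has]),
               grade3plus = sum(assessments$ae_grade >= 3))
  } else {
    ae <- list(n_events = nrow(ev),
               n_patients_with_event = length(unique(ev$patient_id)),
               events_by_dose = table(dose_factor(ev$dose_mg)),
               by_category = table(ev$category),
               grade3plus = sum(ev$grade >= 3))
  }
  list(n_assessments = nrow(assessments),
       n_patients = length(unique(assessments$patient_id)),
       dose_groups = list(dose_mg = levels(g), n = counts,
                          percent = round_half_up(100 * counts /
                                                  nrow(assessments), 1)),
       concentration = c(list(overall = summ_stats(v)), per_dose),
       adverse_events = ae)
}

#' Full cohort analysis report
#'
#' Runs the whole pipeline on an assessment table (or CSV path): descriptives,
#' threshold attainment by dose with exact tests, molecular response by
#' threshold (2x2 Fisher) and by dose, at both efficacy thresholds. The
#' report is deterministic: rerunning on the same input yields an identical
#' structure (no timestamps), and every rendered number is present in the
#' JSON-serializable structure.
#'
#' @param input data.frame of assessments or path to a CSV with the same
#'   columns.
#' @param thresholds_ng_ml trough thresholds analysed (display scale, 1 dp).
#' @param conc concentration column choice, as in [attainment_by_dose()].
#' @param out optional path prefix: writes `<out>.json` and `<out>.md`.
#' @return object of class `analysis_report` (a nested list): `provenance`,
#'   `descriptives`, `attainment` (per threshold), `mr_by_threshold` (per
#'   threshold x level), `mr_by_dose` (per level), `pooled_attainment`.
#' @examples
#' rep <- run_report(counts_matched_fixture())
#' rep$attainment[["10.7"]]$p_exact
#' @export
run_report <- function(input, thresholds_ng_ml = c(10.7, 21.3),
                       conc = c("predicted_cmin", "true_cmin", "measured_conc"),
                       out = NULL) {
  assessments <- if (is.character(input)) {
    d <- utils::read.csv(input, stringsAsFactors = FALSE)
    d$mr_band <- factor(d$mr_band, levels = MR_BANDS, ordered = TRUE)
    d
  } else input
  need <- c("patient_id", "dose_mg", "mr_band")
  miss <- setdiff(need, names(assessments))
  if (length(miss))
    stop("assessment table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(assessments$mr_band)))
    stop("mr_band contains values outside ", paste(MR_BANDS, collapse = "/"),
         call. = FALSE)
  conc <- match.arg(conc)
  v <- pick_conc(assessments, conc)
  att_list <- lapply(thresholds_ng_ml, function(th)
    attainment_by_dose(assessments, th, conc))
  names(att_list) <- format(thresholds_ng_ml)
  mrth <- list()
  for (th in thresholds_ng_ml) for (lv in c("MR3", "DMR"))
    mrth[[format(th)]][[lv]] <- mr_by_threshold(assessments, th, lv, conc)
  mrd <- lapply(c(MR3 = "MR3", DMR = "DMR"),
                function(lv) mr_by_dose(assessments, lv))
  pooled <- lapply(thresholds_ng_ml, function(th)
    fraction_list(sum(v >= th), length(v)))
  names(pooled) <- format(thresholds_ng_ml)
  report <- structure(list(
    provenance = list(package = "ponatdm",
                      version = as.character(utils::packageVersion("ponatdm")),
                      conc_column = conc,
                      thresholds_ng_ml = thresholds_ng_ml,
                      n_input_rows = nrow(assessments)),
    descriptives = summarize_cohort(assessments, conc),
    attainment = att_list, mr_by_threshold = mrth, mr_by_dose = mrd,
    pooled_attainment = pooled), class = "analysis_report")
  if (!is.null(out)) {
    write_report_json(report, paste0(out, ".json"))
    writeLines(render_report_md(report), paste0(out, ".md"))
  }
  report
}

#' Serialize an analysis report to JSON
#' @param report [run_report()] result.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (inherits(x, "table") || is.matrix(x)) {
    m <- as.matrix(x)
    return(list(rows = rownames(m), cols = colnames(m),
                counts = apply(m, 1, as.vector, simplify = FALSE)))
  }
  if (is.factor(x)) return(as.character(x))
  x
}

#' Render an analysis report as markdown lines
#' @param report [run_report()] result.
#' @return character vector of markdown lines.
#' @export
render_report_md <- function(report) {
  p3 <- function(p) formatC(p, format = "f", digits = 3)
  d <- report$descriptives
  lines <- c("# Ponatinib TDM cohort report", "",
             sprintf("%d assessments in %d patients; dose groups %s mg/day: n = %s (%s%%).",
                     d$n_assessments, d$n_patients,
                     paste(d$dose_groups$dose_mg, collapse = "/"),
                     paste(d$dose_groups$n, collapse = "/"),
                     paste(format_display(d$dose_groups$percent, 1),
                           collapse = "/")),
             "", "## Threshold attainment by dose")
  for (th in names(report$attainment)) {
    a <- report$attainment[[th]]
    lines <- c(lines, sprintf(
      "- >= %s ng/mL: %s (exact p = %s, Pearson p = %s)", th,
      paste(sprintf("%d/%d at %s mg", a$fractions$numerator,
                    a$fractions$denominator, a$fractions$dose_mg),
            collapse = ", "),
      p3(a$p_exact), p3(a$p_pearson)))
  }
  lines <- c(lines, "", "## Molecular response by threshold")
  for (th in names(report$mr_by_threshold))
    for (lv in names(report$mr_by_threshold[[th]])) {
      m <- report$mr_by_threshold[[th]][[lv]]
      lines <- c(lines, sprintf(
        "- %s at %s ng/mL: %s (Fisher p = %s)", lv, th,
        paste(sprintf("%d/%d %s", m$fractions$numerator,
                      m$fractions$denominator, m$fractions$side),
              collapse = ", "),
        p3(m$p)))
    }
  lines <- c(lines, "", "## Molecular response by dose")
  for (lv in names(report$mr_by_dose)) {
    m <- report$mr_by_dose[[lv]]
    lines <- c(lines, sprintf(
      "- %s: %s (exact p = %s, Pearson p = %s)", lv,
      paste(sprintf("%d/%d at %s mg", m$fractions$numerator,
                    m$fractions$denominator, m$fractions$dose_mg),
            collapse = ", "),
      p3(m$p_exact), p3(m$p_pearson)))
  }
  lines
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
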