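#' Molar mass of ponatinib free base (g/mol)
#'
#' Used to convert between molar (nM) and mass (ng/mL) concentration scales.
#' @export
PONATINIB_MOLAR_MASS <- 532.56

#' Ordered molecular-response bands on the International Scale
#'
#' `BELOW_MR2 < MR2 < MR3 < DMR`: a higher band is a deeper response
#' (a smaller BCR-ABL1/ABL1 IS% ratio).
#' @export
MR_BANDS <- c("BELOW_MR2", "MR2", "MR3", "DMR")

#' Ordered trough-concentration bands
#'
#' `BELOW_MINIMAL < MINIMAL < UNMUTATED_EFFICACIOUS < MUTATION_SUPPRESSING`,
#' delimited by the three efficacy thresholds (10 / 20 / 40 nM by default).
#' @export
CMIN_BANDS <- c("BELOW_MINIMAL", "MINIMAL", "UNMUTATED_EFFICACIOUS",
                "MUTATION_SUPPRESSING")

#' Efficacy thresholds for ponatinib trough concentrations
#'
#' The canonical internal representation is molar: 10 nM (minimal efficacious
#' concentration), 20 nM (efficacious in BCR-ABL1-unmutated disease) and
#' 40 nM (suppression of new mutated clones), equal to 5.33, 10.65 and
#' 21.30 ng/mL at the ponatinib molar mass. The molar triple is the only
#' internally consistent reading of the published thresholds, which are
#' variously quoted as 5 or 5.3 ng/mL at the low end; a literal mass-scale
#' cut-off (e.g. 5.0 ng/mL for the assay's LLOQ) can be imposed through
#' `ng_ml_override`.
#'
#' @param minimal_nM minimal efficacious concentration, nM.
#' @param unmutated_nM efficacious concentration in unmutated disease, nM.
#' @param mutation_suppressing_nM concentration suppressing selection of
#'   mutated clones, nM.
#' @param molar_mass_g_per_mol molar mass used for the nM to ng/mL conversion.
#' @param ng_ml_override optional named numeric vector (names among
#'   `"minimal"`, `"unmutated"`, `"mutation_suppressing"`) that replaces the
#'   derived ng/mL value(s) with literal mass-scale cut-offs.
#' @return An object of class `concentration_thresholds` with the molar
#'   values, the molar mass, and the derived (or overridden) ng/mL boundaries.
#' @examples
#' thr <- concentration_thresholds()
#' threshold_ng_ml(thr)
#' @export
concentration_thresholds <- function(minimal_nM = 10,
                                     unmutated_nM = 20,
                                     mutation_suppressing_nM = 40,
                                     molar_mass_g_per_mol = PONATINIB_MOLAR_MASS,
                                     ng_ml_override = NULL) {
  nm <- c(minimal = minimal_nM, unmutated = unmutated_nM,
          mutation_suppressing = mutation_suppressing_nM)
  if (!all(is.finite(nm)) || any(nm <= 0))
    stop("all thresholds must be finite and strictly positive", call. = FALSE)
  if (!(is.finite(molar_mass_g_per_mol) && molar_mass_g_per_mol > 0))
    stop("molar mass must be strictly positive", call. = FALSE)
  if (!(nm[["minimal"]] < nm[["unmutated"]] &&
        nm[["unmutated"]] < nm[["mutation_suppressing"]]))
    stop("thresholds must satisfy minimal < unmutated < mutation_suppressing",
         call. = FALSE)
  ng <- nanomolar_to_ng_per_ml(nm, molar_mass_g_per_mol)
  if (!is.null(ng_ml_override)) {
    bad <- setdiff(names(ng_ml_override), names(ng))
    if (length(bad) || is.null(names(ng_ml_override)))
      stop("ng_ml_override names must be among: ",
           paste(names(ng), collapse = ", "), call. = FALSE)
    ng[names(ng_ml_override)] <- ng_ml_override
    if (is.unsorted(ng, strictly = TRUE))
      stop("overridden ng/mL thresholds are no longer strictly increasing",
           call. = FALSE)
  }
  structure(list(nM = nm, molar_mass_g_per_mol = molar_mass_g_per_mol,
                 ng_per_ml = ng),
            class = "concentration_thresholds")
}

#' @export
print.concentration_thresholds <- function(x, ...) {
  cat("Ponatinib trough thresholds (molar mass",
      x$molar_mass_g_per_mol, "g/mol):\n")
  for (n in names(x$nM))
    cat(sprintf("  %-22s %5.1f nM = %s ng/mL\n", n, x$nM[[n]],
                format_display(x$ng_per_ml[[n]], 1)))
  invisible(x)
}

#' ng/mL boundaries of a threshold set
#' @param thresholds a [concentration_thresholds()] object.
#' @return Named numeric vector of the three boundaries in ng/mL.
#' @export
threshold_ng_ml <- function(thresholds) {
  stopifnot(inherits(thresholds, "concentration_thresholds"))
  thresholds$ng_per_ml
}

#' Convert a molar concentration (nM) to a mass concentration (ng/mL)
#'
#' `x_nM * molar_mass / 1000`, exact arithmetic; rounding happens only at the
#' display layer ([round_half_up()]). At the ponatinib molar mass, 40 nM is
#' 21.30 ng/mL.
#'
#' @param x_nM non-negative molar concentration(s), nM.
#' @param molar_mass g/mol.
#' @return mass concentration(s), ng/mL.
#' @examples
#' nanomolar_to_ng_per_ml(40) # 21.3024
#' @export
nanomolar_to_ng_per_ml <- function(x_nM, molar_mass = PONATINIB_MOLAR_MASS) {
  if (any(!is.finite(x_nM)) || any(x_nM < 0))
    stop("molar concentration must be finite and non-negative", call. = FALSE)
  if (!(is.finite(molar_mass) && molar_mass > 0))
    stop("molar mass must be strictly positive", call. = FALSE)
  x_nM * molar_mass / 1000
}

#' Convert a mass concentration (ng/mL) to a molar concentration (nM)
#' @param x_ng_ml non-negative mass concentration(s), ng/mL.
#' @param molar_mass g/mol.
#' @return molar concentration(s), nM.
#' @export
ng_per_ml_to_nanomolar <- function(x_ng_ml, molar_mass = PONATINIB_MOLAR_MASS) {
  if (any(!is.finite(x_ng_ml)) || any(x_ng_ml < 0))
    stop("mass concentration must be finite and non-negative", call. = FALSE)
  if (!(is.finite(molar_mass) && molar_mass > 0))
    stop("molar mass must be strictly positive", call. = FALSE)
  x_ng_ml * 1000 / molar_mass
}

#' Round half away from zero (display convention)
#'
#' Published concentration thresholds use conventional commercial rounding
#' (10.65 prints as 10.7), not banker's rounding.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_display <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Classify a BCR-ABL1/ABL1 IS% ratio into a molecular-response band
#'
#' Bands on the International Scale, boundaries inclusive downward:
#' DMR if IS% <= 0.01, MR3 if 0.01 < IS% <= 0.1, MR2 if 0.1 < IS% <= 1,
#' BELOW_MR2 if IS% > 1. The MR3 boundary is taken as inclusive (<= 0.1%),
#' matching ELN convention.
#'
#' @param is_percent non-negative IS-scale ratio(s) in percent.
#' @return ordered factor with levels [MR_BANDS].
#' @examples
#' classify_molecular_response(c(0.01, 0.05, 2))
#' @export
classify_molecular_response <- function(is_percent) {
  if (any(!is.finite(is_percent)) || any(is_percent < 0))
    stop("IS% must be finite and non-negative", call. = FALSE)
  band <- ifelse(is_percent <= 0.01, "DMR",
          ifelse(is_percent <= 0.1,  "MR3",
          ifelse(is_percent <= 1,    "MR2", "BELOW_MR2")))
  factor(band, levels = MR_BANDS, ordered = TRUE)
}

#' Classify a trough concentration against the efficacy thresholds
#'
#' Attainment is inclusive (`>=`), so a measurement exactly on a boundary
#' counts as reaching it. The bands partition `[0, Inf)` at the three
#' ng/mL boundaries of `thresholds`.
#'
#' @param c_ng_ml non-negative trough concentration(s), ng/mL.
#' @param thresholds a [concentration_thresholds()] object.
#' @return ordered factor with levels [CMIN_BANDS].
#' @examples
#' classify_cmin(c(3.16, 15.25, 27.13))
#' @export
classify_cmin <- function(c_ng_ml, thresholds = concentration_thresholds()) {
  if (any(!is.finite(c_ng_ml)) || any(c_ng_ml < 0))
    stop("concentration must be finite and non-negative", call. = FALSE)
  stopifnot(inherits(thresholds, "concentration_thresholds"))
  ng <- thresholds$ng_per_ml
  band <- ifelse(c_ng_ml >= ng[["mutation_suppressing"]], "MUTATION_SUPPRESSING",
          ifelse(c_ng_ml >= ng[["unmutated"]], "UNMUTATED_EFFICACIOUS",
          ifelse(c_ng_ml >= ng[["minimal"]], "MINIMAL", "BELOW_MINIMAL")))
  factor(band, levels = CMIN_BANDS, ordered = TRUE)
}

#' Test whether a response band is at least a given level
#' @param band ordered factor or character of MR bands.
#' @param level target band, e.g. `"MR3"`.
#' @return logical.
#' @export
mr_at_least <- function(band, level = "MR3") {
  level <- match.arg(level, MR_BANDS)
  b <- if (is.factor(band)) as.character(band) else band
  stopifnot(all(b %in% MR_BANDS))
  match(b, MR_BANDS) >= match(level, MR_BANDS)
}
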