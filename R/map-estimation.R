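# Parameters that may carry between-subject variability (log-normal).
ETA_PARAMS <- c("ktr", "ka", "CL", "Vc", "Q", "Vp")

#' Population prior for individual (empirical-Bayes) estimation
#'
#' Typical parameter values plus log-normal between-subject variability and a
#' combined residual-error model. An individual's parameters are
#' `theta * exp(eta)` with `eta ~ N(0, Omega)` on the log scale. The residual
#' standard deviation of an observation with model prediction `f` is
#' `sigma_add + sigma_prop * f` (combined additive/proportional model).
#'
#' @param theta [pk_parameters()] with the typical values.
#' @param omega either a named non-negative numeric vector of log-scale
#'   standard deviations (names among `ktr, ka, CL, Vc, Q, Vp`; missing names
#'   mean no variability), or a full symmetric positive semi-definite
#'   covariance matrix on the log scale with those dimnames.
#' @param sigma_add additive residual error, ng/mL (>= 0).
#' @param sigma_prop proportional residual error fraction (>= 0). `sigma_add`
#'   and `sigma_prop` must not both be zero.
#' @return object of class `population_prior`.
#' @examples
#' population_prior()
#' @export
population_prior <- function(theta = pk_parameters(),
                             omega = c(ktr = 0.3, ka = 0.3, CL = 0.3,
                                       Vc = 0.3, Q = 0.3, Vp = 0.3),
                             sigma_add = 0.5, sigma_prop = 0.2) {
  stopifnot(inherits(theta, "pk_parameters"))
  if (is.matrix(omega)) {
    nm <- rownames(omega)
    if (is.null(nm) || !all(nm %in% ETA_PARAMS) || !identical(nm, colnames(omega)))
      stop("omega matrix needs matching dimnames among: ",
           paste(ETA_PARAMS, collapse = ", "), call. = FALSE)
    if (!isSymmetric(omega) || any(eigen(omega, symmetric = TRUE,
                                         only.values = TRUE)$values < -1e-10))
      stop("omega matrix must be symmetric positive semi-definite", call. = FALSE)
    Om <- omega
  } else {
    if (is.null(names(omega)) || !all(names(omega) %in% ETA_PARAMS))
      stop("omega names must be among: ", paste(ETA_PARAMS, collapse = ", "),
           call. = FALSE)
    if (any(!is.finite(omega)) || any(omega < 0))
      stop("omega entries must be finite and non-negative", call. = FALSE)
    keep <- names(omega)[omega > 0]
    Om <- diag(omega[keep]^2, nrow = length(keep))
    dimnames(Om) <- list(keep, keep)
  }
  if (!(is.finite(sigma_add) && sigma_add >= 0) ||
      !(is.finite(sigma_prop) && sigma_prop >= 0))
    stop("residual error components must be finite and non-negative",
         call. = FALSE)
  if (sigma_add == 0 && sigma_prop == 0)
    stop("sigma_add and sigma_prop must not both be zero", call. = FALSE)
  structure(list(theta = theta, omega = Om, sigma_add = sigma_add,
                 sigma_prop = sigma_prop),
            class = "population_prior")
}

#' @export
print.population_prior <- function(x, ...) {
  cat("Population prior\n  typical values:\n")
  print(x$theta)
  sds <- sqrt(diag(x$omega))
  cat("  log-normal BSV (sd): ",
      if (length(sds)) paste(sprintf("%s=%.3g", names(sds), sds), collapse = ", ")
      else "none", "\n", sep = "")
  cat(sprintf("  residual error: sd = %.3g + %.3g * f ng/mL\n",
              x$sigma_add, x$sigma_prop))
  invisible(x)
}

#' One or more random-time plasma samples
#'
#' @param t_since_dose_h hours since the last dose, within `[0, tau_h]`.
#' @param conc_ng_ml measured concentration(s), ng/mL (>= 0).
#' @param dose_mg daily dose, mg.
#' @param tau_h dosing interval, hours.
#' @param below_loq logical flag(s); defaults to `conc_ng_ml < lloq`.
#' @param patient_id optional identifier.
#' @param lloq assay lower limit of quantitation, ng/mL.
#' @return data.frame of class `concentration_samples`.
#' @export
concentration_samples <- function(t_since_dose_h, conc_ng_ml, dose_mg,
                                  tau_h = 24, below_loq = NULL,
                                  patient_id = NA_character_, lloq = 5) {
  n <- max(length(t_since_dose_h), length(conc_ng_ml))
  d <- data.frame(patient_id = rep_len(patient_id, n),
                  dose_mg = rep_len(dose_mg, n),
                  tau_h = rep_len(tau_h, n),
                  t_since_dose_h = rep_len(t_since_dose_h, n),
                  conc_ng_ml = rep_len(conc_ng_ml, n))
  d$below_loq <- if (is.null(below_loq)) d$conc_ng_ml < lloq
                 else rep_len(as.logical(below_loq), n)
  validate_samples(d)
  class(d) <- c("concentration_samples", "data.frame")
  d
}

validate_samples <- function(d) {
  need <- c("dose_mg", "tau_h", "t_since_dose_h", "conc_ng_ml")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("samples lack required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d) == 0) return(invisible(d))
  with(d, {
    if (any(!is.finite(conc_ng_ml)) || any(conc_ng_ml < 0))
      stop("concentrations must be finite and non-negative", call. = FALSE)
    if (any(t_since_dose_h < 0) || any(t_since_dose_h > tau_h))
      stop("t_since_dose_h must lie within [0, tau_h]", call. = FALSE)
  })
  invisible(d)
}

#' Read plasma samples from CSV
#'
#' Expected columns: `patient_id, dose_mg, tau_h, t_since_dose_h, conc_ng_ml,
#' bloq_flag` (UTF-8, comma-separated, `.` decimal).
#' @param path CSV file.
#' @param lloq LLOQ used when `bloq_flag` is absent.
#' @return `concentration_samples` data.frame.
#' @export
read_samples_csv <- function(path, lloq = 5) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("bloq_flag" %in% names(d)) {
    d$below_loq <- as.logical(d$bloq_flag)
    d$bloq_flag <- NULL
  } else d$below_loq <- d$conc_ng_ml < lloq
  if (!"patient_id" %in% names(d)) d$patient_id <- NA_character_
  if (!"tau_h" %in% names(d)) d$tau_h <- 24
  validate_samples(d)
  class(d) <- c("concentration_samples", "data.frame")
  d
}

#' Read or write a population prior as JSON
#'
#' The schema records the typical values (with units mg, L, h), the log-scale
#' covariance, and the residual-error components.
#' @param path JSON file.
#' @return [population_prior()].
#' @export
read_prior_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- do.call(pk_parameters, as.list(j$theta))
  om <- j$omega
  if (is.list(om) || (is.numeric(om) && !is.matrix(om))) om <- unlist(om)
  population_prior(theta = th, omega = om,
                   sigma_add = j$sigma_add, sigma_prop = j$sigma_prop)
}

#' @rdname read_prior_json
#' @param prior [population_prior()] to serialize.
#' @export
write_prior_json <- function(prior, path) {
  sds <- sqrt(diag(prior$omega))
  jsonlite::write_json(
    list(theta = unclass(prior$theta), omega = as.list(sds),
         sigma_add = prior$sigma_add, sigma_prop = prior$sigma_prop,
         units = list(dose = "mg", volume = "L", time = "h",
                      concentration = "ng/mL")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

apply_eta <- function(theta, eta) {
  p <- unclass(theta)
  for (nm in names(eta)) p[[nm]] <- p[[nm]] * exp(eta[[nm]])
  do.call(pk_parameters, p[c("n_transit", "ktr", "ka", "CL", "Vc", "Q", "Vp", "F")])
}

# Steady-state concentrations at several offsets, without S3 validation:
# the hot path of the MAP objective. `pv` is the full named parameter vector.
fast_ss_conc <- function(pv, n_transit, dose, tau, times) {
  n <- n_transit
  m <- n + 3L
  A <- matrix(0, m, m)
  rates <- c(rep(pv[["ktr"]], n), pv[["ka"]])
  for (i in seq_len(n + 1L)) {
    A[i, i] <- A[i, i] - rates[i]
    A[i + 1L, i] <- A[i + 1L, i] + rates[i]
  }
  ce <- n + 2L; pe <- n + 3L
  k10 <- pv[["CL"]] / pv[["Vc"]]; k12 <- pv[["Q"]] / pv[["Vc"]]
  k21 <- pv[["Q"]] / pv[["Vp"]]
  A[ce, ce] <- -k10 - k12; A[pe, ce] <- k12
  A[ce, pe] <- k21; A[pe, pe] <- -k21
  M <- expm_dense(A * tau)
  u <- numeric(m); u[1L] <- pv[["F"]] * dose
  xs <- solve(diag(m) - M, M %*% u)
  x <- xs + u
  ord <- order(times)
  conc <- numeric(length(times))
  t_prev <- 0
  for (i in ord) {
    if (times[i] > t_prev) {
      x <- expm_dense(A * (times[i] - t_prev)) %*% x
      t_prev <- times[i]
    }
    conc[i] <- x[ce]
  }
  pmax(conc / pv[["Vc"]] * 1000, 0)
}

# -2 log posterior (up to an additive constant independent of eta)
map_objective <- function(eta, sample_groups, theta_vec, n_transit, prior,
                          omega_inv, lloq, blq) {
  pv <- theta_vec
  if (length(eta)) {
    nm <- colnames(prior$omega)
    pv[nm] <- pv[nm] * exp(eta)
  }
  ll <- 0
  for (g in sample_groups) {
    f <- tryCatch(
      fast_ss_conc(pv, n_transit, g$dose, g$tau, g$t),
      error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(1e10)
    y <- g$y
    sd <- prior$sigma_add + prior$sigma_prop * f
    if (blq == "replace_half_lloq") {
      y[g$bloq] <- lloq / 2
      sd[g$bloq] <- pmax(sd[g$bloq], lloq / 4)  # additive-error floor
    }
    sd <- pmax(sd, 1e-6)
    ll <- ll + sum(stats::dnorm(y, mean = f, sd = sd, log = TRUE))
  }
  lp <- if (length(eta)) -0.5 * drop(eta %*% omega_inv %*% eta) else 0
  v <- -2 * (ll + lp)
  if (!is.finite(v)) 1e10 else v
}

#' MAP (empirical-Bayes) estimation of individual PK parameters
#'
#' Maximizes the posterior combining the sample likelihood (combined residual
#' error, residual sd `sigma_add + sigma_prop * f`) with the log-normal
#' population prior on the individual deviations `eta`, by multi-start local
#' optimization (`eta = 0` plus `starts - 1` perturbed starts from a seeded
#' generator) under the box constraint `|eta_i| <= 5 * omega_i`. With no
#' samples the prior mode `eta = 0` is returned exactly.
#'
#' @param samples a [concentration_samples()] data.frame (may have 0 rows).
#' @param prior a [population_prior()].
#' @param regimen [dosing_regimen()] used for the predicted trough; defaults
#'   to the regimen of the samples (which must then be unique).
#' @param blq handling of below-LLOQ observations: replace by LLOQ/2 with an
#'   additive-error floor (default), exclude, or use the reported value as-is.
#' @param lloq assay lower limit of quantitation, ng/mL.
#' @param starts number of optimization starts.
#' @param max_doses dose cap for declaring the individual's steady state
#'   when predicting the trough; more permissive than the
#'   [steady_state_cmin()] default because a MAP fit may land on
#'   slow-eliminating parameter combinations whose trough still exists but
#'   accrues over more dosing intervals.
#' @param seed integer seed for the perturbed starts (the estimate is a
#'   deterministic function of `samples`, `prior` and `seed`).
#' @return object of class `individual_estimate`: `eta` (named log-scale
#'   deviations), `params` ([pk_parameters()] after applying `eta`),
#'   `predicted_cmin` (ng/mL), `objective` (-2 log posterior at the optimum),
#'   `converged`.
#' @examples
#' pr <- population_prior()
#' s <- concentration_samples(6, 45, dose_mg = 30)
#' map_estimate(s, pr)
#' @export
map_estimate <- function(samples, prior, regimen = NULL,
                         blq = c("replace_half_lloq", "exclude", "as_is"),
                         lloq = 5, starts = 5L, seed = 1L,
                         max_doses = 1000L) {
  stopifnot(inherits(prior, "population_prior"))
  blq <- match.arg(blq)
  validate_samples(samples)
  if (blq == "exclude" && nrow(samples)) samples <- samples[!samples$below_loq, ]
  if (is.null(regimen)) {
    if (!nrow(samples))
      stop("a regimen is required when no samples are supplied", call. = FALSE)
    if (length(unique(samples$dose_mg)) > 1 || length(unique(samples$tau_h)) > 1)
      stop("samples span several regimens; pass `regimen` explicitly",
           call. = FALSE)
    regimen <- dosing_regimen(samples$dose_mg[1], samples$tau_h[1])
  }
  enames <- colnames(prior$omega)
  k <- length(enames)
  theta_vec <- unlist(unclass(prior$theta)[c("ktr", "ka", "CL", "Vc", "Q",
                                             "Vp", "F")])
  n_transit <- prior$theta$n_transit
  sample_groups <- lapply(
    split(samples, list(samples$dose_mg, samples$tau_h), drop = TRUE),
    function(g) list(dose = g$dose_mg[1], tau = g$tau_h[1],
                     t = g$t_since_dose_h, y = g$conc_ng_ml,
                     bloq = g$below_loq))
  if (k == 0L || nrow(samples) == 0L) {
    eta <- stats::setNames(numeric(k), enames)
    obj <- map_objective(eta, sample_groups, theta_vec, n_transit, prior,
                         if (k) solve(prior$omega) else matrix(0, 0, 0),
                         lloq, blq)
    est <- list(eta = eta, params = prior$theta,
                predicted_cmin = steady_state_cmin(prior$theta, regimen,
                                                   max_doses = max_doses),
                objective = obj, converged = TRUE)
    class(est) <- "individual_estimate"
    return(est)
  }
  omega_inv <- solve(prior$omega)
  sds <- sqrt(diag(prior$omega))
  bound <- 5 * sds
  fn <- function(e) map_objective(e, sample_groups, theta_vec, n_transit,
                                  prior, omega_inv, lloq, blq)
  start_mat <- rbind(numeric(k),
                     local_rng(seed, function()
                       matrix(stats::rnorm((starts - 1L) * k, 0, 0.5 * sds),
                              ncol = k, byrow = TRUE)))
  best <- NULL
  any_ok <- FALSE
  last_err <- NULL
  for (i in seq_len(nrow(start_mat))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(start_mat[i, ], -bound), bound), fn,
                   method = "L-BFGS-B", lower = -bound, upper = bound,
                   control = list(factr = 1e8, maxit = 100L)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (is.null(fit)) next
    any_ok <- any_ok || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("MAP optimization failed from every start",
         if (!is.null(last_err)) paste0(" (last error: ", last_err, ")"),
         call. = FALSE)
  obj0 <- fn(numeric(k))
  if (obj0 < best$value) {  # never worse than the prior mode
    best <- list(par = numeric(k), value = obj0, convergence = 0L)
    any_ok <- TRUE
  }
  eta <- stats::setNames(best$par, enames)
  params <- apply_eta(prior$theta, eta)
  est <- list(eta = eta, params = params,
              predicted_cmin = steady_state_cmin(params, regimen,
                                                 max_doses = max_doses),
              objective = best$value, converged = any_ok)
  class(est) <- "individual_estimate"
  est
}

#' @export
print.individual_estimate <- function(x, ...) {
  cat("Individual MAP estimate",
      if (!x$converged) "(NOT CONVERGED)" else "", "\n")
  cat("  eta:", paste(sprintf("%s=%+.3f", names(x$eta), x$eta), collapse = ", "),
      "\n")
  cat(sprintf("  predicted steady-state C_min: %.2f ng/mL  (-2 log posterior %.3f)\n",
              x$predicted_cmin, x$objective))
  invisible(x)
}

#' Predict the steady-state trough from a single random-time sample
#'
#' Runs [map_estimate()] on the singleton sample and returns the trough of
#' the individualized model — the trough-prediction step of TDM from sparse
#' sampling. The prediction is shrunk between the observation-implied and
#' population-typical troughs by the prior.
#'
#' @param sample a one-row [concentration_samples()] data.frame.
#' @inheritParams map_estimate
#' @return predicted steady-state trough, ng/mL.
#' @export
predict_cmin_from_single_sample <- function(sample, prior,
                                            blq = c("replace_half_lloq",
                                                    "exclude", "as_is"),
                                            lloq = 5, starts = 5L, seed = 1L) {
  if (nrow(sample) != 1L)
    stop("exactly one sample expected", call. = FALSE)
  est <- map_estimate(sample, prior, blq = blq, lloq = lloq,
                      starts = starts, seed = seed)
  est$predicted_cmin
}

# Run `f` under a temporary RNG state seeded with `seed`. The seed must be
# forced before the state snapshot: its expression may itself consume random
# numbers (e.g. a seed drawn by the caller).
local_rng <- function(seed, f) {
  force(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}
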