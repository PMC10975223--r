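# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (enumeration by label assignment instead of
# margin-conditioned table enumeration; closed forms and a numerical ODE
# integrator instead of the matrix-exponential engine).

# Brute-force exact test: enumerate every distinct assignment of the column
# labels (as a multiset) to the N items, with row membership fixed; each
# assignment is equally likely under the null. Feasible for N <= ~12.
brute_force_exact_p <- function(tab, tol = 1e-7) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  N <- sum(tab)
  row_of <- rep(seq_along(rs), rs)
  freq <- new.env(parent = emptyenv())
  total <- 0
  assign_next <- function(i, remaining, cells) {
    if (i > N) {
      key <- paste(cells, collapse = ",")
      freq[[key]] <- (if (is.null(freq[[key]])) 0 else freq[[key]]) + 1
      total <<- total + 1
      return(invisible())
    }
    for (j in seq_along(remaining)) {
      if (remaining[j] > 0) {
        remaining[j] <- remaining[j] - 1
        cells[row_of[i], j] <- cells[row_of[i], j] + 1
        assign_next(i + 1, remaining, cells)
        remaining[j] <- remaining[j] + 1
        cells[row_of[i], j] <- cells[row_of[i], j] - 1
      }
    }
  }
  assign_next(1, cs, matrix(0, nrow(tab), ncol(tab)))
  keys <- ls(freq)
  probs <- vapply(keys, function(k) freq[[k]] / total, numeric(1))
  obs_key <- paste(tab, collapse = ",")
  p_obs <- probs[[obs_key]]
  sum(probs[probs <= p_obs * (1 + tol)])
}

# One-compartment closed forms (oral bolus limit: instantaneous absorption).
one_cpt_bolus_conc <- function(dose, F, CL, Vc, t) {
  k <- CL / Vc
  F * dose * exp(-k * t) / Vc * 1000
}

one_cpt_ss_trough <- function(dose, F, CL, Vc, tau) {
  k <- CL / Vc
  F * dose * exp(-k * tau) / (Vc * (1 - exp(-k * tau))) * 1000
}

# Numerical ODE integration of the transit-absorption two-compartment model,
# single dose into the depot at t = 0.
ode_oracle_conc <- function(params, dose_mg, times) {
  n <- params$n_transit
  deriv <- function(t, y, p) {
    rates <- c(rep(params$ktr, n), params$ka)
    m <- n + 3
    dy <- numeric(m)
    for (i in seq_len(n + 1)) {
      dy[i] <- dy[i] - rates[i] * y[i]
      dy[i + 1] <- dy[i + 1] + rates[i] * y[i]
    }
    ce <- n + 2; pe <- n + 3
    dy[ce] <- dy[ce] - (params$CL / params$Vc + params$Q / params$Vc) * y[ce] +
      params$Q / params$Vp * y[pe]
    dy[pe] <- dy[pe] + params$Q / params$Vc * y[ce] - params$Q / params$Vp * y[pe]
    list(dy)
  }
  y0 <- c(params$F * dose_mg, numeric(n + 2))
  out <- deSolve::lsoda(y0, unique(c(0, times)), deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  conc <- out[match(times, out[, 1]), n + 3] / params$Vc * 1000
  unname(conc)
}

# Draw a random small contingency table with positive margins.
random_table <- function(nr, nc, N) {
  repeat {
    cells <- as.vector(stats::rmultinom(1, N, rep(1, nr * nc)))
    tab <- matrix(cells, nr, nc)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

make_individual <- function(theta, eta) {
  pl <- unclass(theta)
  for (nm in names(eta)) pl[[nm]] <- pl[[nm]] * exp(eta[[nm]])
  do.call(pk_parameters,
          pl[c("n_transit", "ktr", "ka", "CL", "Vc", "Q", "Vp", "F")])
}
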