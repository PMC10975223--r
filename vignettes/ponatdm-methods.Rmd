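---
title: "Methods: trough-guided ponatinib dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trough-guided ponatinib dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ponatdm)
```

## The problem

Ponatinib is a third-generation BCR-ABL1 inhibitor used in chronic myeloid
leukemia (CML) after failure of, or intolerance to, earlier tyrosine kinase
inhibitors. Its efficacy is exposure-dependent — in vitro, a trough
concentration ($C_\min$) of 40 nM suppresses the outgrowth of newly mutated
clones, 20 nM is efficacious against unmutated BCR-ABL1, and 10 nM is the
minimal efficacious level — while its vascular toxicity is dose-dependent.
Therapeutic drug monitoring (TDM) therefore aims to keep patients at the
lowest dose whose trough still clears the relevant efficacy threshold.

Routine clinic visits do not happen at trough: samples are drawn at a random,
but recorded, time after the morning dose. The package's core task is to turn
one such random-time measurement into a trough estimate, classify it against
the molar thresholds, relate it to the molecular response on the
International Scale (IS), and feed a transparent dose-recommendation rule.

## Units and classification

The thresholds are represented in molar units (10 / 20 / 40 nM) and converted
with $c_{\text{ng/mL}} = c_{\text{nM}} \cdot M / 1000$ at the ponatinib
free-base molar mass $M = 532.56$ g/mol, giving 5.33, 10.65 and 21.30 ng/mL.
The literature quotes the display-rounded values 5.3, 10.7 and 21.3 ng/mL
(and sometimes a literal 5 ng/mL, which coincides with the assay LLOQ; a
`ng_ml_override` exists for that reading). The molar triple is the canonical
representation because it is the only internally consistent one. Rounding is
half-away-from-zero and happens only at the display layer.

Molecular response bands follow the IS conventions with boundaries inclusive
downward: DMR at IS% $\le 0.01$, MR3 at $\le 0.1$, MR2 at $\le 1$. The MR3
boundary is taken inclusive (as in ELN usage) although some tabulations write
$< 0.1\%$. Threshold attainment for classification is inclusive ($\ge$), so a
boundary measurement counts as attainment; the dose-decision rule instead
uses a strict $> 10.7$ ng/mL comparison, because that is how the decision
rule is stated. Both choices are documented and deliberate.

## The pharmacokinetic model

Disposition is linear and bi-compartmental with first-order elimination from
the central compartment; absorption is extravascular through a chain of
`n_transit` transit compartments (exit rate $k_{tr}$) with final absorption
into plasma at $k_a$. Amounts are in mg, volumes in L, times in h;
concentration is central amount / $V_c$, scaled by 1000 to ng/mL in exactly
one function.

The model is a linear ODE system $\dot x = A x$, solved exactly with the
matrix exponential (compiled, Padé scaling-and-squaring; a transit chain with
equal rates makes $A$ defective, so an eigendecomposition would not do).
A numerical ODE integration serves as an independent oracle in the test
suite, as do the one-compartment closed forms in the appropriate limits
($Q \to 0$, no transit chain, near-instantaneous absorption).

The steady-state trough is the pre-dose concentration. Convergence is
*declared* by iterating the dose-to-dose map $x \mapsto M(x + u)$,
$M = e^{A\tau}$, and requiring successive troughs to agree to better than
$10^{-6}$ relative within 60 doses (an error otherwise); the *returned* value
is the exact fixed point $x^\ast = (I - M)^{-1} M u$, so the trough and any
within-interval prediction derived from $x^\ast$ are consistent to machine
precision. Internal consumers that may legitimately visit slow-eliminating
parameter combinations — the MAP optimizer's end-point prediction and the
stochastic cohort generator, where log-normal tails produce individuals with
terminal half-lives of weeks — use a permissive 1000-dose cap instead;
user-facing calls keep the strict default.

### Synthetic default parameters

No fitted population estimates are published for this model, so the package
ships synthetic defaults chosen once: `n_transit = 3`, `ktr = ka = 1` /h
(mean absorption time 5 h, matching ponatinib's late peak), `Vc = 120` L,
`Q = 70` L/h, `Vp = 900` L (a large distribution volume and a terminal
half-life near 32 h), `F = 1` (rates and clearances are apparent, i.e.
relative to oral bioavailability), and `CL = 29.7` L/h. The clearance was
calibrated so that, under the default between-subject variability
($\omega = 0.3$ on all six disposition/absorption parameters), the *mean*
steady-state trough of a 45 mg/day regimen is approximately 42 ng/mL — the
cohort-mean anchor for the highest dose group. The model is dose-proportional,
so the three published dose-group means (41.99 / 34.27 / 15.25 ng/mL at
45 / 30 / 15 mg) cannot all be matched: they are not proportional to dose.
The 45 mg anchor was prioritized; the implied 30 and 15 mg means are 28 and
14 ng/mL. These defaults are a calibration aid for synthetic data, not
estimates of any real population.

## MAP (empirical-Bayes) trough estimation

Individual parameters are $\theta_i = \theta \cdot e^{\eta_i}$ with
$\eta \sim N(0, \Omega)$ on the log scale. Given samples $y_j$ at offsets
$t_j$ within a (steady-state) dosing interval, the estimate minimizes

$$-2\left[\sum_j \log N\!\big(y_j;\, f_j(\eta),\, g_j^2\big) +
\log N(\eta;\, 0,\, \Omega)\right],\qquad
g_j = \sigma_{add} + \sigma_{prop} f_j ,$$

a combined residual-error model with default $\sigma_{add} = 0.5$ ng/mL and
$\sigma_{prop} = 0.2$ (the residual model of the original assay is not
published; these are ordinary TDM magnitudes). Optimization is multi-start
local (L-BFGS-B): $\eta = 0$ plus four perturbed starts from a seeded
generator, under the box $|\eta_i| \le 5\,\omega_i$; the best start wins, and
the result is never allowed to be worse than the prior mode. With no samples
the prior mode is returned exactly. Everything is a deterministic function of
(samples, prior, seed).

Below-LLOQ observations (LLOQ 5 ng/mL) are replaced by LLOQ/2 with an
additive-error floor by default; `exclude` and `as_is` are selectable. The
`as_is` option exists because reported sub-LLOQ concentrations (e.g.
3.16 ng/mL) suggest values below the quantitation limit were sometimes
reported as measured.

One behavior of the combined error model is worth knowing: because the
residual standard deviation grows with the prediction, an observation *far*
below the population-typical level (roughly an order of magnitude, e.g.
5 ng/mL six hours post-dose when ~70 ng/mL is typical) is more cheaply
attributed to noise than to a plausible individual deviation, so the
estimate shrinks strongly toward the prior. The single-sample trough
prediction is therefore monotone in the observed value over the assay's
quantifiable range, but not globally — a wildly discordant low value can
yield a *higher* predicted trough than a moderately low one. The test suite
pins down both facets.

Whether reported troughs are model predictions or raw measurements taken as
troughs is ambiguous in routine records; both pathways are supported (the
pipeline's `conc` argument selects the column, and `predicted_cmin` falls
back to `measured_conc` when no predictions exist).

## Exact contingency statistics

The two-sided Fisher test uses the point-probability convention: conditional
on the margins, sum the hypergeometric probabilities of all tables no more
probable than the observed one (relative tie tolerance $10^{-7}$). This
convention reproduces all four published 2x2 response-by-threshold p-values
(0.268, 0.722, 0.709, 0.473) from the printed counts. The Freeman-Halton
test generalizes the same rule to r x c tables by enumerating all tables
with the observed margins (recursive allocation with remaining-margin
bounds, log-space probabilities, an explicit enumeration guard), and reduces
exactly to the 2x2 case.

For the four published 3x2 dose-group tables the printed p-values (0.038,
0.025, 0.096, 0.239) are *not* reproduced by the exact convention, which
gives 0.033, 0.023, 0.059, 0.246 (verified against a brute-force
label-assignment oracle), nor by the Pearson chi-squared (0.024, 0.038,
0.049, 0.220) — though the Pearson pair for the two attainment tables
matches the printed pair transposed. The pipeline therefore reports both
conventions side by side for every r x c table, and the package treats the
running text's counts, not its p-values, as the reproducible quantity. The
Pearson statistic carries no Yates correction by default so it matches the
textbook formula; the correction is selectable.

Group comparisons for continuous data (two-tailed t, Mann-Whitney,
Kruskal-Wallis with Bonferroni-adjusted pairwise Mann-Whitney, Spearman)
delegate to the standard implementations; the Bonferroni adjustment
multiplies each pairwise p by the number of comparisons and caps at 1.

## The dose-decision rule engine

The engine encodes the risk-stratified algorithm as explicit first-match
rules over a validated `patient_state`; every recommendation carries an
ordered rationale trace whose final rule id alone determines the action
(tested as an audit property). Starting doses: high / very-high
cardiovascular risk starts at 15 mg/day with at least MR3, otherwise
30 mg/day; low / moderate risk starts at 30 mg/day, or 45 mg/day with a
demonstrated T315I or compound mutation. Adjustments: a grade >= 3 active
adverse event interrupts with restart one step down the 45-30-15 ladder (the
step size is a package decision; the practice, not the magnitude, is
published); six months at 30 mg/day with MR3 and a trough above 10.7 ng/mL
reduces to 15 mg/day under strict molecular monitoring; low/moderate-risk
patients on 45 or 30 mg/day with MR3 and a trough above threshold also
reduce. A missing trough disables the reduction rules; a missing risk
category yields `insufficient_information` rather than a guess.

Three points were genuinely open and decided here: a T315I/compound mutation
in a high-risk patient is capped at 30 mg/day with a warning flag (the
45 mg recommendation is stated only for the low/moderate branch; a
configuration switch lifts the cap); a patient at 15 mg/day below threshold
is maintained with a `below_threshold_no_escalation_rule` flag because no
escalation rule is published; and the six-month clock is attached only to
the 30 mg rule where it is stated, not to the low/moderate branch.

## The synthetic cohort generator

Patient-level data from the motivating cohort were never deposited, so the
generator is the package's test bed. It emulates: ~32 patients contributing
~38 dose-occasions (each patient contributes a second occasion with
probability 6/32), dose allocation 9:17:12 over 45/30/15 mg/day, log-normal
between-subject variability ($\omega = 0.3$), one random-time sample per
occasion on [0, 24] h with combined residual error and LLOQ flagging at
5 ng/mL, molecular response from a logistic model on log trough whose
default slope is 0 — encoding the cohort's null exposure-response finding,
with intercepts matching the observed MR3 (25/38) and DMR-given-MR3 (15/25)
rates — and per-occasion Poisson adverse-event counts with rates 7/9, 4/17,
2/12 and the observed grade >= 3 (6/13) and hematological (5/13) fractions.

What it does not emulate: treatment-line history, response durability and
time-to-response dynamics, within-patient correlation of repeated molecular
results, non-adherence, drug interactions, or any real exposure-response
slope. A passing test on synthetic data therefore validates the machinery
and the statistical conventions, not any clinical effect size.

The deterministic `counts_matched_fixture()` complements the stochastic
generator: a 38-row table reproducing, simultaneously, every published
marginal and cross count (dose groups 9/17/12; attainment 8/14/5 at
10.7 ng/mL and 4/6/0 at 21.3 ng/mL; MR3 3/12/10 and DMR 2/6/7 by dose; all
threshold-by-response cross counts; the 13-event adverse-event tally). The
three-way allocation is under-determined by those margins, so an exhaustive
integer-feasibility search picks the lexicographically smallest feasible
allocation — the fixture is unique and stable, and the search fails loudly
if the published constraints were jointly infeasible. Trough values sit at
band midpoints (5.35, 16.0, and 25.0 ng/mL for the open top band) and IS%
at band representatives (0.5 / 0.05 / 0.005); downstream statistics depend
only on band membership. Two published figures are knowingly *not*
honored because they contradict the per-dose counts in the same source: a
sentence that swaps the two thresholds' pooled attainment (the fixture
follows the self-consistent per-dose counts, pooling to 27/38 at 10.7 and
10/38 at 21.3 ng/mL), and a "best-ever response" DMR figure of 20/38 that is
inconsistent with the per-occasion DMR counts (which sum to 15).

## Numerical choices

* Matrix exponential: compiled Padé scaling-and-squaring; amounts agree with
  a high-accuracy ODE integration to $10^{-6}$ relative and better.
* Steady state: fixed-point solve guarded by the trough-iteration
  convergence declaration ($10^{-6}$ relative, 60 doses; 1000 for the
  internal consumers named above).
* Exact tests: log-space probabilities; tie tolerance $10^{-7}$ relative on
  point probabilities; enumeration guard $10^{7}$ tables.
* MAP: L-BFGS-B, `factr 1e8`, 5 starts, box $\pm 5\omega$; non-convergence
  is flagged on the estimate, never silently replaced.
* Percentages display at 1 dp, half-away-from-zero; p-values display at
  3 dp; full precision is always carried alongside.
* Degenerate inputs fail with explicit messages (zero margins, unsorted
  times, offsets outside the interval, constant input to a rank
  correlation); an all-attain threshold column returns p = 1 with a
  degeneracy marker rather than an error.

## Problem sizes used by the checks

The reproducibility suite uses the 38-row fixture (seconds); the simulation
studies use 200 subjects for MAP recovery and for the single-sample rank
correlation, 2000 patients for generator calibration, 500 replicates for the
null-calibration of the 2x2 exact test through the generator, and 10,000
null replicates for the Kruskal-Wallis size check. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands.

## Known limitations

* The PK layer is linear: no nonlinear elimination, covariates, food or
  interaction effects; population parameters are configuration, not
  estimates (no SAEM/FOCE fitting).
* The published r x c p-values cannot be reproduced under any convention
  implemented (or, as far as we can tell, any standard one); both available
  conventions are reported instead.
* The decision engine is a faithful encoding of a published proposal, with
  the open points resolved as documented above; it is not a certified
  clinical decision-support system.
* Cohort-level concentration means are calibration anchors only; without
  the patient-level data they are not reproducible quantities.
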