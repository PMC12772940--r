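---
title: "Retrodicting medication adherence from TDM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrodicting medication adherence from TDM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

A steady-state trough concentration carries information about recent
dosing behavior because each missed dose removes one term from the
linear-pharmacokinetic superposition that builds the concentration. Over
the last $n$ scheduled doses there are $2^n$ dosing hypotheses
$\omega \in \{0,1\}^n$, written most-recent-first: the first digit
describes the last dose before sampling, `1` = taken, `0` = missed. Given
scenario priors $P(\omega_j)$ and Monte-Carlo-estimated conditional
densities $P(C\mid\omega_j)$, the posterior at an observed concentration
$C$ is

$$P(\omega_j \mid C) = \frac{P(\omega_j)\,P(C \mid \omega_j)}{P(C)},
\qquad P(C) = \sum_j P(\omega_j)\,P(C \mid \omega_j).$$

Everything else in the package is machinery around this identity:
simulating $P(C\mid\omega_j)$ honestly, locating the concentrations where
adjacent posteriors cross (discrimination thresholds), classifying how much
of the recent dosing history is recoverable, and propagating patient
covariates, priors and residual error through the answer.

## Pharmacokinetic model

Individual concentrations come from closed-form superposition over the
dose history: a one-compartment first-order-absorption (Bateman) term, a
one-compartment bolus monoexponential, or a two-compartment
tri-exponential with absorption. Parameters are apparent oral-dose
parameters (CL/F in L/h, V/F in L, Ka in 1/h, plus Q/F and Vp/F for the
peripheral compartment); units are fixed internally to h, mg, L, mg/L.
Population structure is standard nonlinear mixed effects:

* **Typical values** adjusted by multiplicative covariate relations, one of
  four closed forms — power $(x/x_{ref})^\theta$, proportional
  $1+\theta x$ (flags: comedication and formulation tags resolve to 0/1),
  linear $1+\theta(x-x_{ref})$, exponential $e^{\theta(x-x_{ref})}$ —
  applied in spec order. Restricting to these forms keeps model files
  statically validatable; free-text expressions are deliberately excluded.
* **Between-subject variability**: lognormal, $P_i = TV\,e^{\eta_i}$ with
  $\eta \sim N(0, \Omega)$, $\Omega$ built from per-parameter standard
  deviations and an optional correlation matrix (validated symmetric PSD,
  unit diagonal).
* **Residual error**: $C_{obs} = C_{pred}(1+\varepsilon_p) +
  \varepsilon_a$, truncated at 0. Defaults follow the idealized-simulation
  convention of minimizing residual noise: $\sigma_a = 0.01$ mg/L,
  $\sigma_p = 0.1\%$; both are user-adjustable because real assays are far
  noisier, and widening them is the correct response when an observation
  falls outside every scenario's support.

An independent Dormand–Prince RK5(4) integrator of the same mass-balance
ODE systems ships as a test oracle (`concentration_ode()`); the two code
paths share nothing and agree to $10^{-6}$ relative on randomized
parameter sets.

**Numerical guards.** The Bateman denominator vanishes when
$K_a = CL/V$; specs within $10^{-6}$ relative are rejected, within
$10^{-4}$ the spec-level $K_a$ is nudged by $10^{-6}$ relative, and the
evaluation kernel substitutes the exact $K_a \to k$ limit
$F D k t e^{-kt}/V$ for individual draws that collide. Missed doses are
amount-0 events, never deleted, so schedule indices always align with
scenario digits.

**Steady state** is reached by explicit run-in rather than analytic
steady-state formulas, so one code path serves every structure. The run-in
length is derived from the terminal half-life: at least
$\lceil 10\,t_{1/2}/\tau\rceil + 1$ doses *and* long enough that
consecutive pre-dose troughs differ by less than $10^{-4}$ relative (the
analytic geometric-tail criterion; the half-life rule alone misses the
$10^{-4}$ contract in edge cases such as $t_{1/2} = 10$ h, $\tau = 12$ h).
Sampling is one interval after the last considered dose slot — immediately
before the next scheduled dose — plus any user sampling offset.

## Monte Carlo simulation and density estimation

40,000 virtual patients per scenario by default. Common random numbers are
on by default: one draw bundle (etas and residual errors) is shared across
scenarios, and draws are blocked per individual so that enlarging the
cohort extends it without redrawing anyone — this pairs scenarios exactly
(sharpening thresholds), makes one-bit-flip monotonicity hold per patient,
and makes stability comparisons across cohort sizes meaningful. Run-in and
per-slot dose contributions are computed once and recombined per scenario.

$P(C\mid\omega_j)$ is a Gaussian kernel density on log-transformed
positive samples, back-transformed; all scenarios share one linear grid of
512 points on $[0, 1.1\times\max C]$. Samples at or below a quantitation
floor $\max(2\sigma_a, 10^{-3}\ \mathrm{mg/L})$ are carried as an explicit
probability atom at 0 — fully missed scenarios of rapidly eliminated drugs
concentrate there, and no finite density can represent that honestly. A
zero-variance sample (e.g. all omegas 0 with no residual error) becomes a
flagged point mass rather than an error. In Bayes' rule, atoms dominate
the continuous part wherever they match (a point mass has infinite density
relative to any continuous component); the atom at 0 matches any
observation at or below the floor.

**Bandwidth.** Silverman's rule is inflated by a factor of 2.5
(`bw_adjust`). Silverman bandwidths minimize pointwise density error near
the mode, but posterior curves depend on *density ratios* out to roughly
the 1% tails, where unadjusted bandwidths leave order-one Monte Carlo
noise — in development this flipped retrodiction labels between seeds and
made doubled-cohort curves disagree by far more than their bulk accuracy
suggested. Because every scenario's kernel is inflated equally, points of
equal density (the thresholds) are essentially unmoved; the cost is a few
percent of peak-height bias, irrelevant to ratios.

**Support masking.** Posterior curves are reported only where the
marginal, measured per unit *log*-concentration ($c \cdot P(c)$, the scale
the kernels live on and on which every scenario's density has comparable
height), exceeds $10^{-4}$ of its maximum. Below that level a 40,000-draw
cohort contributes less than one expected sample per bandwidth: the KDE
value there is pure tail extrapolation, and order statistics of the sample
extremes would otherwise hand the outermost scenario a posterior of 1 in
regions no data supports. Single-observation assessments are never masked;
an observation with zero marginal is reported as *undefined* with the
advice to raise the residual-error settings, not silently zeroed.

## Thresholds, taxonomy, assessment

The most-probable scenario is taken per grid column (ties broken toward
the lower bitstring — more missed doses — a deliberately conservative
choice); boundaries between adjacent runs of the resulting partition are
located by linear interpolation of the posterior difference between the
bracketing grid points. Crossings are defined on this partition (matching
how threshold ranges are quoted in practice); the full pairwise crossing
list is available for diagnostics. Scenarios never most-probable anywhere
are reported as absent; indistinguishable scenario sets yield a flagged
degenerate partition.

Retrodiction labels follow the 80% rule over scenario curves: *complete*
if every scenario's maximum posterior reaches the cutoff, *none* if at
most one does, *partial* otherwise. The rule is applied to scenario
posterior curves (not per-dose marginals), the reading consistent with the
taxonomy's illustrating panels; the cutoff is a parameter.

Priors: *equal* ($2^{-n}$, the maximum-uncertainty default), *per-dose*
(each dose independently taken with probability $p$, so
$P(\omega)=p^{\#1}(1-p)^{\#0}$ — the interpretation we adopt for
single-number prior sensitivity sweeps, since one percentage cannot
otherwise parameterize $2^n$ scenarios), or fully *custom* tables
(normalized).

## Sensitivity machinery

`sweep_factor()` re-runs the whole pipeline per factor level under one
root seed (common random numbers across levels) for eGFR, comedication
tags, dosing interval (at constant daily dose, emulating an
extended-release switch), sampling offset, per-dose prior and proportional
residual error. Threshold shifts are quoted against the lowest crossing —
the boundary of the fully-nonadherent region — by default, as
$(T - T_{ref})/T_{ref} \times 100$.

**The clearance-reciprocity regime.** A clearance multiplier $\theta$
(enzyme inducer > 1, inhibitor < 1) scales the average steady-state
concentration exactly as $1/\theta$, and therefore shifts thresholds by
approximately the reciprocal factor. For *troughs* the scaling is only
first-order: the log-threshold excess over $-\log\theta$ is approximately
$(\theta-1)\,k\tau\,(\ell - \tfrac12)$, where $\ell$ is how many intervals
before sampling the scenario's remaining doses sit. For mild interactions
($\theta = 1.2$) on a long-half-life drug dosed q12h this is ~1% for the
crossings among the terminal doses but ~2.5% for the lowest crossing
($\ell \approx 2\!-\!3$); for strong inducers ($\theta \approx 3$, the
carbamazepine-on-lamotrigine scale) the excess reaches tens of percent and
thresholds move *more* than reciprocally. The test suite asserts the
reciprocal law at its stated 2% band and documents that the lowest
crossing structurally exceeds it; the module-level check validates the
pipeline against the exact deterministic oracle (geometric means of the
closed-form scenario troughs) instead.

## The synthetic fixtures — what they do and do not establish

Published popPK parameter sets for the real drugs live in supplementary
tables outside this package, so all tests run on synthetic fixture models
generated in code (`generate_fixture_spec()`), chosen once to span the
regimes that drive the scientific findings and then frozen:

* `fast_clearance` — $t_{1/2}\approx 3.5$ h, moderate variability
  (ω = 0.25/0.15/0.50), 500 mg q12h: the rapid-elimination regime in which
  the concentration signal of doses more than ~2 intervals old is gone
  before sampling.
* `slow_clearance` — phenobarbital-like, $t_{1/2}\approx 120$ h with that
  drug's characteristically low variability (ω = 0.10/0.05/0.20), dosed at
  its clinically standard once-daily 100 mg: the persistence/low-noise
  regime in which deeper dosing history remains readable.
* `two_cpt` — generic two-compartment oral model (engine coverage).
* `with_covariates` — the slow base plus allometric weight scaling, an
  eGFR power relation and mild ±20% inducer/inhibitor comedication
  relations.

Under these worlds the suite computes: last-dose retrodiction *complete*
on both profiles; depth 2 *partial* on both; depth 3 *none* (fast) versus
*partial* (slow) — stable across seeds. A seed jitters fixture typical
values by 5% CV so distinct seeds give distinct, equally plausible drugs.

What a green suite does **not** establish: drug-specific numbers
(oxcarbazepine threshold values, lamotrigine shift percentages) — those
require transcribing the real parameter tables into model YAML, which the
format supports but the repository does not contain; behavior under
nonadherence patterns other than wholly missed doses (delays, partial
doses, double doses are out of scope); and real-data performance, since the
generator emulates the popPK *model* world (lognormal BSV, known
covariates, stationary regimen), not model misspecification, assay bias,
or within-subject parameter drift.

## Known limitations

* Posterior tails beyond the data-support mask are reported as undefined;
  with 40,000 virtual patients the far-tail behavior of near-degenerate
  scenario pairs (gaps ≪ BSV) is genuinely unresolvable and labels for
  them correctly fall to *none*.
* The threshold partition assumes the posterior curves cross transversally
  on the grid; crossings are linear interpolations between grid points
  (512-point grids make this sub-percent).
* Residual-error truncation at 0 slightly inflates the zero atom when
  $\sigma_a$ is large relative to predicted concentrations; at the default
  minimized RUV this is negligible.
* ER formulations are modeled as distinct specs (different Ka, longer
  interval), not as mechanistic release models.
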