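---
title: "Methods: the HIF-1α regulatory network model and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HIF-1α regulatory network model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hifnk)
```

This vignette explains the model the package implements, the choices made
where the design was genuinely open, and the numerical machinery behind
simulation and calibration. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model and its assumptions

The network couples ten normalized species: IL-15, activated AKT,
activated mTOR, free HIF-1α, HIF-1β, the HIF-1 complex, activated NF-κB,
phosphorylated STAT3, HIF-1α mRNA, and asparaginyl-hydroxylated HIF-1α
(HIF-1α-aOH). The structural assumptions are:

* IL-15 enters at a constant external rate `a1` and decays first-order
  (`d1`); stimulation of cultured cells is an *impulse* that raises the
  IL-15 state by the dose at the event time, so "primed" cells start at
  `y1 = 1`.
* IL-15 activates AKT, NF-κB and STAT3 through linear terms; STAT3 also
  feeds back on AKT through a Hill term with coefficient `n2 = 2`.
* mTOR is activated by AKT and inhibited by the HIF-1 complex through the
  rational factor `α1/(α2 + y6)` — the hypoxia→mTOR negative feedback.
* HIF-1α mRNA is produced by NF-κB (`k9`) and STAT3 (`k3`), translated at
  `kα`; free HIF-1α dimerizes reversibly with HIF-1β.
* Hydroxylation is oxygen-dependent (binding force `K_O2`): FIH sits at a
  fixed level `φ`, PHD at the quasi-steady level `Δ·y6 + a11`
  (upregulated by HIF-1, a negative feedback). Prolyl-hydroxylated
  HIF-1α is treated as instantly degraded and is not a state; HIF-1α-aOH
  can be de-hydroxylated at `k11` or further processed and degraded.
* Every species has a first-order basal decay.

Nuclear/cytoplasmic compartments, receptor trafficking, and the
JAK/STAT5 and Ras-Raf-MEK cascades are outside the model's scope.

Two conventions are worth flagging. `k11` is tabulated with
concentration-rate units but acts first-order in the equations
(`k11·y10`); the equations are implemented literally. Thresholds such as
`ξ28 = 38.44` nM are likewise used verbatim against normalized
(dimensionless) states, as in the published fit. One catalytic constant
is described in the source tables as PHD-mediated although it multiplies
the FIH level `φ`; we follow the equations, not the description.

## Treatments and their placement

The detailed mapping of pharmacology into the equations is not fully
specified by the published material, so the placement below is a design
decision of this package (each factor is an explicit input scale, so
alternative placements are a one-line change):

* **DMOG** (dose fraction `δ ∈ [0, 1]`, 1 ≡ 20 μM) scales the three
  oxygen-dependent hydroxylation fluxes by `1 − ρ6·δ`, linear in dose.
  It additionally reduces IL-15-mediated STAT3 activation by `1 − ρ4`,
  implemented all-or-nothing while DMOG is active; whether that effect
  should scale with dose is unknowable from the published material, and
  the all-or-nothing reading is the simpler one.
* **S3I-201** scales the entire STAT3 activation input by `1 − ρ3`.
* **Rapamycin** scales the mTOR activation input `(a3 + k2·y2)` by
  `1 − ρ_rapa`; **an NF-κB inhibitor** scales all NF-κB activation
  inputs by `1 − ρ_nfkb`. Neither efficacy is published; both default
  to 1 (complete inhibition) as an explicit assumption.

IL-15 events are impulses; all other agents are persistent conditions
where a later event for the same agent replaces the earlier dose.

## Steady-state consistency

Untreated cells are assumed to be at equilibrium, which (i) ties
`a1 = 0` and `d8 = k8`, and (ii) turns the right-hand side at the
reference state into ten algebraic constraints. Because the published
values are printed rounded to three decimals, the canonical reference
state satisfies those constraints only to about `1e-3`.
`solve_consistent_equilibrium()` restores exact consistency by Newton
iteration over a small slack set while holding the canonical
normalization (`y = 1` for the six normalized species,
`y4 + y6 + y10 = 1`) fixed. Counting equations shows that the basal
rates and the HIF split alone cannot absorb all ten residuals — four
equations constrain the two degrees of freedom of the split — so the
slack set is `{a2, a3, a5, a9, kα, d10, y4, y6}` with
`y10 = 1 − y4 − y6`. All resulting adjustments to the published values
are below 2 % (most below 0.3 %), i.e. within rounding. The adjusted
set is the package's reference parameterization, and the calibration
priors re-center on it.

The `a1` tie deserves a note: `a1 = 0` is the *published value* under
the equilibrium argument and `a1` is never a free calibration parameter,
but it is deliberately variable — the external-regulation sweeps raise
it to 10 nM/h — so only `d8 = k8` is enforced unconditionally.

For arbitrary parameter values (during calibration), the untreated
equilibrium `y0(p)` is re-solved in the state space by a damped Newton
iteration started from the canonical state, with non-negativity enforced
by step clipping and an integrate-then-polish fallback.

## Simulation

The right-hand side exists twice: a pure-R reference implementation and
a compiled C version used by `deSolve`; their agreement is a test.
Events are handled by restarting the integrator at each event time with
the new input scales (and the impulse applied), which keeps every solver
exact at discontinuities. The default integrator is `lsoda`
(stiff-capable, variable order/step) with `rtol = 1e-8`,
`atol = 1e-10`; the explicit Dormand–Prince pair (`ode45`) is the
independent second family, and the two agree on the observables to
better than `1e-5` in the tests. States that undershoot zero by less
than `1e-9` are clipped silently; larger undershoots clip with a
warning.

"Steady state" is operationalized as the 100 h endpoint plus a
convergence diagnostic (no component moving more than 0.1 % over the
final 10 h, with components below `1e-3` judged absolutely so that
species decaying exponentially to zero can converge). One genuine
feature of the published parameterization: after an IL-15 impulse the
slowest mode is IL-15 decay itself (`1/d1 ≈ 16` h) and its tail is
amplified strongly into total HIF-1α, so the 100 h snapshot of a primed
protocol is *not* yet converged — the diagnostic reports this — while by
250 h the stimulated and unstimulated endpoints agree to well under 1 %.

For the external-regulation sweeps the swept basal rate *is* the
perturbation: the initial state stays at the reference equilibrium and
is deliberately not re-solved per grid point. Sweeps re-use the 100 h
snapshot; failed grid points are recorded and skipped, not fatal.

## Calibration

The estimator minimizes

```
1/2 Σ_ij,ex [(η_ij − g_i(t_j))/σ_ij]²  +  1/2 Σ_m [(p_m − p0_m)/λ_m]²
```

over the free parameters (25 in the default configuration), subject to
the ties and the equilibrium initial condition `y0(p)`. The Tikhonov
scales are never published; the default `λ = 10·|p0|` keeps the prior a
weak stabilizer that the data dominate, while still selecting a unique
point along structurally non-identifiable directions (see below).
A zero or infinite scale disables a prior.

The solver is a generalized Gauss-Newton iteration with Armijo
backtracking (`t_k ∈ {1, 1/2, …, 2⁻¹⁰}`) on the full objective, so the
objective decreases monotonically across accepted steps; convergence is
declared when the damped step satisfies `‖Δp‖/(1 + ‖p‖) < 1e-8` *in the
original parameter scale* or no descent direction remains. Rates are
optimized as logarithms and efficacies as logits clamped to
`[1e-9, 1 − 1e-9]`; the clamp matters because one published efficacy
(`ρ3 = 1`) sits exactly on its boundary, where the logit-scale Jacobian
column vanishes. A tiny absolute damping (`μ = 1e-8`) on the internal
Gauss-Newton step regularizes such numerically dead directions without
touching informative ones. If no priors are active and the linearized
system is rank-deficient, the fit aborts with a pointer to
`identifiability_screen()`.

Two numerical choices are deliberate. Finite-difference Jacobians use a
step of `1e-3` in log/logit scale — a ~0.1 % parameter perturbation —
sized against the integration-noise floor of the residuals rather than
machine precision; a much smaller step drowns the weak prior signal
along flat directions in noise. Fitting-time integrations run at
`rtol = 1e-10`, `atol = 1e-12` so the line search can resolve objective
differences near the optimum.

**Multiple shooting.** In multiple-shooting mode the states at the
shooting nodes (default grid: the measurement times of each experiment)
become additional unknowns, measurements at node times read off the node
states directly, and continuity ("matching") conditions between adjacent
segments enter as equality constraints. Each linearized problem is
solved on the constraint null space (QR of the constraint Jacobian), a
merit function combining the objective and the constraint norm governs
the damping, and the covariance is formed on the null space. Single and
multiple shooting agree on the synthetic suite to `1e-4` relative in the
objective; the test uses a reduced free set (three parameters, two
experiments), a problem size chosen to exercise every code path of the
constrained iteration.

**Uncertainty.** Standard deviations come from the first-order
variance-covariance approximation `(JᵀJ)⁻¹` in the internal scale
(the generalized inverse on the constraint null space in
multiple-shooting mode), transformed by the delta method. These are
local, first-order statements; strongly curved valleys are reported
honestly as large standard deviations, not resolved.

**Identifiability.** The screen computes singular values of the
column-scaled sensitivity matrix (forward differences, relative step
`1e-6`, absolute floor `1e-8`, stepping backwards at an efficacy bound)
and greedily fixes the parameter with the largest weight in the smallest
singular vector until the smallest singular value reaches the 0.1
threshold. The greedy one-at-a-time rule is this package's
concretization of subset selection; the published material names the
threshold but not the algorithm. One structural fact the screen
reliably finds: with only total HIF-1α, STAT3 and AKT observed, scaling
`(k9, k3)` by a constant and `kα` by its inverse leaves every observable
unchanged (mRNA is unobserved and enters the observables only through
the product), so that triple is non-identifiable by data alone and only
the prior selects a point along the ray.

## The synthetic-data generator

The study's raw time series are not publicly deposited, so the package
generates measurements with exactly the statistical structure the
estimator assumes: observables evaluated on the true trajectory plus
independent additive zero-mean Gaussian noise with known per-point
standard deviation, negative values allowed (normalized densitometry
ratios can dip below zero). The default design mirrors the study
layout: ground truth is the consistency-adjusted published set; four
calibration experiments (IL-15; DMOG; IL-15 + DMOG + rapamycin;
IL-15 + DMOG + S3I-201) plus an IL-15 + DMOG validation experiment;
measurement times inside the 0–27 h observation window; 39 calibration
points in total (total HIF-1α at 2, 4, 6, 8, 12, 27 h and STAT3/AKT at
1 and 6 h per experiment, with one AKT point dropped from the S3I-201
arm to reach 39). The exact times and per-point standard deviations of
the original experiments are unknown; the defaults — in particular
`sd = 0.1` on the normalized scale, the order of the error bars in the
published figures — are documented stand-ins and fully configurable.
`noise_sd` can be set apart from the recorded weighting sd, e.g. to zero
for noise-free data with realistic weights.

What passing recovery tests do and do not show: they demonstrate that
the estimator recovers parameters when the model is *correct* and the
noise is independent Gaussian with known scale. Real densitometry data
bring correlated errors, normalization artifacts, donor-to-donor
variability and model misspecification, none of which the generator
emulates; recovery results therefore validate the estimation machinery,
not the biology.

## Problem sizes

The shipped tests and the acceptance script use: 1000 Monte Carlo
samples per robustness element (±25 % uniform); an 11-point grid for the
IL-15 supply sweep over [0, 10] nM/h and the dose–response over
[0, 100 %]; 20 seeded replicates for the noisy recovery study
(5 free parameters, start at 1.5× truth, ±2 sd coverage); and one
noise-free fit of the full 25-parameter free set from a 10 %-perturbed
start. These sizes were chosen once as adequate for the statistics they
feed and are not tuned to outcomes.

## Known limitations

* Quantities never observed (NF-κB, mTOR, mRNA) are meaningful only on a
  relative scale, and the `(k9, k3, kα)` ray is fixed by the prior, not
  the data.
* The covariance is first-order; profile likelihoods and second-order
  confidence regions are out of scope.
* The Gauss-Newton iteration is local; a multi-start policy (perturbed
  starts, as in `recovery_study()`) is the provided remedy, not global
  optimization.
* Figure-level aesthetics of the original study are not reproduced; the
  package emits tidy tables.
* The published text reports a two-to-three-fold DMOG/untreated
  steady-state ratio for the supply sweep; the exact comparison behind
  that number is not recoverable from the text, and the package reports
  both the baseline-relative and the matched-supply ratio curves rather
  than asserting one reading.
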