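# hifnk

Mechanistic modelling of HIF-1α accumulation in IL-15-stimulated natural
killer (NK) cells.

## The problem

NK cells respond to infection and cancer inside inflamed, frequently
hypoxic tissue. Their adaptation is orchestrated by the transcription
factor **HIF-1**, whose α-subunit is continuously hydroxylated by the
oxygen-dependent enzymes PHD and FIH and degraded under normoxia. Two
signals stabilize and enrich HIF-1α in NK cells:

* **chemical hypoxia** — the pan-hydroxylase inhibitor DMOG (a dose of
  100 % corresponds to 20 μM) blocks PHD/FIH activity; and
* **inflammation** — the cytokine IL-15, acting through AKT/mTOR, NF-κB
  and STAT3, raises HIF-1α transcription and translation.

`hifnk` implements a ten-state nonlinear ODE model of this regulatory
network, the published parameterization, and everything needed to use it
quantitatively: fast compiled simulation under arbitrary treatment
protocols, steady-state-consistent parameter handling,
constrained weighted-least-squares calibration, identifiability
screening, Monte Carlo robustness analysis, and a synthetic measurement
generator for parameter-recovery studies.

## The model

States are concentrations normalized to untreated cells at *t* = 0:
IL-15 (*y₁*), activated AKT (*y₂*), activated mTOR (*y₃*), free HIF-1α
protein (*y₄*), HIF-1β (*y₅*), the HIF-1 complex (*y₆*), activated NF-κB
(*y₇*), phosphorylated STAT3 (*y₈*), HIF-1α mRNA (*y₉*) and
asparaginyl-hydroxylated HIF-1α-aOH (*y₁₀*). The couplings, with
first-order turnover on every species:

    y1' = a1 − d1·y1
    y2' = a2 + k1·y1 + kS·y8ⁿ/(ξ28ⁿ + y8ⁿ) − d2·y2
    y3' = (a3 + k2·y2)·α1/(α2 + y6) − d3·y3                (HIF-1 feedback)
    y8' = a8 + k8·y3 + k6·y1 − d8·y8
    y7' = a7 + k7·y1 + k14·y6 + k15·y3 − d7·y7
    y9' = a9 + k9·y7 + k3·y8 − d9·y9
    y4' = kα·y9 − d4·y4 − k4·y4·y5 + k5·y6
          − k13·K_O2·(Δ·y6 + a11)·y4/(ξ44 + y4)            (PHD)
          − k10·K_O2·φ·y4/(ξ4 + y4) + k11·y10              (FIH)
    y10' = k10·K_O2·φ·y4/(ξ4 + y4)
          − k12·K_O2·(Δ·y6 + a11)·y10/(ξ10 + y10) − (k11 + d10)·y10
    y5' = a5 − k4·y4·y5 + k5·y6 − d5·y5
    y6' = k4·y4·y5 − k5·y6 − d6·y6

PHD is taken at quasi-steady state (level Δ·y₆ + a₁₁, upregulated by
HIF-1), FIH at the fixed level φ. Treatments act multiplicatively: DMOG
scales the three K_O2-bearing hydroxylation fluxes by 1 − ρ₆·dose and the
IL-15→STAT3 term by 1 − ρ₄; S3I-201 scales the whole STAT3 activation
input by 1 − ρ₃; rapamycin scales the mTOR input; an NF-κB inhibitor
scales all NF-κB inputs. IL-15 stimulation is an impulse on *y₁*.
The measured observables are total HIF-1α (*y₄ + y₆ + y₁₀*), STAT3 and
AKT. Untreated cells are required to sit at equilibrium, which ties
a₁ = 0 and d₈ = k₈ and yields ten algebraic steady-state constraints.

Calibration minimizes the weighted least-squares misfit plus a weak
Tikhonov prior by a damped generalized Gauss-Newton iteration, in single-
or multiple-shooting form (node states as unknowns under continuity
constraints), with parameter uncertainty from the constrained covariance
approximation and a collinearity-index screen (singular values of the
column-scaled sensitivity matrix, threshold 0.1) for identifiability.

## Worked example

```r
library(hifnk)

# published parameterization, made exactly steady-state consistent
eq <- solve_consistent_equilibrium()
round(eq$residual, 12)
#> [1] 0

# IL-15 priming at t = 0, DMOG from t = 6 h
tr <- hif_simulate(eq$params,
                   protocol_standard(il15_at = 0, dmog_at = 6, horizon = 30),
                   times = seq(0, 30, by = 0.5), y0 = eq$state)
tr
#> hif_trajectory: 61 time points over [ 0 , 30 ] h; 2 protocol event(s)
#>   final observables: total HIF-1a = 14.86  STAT3 = 1.449  AKT = 1

# which treatment timing maximizes HIF-1a at 12 h?
timing_experiment(eq$params, y0 = eq$state)
#>        protocol total_hif fold_change
#> 1     untreated      1.00        1.00
#> 2        il15_0      8.00        8.00
#> 3        dmog_0     14.61       14.61
#> 4 il15_0_dmog_0     17.83       17.83
#> 5        il15_6      8.22        8.22
#> 6        dmog_6     12.36       12.36
#> 7 il15_6_dmog_6     16.80       16.80
#> 8 dmog_0_il15_6     18.44       18.44
#> 9 il15_0_dmog_6     19.12       19.12

# robustness of the steady state to intrinsic noise in AKT activation
monte_carlo_robustness(eq$params, "a2", n = 200, seed = 1, y0 = eq$state)
#> Monte Carlo robustness: a2 +/- 25 % x 200 samples (seed 1)
#>   baseline steady-state total HIF-1a: 13.782
#>   relative spread: 0.264 %
#>   2.5-97.5% band: [ 13.75 , 13.816 ]
```

The timing table reproduces the study's central prediction: the largest
12 h fold change (19.1× untreated) needs IL-15 priming *first* and DMOG
6 h later, and the order of the two treatments matters (19.1 vs 18.4).

Calibration runs through `hif_fit()`:

```r
suite <- generate_calibration_suite(synth_design(seed = 1))
fit <- hif_fit(suite$calibration, hif_parameters(),
               pep_config(free = c("d1", "k6", "k9", "k3", "kalpha")))
summary(fit)      # estimates, standard deviations, objective split
plot(fit)         # fitted curves over the measurement points
```

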