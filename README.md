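# emuflux

Quantitative modeling of microbial metabolism in R: flux balance analysis and
¹³C metabolic flux analysis in one package, built around an elementary
metabolite unit (EMU) labeling engine with open solver contracts (dense LP,
quadprog QP, Levenberg–Marquardt least squares, and a small branch-and-bound
for the one mixed-integer problem).

For metabolic engineers and systems biologists, the package covers the
working loop of isotope-assisted flux analysis:

- **Reaction networks** with carbon atom transitions (`ReactionNetwork`,
  `C13ReactionNetwork`, `TwoScaleNetwork`), read/written as an SBML subset
  plus a plain-text atom-transition dialect, with a consistency validator
  (`carbonTransitionsOK()`).
- **Forward labeling simulation**: EMU decomposition and a size-partitioned
  linear cascade (`simulateLabeling()`), cross-checked against an exact
  brute-force isotopomer oracle (`bruteForceIsotopomerSimulate()`).
- **¹³C MFA**: variance-weighted least-squares flux fitting with null-space
  parametrization and multistart (`c13Fit()`), profile-likelihood confidence
  intervals (`c13FVA()`), attainable-labeling ranges for unmeasured
  metabolites (`elva()`), and two-scale fitting where a genome-scale
  stoichiometry constrains a carbon-mapped core (`twoScaleFit()`).
- **Constraint-based analysis**: `fba()`, `fva()`, knockout prediction by
  MoMA (`moma()`) and ROOM (`room()`), and carbon use efficiency for
  community flux models (`communityCUE()`).
- **Labeling data handling**: mass distribution vectors (`MDV`), an MS
  fragment database, and natural isotope-abundance correction by NNLS
  (`correctionMatrix()`, `correctMDV()`).
- **PCAP**: principal component analysis of proteomics with a
  production-titer overlay and target ranking (`pcapAnalyze()`,
  `rankTargets()`).

The model at the core of the ¹³C machinery: at isotopic steady state the mass
distribution vectors X_s of the unknown EMUs of size s satisfy the
flux-linear system A_s X_s = −B_s, where condensation inputs are Cauchy
products of smaller EMU MDVs; fitting minimizes
Σ_i ((m_i^obs − m_i^pred(v))/σ_i)² over {v : S v = 0, lb ≤ v ≤ ub} with one
bounded exchange parameter per reversible reaction.

## Worked example

The classic TCA-cycle toy model: acetyl-CoA and aspartate in, glutamate and
CO₂ out, feed 50% unlabeled / 25% [2-¹³C] / 25% [1,2-¹³C] acetyl-CoA.

```r
library(emuflux)

net <- tcaToyNetwork()                      # validated C13ReactionNetwork
fluxes <- tcaToyFluxes(v4 = 50, exchange6 = 50)

sim <- simulateLabeling(net, fluxes, targets = "glu_1_2_3_4_5")
sim[["glu_1_2_3_4_5"]]
#> MDV: m0=0.3464 m1=0.2695 m2=0.2708 m3=0.0807 m4=0.0286 m5=0.0039
```

This is the glutamate labeling pattern implied by the fluxes — the forward
problem. The inverse problem: generate noisy measurements at hidden "true"
fluxes (v4 = 37, exchange 12) and estimate them back with confidence
intervals:

```r
meas <- synthMeasurements(net, tcaToyFluxes(v4 = 37, exchange6 = 12),
                          fragments = c("glu_12345", "fum_1234"),
                          noiseSd = 0.01, seed = 42)
fit <- c13Fit(meas)
fit
#> FitResult: SSR 6.11252 over 11 measurements, 2 free fluxes, converged
round(netFlux(fittedFluxes(fit)), 3)
#>      v1      v2      v3      v4      v5      v6      v7
#> 100.000 100.000  63.624  36.376  36.376  36.376  63.624

fluxRanges(c13FVA(meas, fit, confidence = 0.95, reactions = c("v3", "v4")))
#>   reaction       lo     best       hi
#> 1       v3 58.91871 63.62445 68.51886
#> 2       v4 31.48114 36.37555 41.08129
```

The fitted v4 (36.4) sits within noise of the truth (37), the SSR is
consistent with the χ² expectation for 9 residual degrees of freedom, and the
95% profile-likelihood interval [31.5, 41.1] covers the true flux. (Fumarate
is measured alongside glutamate because the fumarate↔oxaloacetate exchange
flux is invisible to any metabolite downstream of the symmetric pool — see
the methods vignette.)

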