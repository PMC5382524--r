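---
title: "Methods: EMU-based 13C flux analysis in emuflux"
author: "emuflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMU-based 13C flux analysis in emuflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

# The modeling problem

Intracellular metabolic fluxes — the rates of the reactions of cellular
metabolism — cannot be measured directly. Two complementary strategies
estimate them from what can be measured. Constraint-based methods (flux
balance analysis, FBA) assume steady state, so that the stoichiometric matrix
$S$ annihilates the flux vector, $S v = 0$, and select a flux vector by
optimizing an objective over the bounded polytope
$\{v : S v = 0,\ lb \le v \le ub\}$. Isotope-assisted methods
(^13^C metabolic flux analysis, ^13^C MFA) feed the organism a
position-specific ^13^C tracer and infer fluxes from the resulting labeling
patterns of intracellular metabolites, measured by mass spectrometry as mass
distribution vectors (MDVs): the fractions of a fragment's molecules carrying
$0, 1, \dots, n$ labeled carbons. emuflux implements both, their combination
at genome scale (two-scale ^13^C MFA), knockout phenotype prediction (MoMA,
ROOM), and a statistical route from proteomics to engineering targets (PCAP).

# Forward labeling simulation with elementary metabolite units

The forward problem — given fluxes and a feed labeling, what MDVs result? —
is solved with the elementary metabolite unit (EMU) decomposition. An EMU is
a distinct subset of a metabolite's carbons (`pyr_1_2`, `pyr_2_3`, ...).
Starting from the target EMUs (the measured fragments) the engine walks each
reaction's atom transitions backward, mapping the target carbons onto the
reactant molecules; a reaction either transfers an EMU intact or condenses
two or more source EMUs into a larger one (citrate synthase condenses
`accoa_1_2` and `oac_2` into `cit_3_4_5`). The closure of this traversal is
the minimal set of EMUs whose balances must be solved.

At isotopic steady state the unknown EMU MDVs of each size $s$ satisfy a
linear system $A_s X_s = -B_s$: the diagonal of $A_s$ carries the negative
total production flux of each EMU, off-diagonal entries carry same-size
transfer fluxes, and $B_s$ accumulates the flux-weighted known inputs — feed
EMUs and convolutions (Cauchy products) of already-solved smaller EMUs for
condensations. Solving sizes in ascending order (the cascade) resolves all
dependencies; this is the production path. A fixed-point solve of the fully
coupled system, which never partitions by size, is kept as an independent
path and agrees with the cascade to $10^{-10}$ in the tests.

Three conventions matter:

* **MDVs include the unlabeled component.** An $n$-carbon fragment has an
  $(n+1)$-vector $m_0 \dots m_n$; normalization requires $m_0$.
* **Fluxes are stored as (net, exchange)** with
  $forward = exchange + \max(net, 0)$ and
  $backward = exchange + \max(-net, 0)$ — the standard decomposition; the
  exchange flux scrambles labeling without net conversion.
* **Symmetric molecules** (succinate, fumarate) are handled by duplicate
  atom-transition rows with equal fractional weights, one per indistinguishable
  orientation. This puts the scrambling where it physically happens — at every
  reaction producing the symmetric pool.

The diagonal of $A_s$ uses total *production* rather than consumption. The
two agree when $S v = 0$, but the production convention also gives correct,
normalized MDVs for metabolites whose consumption includes an unmapped drain —
exactly the situation two-scale MFA creates (below).

## The brute-force oracle

`bruteForceIsotopomerSimulate()` enumerates all $2^n$ positional isotopomers
per metabolite and solves the steady-state balances by damped successive
substitution, guarded to networks with $\sum_m 2^{n_m} \le 2^{16}$. It shares
no code path with the EMU engine beyond the network container, so agreement
(achieved at $\sim 10^{-14}$, asserted at $10^{-8}$) is a genuine
cross-validation, and the oracle — not any external package — is the ground
truth for every labeling number in the tests.

# The TCA toy model

The demonstration network is the classic minimal TCA cycle used to exercise
^13^C MFA tools: acetyl-CoA and aspartate in, glutamate and CO~2~ out, with
citrate synthase condensation, two decarboxylations, symmetric
succinate/fumarate chemistry and a reversible fumarate/oxaloacetate step. The
feed is 50% unlabeled, 25% [2-^13^C] and 25% [1,2-^13^C] acetyl-CoA with
aspartate unlabeled. Uptake is normalized to 100; the toy then has exactly
two degrees of freedom: the 2-oxoglutarate split `v4` and the `v6` exchange
flux. The fixture's default fixed fluxes (`v4 = 50`, exchange 50) are
representative values for the demonstration; since labeling depends only on
flux ratios, nothing downstream depends on the absolute scale.

## An identifiability subtlety

Working through the symmetric-pool algebra shows that the oxaloacetate
labeling is $x_{oac} = (V s + A u)/(V + A)$ — with $V$ the net flux from
fumarate, $A$ the aspartate input, $s$ the (already symmetrized) fumarate
labeling and $u$ the unlabeled aspartate — *independent of the exchange
flux*. Every metabolite downstream of oxaloacetate, glutamate included, is
therefore blind to the `v6` exchange: it is structurally unidentifiable from
a glutamate measurement alone. Fumarate's own MDV does respond to exchange
(it mixes in oxaloacetate-derived, aspartate-diluted molecules). The
parameter-recovery and interval-coverage studies consequently measure both
`glu_12345` and `fum_1234`; the fixed-flux demonstration keeps the
traditional glutamate-only setup.

# Fitting fluxes to labeling data

`c13Fit()` minimizes the variance-weighted sum of squared residuals
$\sum_i ((m_i^{obs} - m_i^{pred}(v)) / \sigma_i)^2$ over the balanced,
bounded flux space. The parametrization follows the null-space approach: the
equality system ($S v = 0$ plus every bound with $lb = ub$) yields a
particular solution and an orthonormal null-space basis $N$, so
$v = v_0 + N\theta$; each reversible reaction adds one exchange parameter in
$[0, 100]$ (the default bound is configurable; reported standard deviations
are floored at 0.003, typical MS precision, to avoid zero-weight divisions).
Levenberg–Marquardt handles the least squares with hinge-penalty residuals
keeping net fluxes inside their bounds, restarted from 10 uniform samples of
the flux polytope (hit-and-run in $\theta$-space from a slack-maximizing
interior point; uniform draws for exchanges). The best SSR wins; equal-SSR
optima differing by more than $10^{-3}$ in any flux flag the fit degenerate.

Confidence intervals (`c13FVA()`) are profile likelihood: a flux is
compatible with the data when re-minimizing the SSR with that flux pinned
stays within $\chi^2_{1,\alpha}$ of the best fit (one degree of freedom per
profiled flux, the standard construction). Endpoints are found by bisection
inside the stoichiometrically attainable range, warm-started by projecting
the best fit onto the pinned space. In the simulation study (noise
$\sigma = 0.01$, 50 replicates) the 95% intervals cover the true free flux at
the nominal rate (observed 0.94).

`elva()` answers the complementary question: how much can the labeling of an
*unmeasured* EMU still vary across flux vectors the measurements accept? It
explores the SSR confidence region by directional boundary search (random
directions from the best fit, doubling plus bisection to the SSR threshold)
and reports attainable min/max per mass fraction. As a sampling method its
ranges are inner approximations; on the test toys they reach the analytic
extremes within 0.02.

# Two-scale analysis

`twoScaleFit()` keeps the labeling simulation on the carbon-mapped core while
the *genome-scale* stoichiometry constrains the flux space: the null-space
parametrization is built from $S_{gs}$, and core fluxes are read off the
genome-scale vector (summing lumped sets where a mapping is given). With
core = entire network this is plain ^13^C MFA (tested to $10^{-3}$); adding a
fixed biomass drain shifts the balancing core flux by exactly the drain,
which is the point of embedding the core in a genome-scale model — drains to
biomass are represented explicitly instead of being approximated away.

# Knockout predictions and community carbon use

MoMA solves the strictly convex QP
$\min \lVert v - v^{ref} \rVert^2$ s.t. $S v = 0$, bounds, $v_{ko} = 0$;
ROOM minimizes the *count* of reactions leaving the window
$v^{ref} \pm (\delta |v^{ref}| + \epsilon)$, a small mixed-integer program
solved exactly by branch-and-bound over the binary change indicators with
big-M constraints from the flux bounds. The defaults $\delta = 0.03$,
$\epsilon = 0.001$ are the thresholds of the original ROOM formulation.

For community flux states, `communityCUE()` computes the carbon use
efficiency $CUE = C_{bio} / (C_{bio} + C_{CO_2})$, each term a net flux times
the carbon atoms delivered to excreted products. The soil-community fixture
is a deliberately small glycolysis + pyruvate-oxidation lump with the two
carbon sources and position-specific tracer pairs used in soil incubation
studies ([1-^13^C]/[U-^13^C] glucose, [1-^13^C]/[2,3-^13^C] pyruvate).
Its biomass drain branches from acetyl-CoA — not pyruvate — because the CO~2~
routes then release *different* carbon positions (C1 via decarboxylation,
C2/C3 via oxidation), which is what makes position-specific tracers
informative about the biomass diversion at all.

# Natural-abundance correction

Measured envelopes include mass contributed by naturally occurring heavy
isotopes of every atom outside the measured carbon backbone (derivatization
carbons, H, N, O, Si, S). `correctionMatrix()` convolves the standard
isotope-abundance mass-shift distributions of the non-backbone composition
into an envelope, builds the column-stochastic matrix whose column $m$ is the
envelope shifted by $m$ backbone labels (truncated to the measured masses),
and `correctMDV()` inverts it by nonnegative least squares — NNLS rather than
a triangular solve so that measurement noise cannot produce negative
fractions. With all abundances set to 1 at mass shift 0 the correction is the
identity, and forward-generated envelopes invert to machine precision. The
abundance table ships in code and can be overridden per call. Note that
simulation (`simulateLabeling()`) deliberately uses the feed exactly as
specified with no natural-abundance envelope — correction belongs on the
measured-data side.

# PCAP

`pcapAnalyze()` is PCA on the column-centered, by default unit-variance
scaled protein abundance matrix (log transform available but off by default,
since the synthetic design generates already-comparable abundances), with the
sign of each component fixed by making its largest-magnitude loading
positive. `rankTargets()` picks the component whose scores correlate most
with production and orders proteins by loading magnitude, reporting the sign
so "increase" versus "decrease" recommendations are explicit; both the score
overlay and the correlation route are available since either may be wanted.
The synthetic generator mirrors a combinatorial pathway-engineering design
(27 strains by default, a 3×3×3 factor structure) with a planted set of
informative proteins; passing tests show the planted signal is recovered,
not that any particular real proteomics study would be.

# What the generators do and do not emulate

All tests and the acceptance script run exclusively on generated fixtures:
small networks (≤ 10 reactions) with exact arithmetic oracles, Gaussian
measurement noise, and planted ground truth. Real ^13^C MFA data adds model
mismatch (incomplete atom maps, compartmentation, channeling), correlated
measurement error, and natural-abundance effects upstream of the correction;
recovery at $10^{-4}$ on the toys demonstrates correctness of the machinery,
not expected accuracy on experimental data. Problem sizes in the shipped
studies — 20 random flux vectors for the oracle comparison, 20 noiseless
recovery truths, 50 noisy replicates for interval coverage — were chosen as
the smallest designs that make the corresponding statements statistically
meaningful.

# Numerical choices

* Steady-state tolerance on inputs: $\max |S v| \le 10^{-6}$; solved MDVs are
  normalized and nonnegative to $-10^{-12}$.
* The coupled solve iterates to $10^{-14}$ sweep-to-sweep change.
* LP backend: the dense simplex from pracma behind a wrapper that shifts
  variables to nonnegativity and expands equalities; its random pivot
  tie-breaking runs under isolated fixed seeds with retry, so all LP results
  are deterministic.
* QP (MoMA): quadprog's dual active-set method. MILP (ROOM): depth-first
  branch-and-bound, most-fractional branching, $10^4$ node budget (the toys
  need a handful).
* Profile bisection tolerance $10^{-4}$ in flux units; fitting runs
  Levenberg–Marquardt with `ftol` $10^{-15}$ so noiseless recovery reaches
  the $10^{-4}$ assertion with orders of magnitude to spare.
* Degenerate inputs: empty networks give 0×0 matrices; infeasible or
  unbounded LPs, lethal knockouts, singular (zero-throughput) EMU systems,
  undefined CUE and degenerate-variance PCA all raise classed conditions
  naming the offending object.

# Known limitations

Steady-state labeling only (no isotopically nonstationary MFA); carbon
isotopes only (no ^2^H/^15^N tracking); reaction-level knockouts (no
gene–protein–reaction logic); the SBML reader covers the constraint-based
subset (no kinetic laws, events or rules); ELVA ranges are sampling-based
inner bounds; and the brute-force oracle is limited by design to networks
small enough to enumerate.
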