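---
title: "Methods: sequential mixture and response-surface optimization of rAAV production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential mixture and response-surface optimization of rAAV production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavdoe)
```

## Overview

`aavdoe` optimizes three responses of an rAAV triple-transfection process
— log volumetric productivity Log(Vp) = log10(titer/time) in
log10(vg·mL^-1·day^-1), the full-capsid percentage
(100 × genome titer / capsid titer), and cell viability (%) — over two
factor spaces explored sequentially:

1. the **plasmid simplex**: mass fractions of pHelper, pRepCap and pGOI,
   each constrained to [0.10, 0.60], summing to 1, at a fixed total DNA of
   2 µg/mL and a 1:1 DNA:FV reagent ratio;
2. the **DNA/FV square**: total DNA and the FV-to-DNA ratio on the coded
   [-1, +1] scale of a face-centered central composite design (FCCD),
   with the plasmid ratio fixed at the stage-1 optimum.

The sequential split assumes the plasmid-ratio effect and the
dose/reagent effect are separable enough that optimizing them in turn
loses little; the simulator encodes exactly this assumption (see below),
so pipeline tests validate the machinery, not the separability of any
particular cell line.

## Designs

**Candidate lattice.** The constrained simplex is discretized at a
0.05 fraction step (default), the granularity at which plasmid ratios are
realistically pipetted and reported. Candidates are every lattice
composition inside the bounds; enumeration is exact and ordered
lexicographically, so candidate sets are reproducible byte-for-byte.

**D-optimal selection.** Runs are chosen to maximize log |X'X| for the
Scheffé quadratic model matrix (6 terms for 3 components). The search is
a Fedorov point exchange: from a random start, every (design point,
candidate) swap is tried and the best strict improvement (> 1e-10 in
log-determinant, ties to the lowest candidate index) is accepted until a
full pass yields none; 10 random restarts guard against local optima, and
an integer seed makes the whole search deterministic. Selection is a
subset without replacement while the run count does not exceed the
candidate count — an exchange over subsets is exactly comparable to
exhaustive subset enumeration, which the tests use as an oracle up to
C(12, 6) — and replicates candidates beyond that. The default of 13 runs
is the smallest design leaving a comfortable 7 residual degrees of
freedom for the 6-term model's ANOVA.

**FCCD.** Four factorial corners, four face centers and n_center = 3
center replicates (11 runs), coded -1/0/+1 per factor. The decode map is
affine with decode(0) at the factor midpoint; default actual ranges are
DNA 1–3 µg/mL (centered on the mixture stage's 2 µg/mL) and FV ratio
0.5–2 (centered on 1:1). These ranges are configuration inputs, not
constants of the method. Internally all model columns use the centered
±1 coding; `coded_to_unit()` is provided only for displays that label the
same limits from 0 to 1.

## Models and inference

The mixture stage fits the intercept-free Scheffé quadratic; because
compositions sum to one, the constant is implicit in the linear blending
terms and β_i is the expected pure-blend response. The FCCD stage fits
the full second-order polynomial (intercept, linear, quadratic,
interaction; 6 coefficients for 2 factors). Both are ordinary least
squares; rank deficiency is reported with the names of the collinear
terms rather than silently dropping them.

Whole-model significance is an F test of the mean-corrected partition
(df_model = p − 1, df_residual = n − p) for both families — for the
Scheffé model this is the standard mixture-analysis convention, and it is
the partition under which the test holds its nominal 5% type-I rate,
which the acceptance suite verifies by simulation (1000 pure-noise
responses on the default designs). Saturated fits return their table with
the p-value explicitly marked undefined instead of erroring. Coefficient
confidence intervals are t-based from σ²(X'X)⁻¹; their 95% empirical
coverage is likewise simulation-checked.

## Desirability optimization

Each response is maximized through the one-sided desirability
d = 0 below L, ((y−L)/(T−L))^r between L and T, 1 above T. Defaults: r = 1
for every response (linear credit is the neutral choice consistent with
giving the three responses equal weight), L and T auto-scaled to the
minimum and maximum prediction over the explored region — optimization is
relative to what the design space can deliver, not to absolute
specifications. The overall score is the geometric mean D = (∏ dᵢ)^(1/k),
so any response at its floor vetoes the point.

The optimizer scans a dense feasible grid (step 0.02 on the simplex,
0.05 on the coded square — profiler granularity) and polishes the best
grid point with Nelder-Mead on the region's free coordinates (the simplex
is charted by (x1, x3)), capped at 200 iterations, with infeasible
proposals penalized; the polished point is kept only if feasible and
better. With `top = m` the scan instead ranks distinct grid-local maxima
(no better neighbor within 1.5 grid steps, separated by at least 3 steps)
and polishes each — this is how conflicting-objective landscapes report
two operating points. A region where D = 0 everywhere is returned with a
flag, distinct from an empty feasible region, which errors.

Threshold-region masks reproduce profiler-style maps: per grid point, a
pass flag per response (prediction ≥ threshold) and their conjunction,
the "white area" where all responses clear their thresholds.
`equal_weight_thresholds()` inverts the desirability at a common level —
threshold = L + (T−L)·level^(1/r) — so the contour drawn at the same
d-level for every response weighs them equally.

## The synthetic generator

`make_archetype()` returns fixed, published coefficient sets (optionally
jittered ±1% under a seed) for three gene-of-interest archetypes:

* **egfp_like** — Log(Vp) increases with pHelper/pRepCap and decreases
  with pGOI while viability moves oppositely; % full peaks away from
  both.
* **msh2_like** — all three responses peak together where pRepCap is at
  its 60% bound and pHelper = pGOI, so the combined optimum is exactly
  0.2:0.6:0.2.
* **bdnf_like** — Log(Vp) and % full gradients oppose each other, and the
  viability surface is a saddle built directly in the (pHelper, pGOI)
  simplex chart: convex along the Log(Vp)↔%-full trade-off axis (carving
  a low-viability valley between the two candidate operating points) and
  concave across it. This makes the combined desirability genuinely
  bimodal, so the top-2 optimizer returns two points that rank oppositely
  on Log(Vp) vs % full.

The constructor self-verifies these constitutive properties (directional
derivatives at the centroid, Hessian indefiniteness, argmax location,
responses within [0, 100] over the feasible region) and refuses to return
an archetype violating them.

The two-stage truth is additive: response(x, z) = Scheffé(x) + (RSM(z) −
RSM(0,0)), so the FCCD center reproduces the mixture surface exactly and
optimizing the second stage can only improve the zero-noise optimum —
the cleanest self-consistent encoding of the sequential strategy.
Simulated runs add Gaussian noise (defaults σ = 0.1 log10 units for
Log(Vp), 2 percentage points for % full and viability, consistent with
replicate-level scatter of titer and viability assays), clip % full and
viability to [0, 100] (events counted in an attribute), and back-compute
raw titers (vg_titer = 10^Log(Vp) × time at a fixed 2-day harvest;
capsid_titer = vg_titer × 100 / % full with a 1e-3 assay floor) so the
derived responses round-trip exactly through the measurement formulas.

What the generator does **not** emulate: mechanistic transfection or
packaging biology, non-Gaussian or heteroscedastic assay error,
plate/batch effects, harvest-time kinetics, or any real GOI's effect
sizes — surface steepness is a package choice. Passing tests therefore
demonstrate that the designs, fits and optimizer recover what quadratic
landscapes of this character encode, not that any particular cell line
behaves this way.

## Pipeline conventions

`run_pipeline()` chains the stages and hands the mixture optimum to the
FCCD **exactly** (no re-rounding). When a measured run table contains
multiple harvests per run, the default rule keeps the harvest with the
highest Log(Vp) together with its paired % full and viability
(configurable to keep all rows). The report always evaluates the
unoptimized reference condition — 1:1:1 plasmid ratio at the DNA/FV
center — through the same fitted models, and fold improvements are
10^(ΔLog(Vp)) for productivity and plain ratios otherwise, so reported
gains are model-consistent rather than mixing measured and predicted
values. Reports are deterministic given the config seed; design matrices
are hashed into the log so reruns are verifiable.

% full values above 100 are physically impossible (genome titer cannot
exceed capsid titer); the reader and `pct_full()` return them but flag
them, since discarding them would hide a measurement inconsistency the
scientist must resolve.

## Problem sizes and runtime choices

Simulation-based checks run at sizes chosen to keep the full suite fast
while leaving Monte-Carlo error well inside the asserted bands: 1000
replicates for the type-I rate and interval coverage, 100 replicate
studies for noisy optimum recovery, 20 random 12-point candidate sets for
the exchange-vs-enumeration oracle, and 100 random coefficient draws for
the exact-recovery round trips. The noisy-recovery check uses the
default 13-run design with single observations per run — the spirit of
the workflow's run budget — which is why its median error is quoted in
grid cells (2 cells = 0.04 in fraction units) rather than as a
convergence claim.

## Known limitations

* Only 3-component mixtures are exercised (the model-matrix builder is
  generic, but bounds, charts and tests assume the three-plasmid system).
* D-optimality only; no I- or G-optimal criteria.
* One-sided (larger-is-better) desirability only; target-is-best shapes
  are out of scope.
* The exchange search guarantees monotone improvement and matches
  exhaustive enumeration at oracle-checkable sizes, but global optimality
  at production sizes rests on the 10-restart heuristic, as in standard
  DoE software.
* Plotting is intentionally absent: region masks and grids export as
  data frames/CSV for the user's preferred graphics layer.
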