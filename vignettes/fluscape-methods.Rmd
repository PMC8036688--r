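---
title: "Methods: scenario land-use simulation and ecosystem-service valuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario land-use simulation and ecosystem-service valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fluscape` implements a four-stage chain for asking how land-use change under
policy scenarios reshapes the monetary value of ecosystem services in a
rapidly urbanising region: (1) Markov projection of per-class land demand,
(2) neural-network suitability surfaces coupled to a cellular automaton (CA)
that spatially allocates the demand, (3) equivalent-factor valuation of the
resulting mosaics, and (4) bivariate spatial-autocorrelation analysis of
trade-offs and synergies between service categories. Because studies of this
kind rarely deposit their interpreted rasters, the package is built around a
seeded synthetic-landscape generator: every stage can be validated against a
planted ground truth, and the whole chain runs end to end on generated data.

## Land-use representation

Maps are categorical rasters with six classes (1 cultivated, 2 woodland,
3 grassland, 4 water, 5 built, 6 unused) and 0 for nodata; the cell edge
length (default 30 m, the usual Landsat-derived product resolution) is
carried as metadata and drives all area computations.

## Markov demand

`estimateTransition()` row-normalises the cross-tabulation of two snapshots;
classes unobserved at the first date keep identity rows. `projectDemand()`
applies the matrix power to the latest class counts and rounds by largest
remainder so the projected demand is integer and conserves the active-cell
total exactly — the CA needs integer targets, and any other rounding rule
either loses cells or changes a class by a full cell more than necessary.

How published scenario demands are derived from a Markov baseline is usually
left unstated; the package makes its convention explicit and configurable:
`applyScenarioDemand()` floors the protected classes (cultivated; or
woodland + water) at their last observed counts and takes any deficit out of
built-land demand proportionally. This reproduces the qualitative ordering
such studies report — protection scenarios damp built-land growth — while
keeping the total conserved; infeasible floors raise an error rather than
silently rescaling.

## Suitability network

The suitability of each cell for each class is a single-hidden-layer network
(sigmoid hidden units, softmax output) over the driver layers, so each
cell's six probabilities are non-negative and sum to one by construction;
the normalisation is applied as an output-stage softmax because the
probability-sum condition is a constraint on the output, not a mechanism of
the hidden layer. Drivers are min–max rescaled to [0, 1] before training.

Defaults — 12 hidden units, 20·(classes)·(drivers) training cells sampled
uniformly per class, 200 full-batch steps — are exposed in the
configuration. Training uses resilient backpropagation (iRprop-): its
sign-based per-weight steps make the fit insensitive to gradient scale, and
the `lr` argument is the initial step (0.01). Two reproducibility
guarantees matter downstream: the fit is bit-identical under a fixed seed,
and it is invariant to the order the training set was assembled in, because
rows are canonically sorted before the seed-derived shuffle. On planted-logit
landscapes the held-out one-vs-rest AUC averages above 0.8 — the planted
rule is softmax-linear in the drivers, so this measures optimisation quality
rather than model capacity.

## Cellular automaton

Per iteration and cell, the combined probability of class $k$ is

$$\mathrm{TProb}(p,k) = sp(p,k)\;\Omega(p,k)\;\mathrm{Inertia}_k\;(1 - sc_{c \to k})$$

with $sp$ the suitability, $\Omega$ the share of the 8 Moore neighbours
holding $k$ (window fixed at 3×3) scaled by a per-class weight
$\omega_k$ (default 1), and $sc$ a conversion-cost matrix in [0, 1] whose
diagonal is 0 and where 1 forbids a conversion. The natural-evolution
default costs 0.5 off-diagonal; protection scenarios forbid conversion out
of the protected classes. Out-of-bounds and nodata neighbours count zero,
so borders genuinely see fewer neighbours.

The adaptive inertia coefficient of a class is unchanged while its absolute
demand gap does not worsen, is boosted by $D^{t-1}/D^{t-2}$ under a
worsening undershoot, damped by $D^{t-2}/D^{t-1}$ under a worsening
overshoot, and clamped to $[10^{-3}, 10^{3}]$; a zero previous gap counts as
ratio 1. The published typesetting of this rule is ambiguous about its case
boundaries; the implemented form is the canonical one that provably pushes
allocation toward demand.

Allocation resolves by roulette-wheel selection: each convertible cell draws
a candidate class with probability proportional to its scores (all-zero
scores keep the current class), in a visitation order re-randomised each
sweep to avoid raster-order artifacts. A change is accepted only while the
candidate class is under its demand and the source class is over its own.
This demand gating — the accounting detail such models usually leave
unstated — makes every class's absolute gap non-increasing across sweeps, so
convergence to within `tol` (default 0.1% of active cells) is monotone;
frozen cells (constraint mask 0) and nodata never change, and demand below a
class's frozen count is rejected as infeasible up front.

Validation uses overall accuracy, Cohen's kappa (defined as 1 when two
constant maps agree, where chance agreement is total) and the
four-component Pontius figure of merit $B/(A+B+C+D)$, which the package
defines explicitly since the literature often names it without defining it:
A missed change, B correctly-placed change, C change to the wrong class,
D false alarms.

## Equivalent-factor valuation

The regional unit value is $E = \tfrac{1}{7}\sum_i m_i p_i q_i / M$ over the
regional crop statistics (sown areas $m_i$, prices $p_i$, yields $q_i$,
total area $M$); the 1/7 factor is the convention that unmanaged ecosystems
deliver one seventh of farmed food-production value per unit area. The
package ships the published regional coefficient table (11 services × 6
classes, 100 yuan·hm⁻²·yr⁻¹, negative entries allowed for built-land sinks)
keyed by class *name*, because the source table orders its grassland and
woodland columns against this package's class codes. Note a unit
inconsistency in the source statistics: applying the formula to the printed
crop rows gives E ≈ 1729 yuan/hm² (reading the yield column, labelled
10⁴ t, as t/hm² — the only dimensionally coherent reading), which does not
reproduce the source's printed 127.32 yuan/hm² under any consistent unit
choice. The package implements the formula literally and does not
reverse-engineer the printed value; the shipped coefficient table itself is
used as published.

`computeEsv()` is the linear form $\mathrm{ESV} = \sum_k A_k V_{ck}$;
`computeUesvGrid()` aggregates to an analysis grid (default 1 km) assigning
cells by block membership (centroid rule) and normalising each grid unit by
the member area actually present, so irregular edge units are comparable.
UESV surfaces are classified into five levels by Jenks natural breaks,
implemented as Fisher's dynamic program — exactly optimal in within-class
variance, verified against exhaustive partition search in the tests.

## Trade-offs and synergies

Category UESV surfaces are compared pairwise with Pearson correlation and
bivariate Moran's I on queen-contiguity, row-standardised weights (GeoDa
conventions). With population (1/n) z-scores $z^x, z^y$:
global $I = \tfrac1n \sum_i z^x_i (Wz^y)_i$ and local
$I_i = z^x_i (Wz^y)_i$; the population standardisation is what makes the
mean of the local statistics equal the global index exactly. The
widely-quoted claim that $I \in [-1, 1]$ is stated as-is in the
documentation; the implementation does not clip, since extreme weight
configurations can exceed the interval slightly.

Significance uses conditional permutation: per cell, the other locations'
values are permuted (999 by default), and the two-sided pseudo p-value is
$(\#\{|I^{perm}| \ge |I^{obs}|\} + 1)/(n_{perm}+1)$. Whether the original
analyses were one- or two-sided is typically unstated; two-sided on $|I|$
is the default here, and its type-I error is verified at 0.05 ± 0.02 on
independent fields. Significant cells are labelled HH/LL (synergy) or
HL/LH (trade-off) by the quadrant of $(z^x_i, (Wz^y)_i)$; the pair report
tabulates all six unordered pairs of the four categories.

## Synthetic landscapes

The generator emulates the statistical structure the chain assumes, not any
real terrain: smooth fields are Gaussian-filtered white noise with kernel
width `corrLength` (only spatial autocorrelation is needed, not
geostatistical fidelity); slope and aspect come from finite differences of
the DEM analogue; socioeconomic layers are further smooth fields; and at
least three Euclidean distance-to-point layers stand in for the
distance-to-town/highway/railway/water drivers. Class membership follows a
planted softmax-linear rule in the drivers (coefficients row-centred so no
class dominates in expectation; scale 3 gives moderate separability) with
optional majority-filter contagion; the second date evolves each cell
independently under a sticky (diagonal 0.85) transition matrix with an
urbanisation drift (inflow to built tripled, inflow to cultivated damped to
a fifth) mirroring the monotone built-land growth and cultivated-land loss
of rapidly urbanising prefectures. Constraint masks grow contiguous frozen
patches inside the protected classes by randomised flood fill — a purely
structural analogue of rasterised basic-farmland and reserve polygons.

What passing on these landscapes shows: the estimators recover planted
transition matrices and suitability patterns, the allocator meets demand
under constraints, and the statistics are calibrated. What it does not
show: behaviour under class imbalance more extreme than the generator's,
real terrain anisotropy, registration error between dates, or classified
imagery's spatially correlated label noise.

## Problem sizes and numerical choices

Recovery tests use 256×256 maps (transition recovery, 3-standard-error
bands per entry), 64×64 for the suitability and end-to-end runs, and
32×32 with 999 permutations for the significance calibration — sizes at
which every statistical check has the power it needs while a full suite run
stays interactive. The scenario orchestrator derives all stage seeds from
one master seed through fixed named offsets, which is what makes a bundle
reproducible byte for byte (checksummed in its manifest). Degenerate inputs
are defined, not left to fall through: identical constant maps have kappa 1,
a changeless figure-of-merit triple returns 0 with a warning, all-zero
roulette scores keep the current class, a zero previous demand gap counts as
inertia ratio 1, and constant layers rescale to all zeros.

## Limitations

Allocation is strictly cell-based (no patch-growing or multi-resolution
moves); the Markov chain is spatially unstratified; valuation coefficients
are annual, fixed in time and not discounted; spatial weights are limited to
contiguity on the analysis grid; and raster I/O uses the plain-text ESRI
ASCII grid format, one band per file.
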