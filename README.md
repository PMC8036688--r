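# fluscape

Scenario-based land-use change simulation and ecosystem-service valuation.

Rapidly urbanising regions face a three-way tension between economic
development, food production and ecological protection. A standard way to
quantify it is to project land-use change under alternative policy
scenarios, value the resulting land mosaics in monetary terms, and map where
ecosystem services reinforce or undercut each other. `fluscape` implements
that full chain as a tested R package:

1. **Markov demand** — estimate the 6×6 land-class transition matrix
   $P_{ck} = \Pr(k \text{ at } t_1 \mid c \text{ at } t_0)$ from two
   categorical rasters and project per-class cell demand
   $D = n_{t_1} P^s$, then bend it to a scenario (natural evolution,
   cultivated-land protection, ecological protection) by floor-and-rebalance
   rules.
2. **Suitability + CA allocation** — train a single-hidden-layer neural
   network on spatial drivers (DEM, slope, aspect, GDP, population,
   distance layers) to get per-cell class probabilities $sp(p,k)$ with
   $\sum_k sp(p,k) = 1$, then allocate demand with a cellular automaton
   whose combined probability is
   $\mathrm{TProb} = sp \cdot \Omega \cdot \mathrm{Inertia}_k \cdot (1-sc_{c\to k})$
   ($\Omega$: 3×3 Moore-neighbourhood share; adaptive inertia from demand
   gaps; conversion costs and constraint masks per scenario), resolved by
   roulette-wheel competition under demand gating.
3. **Valuation** — equivalent-factor ecosystem-service value
   $\mathrm{ESV} = \sum_k A_k V_{ck}$ with a packaged 11-service × 6-class
   regional coefficient table (100 yuan·hm⁻²·yr⁻¹), aggregated to an
   analysis grid as UESV = ESV/S and classed into 5 Jenks natural-break
   levels.
4. **Trade-offs and synergies** — Pearson correlation and bivariate
   global/local Moran's I between service-category surfaces on
   queen-contiguity weights, with conditional-permutation significance and
   HH/LL (synergy) vs HL/LH (trade-off) LISA labels.

Simulated maps are validated with overall accuracy, Cohen's kappa and the
Pontius figure of merit. A seeded synthetic-landscape generator provides
planted ground truth (drivers, logit class rule, true transition matrix,
constraint masks, crop statistics), so every stage is verifiable without
proprietary rasters. See `vignettes/fluscape-methods.Rmd` for the models,
conventions and their rationale.

## Worked example

```r
library(fluscape)

cfg <- scenarioConfig("cultivated_protection", seed = 42)
cfg$association$nPerm <- 199L          # permutations for the LISA report
bundle <- runScenario(cfg)             # synthetic 64x64 landscape end to end

bundle$transition
#> TransitionMatrix (period 10 yr):
#>            cultivated woodland grassland  water  built unused
#> cultivated     0.8673   0.0142    0.0379 0.0221 0.0506 0.0079
#> woodland       0.0044   0.8767    0.0573 0.0220 0.0264 0.0132
#> ...

rbind(demand = bundle$demand, simulated = classCounts(bundle$simulated))
#>           cultivated woodland grassland water built unused
#> demand           569      413       922   552   776    864
#> simulated        569      413       922   552   776    864

bundle$metrics
#>                       metric     value
#> 1 overall_accuracy_t1_vs_sim 0.9589844
#> 2            kappa_t1_vs_sim 0.9498240
#> 3            figure_of_merit 0.7744966

head(bundle$pairReport[, c("pair", "pearson", "moran_i", "synergy", "tradeoff", "ns")], 3)
#>   pair   pearson    moran_i synergy tradeoff ns
#> 1  p-r 0.4267662 0.04392007       6        9 49
#> 2  p-s 0.5306560 0.28879078      22        9 33
#> 3  p-c 0.4978428 0.17980940      12        9 43
```

Reading the output: the estimated transition matrix is sticky (diagonals
~0.84–0.88) with an urbanisation drift; the CA hits the scenario demand
exactly (gap 0 for every class); agreement between the observed second date
and the simulation is high (kappa 0.95) with a figure of merit of 0.77 for
the changed cells; and the pair report shows mostly synergistic
(positive-correlation, HH/LL-dominated) relations between provisioning and
the other service categories on this landscape, with scattered trade-off
cells. With `outDir =` set, `runScenario()` writes the maps (ASCII grids),
CSV reports and a `manifest.json` with parameter values and file checksums;
rerunning with the same seed reproduces the bundle byte for byte.

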