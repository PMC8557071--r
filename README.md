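# cellforest

Lineage-forest analytics for bacterial single-cell movies.

Time-lapse microscopy of growing micro-colonies, after segmentation and
tracking, yields thousands of per-frame, per-cell measurements: lengths,
areas, fluorescence, mother–daughter links. `cellforest` organises that
tracker output into two tree representations and builds a complete analysis
stack on top of them, for microbiologists studying single-cell growth
stochasticity, lineage inheritance, and persister-like subpopulations:

* **FLT** (forest of lineage trees): one node per *cell instance* (a cell at
  one frame); tree levels are movie frames, with a synthetic master root and
  one synthetic root per colony, so the instance at frame *f* sits at level
  *f* + 2.
* **FDT** (forest of division trees): each lifespan collapsed to one node;
  levels are generations (progenitors = generation 0 at level 3), nodes carry
  *life attributes* (birth/division times, interdivision time, per-attribute
  min/max/mean/sd, fitted growth parameters).

On these it provides:

* constraint-based subpopulation selection (AND of atomic constraints,
  OR via node-set union, mean ± k·sd outlier flagging);
* per-cell growth fits *y* = *y*₀·e^(*kt*) (or linear) by nonlinear least
  squares, with the population curve ȳ = ȳ₀·e^(k̄t) and its variance band
  ȳ± = (ȳ₀ ± s²ᵧ₀)·e^((k̄ ± s²ₖ)t);
* Baranyi–Roberts colony growth curves in log₁₀ cell counts,

  y(t) = log₁₀N(max) + log₁₀[(−1 + e^(μλ) + e^(μt)) / (−1 + e^(μt) + e^(μλ)·10^(log₁₀Nmax − log₁₀N₀))],

  with lag λ (h) and maximum specific growth rate μ (1/h); colonies that
  never grow, or never reach a plateau, are flagged rather than forced;
* maximum-likelihood fits of Normal/Gamma/Lognormal to any life attribute,
  BIC model selection with ΔBIC on Jeffreys' scale, and the dominant-family
  rule across generations or colonies;
* kin-pair enumeration (siblings, cousins, mother–daughter,
  grandmother–granddaughter) with per-generation Pearson correlation and
  regression of life attributes;
* tracking-error QC (motherless-branch reports with ranked candidate
  mothers, RMSE and rate-of-change anomaly detection) and explicit tree
  surgery (`extractBranch()` / `addBranch()`) to repair missed divisions;
* a seeded agent-based micro-colony simulator with generation-indexed or
  lineage-inherited Gamma growth parameters, plus a corruption tool that
  injects lost-division errors with ground truth — so the whole pipeline is
  testable without imaging data;
* radial forest plots, density-binned scatter plots with regression
  line/plane, violin/box/pdf-overlay group summaries; every plotting
  function returns the statistics it draws.

## Worked example

```r
library(cellforest)

sim <- simulateMovie(simConfig(seed = 1, nProgenitors = 4, nFrames = 80))
flt <- buildFLT(sim$cells)
flt
#> LineageForest (FLT): 282 cells / 3149 instances in 4 colonies; node count 3154
#>   frames: 80 @ 5 min; generations 0.. 9

fdt <- computeLifeAttributes(flt, buildFDT(flt, minLife = 5,
                                           requireComplete = TRUE))
fits <- fitGrowthForest(flt, "length", "exp")
populationGrowthSummary(fits[fits$cell_id %in% cellTable(fdt)$cell_id, ])
#> Population exponential growth (68 cells):
#>   k_mean = 0.7464 /h   k_var = 0.1575
#>   y0_mean = 1.627     y0_var = 0.1455

bestFitAuto(cellTable(fdt)$division_duration)
#> BIC model selection — best: lognormal
#>   normal    BIC =     736.37  dBIC =    57.32  (decisive)
#>   gamma     BIC =     691.38  dBIC =    12.33  (decisive)
#>   lognormal BIC =     679.05  dBIC =     0.00  (best)
```

The population's mean elongation rate is 0.746 per hour with variance 0.158
across cells — single cells of the same colony differ strongly in their
growth kinetics — and the interdivision time is best described by a
lognormal law (ΔBIC 57 against a symmetric normal), with mean 68.7 min and
standard deviation 43.1 min under the fitted parameters.

Tracking-error QC and repair:

```r
bad <- corruptTracking(sim$cells, 3, seed = 7)   # sever 3 division links
fltBad <- buildFLT(bad$cells)
listMotherless(fltBad)                           # 3 branches + candidate mothers
repaired <- repairLostDivisions(fltBad, bad$log)
forestIdentical(flt, repaired)
#> [1] TRUE
```

A thin command-line wrapper over the same functions lives in
`inst/scripts/forest-tools.R` (`convert`, `simulate`, `corrupt`, `qc`,
`export` subcommands).

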