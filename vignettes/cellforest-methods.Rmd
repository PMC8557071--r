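---
title: "Models and methods behind cellforest"
author: "cellforest authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cellforest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellforest)
```

# The data model

A *single-cell movie* is a time-lapse of growing bacterial micro-colonies
that image analysis has reduced to per-frame, per-cell measurements. The
canonical interchange object, `CellList`, stores one record per tracked
cell: colony, mother link, a contiguous 1-based frame range, and one value
per frame for each numeric/boolean attribute. Frames are 1-based and the
time of frame *f* is (*f* − 1)·Δt minutes, so *t* = 0 at movie start.
Validation is total: non-contiguous frames, attribute series of the wrong
length, duplicate ids, and mother links that do not end exactly one frame
before the daughter's birth are each rejected with the offending cell named.
A *missing* mother is legal — it marks a frame-1 progenitor or an unresolved
track — whereas a mother id that names no record is an error; the two cases
carry different information and are never conflated.

Two tree views are built from a `CellList`:

* the **FLT** keys nodes by (cell, frame). A synthetic master root (level 1)
  parents one synthetic colony root per colony (level 2); the instance at
  frame *f* is at level *f* + 2. Edges join consecutive instances of a cell
  and a mother's last instance to each daughter's first. Node count is
  therefore Σ lifespans + #colonies + 1, an identity asserted on every
  simulated movie in the tests.
* the **FDT** collapses each retained lifespan to a node at level
  generation + 3, generations counting from 0 at the progenitors.

Cells appearing after frame 1 without a resolved mother root *motherless
branches*. These are stored apart from the main forest, with full structure
(they may contain divisions), because they are exactly the signature of a
lost-division tracking error — or of a cell entering the field of view — and
must be inspectable and re-attachable atomically.

Internally both forests are S4 objects wrapping two plain tables (per-cell,
per-instance) rather than a general graph structure: every operation the
package performs — selection, per-lifespan reduction, count tallies, surgery
— is a table operation with the tree implicit in the mother links, and this
keeps a 100 000-instance movie comfortably fast in plain R. `igraph` is used
at the boundary, for GraphML export; the test suite also uses igraph
shortest-path depths as an *independent* check of the level conventions.

## Filters when building the FDT

`minLife` (default 5 frames) drops cells tracked too briefly for any
per-cell fit to be meaningful; `requireComplete` additionally drops every
cell with no recorded daughter — a trajectory that ends without an observed
division is incomplete whether it ends at the last movie frame or
mid-movie (a lost track). Excluding a cell orphans its FDT descendants;
re-rooting them would fabricate ancestries, so they are dropped and
reported, each with a reason (`short_life`, `incomplete`, `orphaned`).

## Interdivision time convention

`division_duration` counts (last − first + 1) frames by default
("inclusive"): the division falls between the last observed instance and the
next frame, and with the +1 the durations of successive generations tile the
movie exactly — visible in the deterministic simulator test, where a
30-minute doubler yields durations of exactly 30 min. The convention is a
genuine choice the data cannot settle, so an "exclusive"
((last − first)·Δt) variant is available as an argument.

# Branch surgery

`extractBranch()` detaches the subtree under any instance — splitting a
lifespan when the site is mid-life — and `addBranch()` glues a branch under
a target instance, requiring frame continuity (root frame = target frame
+ 1). When the branch root starts a *different* cell, the target must be its
cell's last instance, because a mother–daughter edge leaves a last instance
by construction; re-attaching a split-off fragment of the same cell
re-merges the lifespan. Generation and colony labels are recomputed after
every surgery rather than stored immutably, since an attachment changes all
downstream generations. The extract-then-add round trip is the identity
(structure and attributes), property-tested at 100 random sites.

# Growth models

**Single cells.** Exponential elongation *y* = *y*₀·e^(*kt*) is fitted per
cell by Levenberg–Marquardt least squares (`minpack.lm::nls.lm`,
residual-function interface; the formula interface mis-steps when a start
value is exactly 0, as happens for constant series). Time is converted to
hours internally so *k* is always per hour; the start comes from the
log-linear regression, which is already exact on noiseless data. Cells with
fewer than 3 points or a failed solve are reported, never silently dropped.
Solver acceptance includes the gradient-orthogonality convergence code,
which is what the solver returns at a numerically perfect fit.

**Population.** The average curve uses the means of (*y*₀, *k*) over
converged fits and the band offsets use their *sample variances* — the
printed convention in this field even though a standard deviation would be
dimensionally conventional; `band = "sd"` provides the alternative.

**Colonies.** The Baranyi–Roberts three-phase curve is fitted to log₁₀ cell
counts. All logarithms of the count terms are base 10: under that reading
the curve's limits are exactly log₁₀N₀ at *t* → 0 and log₁₀Nmax at
*t* → ∞ (unit-tested numerically), which fails under a natural-log reading.
μmax stays in natural-log units (1/h), the slope of ln *N* in the
exponential phase. Initialisation: first value, max value, steepest
ln-count slope, and the first sustained-increase time for λ. Two failure
modes are detected rather than fitted through: a count range below one
doubling ("never grew" — single-cell persister colonies), and a fitted
plateau far above the observed data ("no stationary phase" — a colony still
in exponential growth). Both return `converged = FALSE` with the reason.

# Stochasticity

Normal and Lognormal are fitted by closed-form MLE (variance denominator
*n*; the descriptive life-attribute `sd` uses *n* − 1 — the two conventions
are deliberate and documented at both sites). Gamma uses shape–rate — so the
mean is α/β, matching the standard formula table — via Newton iteration on
the shape score equation log α − ψ(α) = log x̄ − mean(log x) to 1e-10 from
the moment start; an installed general-purpose optimiser is used only as an
independent oracle in the tests. BIC = −2·loglik + 2·ln *n* (two free
parameters per family). `bestFitAuto()` keeps every family the data domain
allows, selects the minimal BIC, and reports ΔBIC with Jeffreys-scale
annotations (> 5 strong, > 10 decisive). Across groups, the *dominant*
family is the one most often within ΔBIC ≤ 5 of the winner; ties break by
the smallest mean ΔBIC (the tie rule is this package's choice). The printed
"standard deviation" expressions circulating for Gamma (α/β²) and Lognormal
((e^{σ²} − 1)e^{2μ+σ²}) are variances, so `distMeanSd()` returns mean, true
sd, and variance, all labelled. A minimum of *n* = 8 observations is
required — below that a two-parameter MLE is numerically legal but
scientifically meaningless.

# Kin correlations

Pairs are enumerated on the FDT: siblings share a mother (possible from
generation 1), cousins share a grandmother but not a mother (from
generation 2); mother–daughter and grandmother–granddaughter pairs are
ordered ancestor → descendant. Same-generation pairs are unordered, so
`pairStats()` symmetrises them — each pair enters as (a, b) and (b, a) —
making Pearson's r and the regression slope orientation-invariant (swapping
every pair is a no-op, which is tested); `n_pairs` still counts unique
pairs. Cross-generation regressions are descendant-on-ancestor. Groups with
fewer than 3 pairs report NA together with their count.

# Error QC

QC never repairs; it reports, and surgery is explicit. `listMotherless()`
ranks candidate mothers for each stored branch by a transparent
equal-weight score over three signals: a track ending exactly one frame
before the branch starts, an abrupt relative drop of length/area at that
transition, and (when centroids exist) spatial proximity. Candidates are
searched over the whole movie including *other* stored branches, because
cascaded errors can detach a true mother too. `detectBadFits()` flags
non-converged cells plus RMSE above a threshold, with `auto` proposing
mean + 2·sd of the converged RMSEs — an explicit histogram-tail heuristic,
since no principled universal threshold exists. `detectRocAnomalies()`
flags |normalized rate of change| above a percent threshold; the rate of
change is a forward difference per lifespan that never crosses a division
boundary.

# The simulator

`simulateMovie()` is an agent-based generator of the data the package
analyses, and the ground truth for its tests. Each cell elongates
exponentially with its own rate *k* and divides at the first sampled frame
where its true length reaches its drawn division threshold (a sizer rule —
chosen as configurable ground truth, not as a biological claim); daughters
receive L/2·(1 ± ε) with one asymmetry draw per division, and observed
lengths carry multiplicative lognormal measurement noise.

Default conditions emulate a multi-colony *S.* Typhimurium movie: 5-minute
frames, 8 progenitors, elongation rates Gamma(shape 3.026, rate 4.520) per
hour, division lengths Gamma(shape 10.666, rate 3.474) μm, progenitor birth
lengths Normal(1.907, 0.522) μm, 2% measurement noise — the parameter scale
such movies yield when fitted. A drawn division threshold at or below the
cell's birth length can never trigger; it is *redrawn* from the same
distribution (truncated-draw semantics). An earlier design replaced such
draws with a deterministic doubling of the birth length, which silently
correlated sibling parameters through their shared birth size and violated
the independence the generation-indexed mode promises; redrawing keeps
daughters' parameters independent, with the deterministic fallback only
when twenty redraws fail.

Two inheritance modes set how daughters obtain parameters:
`"generation"` draws each daughter independently from her generation's
distribution; `"lineage"` draws one family value per division centred on
the mother's value (relative noise `inheritLineSd`) and perturbs it per
daughter (`inheritSibSd`), so siblings share a draw up to small noise and
cousins share a grandmother's value through two line steps — producing the
sibling-above-cousin correlation ordering that inheritance-strong colonies
show. Note that in lineage mode selection favours fast-dividing lineages,
so colonies grow markedly faster than the per-cell means suggest; test and
script movie lengths are chosen so the cell cap is not reached.

One seeded RNG stream drives a simulation (and a separate one drives
`corruptTracking()`); the same seed reproduces the movie exactly, and the
caller's RNG state is left untouched. Per-cell derived streams were
considered and rejected: they add bookkeeping without strengthening any
testable contract here.

What the simulator deliberately does *not* emulate: cell–cell mechanics,
spatial packing and crowding, nutrient depletion, lag phase, segmentation
noise other than multiplicative length error, and colony merging. Tests
passing on simulated movies therefore validate the analytics' correctness
on clean lineage data, not robustness to every real-world imaging artifact.

# Problem sizes and numerical choices

The test suite runs on movies of roughly 40–150 frames and up to a few tens
of thousands of cells; the structural invariants are checked across 50
seeds, surgery at 100 random sites, BIC family recovery at *n* = 5000 over
100 replicates per family, and kin-correlation nulls at ≥ 10⁴ sibling
pairs. The elongation-rate recovery study samples at 2-minute frames so
that essentially no lifespan is too short to fit; at 5-minute sampling the
unavoidable exclusion of 1–2-frame lifespans visibly truncates the fast
tail of the recovered rate distribution — a selection effect of the
measurement design, not of the estimator. Observed division lengths of
littermates are right-censoring-coupled (both must fit inside the movie),
so independence checks are run on the *drawn* parameters from the ground
truth; the observed-value coupling is real and worth knowing about when
interpreting kin correlations near the end of any finite movie.

Division triggering uses a 1e-9 relative tolerance so an exactly-configured
threshold (division at precisely one doubling) fires on the intended frame
despite floating-point rounding. Nonlinear solvers run with cost tolerances
of 1e-12 and bounded parameters where bounds are physical (λ ≥ 0, μ > 0).
Boolean life attributes reduce by strict majority with ties resolved to
FALSE and flagged — conservative for flags like "touching other cells".

# Known limitations

* Colony labels inherit from progenitors; movies whose tracker re-labels
  colonies after merges are handled, but colonies that physically merge are
  still treated as independent trees by the Baranyi fits.
* The CSV adapter covers long-format exports; binary tracker outputs must
  be converted to CSV/JSON upstream.
* `plotScatter3`'s figure is a static perspective rendering; the fitted
  plane statistics, not the image, are the tested product.
* The dominant-family tie rule and the `auto` RMSE threshold are documented
  heuristics, not inferences; both are exposed as parameters.
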