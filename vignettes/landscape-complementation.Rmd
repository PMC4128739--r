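---
title: "Methods: landscape complementation from telemetry to movement needs"
author: "landcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape complementation from telemetry to movement needs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures implemented in `landcomp`,
the assumptions behind them, the parameters that matter and why their
defaults are what they are, and the places where a genuinely open design
choice had to be made. It states no numerical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The scientific question

Landscape *composition* (how much of each cover type a landscape holds) and
landscape *configuration* (how those covers are arranged) can vary
independently. For a species that needs several non-substitutable habitats —
a nest in open shrubland, a shaded day roost in pinewood, foraging sites on
roads and open ground — configuration controls *landscape complementation*:
whether an individual can link all required resources with short daily
movements. The package's central experiment holds composition nearly fixed
(usable fractions of 60.9% versus 74.1%) while contrasting a clumped
configuration against an interspersed one, and measures the consequence as
the summed distance from each nest to the nearest roosting and foraging
habitat.

## Synthetic landscapes

Real vegetation maps and telemetry for such a study are rarely released, so
the package generates both study plots with known ground truth. The raster
representation (10-m cells by default) was chosen over polygons because
every downstream quantity — areal fractions, Moran's I on aggregated blocks,
nearest-habitat distances — is grid-computable, testable against brute
force, and free of heavy geometry dependencies. All coordinates are metres;
the origin is the lower-left corner; cell centres sit at
`origin + (index + 0.5) * cell_size`.

### Clumped ("natural reserve") configuration

Each non-dominant functional class is grown as at most five contiguous
blobs by multi-seed frontier accretion: seeds are placed uniformly on
unclaimed cells and the class repeatedly annexes a random subset of its
4-neighbour frontier until the target cell count is met. Because every
annexed cell touches the already-grown set, contiguity is guaranteed; blobs
may merge, which only lowers the patch count. The number of seeds per class
is derived from a characteristic patch diameter (`patchScale`, defaults
2,000 m for non-usable and 1,000 m for roosting/foraging at full plot size),
capped at five. If a class gets boxed in, it re-seeds while under the cap
and otherwise retries with fresh seeds before declaring the composition
infeasible. The dominant class (shrubland, 47.5%) is the background.

### Interspersed ("managed property") configuration

The managed plot is a regular parcel mosaic (100-m parcels), mirroring an
intensively managed agricultural property of regularly shaped blocks. Three
deliberate structural choices matter:

* **Non-usable parcels are placed by uniform sampling without
  replacement.** The usable/non-usable field is therefore *exchangeable* at
  the parcel scale: aggregated to parcel-aligned blocks, its Moran's I
  follows the randomization null exactly, which is the defining property of
  an interspersed landscape. Unaligned random squares would straddle
  aggregation blocks and induce spurious autocorrelation that grows with
  the number of blocks — with thousands of blocks, even slight straddling
  makes Z-scores of a "random" mosaic significant, contradicting the very
  contrast the design needs.
* **Roosting habitat forms compact plantation blocks** (about 14 parcels
  each) grown on the usable mosaic.
* **Foraging habitat is tied to the blocks**: narrow road strips along two
  sides of each block (15% of the foraging budget, 1 cell deep) and whole
  crop parcels converted from the breeding remainder adjacent to the blocks
  (the rest), both dealt round-robin so that essentially every block has
  foraging habitat at its edge. This juxtaposition — roads and crops
  serving the plantation blocks — is what makes nest-to-roost and
  nest-to-forage distances co-vary positively in the interspersed plot:
  both distances are driven by the same "distance to the nearest block"
  field. Without it (foraging placed independently of roosting), the two
  nearest-distance fields are independent by construction and their
  correlation is near zero, not positive.

Remaining usable parcels are breeding remnants, which lands the breeding
fraction on its 14% target without further adjustment.

### Structural layer and telemetry

`attachStructuralLayer()` refines the four functional classes into ten cover
typologies. Typologies are assigned per 100-m tile (stands and segments, the
way real cover maps look), except typologies named in `linear_typologies`
(default `"road"`), which take the *thinnest* cells of their class — those
with the fewest same-class neighbours — because roads and paths run along
patch margins and block rims. Tile-coherence is not cosmetic: with
independent per-cell assignment, a 35-m positional error relocates every fix
onto an effectively random typology and typology-level selection becomes
unrecoverable in principle.

`simulateIndividualFixes()` emulates one tracked breeder: one nest placed on
a patch-interior breeding cell (about 20 m in), two day roosts on
woodland-interior cells (about 50 m in, drawn from the few hundred roosting
cells nearest the nest, i.e. a few stands), and foraging fixes on foraging
cells with an exponential distance decay (800 m scale) around the nest. A
fixed share of foraging fixes (default 31%) falls on the road typology.
Positional error is isotropic Gaussian: 35 m per axis for triangulated
fixes and 3 m for road fixes, which in the field protocol are GPS-recorded
sightings of road-sitting birds. The distinction is essential: with 35-m
error on 10-m road cells, road selection would be statistically invisible.
The default behaviour mix (20% nest, 30% roost, 50% forage at 50 fixes per
bird) reflects a season of day and night tracking sessions.

`generateAbundanceSeries()` provides the paired weekly transect counts for
the abundance comparison: negative-binomial counts (size 8) around
`rate × 10 km × seasonal effect`, with a lognormal weekly effect (σ = 0.5)
shared by the two plots so that weeks are properly paired. The default
rates, 1.1 and 1.6 birds/km, are the package's realistic choice for a
nocturnal insectivore counted along roads; only their contrast matters
downstream.

## Home ranges

`estimateUD()` evaluates the equal-weight mixture of isotropic bivariate
normal kernels (per-axis standard deviation `h_m = 200`) on a 25-m grid
padded four bandwidths beyond the fix bounding box. The kernel is separable,
so the surface is a product of two one-dimensional Gaussian design matrices
— no per-cell summation over fixes. With 4σ padding, the probability mass
truncated off-grid is below 10⁻³, so cell sums integrate to 1 within that
tolerance without renormalization, and the grid is anchored so a cell centre
falls exactly on the bounding-box corner (which is what makes the
closed-form single-kernel checks exact). Individuals with fewer than five
fixes are refused — too few to represent a home range. The 95% isopleth for
`volumeContour()` is the field's convention; the home range is the smallest
set of highest-density cells reaching the level, which makes enclosed mass
minimal by construction. The bandwidth is deliberately not estimated:
200 m is the design value, and least-squares cross-validation is out of
scope.

## Habitat selection and the functional map

Availability is the cover-type distribution of landscape cells inside the
home-range mask; use is the distribution of reported (error-containing) fix
locations of one behaviour. `selectionTest()` computes the Pearson
goodness-of-fit χ² against expected-under-random-use counts and, per cover
type, an Agresti–Coull interval at the Bonferroni-adjusted level
`1 − (1 − conf)/k` for the k available types. Agresti–Coull was chosen over
Goodman's simultaneous multinomial intervals as the simplest add-z²
interval consistent with per-type calls; the family level is configurable.
A type is *selected* when availability falls below the interval's lower
limit — the direction that makes roads (under 1% available, around a third
of foraging locations) come out selected. Types used despite zero
availability are flagged selected and excluded from the χ².

`buildFunctionalMap()` pools individuals. For foraging, an individual backs
a typology when its table calls it selected. For nesting and roosting the
package also accepts a *placement* vote: a typology holding at least a
quarter of the behaviour's locations. Two reasons. First, nests and day
roosts are directly observed sites in the field protocol, not statistical
inferences. Second, the use-versus-availability test is intrinsically
underpowered when the habitat class dominates the home range (shrubland at
~50% availability in the natural plot, pinewood at ~55% in the managed
plot): a 100%-used habitat available at 60% cannot clear a simultaneous
confidence limit at realistic fix counts, so a purely CI-based rule would
fail to recover even a perfectly clean signal. A typology is assigned when
backed by a strict majority of tested individuals, or by at least two
individuals (`secondary_min`) — the latter covers secondary habitats used
consistently by a minority, such as crop plantations foraged in by some
birds only; a single individual's call never defines a class. Conflicts go
to the behaviour with the highest vote share; exact ties and never-backed
typologies become non-usable.

## Configuration: Moran's I

`aggregateToBlocks()` reduces the functional map to the usable fraction per
100-m block (partial edge blocks dropped); `globalMoransI()` computes the
global statistic with binary rook contiguity (queen available), not
row-standardized, and the analytical variance under the randomization
(permutation-moment) null by default, the normality null optionally. The
weight scheme is recorded in the result because the original GIS
implementation of such analyses rarely documents its conceptualization;
printed I/Z values from any particular GIS run are therefore not exactly
reproducible, and the package treats the *contrast* (clumped Z ≫ 1.96,
interspersed |Z| < 1.96) as the meaningful output. The permutation
consistency of the analytical p is verified in the test suite against 999
physical shuffles.

## Movement needs

`simulateNests()` rejection-samples nest points uniformly within breeding
cells under the 50-m minimum-spacing constraint (territorial spacing), with
a whole-pass restart if a pass exhausts its attempt budget — simple,
reproducible, and adequate far from the packing limit. Whether nests should
be spread per patch or globally across all breeding habitat is not
determined by the study design; global uniform sampling is implemented.
`nearestHabitatDistance()` is the exact Euclidean distance transform
(computed by `EBImage::distmap` and verified cell-for-cell against
brute-force minimization in the tests), consistent with the assumption that
commuting flights are straight minimum-length routes. `costDistance()`
generalizes to least-cost geodesics on the 8-connected grid (igraph
shortest paths; step length times mean cell cost, diagonal steps √2
longer); with uniform cost it matches the Euclidean transform within the
8-connectivity metric bound of `1/cos(π/8) − 1 ≈ 8.24%`. Movement needs are
evaluated at the nest's containing cell without interpolation — positional
refinement below one cell is meaningless given 10-m cells.

## Comparison statistics

All comparison statistics are implemented in closed form and cross-checked
against independent fits in the tests:

* `poissonRateComparison()` — the two-group log-link Poisson regression has
  closed-form MLEs (the group means); the Wald standard error is
  `sqrt(1/ΣA + 1/ΣB)`. Applying Poisson score equations to continuous
  metre-scale distances is a quasi-likelihood device inherited from the
  study design, not a distributional claim; with distances in the hundreds
  of metres the resulting standard errors are extremely small and the
  p-values should be read accordingly (the effect size, a distance ratio,
  is the meaningful quantity).
* `bootstrapPearson()` — percentile intervals over paired resamples (BCa
  was considered and rejected as a less direct reading of "bootstrap
  correlations"); degenerate zero-variance resamples are redrawn.
* `fisherZDifference()` — the standard z test for two independent
  correlations, `(atanh r₁ − atanh r₂)/sqrt(1/(n₁−3) + 1/(n₂−3))`.
* `wilcoxonSignedRank()` — pairs with zeros in both series are dropped
  first (uninformative survey weeks), then zero differences (Wilcoxon's
  convention, not Pratt's); ties get average ranks. Up to 12 effective
  pairs the null is enumerated exactly over all 2ⁿ sign assignments.
  Beyond that, the p-value uses the continuity-corrected normal with
  tie-corrected variance, refined by the kurtosis (Edgeworth) term of the
  symmetric signed-rank null: the plain corrected normal deviates from the
  exact tail by up to ~0.014 at n = 12, the refined version by ~0.001, so
  the exact and approximate branches agree across the switchover. The
  reported `z_approx` stays the plain continuity-corrected deviate.

## Determinism

Every stochastic operation takes a seed; `runExperiment()` derives one child
seed per stage and plot from the root seed via a deterministic hash, so the
full experiment is byte-identical under a fixed root seed and single stages
can be re-run in isolation. Seeded operations restore the caller's RNG
state.

## What the generator does and does not emulate

The generator reproduces the *statistical structure* the analysis rests on:
compositions (47.5% shrubland; 54.3% pinewood versus 14% remnants; roads
under 1%; usable fractions near 61% and 74%), the clumped-versus-random
configurational contrast, behaviour-dependent habitat use with a 31% road
share of foraging, realistic fix counts and positional error, and paired
weekly abundance counts. It does not emulate: curved or networked real road
geometry (strips follow block rims; in clumped plots, linear typologies sit
on patch margins), temporal autocorrelation or serial dependence of fixes
(the field protocol's thinning to ≥1 h / ≥52 m spacing is taken as given,
so fixes are independent draws), heterogeneous individual behaviour (sex
differences in roosting, floaters), observation failure (signal loss,
dropped transmitters), or habitat quality gradients within a class.
Passing tests therefore demonstrate that the *pipeline* recovers known
structure under realistic noise — not that real landscapes obey the
generator's geometry.

A related honest caveat: emergent distance scales depend on patch geometry
choices (blob counts capped at five, block sizes around 350 m), so the
clumped-to-interspersed distance ratio in synthetic runs is of the order of
several-fold and varies by seed; the package treats direction and contrast,
not the metre values, as the reproducible quantities.

## Problem sizes used by the tests

Unit tests run the generators at 120–250 cells a side; the end-to-end
property tests (selection recovery, configuration-versus-movement contrast,
distance correlations) run 50 seeded replicates each, at 250 cells a side
for recovery and at the full plot sizes (697² and 454² cells, i.e. 4,858 ha
and 2,061 ha) for the landscape-level contrasts; the determinism check runs
the complete default experiment twice. These sizes keep the whole suite in
the minutes range while exercising every stage at the design's full spatial
scale where it matters.
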