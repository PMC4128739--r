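# landcomp

Landscape complementation analysis for animals with multiple habitat
requirements.

Many species need several *non-substitutable* habitat types to complete their
daily routine — a nest site in open shrubland, a shaded day roost in woodland,
open foraging ground such as roads and bare fields. When those habitats are
clumped into large separate blocks, a breeding animal must commute long
distances every day to link them; when the same areal fractions are finely
interspersed, the commutes collapse. `landcomp` implements the full analysis
chain that quantifies this effect, from radio-telemetry to landscape-scale
inference, together with a synthetic landscape/telemetry generator with known
ground truth so the entire chain can be validated end to end.

## What the package computes

Given a categorical landscape raster and telemetry fixes, the pipeline:

1. **Home ranges** — kernel utilization distributions as equal-weight
   mixtures of isotropic bivariate normal kernels with bandwidth *h* (default
   200 m), and *p*-volume contour home ranges (default 95% isopleth):
   the UD at location *x* is
   `f(x) = (1/n) Σᵢ φ₂((x − xᵢ)/h) / h²`.
2. **Habitat selection** — for each individual and behaviour (nesting,
   roosting, foraging), observed use per cover typology versus availability
   inside the home range: a Pearson goodness-of-fit χ² against random use,
   plus simultaneous Agresti–Coull confidence intervals for the used
   proportions (Bonferroni-adjusted across the *k* available typologies). A
   typology is *selected* when its availability lies below the lower
   confidence limit of its use.
3. **Functional map** — cover typologies are reclassified into four
   functional classes (breeding / roosting / foraging / non-usable) by
   pooling selection across individuals; the usable fraction of each plot is
   the non-zero share of this map.
4. **Configuration** — global Moran's *I* of the usable-habitat fraction
   aggregated to 100-m blocks, with binary rook contiguity and the
   analytical randomization (permutation-moment) Z-score:
   `I = (n/W) Σᵢⱼ wᵢⱼ zᵢ zⱼ / Σᵢ zᵢ²`, `E[I] = −1/(n−1)`.
5. **Movement needs** — *n* = 60 nests placed uniformly in breeding habitat
   with ≥ 50 m spacing; for each nest the exact Euclidean distance to the
   nearest roosting and foraging cells (distances are straight-line minimum
   routes; a grid-geodesic `costDistance()` generalization is provided), and
   their sum — the minimum daily travel of a breeding pair.
6. **Comparisons** — Poisson-error (log link) rate comparison of summed
   distances between plots, bootstrap Pearson correlations of nest→roost
   versus nest→forage distances (10,000 resamples) contrasted with Fisher's
   z, a 2×2 χ² on usable fractions, and a Wilcoxon signed-rank test (exact
   sign-flip enumeration up to n = 12) on paired weekly abundance counts.

The synthetic generator builds both study plots: a **clumped** plot
(multi-seed blob growth, each class in ≤ 5 contiguous patches; 60.9% usable,
47.5% shrubland) and an **interspersed** plot (a regular parcel mosaic with
exchangeably placed non-usable parcels, pinewood blocks served by road
strips and crop parcels; 74.1% usable, 54.3% pinewood), plus
behaviour-structured telemetry with 35-m positional error (3-m GPS error for
road sightings) and a 31% road share of foraging fixes.

## Worked example

```r
library(landcomp)
report <- runExperiment(defaultExperimentConfig(seed = 1))

report$plots$natural$usable_fraction_truth   # 0.609  (clumped plot)
report$plots$managed$usable_fraction_truth   # 0.741  (interspersed plot)
report$plots$natural$morans_i$z_score        # 87.5   strongly clumped
report$plots$managed$morans_i$z_score        # -1.53  indistinguishable from random
report$plots$natural$movement_needs$mean_d_total_m   # 2960 m
report$plots$managed$movement_needs$mean_d_total_m   #  386 m
report$cross_plot$movement_rate_comparison$rate_ratio_natural_over_managed
                                             # 7.68
report$cross_plot$correlation_comparison$r_managed   #  0.91
report$cross_plot$correlation_comparison$r_natural   # -0.40
```

Both plots hold a similar usable fraction (61% vs 74%), but only the clumped
plot shows significant spatial aggregation of usable habitat (Moran Z 87.5
vs −1.5). The consequence is landscape complementation: summed
nest-to-roost plus nest-to-forage distances are several times longer in the
clumped plot. In the interspersed mosaic the two distances are positively
correlated (nests far from the block network are far from both resources),
while in the clumped plot the correlation varies around zero from one
realization to the next (roost and forage blocks lie in different
directions). Single-stage functions (`estimateUD`, `selectionTest`,
`globalMoransI`, `simulateNests`, `nearestHabitatDistance`, ...) expose every
intermediate step, and `inst/scripts/landcomp.R` wraps the stages as shell
verbs.

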