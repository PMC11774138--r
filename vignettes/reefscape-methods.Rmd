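---
title: "Methods: synthetic reefscapes and the community-regime analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic reefscapes and the community-regime analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and rationale

`reefscape` implements a site-level benthic monitoring analysis for
photomosaic reef plots: three families of site descriptors (percent cover,
landscape heterogeneity, structural complexity), the multivariate machinery
used to delineate and test community regimes (Bray–Curtis dissimilarity,
hierarchical clustering, NMDS, ANOSIM, PERMANOVA, Mantel correlogram), and
temporal trajectory statistics. Because the survey imagery and annotations
that motivate such analyses are large and not redistributable, the package
pairs every analysis stage with a synthetic reefscape generator that
produces data with known ground truth. Every estimator in the package can
therefore be checked against the quantity it is supposed to recover.

# The site descriptors

**Percent cover.** A plot (default 10 × 10 m; a 12 × 5 m variant is
representable) is sampled at *n* = 2500 stratified random points — one
uniform point in each cell of a 50 × 50 grid; for rectangular plots the
factor pair of *n* with the most nearly square cells is used. Stratum
membership uses half-open intervals, so boundary points are unambiguous.
Cover of category *i* is `p_i = 100 * count_i / n` over a configurable
15-category set. Stratification yields an unbiased estimator whose variance
is never larger than unrestricted uniform sampling on spatially structured
mosaics; both properties are exercised in the test suite.

The default 15 categories (eight named Hawaiian coral taxa, an other-coral
pool, CCA, turf algae, fleshy macroalgae, sand/sediment, sessile
invertebrates, bare limestone) are an assembled stand-in for a
supplementary-material list that is not reproduced in the main text of the
motivating study; the set is an argument everywhere it is consumed.

**Landscape heterogeneity.** The annotated points are interpolated by a
Voronoi tessellation clipped to the plot rectangle, and heterogeneity is
the proportion of *unlike adjacencies*: adjacent cell pairs whose points
carry different categories. Cells are adjacent when their shared boundary
segment is longer than 1 nm — corner-touching cells do not count. Because
the source description does not state whether pairs or boundary length are
the weights, both `edge_count` (default, robust to clipping artifacts) and
`edge_length` weightings are provided. The geometric construction is
incremental half-plane clipping with a security-radius early exit; its
adjacency structure is tested against a dense-grid nearest-site
rasterization oracle.

**Structural complexity.** Depth profiles are extracted along virtual
transects (10 per axis direction, offsets `(k - 1/2) * extent / n`), with
depth sampled by bilinear interpolation at a stated resolution. Linear
rugosity is contour length over planar length — exactly 1 for a flat
profile, and non-increasing as the sampling step coarsens (reported at 1 cm
and 50 cm). Profile fractal dimension uses the divider method: contour
length is measured at a ladder of horizontal steps *s* and
`log L(s) = c + (1 - D) log s` is fitted per profile by least squares, the
mean *D* reported and clamped to [1, 2]. The estimator inside the original
profile-gauge tool is not documented; the divider method is the standard
choice for self-affine depth profiles.

Two numerical points matter here. First, divider steps are kept at least a
factor of two above the grid spacing (default ladder 2–32 cm on a 1 cm
grid): at the grid scale, interpolation smooths the profile and biases *D*
toward 1. Second, the `D = 2 - H` recovery relation for fractional Brownian
profiles holds only where relief dominates the step size (the self-affine
scaling regime); recovery tests therefore use surfaces with relief standard
deviation ≈ 3 m, while survey-realistic surfaces (relief calibrated to
rugosity 1.45–2.2) sit partly below that regime and report correspondingly
tamer *D* values.

# The multivariate pipeline

The feature matrix binds the 15 cover percentages with heterogeneity and
the three complexity metrics, the latter four min–max standardized to
[0, 1] *jointly across all sites and surveys* (the per-column min and max
are retained so later observations can be transformed identically).
Bray–Curtis dissimilarity `BC(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)` is
computed on the full feature rows.

**Clustering.** Agglomerative clustering with complete linkage (default)
cut at *k* = 3 groups, with Ward's method (`ward.D2` on dissimilarities) as
the robustness alternative; `stats::hclust` supplies the (deterministic)
agglomeration. Three groups is a scientific prior of the monitoring
programme — low-cover *Porites*/turf reefs, diverse intermediate reefs,
high-cover *Montipora* reefs — not an optimised quantity.

**NMDS.** Non-metric SMACOF: alternating isotonic regression
(pool-adjacent-violators via `stats::isoreg`, primary tie approach:
within tied dissimilarities the fitted distances are ordered by the current
configuration) and Guttman-transform updates. Stress is Kruskal's stress-1,
`sqrt(Σ(d − d̂)² / Σ d²)`; the accepted trace is non-increasing, and the
best of one metric start (classical scaling) plus seven seeded random
starts is reported. Convergence is declared when the stress improvement
drops below `1e-6` (default), capped at 500 iterations; non-convergence is
flagged but the best configuration is still returned. Two dimensions are
the default, as is conventional for reef community ordinations.

**ANOSIM.** Mid-ranks of all `M = n(n−1)/2` dissimilarities;
`R = (r̄_between − r̄_within) / (M/2)`, so perfectly separated balanced
groups score exactly 1. With at most 10,000 distinct label arrangements the
permutation distribution is enumerated and the p-value is exact; otherwise
9999 free permutations (default) with the add-one estimator
`p = (1 + #{R* ≥ R}) / (1 + B)`, which never reports zero. (A widely used
alternative notation writes the denominator as M/4 with M the full ordered
pair count `n(n−1)`; both conventions give the same statistic.)

**PERMANOVA.** The dissimilarity matrix is Gower-centered
(`G = −½ C D² C`), terms are fitted sequentially (Type I) through
hat-matrix projections, and each term reports `SS`, pseudo-F, and partial
`R² = SS/SS_total`; the partition sums to one by construction, and on
Euclidean distances it reproduces the classical multivariate ANOVA trace
decomposition exactly (a test asserts this to 1e-8). The grouping factor of
interest (island) is entered first; the order is the caller's choice.
Repeated surveys of fixed sites violate free exchangeability, so a
`blocked_by_site` scheme permutes whole sites — all surveys of a site move
together, exchanged among sites with equal survey counts. This is an
accepted exchangeability argument for repeated-measures designs; the
published analysis used a dedicated package whose internal scheme is not
restated, and equality with it is not claimed.

**Mantel correlogram.** Geographic pair distances (planar km, or lon/lat
via the equirectangular approximation, adequate below ~100 km) are binned
by Sturges' rule. Per class, the statistic is minus the Pearson correlation
between community dissimilarity and class membership, so positive values
mean *more similar than expected* at that distance — the ecological sign
convention. Permutation p-values (two-sided, add-one) are corrected
progressively: class *k* receives the Holm-adjusted value within classes
1..*k*, mirroring the progressive corrections recommended for
correlograms. Classes with fewer than two pairs are flagged and skipped.

# Trajectories

Rates of change divide measurement differences by elapsed months (a month
is fixed at 30.4375 days, keeping rates calendar-independent across
unevenly spaced surveys). Transitions are consecutive changes of regime
label; trajectory geometry summarises each site's ordination path by total
length, net displacement, and directionality = net/path ∈ [0, 1].

The published analysis compared community type against island as
predictors of change with mixed-effects models (random site effects,
variance weights, Tukey contrasts, AIC selection) — off-the-shelf model
machinery rather than a methodological contribution. The package
substitutes a self-contained permutation comparison: η² = SS_between /
SS_total of the rates under each grouping, with p-values from permuting
group labels across sites (a site's full rate series moves as a unit).
"Regime explains change better than island" is then a direct comparison of
two η² values. This is a deliberate divergence, chosen to keep the
scientific question while staying fully testable.

# The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions of the monitoring programme it emulates.

**Label fields.** Cover mosaics are built on a 1 cm raster by
capacity-constrained region growing: per-category area targets are drawn
around the archetype means, one seed per expected patch (patch count
follows the archetype's characteristic patch diameter), and cells are
claimed in order of distance from their seed until the category's target is
met; a fill pass resolves enclaves and a boundary-swap pass trims
overshoot. This guarantees contiguous patches and near-exact cover control,
which thresholded Gaussian fields do not. Realized cover sums to 100
exactly, and the per-category jitter (truncated normal, |z| ≤ 2, sd capped
at 2 points) keeps realizations within about 5 points of the archetype
means with a mean absolute error under 2 points.

**Archetypes.** Three built-in community types encode the printed regional
community profiles: low-cover *Porites* (35.09% coral, 53.52% turf, 15.23%
*P. lobata*), diverse intermediate (55.74% coral incl. 11.45%
*P. compressa*, 9.19% CCA, 2.49% macroalgae), and high-cover *Montipora*
(67.82% coral incl. 48.62% *M. capitata*, 13.00% *M. patula*). Categories
not printed in the source are filled with fixed plausible values so each
profile sums to 100; those fills are generator conditions, not estimates.
Patch scale (0.5–1.2 m) and rugosity targets (1.95/1.75/1.60) encode the
qualitative descriptions (intermediate reefs: high heterogeneity and
complexity; high-cover *Montipora*: low both; rugosity within the observed
1.45–2.22 range).

**Depth surfaces.** Spectral synthesis of fractional-Brownian surfaces:
complex Gaussian coefficients shaped by `(f_x² + f_y²)^{−(H+1)/2}`, inverse
FFT, normalised to a target relief standard deviation. The closed form
`D = 2 − H` gives the recovery target for the fractal estimator. Relief is
rescaled about its mean by 1-D root finding so that plot rugosity at 1 cm
hits an archetype's target exactly; rugosity is monotone in the relief
scale, so the calibration is deterministic.

**Time series.** Expected cover drifts linearly at per-category monthly
rates; turf algae — the dominant non-coral space-holder — absorbs the
residual so totals stay at 100, and drift through zero is clamped with a
warning. Site baselines are drawn once per site (so repeat surveys of a
site cluster tightly, as real monitoring shows), with a small per-survey
jitter (0.3 points) on top. Default archetype rates convert the printed net
changes over the 2017–2023 series (+4.89 / −6.32 / −8.81 points over ~72
months) into points per month on each archetype's dominant coral;
between-site rate spread is 0.03 points/month, a deliberately milder
heterogeneity than the field data show.

**Regions.** Four islands × nine sites by default, matching the 36-site
design. Sites sit in within-island clumps whose spread is a quarter of the
autocorrelation range (default 5 km), and each island's archetype counts
follow its mixture row exactly (largest-remainder rounding) laid out in
contiguous blocks over the clump-ordered sites. Sites within the range
therefore share archetypes far more often than chance — the designed
sub-5-km autocorrelation — while every community type keeps its regional
share (no type can vanish by sampling accident). The mixtures concentrate
low-cover reefs on two islands and high-cover reefs on the other two,
reproducing the reported geography. Environmental covariates (depth, wave
power, SST
variability, chlorophyll-a, irradiance, sediment export, effluent) are
truncated normals with island-specific means kept small relative to the
within-island spread, so pairwise covariate correlations stay below the
|0.54| bound reported for the real predictor set.

What the generator does *not* emulate: photographic realism, within-patch
taxonomic microstructure, reef zonation gradients within a plot, episodic
disturbance events (drift is linear between surveys), or any covariate
effect on community change. Passing tests therefore demonstrate that the
estimators recover known structure of this class — not that the original
field conclusions are reproduced from field data.

# Problem sizes and determinism

Every stochastic routine takes an integer seed and fans per-stage seeds
from it deterministically (a Lehmer step), so identical configurations are
bit-identical end to end — the pipeline writes its resolved configuration
next to its outputs. The test suite runs the full default region (36 sites
× 4 surveys, 2500 points, 1 cm rasters) once, in its end-to-end regime
recovery check; unit tests use reduced sizes (4 × 4 m plots, 2 cm rasters,
a few hundred points) chosen so each property is still exercised at
realistic spatial ratios. Calibration checks use 500 null simulations for
ANOSIM and PERMANOVA and 200 for the Mantel correlogram, sizes at which the
nominal error rate can be bracketed within about two percentage points.

# Known limitations

- The Voronoi adjacency threshold (1 nm of shared boundary) is absolute,
  not relative to plot size; for plots much larger than 100 m it would be
  overly permissive.
- The divider-method fractal dimension is resolution-dependent on
  low-relief surfaces (it approaches 1 as relief falls below the step
  ladder); it should be read as a comparative index at fixed settings, as
  in the motivating survey, not as an absolute fractal dimension.
- The blocked PERMANOVA permutes sites only within equal-survey-count
  classes; heavily unbalanced designs lose permutation richness.
- NMDS uses SMACOF-style majorization; like all NMDS implementations it
  can land in local minima — restarts mitigate but do not eliminate this.
- The η² rate comparison treats timesteps as exchangeable within a site
  and does not model temporal autocorrelation of rates.
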