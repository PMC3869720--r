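---
title: "Methods: spatial structure of large-diameter trees in mapped forest plots"
author: "stemspat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial structure of large-diameter trees in mapped forest plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemspat)
```

## The problem

Old-growth conifer forests of the Pacific Northwest carry a large share of
their basal area in a numerically tiny class of stems: live trees of at
least 100 cm diameter at breast height (dbh, measured at 1.37 m). In the
25.6 ha Wind River reference census that this package emulates, trees
>= 100 cm are about 1.5% of the 31,000 live stems but about 32% of the
62 m^2/ha of basal area. Two questions follow. First, how are these
large-diameter trees arranged - clumped, random, or spaced out - and how do
they relate spatially to the small-diameter trees around them? Second, how
much of the quadrat-scale heterogeneity of forest structure (basal area per
100-6400 m^2 cell) is attributable purely to *where* the large trees stand?

`stemspat` implements the full chain: census summarization of fully mapped
stem records, second-order point-pattern statistics with Monte Carlo
inference, point-process simulators spanning a uniformity-to-aggregation
gradient, a permutation experiment that regenerates large-tree coordinates
under that gradient while holding every other tree fixed, and a synthetic
stem-map generator so that the entire pipeline is testable without access
to the (undeposited) census itself.

## Data model

A `stem_map` is one record per tagged stem: coordinates in meters inside a
rectangular window (origin at the southwest corner), species code, dbh in
cm, live/snag status, growth form (tree, tall shrub, liana), and for snags
the height and decay class. Validation enforces the tagging protocol: live
stems >= 1 cm dbh, snags >= 10 cm and >= 1.8 m tall, coordinates inside the
window, unique tags. Basal area is the measured quantity used throughout,
`pi * (dbh/200)^2` m^2 - deliberately not biomass, which would import
allometric uncertainty for exactly the trees that matter most here.

Census summaries count stems and sum basal area above the 1 / 10 / 100 cm
thresholds (inclusive, per the field convention) per species and
population, with the large-diameter proportions defined against the >= 1 cm
classes (>= 10 cm for snags). The printed-table conventions are available
via `format_census()` (densities to 0.1 stems/ha, trace marks below half a
unit of printed precision). `reference_census_fixture()` rebuilds a stem
map whose class-level arithmetic reproduces the published reference table
at printed precision; because the published per-species basal areas are
independently rounded and do not sum exactly to the published totals, the
fixture's class targets are chosen within half an ULP of each printed
species value so that species rows *and* group totals agree with print
simultaneously.

## Second-order statistics

For a pattern of `n` points in a window of area `|A|`, Ripley's K is
estimated with isotropic edge correction,

$$\hat K(r) = \frac{|A|}{n(n-1)} \sum_i \sum_{j \ne i} w_{ij}\,
  \mathbf{1}(d_{ij} \le r),$$

where `w_ij` is the reciprocal of the fraction of the circle of radius
`d_ij` centered on point `i` that lies inside the window. The fraction is
computed from the exact rectangle geometry: each side closer than `d`
removes an arc of half-angle `acos(d_side/d)`, and a corner whose two
adjacent sides are both crossed returns the doubly removed overlap
(`acos(a/d) + acos(b/d) - pi/2`). Property tests compare this closed form
against dense numeric arc integration across the window, including centers
on edges and corners and radii up to the full shorter side; beyond the
shorter side the implementation switches to numeric integration and caps
weights at 4 (the quarter-circle corner case) with a warning - far outside
the estimator's validity range `r <= min(side)/2`, which `ripley_K`
enforces.

All analysis is reported on the variance-stabilized, CSR-centered scale
`L(r) - r = sqrt(K(r)/pi) - r`: zero under complete spatial randomness,
positive under clumping, negative under regularity. The bivariate
`K_12` sums type-2 neighbors around type-1 points (weights centered on the
type-1 point) and equals `pi r^2` under independence of the two
populations.

Evaluation uses a uniform grid of 512 steps from 0 to `r_max` (default: a
quarter of the shorter window side, 80 m for the reference geometry). The
resolution is not critical - curves are smooth - and 512 steps keep the
grid spacing well below a meter at full scale.

## Inference

Two null models generate the Monte Carlo reference distributions:

* **CSR** for univariate patterns: the analyzed subpopulation is
  resimulated uniformly at its observed count.
* **Population independence** for bivariate patterns: the large-diameter
  subpopulation is displaced by one uniform random toroidal shift per
  replicate, exactly preserving both intratype configurations. Shifting
  one population by one vector is distributionally equivalent to shifting
  both "synchronously", since only the relative displacement enters the
  cross statistic; the package does the former.

The goodness-of-fit test integrates squared deviations of the centered-L
curve from the leave-one-out mean of the joint curve set over the tested
interval,

$$u_i = \sum_k \left(H_i(r_k) - \bar H_{-i}(r_k)\right)^2 \Delta r,$$

computed identically for the empirical curve and every simulated curve, so
the rank-based p-value `p = (1 + \#\{u_{sim} \ge u_{obs}\}) / (n_{sim}+1)`
is exact under the null. Ties count toward rejection (conservative). With
the conventional 999 simulations the attainable floor is `p = 0.001`; the
test interval defaults to 0-9 m, the a priori neighborhood radius for
these forests, taken as the prefix of the standard grid. Type-I error is
verified by simulation (500 replicate experiments at `n_sim = 99`), and
p-values under a true null are checked for discrete uniformity.

Family-wise control over a battery of such tests is plain Bonferroni,
`alpha / m`; the reference design of 12 tests at `alpha = 0.05` gives a
per-test threshold of 0.0042, printed as 0.004. Note an interaction with
the Monte Carlo floor: a battery under Bonferroni needs
`n_sim + 1 > m / alpha` (here, at least 240 simulations) for rejection to
be attainable at all, which is why the battery driver uses 999 simulations
even at desk scale.

`power_vs_hardcore()` implements the post-hoc power question: simulate
hard-core (sequential-inhibition) patterns at the observed intensity, test
each against CSR, report the rejection fraction. At 93 points per 25.6 ha
and a hard core at the ~6 m scale of observed large-hemlock inhibition,
power is low (~0.2 in the analysis driver) - regularity of that strength
simply cannot be distinguished from randomness at that sample size.

## Pattern simulators

The simulation experiment spans seven levels:
`ssi-20, ssi-15, ssi-10, random, matern-20, matern-15, matern-10`.

* **Simple sequential inhibition** places points one at a time, uniform
  proposals rejected within the inhibition radius of any accepted point.
  The densest configuration used (451 points at 20 m in 800 x 320 m) sits
  near the jamming density of random sequential adsorption (coverage
  ~0.547, an effective ceiling of roughly 490 points once boundary
  overhang is counted), so placements there legitimately need on the order
  of 10^4-10^5 consecutive rejections before the last points land. The
  default abort budget is therefore 10^5 consecutive rejections, which
  still detects genuinely infeasible packings in seconds.
* **Matern cluster, thinned to exact n**: Poisson parents (default
  `kappa = 0.00055` per m^2) on the window dilated by the cluster radius
  (edge-effect guard; parents are never emitted), Poisson (`mu = 5`)
  offspring uniform in the disc, offspring outside the window discarded,
  then a uniformly random n-subset - independent thinning, which preserves
  the second-order structure. On shortfall the whole realization is
  regenerated, never topped up, to preserve the process distribution. The
  dilated-window convention for `kappa` is adopted; at the reference
  geometry it yields ~700+ expected in-window offspring, comfortably above
  the 451 needed.
* **Randomization** of a reference pattern: fresh CSR at the same count
  (default), or local jitter in a disc with reflection at the boundaries.
  The "spatial randomness" level of the experiment uses full CSR
  resampling: the gradient's middle level should be unconstrained
  randomness, and a bounded jitter with an unstated radius would leave
  residual structure of the empirical pattern in the null level.

## The heterogeneity experiment

`run_experiment()` regenerates the coordinates of every live tree
>= 100 cm under each level (each tree keeps its dbh, so the marginal
diameter distribution and the total basal area are invariant by
construction), holds all smaller trees fixed, sums basal area per quadrat
at grains of 100, 400, 1600, and 6400 m^2 (southwest-anchored grids;
half-open cell boundaries; far-edge stems clamped into the last cell), and
reduces each grid to the coefficient of variation (sample sd over mean)
and the moment-ratio skewness `g1 = m3 / m2^{3/2}` (n-denominator central
moments, the common default of R's ecosystem; a bias-corrected variant
sits behind a flag). Quadrat basal areas are kept in m^2 - both statistics
are scale-free.

By default the seven levels of one realization share their randomness: the
inhibition family filters one proposal stream at different radii (radius 0
accepts everything, which is exactly CSR), and the cluster family scales
one parent/offspring/priority draw to the different radii. Every level's
marginal distribution is rigorously unchanged - a proposal-filter SSI is
the same algorithm as sequential SSI, a Poisson process restricted to a
subregion is Poisson, and selection by iid uniform priorities is a uniform
n-subset - but realizations become positively correlated across levels, so
level contrasts are estimated like a paired design rather than an unpaired
one. Adjacent-level CV differences at desk scale are of order 0.005-0.02;
pairing brings their standard errors from comparable magnitude down to
~0.003 at 20 realizations. `coupled = FALSE` restores fully independent
per-(level, realization) substreams.

`empirical_departure()` then locates the unpermuted map's CV and skewness
within the realization distribution of the randomness level, as percentile
ranks `100 * #{sim <= emp} / (n_real + 1)`. Elevated ranks at coarse
grains indicate heterogeneity that second-order randomization of the large
trees does not reproduce - the signature of a first-order intensity
gradient ("virtual aggregation").

## The synthetic forest

`default_wfdp_spec()` encodes what the analyses assume about the stand:

* Relative abundances of the five principal species, western redcedar, and
  a pooled minor-species profile matching the reference census (vine maple
  35.8% of stems, western hemlock 32.1%, Pacific silver fir 14.3%, Pacific
  yew 6.6%, Douglas-fir 1.8%, western redcedar 0.6%).
* Diameter models per species: a truncated bell (location 103, spread 30)
  for the Douglas-fir pioneer cohort, calibrated so ~54% of its stems
  exceed 100 cm; negative exponentials for the continuously recruiting
  species (redcedar's rate set so ~23% exceed 100 cm); and a "rotated
  sigmoid" for hemlock, implemented as an exponential body plus a
  bell-shaped bump at large diameters (bump weight 0.08 at 70 +/- 25 cm),
  giving ~1% of hemlock stems >= 100 cm. Overall, ~1.5% of live stems come
  out large-diameter, matching the census.
* Spatial models: small stems are Matern-clustered at radii of 6-15 m with
  modest cluster sizes (3-15), reflecting multi-stem growth forms, gap
  recruitment, and dispersal limitation. The radii keep the planted
  aggregation at the sub-9-m scales where it is observed in such stands,
  and the modest cluster sizes keep 20 m-quadrat basal-area CV near the
  census anchor (CV ~0.5 for all trees vs ~0.4 without large trees at
  400 m^2) rather than inflating patchiness at quadrat scale. Large stems
  are CSR by default, optionally inhibited, or tilted west-to-east.
* The gradient form is **log-linear**, `f(x) proportional to
  exp(b x / W)` with `b = 2` by default (about a sevenfold end-to-end
  density contrast). The form matters: a *linear* tilt produces a ramp of
  quadrat means that is symmetric about its midpoint, adding variance but
  no third moment - it actually depresses the skewness statistic while
  inflating CV. The convex log-linear profile concentrates density in a
  minority of quadrats and produces the right-skewed quadrat distribution
  that a real density gradient induces; it is also the canonical
  first-order inhomogeneity model in spatial statistics.
* Snags are generated by an independent draw at 6.3% of the live count;
  their spatial structure is not modeled because they sit outside every
  spatial analysis here.

`generate_pair()` builds two maps sharing every stem, diameter, and
small-tree position, differing only in the large trees' first-order
intensity (gradient vs homogeneous) - the controlled comparison behind the
cross-plot contrast of a gradient stand with a homogeneous one.

What the generator does *not* emulate: topography and environmental
covariates, species-specific bivariate interactions (planted large and
small layers of a species are independent, so the repulsion/attraction
seen in real censuses is absent), snag spatial structure, shrub-patch
geometry, and the fine shape of real diameter distributions beyond their
class proportions. Passing pipelines on synthetic maps therefore
demonstrate estimator correctness and recovery of *planted* structure, not
ecological conclusions about any real stand.

## Problem sizes and statistical power

The workflow's drivers run on a desk-scale map: 10% of the full stem count
(about 3,100 live stems, 45 large trees) on the full 800 x 320 m window,
with 199 simulations for exploratory envelopes, 999 for the Bonferroni
battery, and 50 realizations per level in the heterogeneity experiment.
These sizes keep a complete run under a few minutes while preserving every
qualitative contrast; the package itself handles the full census scale
(the estimators are vectorized; a full-scale battery is minutes, not
hours).

Two power limitations at desk scale are worth stating plainly, because
they are properties of the statistics rather than of the implementation:

* With ~45 large trees, the strict ordering of all seven levels by *mean
  skewness* at 400 m^2 is not guaranteed even with unlimited realizations
  for every generated map - the third moment of quadrat basal area
  interacts with the fixed small-tree layer - while the mean-CV ordering
  holds systematically and resolves at modest realization counts under the
  paired design.
* Detecting a planted first-order gradient through the *skewness*
  percentile at the 6400 m^2 grain is weak at any gradient strength: that
  grain has only 40 quadrats, so the skewness estimate has a sampling sd
  of roughly `sqrt(6/40) ~ 0.4`, while a monotone intensity profile can
  raise expected skewness by at most ~1-1.5. The CV percentile at the same
  grain detects the same gradient far more reliably and is reported
  alongside.

## Numerical and degenerate-input choices

* Duplicate points are permitted with a warning; zero-distance pairs
  contribute at every positive distance.
* Quadrat boundaries are half-open toward north/east; stems exactly on the
  window's far edge are clamped into the last quadrat (conservation-safe).
* A constant quadrat vector has CV 0 and skewness 0; an all-zero vector is
  a degenerate-distribution error.
* Empty stem maps summarize to zeros; an experiment without large trees
  refuses to run.
* All randomness flows from one seed through named substreams
  (`substream_seeds`), so any replicate is reproducible in isolation and
  results do not depend on evaluation order; RNG state of the caller is
  never disturbed.

## Known limitations

Rectangular windows only; no inhomogeneous-K or pair-correlation function;
no random-labeling or antecedent-condition nulls (the toroidal-shift
independence null is the only bivariate null); Bonferroni only, no FDR.
The published p-values for the real census's subpopulations depend on the
unavailable stem map and are not reproduction targets; the package's
validation surface is the census arithmetic, the estimator closed forms
and calibrations, the simulator contracts, and recovery of structure it
plants itself.
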