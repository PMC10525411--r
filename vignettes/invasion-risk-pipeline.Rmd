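---
title: "Modelling invasion risk: maximum-entropy SDMs, niche dynamics, and land-use overlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling invasion risk: maximum-entropy SDMs, niche dynamics, and land-use overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invrisk)
```

`invrisk` implements the analysis chain used in invasion biogeography to
assess where an alien plant can establish and how its realized climatic
niche has moved during invasion: reconstruction of the invasion timeline,
a presence–background maximum-entropy species distribution model (SDM)
with tunable feature classes and regularization, niche-overlap statistics
in a two-axis environmental space, and suitability/land-use overlay with
latitudinal profiling. A seeded virtual-species simulator generates
inputs with known ground truth so every stage is testable offline.

## Invasion timeline and phases

Country first-record tables are binned into an open pre-interval (before
1970 by default) plus fixed-width intervals; the final partial interval
is absorbed into the last full one, so a 2010–2023 tail forms a single
category. Invasion histories classically pass through lag, spread, and
equilibrium phases. The literature segments them narratively; here the
rule is explicit: the lag phase is the maximal prefix of intervals adding
fewer than `spread_rate` (default 6) countries each, spread is the
maximal following run at or above that rate, and the rest is
equilibrium. The open pre-interval never enters the rate comparison. The
threshold is a user parameter; the default reproduces the canonical
before-1980 / 1980–2010 / 2010-onward segmentation when fed the reported
per-decade counts (7, 2, 6, 7, 14, 5).

Spatial thinning keeps one record per 5 km cell. The kilometre size is
converted to a fixed angular cell (`cell_km / 111.32` degrees) anchored
at (−180°, −90°), and the first record in input order wins. This is
deliberately projection-free and seedless so thinning is idempotent and
bit-reproducible; near the poles the angular cell under-covers 5 km in
the east–west direction, which is acceptable for occurrence data that
rarely reach high latitudes (and pseudo-absence sampling drops
latitudes beyond 70° anyway).

## The maximum-entropy model

The SDM is the Gibbs formulation of MaxEnt: with features
$f(x) \in [0,1]^p$ built from the covariates, the model over background
cells $B$ is

$$ P(i) = \frac{e^{\lambda^\top f(x_i)}}{\sum_{j \in B} e^{\lambda^\top f(x_j)}}, $$

and $\lambda$ minimizes the penalized presence negative log-likelihood

$$ -\frac{1}{m}\sum_{\text{presences}} \lambda^\top f(x) +
   \log \sum_{j \in B} e^{\lambda^\top f(x_j)} +
   \sum_k \beta_k |\lambda_k|. $$

Feature classes follow the established taxonomy: linear (min–max scaled
covariate), quadratic (squared scaled value), product (pairwise products
of scaled values), threshold (step indicators), and hinge (forward and
reverse ramps). Hinge and threshold knots sit at equally spaced
quantiles of the background sample, making the dictionary scale-free and
deterministic; 50 knots per covariate is the default. Per-feature
penalties are $\beta_k = \mathrm{rm} \cdot \beta_{\text{class}}(m) \cdot
s_k / \sqrt{m}$, where $\beta_{\text{class}}$ is the
sample-size-interpolated table of published MaxEnt defaults (exposed as
`maxent_reg_table()`), $s_k$ the feature's standard deviation over the
presences, $m$ the presence count, and `rm` the user's regularization
multiplier.

Optimization is FISTA (accelerated proximal gradient with backtracking
and restart-on-increase). Iteration stops when the largest coefficient
change drops below `1e-7`, after `1e4` iterations, or — in practice the
common case — when the composite objective has improved by less than
`1e-12` for 50 consecutive iterations. That stall rule matters: near the
optimum the log-sum-exp objective moves at the double-precision noise
floor while coefficients still rattle at the `1e-6` level, so demanding
the coefficient criterion alone wastes thousands of iterations without
changing any prediction.

Predictions come in three links. `raw` is the normalized Gibbs density
(it sums to 1 over the training background — a tested invariant);
`logistic` and `cloglog` pass the raw value through the stored training
entropy $H$ as $e^H r/(1 + e^H r)$ and $1 - e^{-e^H r}$. `cloglog` is
the default, matching modern MaxEnt practice; all three are strictly
monotone in one another, so rankings, AUC, and thresholded maps agree.

Tuning fits one candidate per (feature-class set, RM) pair — the
conventional grid is RM 0.5–4 in steps of 0.5 — and scores each with
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$, where $k$ counts
non-zero coefficients and $\ln L$ is the sum of log raw probabilities at
presences. Candidates with $n - k - 1 \le 0$ score $+\infty$ (the
formula's correction term is undefined there, which subsumes the usual
$k \ge n$ exclusion). Minimum AICc wins; ties prefer the smaller $k$,
then the larger RM.

Variable importance comes in two flavours. The jackknife refits with
each covariate alone and each left out, reporting training gain (mean
log raw presence probability relative to a uniform background). Percent
contribution is permutation importance — the drop in training AUC when
one covariate is shuffled across the pooled presence + background rows,
averaged over permutations, floored at zero, normalized to 100. The
original MaxEnt path-gain accounting is tied to its coordinate-wise
optimizer; permutation importance is well defined for any penalized fit,
at the cost of splitting credit between strongly correlated covariates.

One property worth stating precisely: the *count* of non-zero
coefficients usually shrinks as RM grows, and the tests assert this on
the linear + quadratic dictionary. It is not a theorem — with large
correlated hinge dictionaries the active set can swap a member while
shrinking overall, and we have observed genuine one-feature growth
between converged fits. What is guaranteed for the exact solution is
that the penalty-weighted norm $\sum_k (\beta_k/\mathrm{rm})
|\lambda_k|$ is non-increasing in RM, and that is what the tests assert
on the full dictionary.

## Niche comparison (COUE)

The environmental space is the first two principal components of the
pooled, standardized background samples of the two ranges. Occurrence
and background densities are estimated on an `R x R` grid (default 100;
bounds pad the pooled scores by 10%) with `MASS::kde2d` and
normal-reference (Silverman) bandwidths per axis. The occupancy of a
range is the occurrence density divided by the background density —
correcting for how much of each environment is available — normalized
to sum 1.

Both the background mask and the occupied-niche support apply a relative
density floor of `1e-4` of the respective KDE maximum. This floor is
load-bearing twice over. Without it, the ratio correction concentrates
essentially all occupancy mass in cells where the background KDE has
decayed to numerical dust (densities at `1e-15` of the peak), and the
expansion/stability/unfilling decomposition — which asks where a niche
density is exactly zero — never finds a zero cell because Gaussian tails
are positive everywhere. With the floor, "occupied" and "available"
mean what a practitioner expects: within four-to-five bandwidths of the
data.

Overlap is Schoener's $D = 1 - \tfrac12 \sum |z_1 - z_2|$. The
equivalency test pools the two occurrence samples and re-splits them at
their original sizes each iteration (background densities are cached —
they do not change under re-splits); the similarity test relocates one
range's occupancy (the invaded one by default) to a random centroid
within its own background mask, wrapping at the grid edges. Both report
the permutation estimator $p = (k+1)/(\text{reps}+1)$, so every p-value
is a multiple of `1/101` at the conventional 100 iterations — the
resolution at which published values such as 0.0297 (= 3/101) and
0.0198 (= 2/101) arise. The equivalency tail is lower ("less equivalent
than random") by default, matching the inference that invaded niches
are similar but not identical; both tails are available.

Dynamics are computed on the intersection of the two background masks:
expansion is the invaded-niche mass where the native niche is absent,
stability its complement, and unfilling the native mass where the
invaded niche is absent. An `intersection_quantile` argument can trim
the shared background to environments above a density quantile; the
default (0) uses the full shared background.

## Thresholding, areas, and latitudinal profiles

Suitability maps threshold into potential geographic distribution (PGD)
at a cutoff the user supplies (0.23 in the motivating analysis); the
boundary value is non-PGD, matching a non-PGD interval closed at the
cutoff, with a `strict` flag to flip the convention for sensitivity
analysis. Cell areas are spherical:
$A = R^2 \,\Delta\lambda\, (\sin\varphi_{top} - \sin\varphi_{bottom})$
with $R = 6371$ km; the 5-arc-minute global grid totals $4\pi R^2$
within 0.5% (tested). Ecosystem areas use fraction-weighted accounting —
each cell contributes `area x fraction` to its ecosystem's total, and
the same restricted to PGD cells to the PGD area — rather than
dominant-type classification, because land-use data express cells as
compositions. Tables report km² and the conventional
$\times 10^4$ km² units side by side.

Latitudinal profiles average suitability in half-open 0.5° bands
weighted by `cell area x fraction`, fit a polynomial per hemisphere by
least squares with pointwise 95% confidence bands, and report the band
centre maximizing the fitted curve. The degree is configurable and
defaults to 2 (a "binomial" two-term fit). Low-degree polynomials
systematically displace the argmax of a narrow bump fitted across a
whole hemisphere — a quadratic can shift a Gaussian peak by a degree or
two — so peak-recovery checks in the test-suite use degree 4–8 on
broader ridges; treat the degree-2 default as a smoother, not an
unbiased peak estimator. A hemisphere with no weighted bands, or a
fitted curve flat to within `1e-6`, reports an undefined peak rather
than a fabricated one.

## The synthetic world

The simulator generates what the analysis consumes, with the statistical
structure the method assumes and nothing more:

- **Climate layers** mix a latitudinal gradient with spatially smoothed
  Gaussian noise (`gradient_weight`, default 0.6; Gaussian blur SD 2
  cells), rescaled to temperature-like (−10..30) and precipitation-like
  (0..3000) ranges. The default world is 50 x 50 cells of 0.5°
  spanning latitudes −12.5°..12.5°, so both hemispheres exercise the
  latitude-dependent code paths.
- **Virtual species** have multiplicative Gaussian responses
  $\exp(-(x - \mu)^2 / 2\sigma^2)$; presences are sampled with
  probability proportional to suitability times cell area (or by
  Bernoulli acceptance) and jittered uniformly within cells so that
  thinning stays non-trivial.
- **Paired ranges** split the world into western (native) and eastern
  (invaded) extents; the invaded optima shift by a programmed number of
  grid-SD units. Shift 0 emulates a conserved niche (the tests require
  stability > 0.8 there); expansion rises monotonically with the
  programmed shift.
- **Land use** draws per-cell compositions over twelve LUH2-style
  states from a symmetric Dirichlet (concentration 1 by default, i.e.
  uniform on the simplex), so the ecosystem aggregation and
  fraction-weighted area code see non-trivial compositions that still
  sum to one.
- **Timelines** place country first records at the quantiles of a
  logistic curve truncated to the study window, so a steep midpoint
  yields lag/spread/equilibrium phases and a near-zero rate degenerates
  to uniform counts (a single phase under the default threshold).

What the simulator does *not* emulate: real bioclim covariance
structure (19 correlated variables), sampling bias, spatial
autocorrelation of occurrences beyond what suitability induces, or
GCM-specific future anomalies. Tests passing on synthetic data therefore
validate the machinery — estimators, transforms, bookkeeping, and
parameter recovery under the model's own assumptions — not the realism
of any particular empirical prediction.

## Problem sizes and numerical choices

The test-suite runs on worlds of 30 x 30 to 40 x 60 cells with 80–300
presences, 500–1500 background points, occupancy grids of R = 40–60,
and 99–100 permutations; the null-calibration check uses 200 simulated
equivalency tests. These sizes were chosen so the full statistical
behaviour (rejection rates, monotonicity across shift magnitudes,
recovery rates over 20 replicates) is exercised in minutes on a single
core while keeping Monte-Carlo noise well inside the asserted margins.
Degenerate inputs are handled explicitly rather than by accident:
constant covariates contribute only a (zero) linear feature with a
warning, zero-variance layers correlate with nothing in the Pearson
filter, all-zero suitability is a hard error for presence sampling, and
empty background intersections abort the niche dynamics rather than
returning numbers.

## Raster formats

Two interchange formats are supported natively: ESRI ASCII grid (plain
text, exact round-trip, convenient for fixtures and inspection) and
single-band float32 GeoTIFF (uncompressed, little-endian, with
ModelPixelScale/ModelTiepoint georeference, EPSG:4326 geokeys, and a
GDAL-style nodata tag). Reading accepts either byte order and
float32/float64 samples. Reprojection and resampling are deliberately
out of scope: stacking layers with mismatched grids is an error, never a
silent fix.
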