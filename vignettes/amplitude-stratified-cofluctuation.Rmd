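---
title: "Amplitude-stratified co-fluctuation analysis: models and design choices"
author: "cofluct package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-stratified co-fluctuation analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofluct)
```

# The model

Functional connectivity (FC) between two parcellated BOLD timeseries is
their Pearson correlation.  Because the correlation of standardized
signals is the temporal mean of their frame-wise product, FC decomposes
exactly into an *edge timeseries* (ETS)

$$E_{ij}(t) = z_i(t)\, z_j(t), \qquad \tfrac{1}{T}\sum_t E_{ij}(t) = r_{ij},$$

where $z_i$ is region $i$'s timeseries standardized over retained frames.
The instantaneous co-fluctuation amplitude is summarized per frame by root
sums of squares over edges,

$$\mathrm{RSS}^{\mathrm{global}}_t = \sqrt{\sum_{i<j} E_{ij}(t)^2},
\qquad
\mathrm{RSS}^{\mathrm{region}}_{i,t} = \sqrt{\sum_{j \ne i} E_{ij}(t)^2},$$

computed by closed forms in the $z$ values (never materializing the
$N(N-1)/2$ edge matrix):
$\mathrm{RSS}^{\mathrm{global}}_t = \sqrt{\big((\sum_i z_i^2)^2 - \sum_i z_i^4\big)/2}$
and
$\mathrm{RSS}^{\mathrm{region}}_{i,t} = \sqrt{z_i^2 (\sum_j z_j^2 - z_i^2)}$,
which satisfy $\sum_i (\mathrm{RSS}^{\mathrm{region}}_{i,t})^2 =
2\,(\mathrm{RSS}^{\mathrm{global}}_t)^2$ at every frame.

Retained frames are ranked by global RSS and cut into $M$ quantile bins
(default $M = 20$, 5% of frames per bin).  The **co-fluctuation score** of
region $i$ in bin $m$ is the ratio of within-bin means,

$$\mathrm{score}_{i,m} =
\frac{\operatorname{mean}_{t \in T_m} \mathrm{RSS}^{\mathrm{region}}_{i,t}}
     {\operatorname{mean}_{t \in T_m} \mathrm{RSS}^{\mathrm{global}}_{t}},$$

the region's relative contribution to whole-brain co-fluctuation in that
amplitude stratum.  The normalization makes maps comparable across bins:
if all regions were exchangeable every score would equal $\sqrt{2/N}$.

Two analyses build on the score matrix.  First, per-region **trajectories**
of score versus the bin-mean global amplitude are modelled with a
generalized additive model (GAM): a penalized thin-plate regression spline
smooth of amplitude plus linear sex and mean head-motion covariates, with
restricted-maximum-likelihood smoothness selection.  The *primary
amplitude effect* is the partial $R^2$ of the smooth — comparing the full
model against a nested reduced model without the smooth — signed by the
averaged first derivative of the fitted curve; the *second amplitude
effect* is the averaged second derivative (negative values indicate an
inverted-U trajectory).  Second, **spatial analyses** correlate score maps
between bins (Pearson, with average-linkage clustering of the bins) and
against reference axis maps such as a sensorimotor-association (SA) rank
map (Spearman), with significance from spatial-rotation ("spin") null
models that preserve the maps' spatial autocorrelation.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_bins` | 20 | bins | 5% of frames per bin; a 10-bin variant is supported for short scans and ranks regions consistently with merged 20-bin scores |
| `fd_threshold` | 0.2 | mm | framewise-displacement censoring applied by the readers; datasets with longer repetition times typically use 0.3 |
| `k` | 10 | basis functions | low-rank smooth; trajectories over 20 bins are smooth and simple, so the effective degrees of freedom stay well below `k` |
| `n_rotations` | 10000 | rotations | p-value resolution $1/(n+1) = 10^{-4}$; validation uses 100–1000 for speed |
| `bin_range_high` | [0.9, 1] | fraction | the top-decile stratum used for band-averaged contrasts |
| `bin_range_mid` | [0.4, 0.6] | fraction | the intermediate stratum |

# The synthetic cohort generator

Real parcellated BOLD cohorts at the scale this method targets are
access-controlled, so the package ships a generator whose
amplitude-dependent structure is known by construction and strong enough
to validate the full pipeline end to end.

Each frame draws a latent global-amplitude state $a_t \sim U(0,1)$ and
three class factors $f_S, f_A, f_L \sim N(0,1)$.  Region $i$ of class $k$
observes

$$x_i(t) = \sqrt{g_k(a_t)}\, f_k(t) + \sigma\, \varepsilon_i(t),
\qquad \varepsilon_i \sim N(0,1),$$

with default noise $\sigma = 0.3$ and gains

$$g_S(a) = 0.1 + 0.9\,a^2, \qquad
g_A(a) = 0.3 + 0.5 \cdot 4a(1-a), \qquad
g_L(a) = 0.05 + 0.1\,(1-a)^2.$$

The S class engages increasingly with amplitude, the A class peaks at
interior amplitudes, and the L class is deliberately *weakly coupled*.
The weak-coupling choice is what realizes a monotone decreasing score
trajectory, and it is worth spelling out why.  Because every region is
z-scored, only the *shape* of a class's gain relative to its own mean
matters; a strongly coupled class with a decreasing gain simply produces
strong co-fluctuation events at low latent amplitude, and those frames
land in high bins of *realized* global RSS — indistinguishable, after
standardization, from the increasing class (a mirrored construction with
$g_L(a) = 0.1 + 0.9(1-a)^2$ is exactly symmetric with the S class under
$a \mapsto 1-a$ and cannot be recovered even in principle).  A weakly
coupled region instead has regional RSS growing like
$|z_i|\sqrt{\sum_j z_j^2}$, i.e. like the square root of the global sum of
squares, while the global RSS grows linearly in it — so its score
declines mechanically with global amplitude.  That is also the natural
reading of the low-engagement (limbic-like) regime: regions whose
contribution is relatively largest when the brain-wide co-fluctuation is
quiet.

One consequence of the single-factor construction is that the A class's
realized trajectory peaks in the upper bins rather than mid-range: frames
where the A factor spikes are strong co-fluctuation events and therefore
sort into high realized-RSS bins.  The class still shows an interior
maximum and uniformly negative mean curvature, which is what the recovery
checks assert.

Ages are uniform on `age_range`, sex is Bernoulli(0.5), and mean
framewise displacement is $|N(0.1, 0.03)|$ — fixed, documented choices
that exist to exercise the covariate terms.  Developmental sharpening
raises the gain-contrast exponent linearly with age,
$e = 1 + \texttt{dev\_sharpening}\,(\mathrm{age} - 6)$, so amplitude
gating grows more selective with age; the default is 0 (adult cohort).
A `"movie"` condition blends the visual S-subset's gain halfway toward
the A profile, lowering those regions' high-amplitude scores and raising
their intermediate-amplitude scores relative to rest.  An AR(1) option
for the latent state exists but is off by default: the binning treats
frames exchangeably, so temporal autocorrelation adds realism without
changing any quantity the pipeline estimates.

What the generator does *not* emulate: hemodynamic response shapes,
physiological noise spectra, scanner drift, spatial noise correlations,
and within-class heterogeneity of coupling strength.  Passing recovery
tests therefore demonstrates that the pipeline's estimators measure what
they claim on data with known amplitude-gated structure — not that real
cortex follows three discrete classes.

# Numerical choices

- **Standardization convention.**  Z-scoring uses the population
  (divide-by-$T$) standard deviation over retained frames, and the edge
  mean divides by $T$; with matching denominators the ETS mean equals the
  Pearson correlation to machine precision.  "Unit variance" on scan
  objects therefore means unit mean square.
- **Censoring order.**  Frames are censored *before* the standardization
  statistics are computed, so corrupted frames cannot bias the z-scores;
  censored frames are dropped, not interpolated, because binning treats
  frames exchangeably.
- **Binning ties and remainders.**  Frames tied on global RSS keep their
  original order (stable sort); when $T$ is not a multiple of $M$ the
  extra frames go to the highest-amplitude bins.  Both rules are
  arbitrary but deterministic.
- **Smooth basis.**  Thin-plate regression splines with a *third-order*
  penalty (`m = 3`): quadratics sit in the penalty null space, so the
  curvature that the second amplitude effect measures is not shrunk
  toward zero by smoothing.  A noiseless quadratic input recovers its
  analytic second derivative ($-2$) to well within 2%, and a noiseless
  line is reproduced with partial $R^2 > 0.999$ and negligible curvature.
  Designs with fewer than five distinct amplitude values fall back to the
  second-order penalty that the basis dimension still supports.
- **Derivatives.**  Central finite differences on a 200-point uniform
  grid over the observed amplitude range, averaged over interior grid
  points; halving the step changes the averages by well under 1% on
  smooth fits.
- **Significance of the smooth.**  An F-type comparison of full versus
  reduced residual sums of squares using effective degrees of freedom
  (trace of the hat matrix), mirroring a nested-model analysis of
  variance.  A constant response short-circuits to partial $R^2 = 0$,
  $p = 1$.
- **Degenerate designs.**  Constant linear covariates are dropped with a
  warning rather than producing a rank-deficient design; zero-variance
  regions are an error at standardization (they cannot be z-scored).
- **Regime labels.**  Regions are labelled `flat` when the smooth is not
  significant at 0.05; `inverted-U` when the mean second derivative is
  below $-10^{-3}$ (a numerical floor) *and* the fitted curve peaks in
  the interior of the amplitude range; otherwise the sign of the mean
  first derivative decides between `increasing` and `decreasing`.  The
  interior-peak condition prevents convex accelerating trajectories from
  being mislabelled by small negative curvature estimates.
- **Spin variant.**  Parcel-level spinning: centroids are rotated by
  Haar-uniform random rotations (mirrored across the midline for the
  right hemisphere) and each parcel takes the value of the nearest
  rotated source centroid within its hemisphere.  Nearest-neighbour
  reassignment duplicates roughly $1 - 1/e \approx 0.6$ of sources per
  rotation — standard behaviour for parcel spins — which makes the test
  mildly anticonservative: simulated type-I error at $\alpha = 0.05$ on
  spatially uncorrelated maps sits near 0.05–0.07.  P-values are
  two-tailed on the absolute correlation, with the permutation floor
  $1/(n_{\mathrm{rotations}}+1)$.
- **Bin clustering.**  Average-linkage hierarchical clustering on
  $1 - r$ cut at $k = 2$, the simplest method that reproduces a two-block
  structure; when all bin maps are identical the bins are reported as a
  single cluster.

# Design choices where the design was open

- **Per-scan binning.**  Subjects with multiple runs are binned per run
  and averaged at the subject level, respecting run-wise amplitude
  distributions, rather than concatenating runs before binning.
- **Observation granularity.**  Trajectory models pool subject-by-bin
  observations per region (population-level smooth), not group means and
  not per-subject smooths; no random effects are fitted.
- **Condition contrasts.**  Two-sided paired t-tests by default (the
  design is within-subject), with a Wilcoxon signed-rank option; the FDR
  family is all regions within one band analysis.
- **Scores of roots, not of squares.**  Bin aggregation averages the RSS
  values themselves (roots), matching the score definition, never the
  squared amplitudes.

# Validation scale

The packaged checks run the full pipeline on cohorts of 20 subjects,
60 regions (20 per class) and 2000 frames per scan across 10 seeds for
regime recovery; 8 subjects and 1200 frames across 10 seeds for the
axis-alignment sign pattern; 1000 simulations with 500 rotations for spin
calibration; and 200 simulated paired cohorts for FDR control.  These
sizes give the recovery invariants comfortable margins (regime recovery
is typically 100% per class) while keeping the whole suite fast enough to
run routinely.

# Known limitations

- The spin test requires spherical centroid coordinates per parcel; maps
  on non-spherical geometries need an external projection first.
- The mild anticonservatism of nearest-neighbour parcel spins noted above
  is intrinsic to the variant; variogram-matched surrogate nulls are out
  of scope.
- Trajectory models assume scores are exchangeable across subjects given
  the covariates; familial or site structure is not modelled.
- The generator's three-class ground truth is a caricature of cortical
  organization — useful for validating estimators, silent on biology.
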