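---
title: "Methods: hyperspectral estimation of rice leaf nitrogen and its resolution sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral estimation of rice leaf nitrogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paddyspec)
```

## The problem

Leaf nitrogen concentration (LNC, percent of leaf dry mass) is the quantity a
rice agronomist needs for in-season fertilizer decisions. Canopy reflectance
carries an LNC signal mostly through chlorophyll absorption (nitrogen and
chlorophyll are tightly coupled within a growth stage) and through canopy
structure. A near-surface imaging spectrometer resolves single leaves at
roughly millimetre scale, which makes it possible to (i) separate pure leaf
pixels from water, soil and panicles before averaging spectra, and (ii)
simulate coarser sensors by aggregating pixels, asking where the estimate
starts to fail. `paddyspec` implements that full analysis and, because no
field imagery ships with it, a synthetic scene generator with complete ground
truth against which every stage of the pipeline is validated.

## The synthetic experiment

`experiment_design()` mirrors a two-year paddy trial: two cultivars, four
nitrogen rates (0/100/200/300 kg N/ha) with two row spacings at the middle
rates, giving 12 treatments in 3 randomized blocks — 36 plots imaged on 6
dates per year across the season (early/late tillering, jointing, booting,
heading, filling), 432 scenes in all.

Per-plot ground truth is drawn as:

* **LNC trajectory** — a stage-mean curve declining from 3.9 to 1.75 %,
  plus a nitrogen-rate offset (±0.45 % between the extreme rates) and plot
  noise (sd 0.12 %). The realized range, roughly 1.3–4.4 %, matches the
  span a full-season rice trial produces, and LNC declines monotonically
  with stage while increasing with N rate.
* **Green fraction (GF)** — stage defaults 0.15, 0.35, 0.60, 0.85, 0.90,
  0.90. Only the early-tillering mean (0.15) is strongly constrained by the
  literature; the later values encode canopy closure by booting and are a
  fixed design choice. GF is modulated by N rate (+10 % from lowest to
  highest), row spacing (−15 % for the wide spacing) and plot noise
  (sd 0.03), so background contamination varies between plots in a way that
  is only partly aligned with LNC — exactly the confound that makes
  whole-image spectra inferior to pure-leaf spectra.
* **Shade fraction** 0.40 ± 0.04 and, after heading, a panicle fraction of
  0.15–0.20 of vegetation.

### Scene rendering

Each 128 x 128 (tests mostly use 64 x 64; see *Problem sizes*) scene at
1.3 mm is built from smooth Gaussian random fields: a vegetation field
(clump scale 8 base pixels ≈ 1 cm) plus a cosine planting-row bias across
the scan axis is thresholded at the exact pixel count matching the target
GF, so the realized green fraction is within 1/npix of target by
construction. Shade and panicle masks come from finer-scale fields the same
way; the background is a water/soil/duckweed mosaic (70/20/10). Every pixel
receives its class endmember spectrum, then multiplicative Gaussian noise
(sd 0.02 of reflectance) and a smooth band-correlated baseline wiggle — the
structure MNF denoising is designed to remove.

### Endmember model

Leaf reflectance is parametric, not radiative-transfer: a visible baseline
joined to a NIR plateau by a logistic red edge, minus Gaussian absorption
features at 450 and 680 nm whose depth scales with a chlorophyll proxy
`chl` in [0, 1]. Two couplings give the model its realism:

* the red-edge inflection moves from 700 to 720 nm as `chl` goes 0 to 1, so
  red-edge indices (CI_Red-edge, MTCI, ND705 …) increase monotonically with
  chlorophyll, as they do on real leaves;
* the NIR plateau scales with a canopy-structure proxy (defaulting to the
  scene's green fraction), reproducing the observed growth of leaf-pixel NIR
  amplitude as the canopy closes. This matters for the global models: the
  season-wide LNC→chlorophyll relation is *stage-specific* (nitrogen
  dilution), so a spectrum must carry stage information beyond pigment depth
  for any global model to work. Structure in the NIR is that information.

Shaded spectra multiply the sunlit spectrum by a wavelength-dependent
brightness factor (≈0.33 in the visible rising to ≈0.72 in the NIR —
multiple scattering preserves NIR) with slightly deepened absorption. A
scalar shade factor cannot work here: it would push shaded vegetation below
the EVI = 0.45 vegetation cut or fail to pull it under the TCARI = 0.172
sunlit/shaded cut. Panicle spectra have a yellow visible slope, placing
their PRI at or below −0.058. The test suite verifies that *every*
endmember lies on the correct side of all four published thresholds over
the whole chlorophyll x structure range the scenes can produce; noiseless
scenes therefore classify at 100 %.

The stage-specific LNC→`chl` maps are linear, distinct for each vegetative
stage and shared across the reproductive stages. This is the mechanism
behind the package's stage-specific-model phenomenon and is the reason a
pooled vegetative VI model validates far worse than per-stage models.

### What the generator does not emulate

No bidirectional reflectance effects beyond the scalar/logistic shade
factor, no sensor point-spread function (aggregation is an ideal block
mean), no within-scene LNC gradients, no leaf angle or 3-D structure, and
chlorophyll is the only pigment axis. Passing tests therefore demonstrate
that the *pipeline* is correct and that the paper-style findings follow
from its assumptions — not that those findings transfer to any particular
field dataset.

## Preprocessing

Calibration is the standard two-point radiometric equation per pixel and
band; dark current is a per-band vector (pushbroom sensors drift by channel,
and the generator synthesizes DN data the same way, so the round trip is
exact at zero noise). MNF estimates the noise covariance from single-pixel
horizontal shift differences within rows; because class boundaries
contaminate differences with signal, only the smaller-magnitude half of the
difference vectors is kept (within-patch, noise-dominated) before the
covariance is formed. The data covariance is whitened against it, the
leading components kept (default: whitened eigenvalue > 2, i.e. SNR above
1), and the transform inverted. Processing order is calibrate → denoise →
subset to 400–900 nm, since out-of-window bands are noisy even after
smoothing but still help the noise estimate.

## Classification and threshold adaptation

The decision tree runs EVI (three-band form, 800/670/470 nm), then PRI,
then TCARI, with the published base-resolution cut-offs 0.45 / −0.058 /
0.172 / 0.241 as defaults. "Greater than" branches are strict; ties fall to
background, panicle, or shaded.

At degraded resolutions mixed pixels shift the index distributions, so
fixed thresholds misstate the green fraction. `adapt_thresholds()` re-solves
the cut-offs so the *class proportions* of the base-resolution reference are
reproduced: three monotone bisections in tree order (GF, then leaf share
among vegetation, then the sunlit shares), each to a share mismatch of at
most 0.005 or 60 iterations. The share function is a step function with
steps of 1/n, so on very coarse grids the target may be unreachable; the
nearest achievable threshold is returned with a warning. Matching
proportions, rather than reproducing any particular threshold trajectory,
is the stated objective of the strategy; the EVI threshold indeed falls
with coarsening on sparse (early tillering) canopies. Adaptation is pooled
per stage-date by default (`threshold_scope = "stage"`), since one
threshold profile per stage is the natural reporting unit; per-plot
adaptation is available.

At the whole-swath ladder entry a single pixel remains, so no per-class
spectra exist: all three leaf pixel types receive the whole-image mean of
the base-resolution cropped cube (`coarsest_level_spectrum()`). The same
rule covers any ladder entry whose aggregated image would not exceed one
pixel for the configured scene size.

## Resolution ladder

Nominal resolutions halve the 450 mm swath: `round(450 / 2^k)` (half-up;
112.5 mm prints as 113) descending while the rounded value exceeds the
base, headed by the base resolution itself — ten levels for (1.3, 450).
Aggregation factors are `round(nominal / base)`, and both the nominal label
and the realized resolution `base * N` are stored (N = 2 realizes 2.6 mm
under the "2 mm" label). Blocks that do not fill are dropped rather than
padded, which keeps block means unbiased; the block mean preserves the
spatial mean exactly and composes dyadically.

## Models and evaluation

Spectra are averaged per pixel type *first* and indices computed from the
mean spectrum (never the mean of per-pixel indices); the three classifier
indices are the necessary exception. Splits hold out one replicate block
(default block 3) for validation, 2:1 by design: 288/144 globally, 144/72
for the reproductive group, 24/12 per single pre-booting stage-date.

* **Stage VI models** are ordinary least squares of LNC on one index.
  Linearity is adequate within a stage because the LNC→chlorophyll map is
  linear there.
* **PLSR** is univariate SIMPLS on mean-centred spectra (no per-band
  scaling); the latent count minimizes leave-one-out RMSE on the
  calibration set, with per-band coefficients exposed for importance
  profiles. The implementation is checked against an independent PLS
  implementation (`mixOmics`) to machine precision in the test suite.
* **GPR** uses a zero-mean GP on per-band standardized spectra with an
  anisotropic squared-exponential kernel — one lengthscale per band plus
  signal and noise variances — fitted by L-BFGS-B on the log marginal
  likelihood with analytic gradients and a fixed-seed multi-start (the
  gradient is computed in O(n²p), so 251-band models remain tractable).
  ARD is the kernel of choice because the per-band lengthscale is the
  band-relevance diagnostic: the smallest lengthscales mark the most
  informative wavelengths, and on constructed problems the known
  informative bands are recovered exactly. Non-convergence returns the
  best-found parameters with a warning rather than failing a sweep.

Metrics are the predictive `R^2 = 1 − SS_res/SS_tot` (not a squared
correlation), RMSE in LNC percentage points, and squared Spearman rank
correlation (average ranks on ties). Stage-scope sensitivity profiles use
rho² over all samples of the scope (calibration and validation pooled);
global profiles use validation R²/RMSE.

## Optimal resolution

Coarser pixels mean faster acquisition, so among statistically similar
resolutions the coarsest is preferable. `select_optimal_resolution()`
formalizes this: the coarsest resolution whose metric is within `delta`
(default 0.03) of the ladder's best. On profiles with the characteristic
plateau-then-decline shape this returns an interior resolution; on flat or
improving profiles it correctly returns the coarsest.

## Numerical choices and degenerate inputs

Continuum removal divides by the upper convex hull (Andrew's monotone
chain) over 550–750 nm, with endpoints set to exactly 1; non-positive
reflectance in the window is an error. Zero denominators in any index give
`NA` with a warning naming the index. Nearest-band lookup refuses distances
over 10 nm and breaks ties toward the lower wavelength. Zero pixels of a
requested class yield a missing-value spectrum, never zeros. Bisections on
share step functions return the endpoint with the smaller miss. The MNF
noise covariance receives a relative ridge (warned) when singular. All
stochastic components flow from a single integer seed per experiment;
identical seeds give bit-identical scenes, samples and profiles.

## Problem sizes

The default scene is 128 x 128 pixels at 1.3 mm with 251 bands (400–900 nm
at 2 nm). The test and acceptance runs size their simulations to what the
questions need: design-arithmetic checks render 16 x 16 scenes (counts do
not depend on scene content), classification fidelity uses full 128 x 128
scenes, and the multi-seed sensitivity sweeps use 64 x 64 scenes — at that
size the cropped image still supports aggregation factors up to 22 (nominal
28 mm) before the whole-image rule takes over, which is enough to exhibit
the plateau-then-decline shape. Ten independently seeded experiments back
the qualitative claims (monotone decline beyond the mixing onset, all-leaf
stability, stage-specific superiority).

## Known limitations

The generator's simplicity caps how far numeric agreement with field
studies can be pushed: absolute rho² values depend on unavailable imagery,
so the package asserts qualitative shape and ground-truth recovery instead.
TCARI/OSAVI, designed to cancel structure effects that this generator
largely lacks, self-normalizes its own chlorophyll response here and is a
weak index in the synthetic world even though it is strong in the field —
the representative red-edge indices (CI_Red-edge, MTCI) carry the synthetic
signal. GPR hyperparameter optimization is non-convex; the fixed-seed
multi-start makes it reproducible but not provably global.
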