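---
title: "Bridging ground, UAS and satellite scales for winter-wheat cover estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging ground, UAS and satellite scales for winter-wheat cover estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatfvc)
```

## The problem

Fractional vegetation cover (FVC) -- the vertically projected fraction of
ground occupied by green canopy -- is a basic trait for monitoring crop
growth, calibrating crop models and estimating biomass. Satellite surface
reflectance gives wall-to-wall coverage but at a 10 m pixel scale, far
coarser than the ~2 m ground plots on which cover can actually be measured;
centimetre-scale UAS multispectral imagery measures cover in exquisite
detail but only over small flight footprints. `wheatfvc` implements a
three-tier workflow that bridges these scales for winter wheat:

1. **Ground**: cover is extracted from RGB plot photos by a two-Gaussian
   fit to the CIE L\*a\*b\* a\*-channel histogram.
2. **UAS**: a regression model (random forest by default) trained on the
   ground samples converts 2 m-aggregated UAS reflectance into
   wall-to-wall 2 m cover labels.
3. **Satellite**: a small backpropagation network (3 inputs, 6 sigmoid
   hidden nodes, linear output) is trained on pairs of *downscaled* 10 m
   satellite reflectance and the 2 m UAS-derived labels, and then predicts
   cover from satellite data alone.

The distinctive element is the *upscaling--downscaling* strategy: instead of
degrading everything to the satellite grid, the satellite raster is
interpolated down to the 2 m plot scale by cubic convolution while the UAS
raster is aggregated up to the same grid, so the learning problem is posed
at the scale where ground truth lives and the product retains sub-pixel
(relative to the satellite) detail.

Because no public field campaign accompanies this problem, the package
ships a seeded synthetic scene generator that reproduces the statistical
structure the workflow relies on; every stage is tested end to end against
known synthetic truth.

## Ground-photo segmentation

In CIE L\*a\*b\*, the a\* axis opposes green (negative) to red (positive).
A wheat-canopy photo therefore shows a bimodal a\* histogram: a vegetation
mode at negative a\* and a soil/residue mode near or above zero. The
density is modelled as

$$f(x) = w_1\,\mathcal N(x;\beta_1,\delta_1) + (1-w_1)\,\mathcal N(x;\beta_2,\delta_2),
\qquad \beta_1 < \beta_2,$$

fitted by nonlinear least squares to a 256-bin density histogram
(`fit_a_mixture()`). The fit is started from both the two dominant
histogram peaks and a k-means split of the raw values, keeping the
better-fitting solution; histograms of single photos (~10^4 pixels over 256
bins) are noisy enough that a single bad start can otherwise send one
component to a wide, meaningless blob. A fit is flagged degenerate when the
means are closer than the wider standard deviation, a weight collapses, or
the fitted density has no valley between the means (the all-vegetation
case); degenerate photos require a manually supplied threshold, mirroring
the visually judged thresholds practitioners use for waterlogged plots.

The segmentation threshold is the point in $(\beta_1, \beta_2)$ where the
two *weighted* component densities are equal -- the boundary that minimises
misclassification under the fitted mixture. Two cover estimates are
reported: the thresholded pixel fraction, and the fitted weight $w_1$. The
weight is the headline estimate because it stays unbiased when the
components overlap: thresholding misassigns the two overlap tails, and the
errors only cancel in the symmetric case. Both numbers are returned so the
user can compare.

Sampling design: each ground site is a 10 m square with five 2 m
sub-squares on its diagonals (centre + four, centres offset 2.5 m along
each axis). The mean of the five is the 10 m reference; the centre
sub-square alone is the 2 m reference.

## Scale bridging

**Downscaling** uses cubic convolution with the interpolating kernel

$$W(x)=\begin{cases}|x|^3-2|x|^2+1 & |x|<1\\ -|x|^3+5|x|^2-8|x|+4 & 1\le|x|\le2\\ 0&\text{otherwise,}\end{cases}$$

the $a=-1$ member of the cubic-convolution family. Each 2 m value is the
separable product of a 1x4 row-weight vector, the 4x4 source
neighbourhood, and a 4x1 column-weight vector. The pixel-centre mapping
`src = (dst + 0.5)/factor - 0.5` was chosen because, for odd factors, the
centre fine pixel of each block coincides exactly with a source pixel, so
the original 10 m radiometry is preserved at the centres of the resampled
2 m pixels -- a property the workflow relies on and the tests assert
exactly. Borders replicate the edge pixel. Nodata handling is
flag-selectable: propagate (any nodata in the 4x4 support poisons the
target, the default) or renormalise over the remaining weights; the kernel
weights sum to one for every fractional offset, which is what makes
constant rasters exact and renormalisation well defined.

**Upscaling** is zonal aggregation: a 2 m cell takes the mean of the fine
pixels whose centres fall inside it, with half-open cell extents so
membership is never ambiguous. 2 m cover maps aggregate to 10 m by 5x5
block means, with nodata propagating so partial blocks stay empty.

## UAS cover models

Four estimators map UAS data to 2 m cover:

* **Random forest** (`train_rfr()`): variance-reduction regression trees on
  the four camera bands (green 550, red 660, red-edge 735, NIR 790 nm).
  The `(mtry, ntree)` pair is selected by seeded 10-fold cross-validated
  RMSE. The defaults probe mtry 1--4 (there are only four predictors; the
  published search range extends to 31 for hyperspectral use) and ntree
  100--500 in steps of 100 -- forests on a four-band problem saturate well
  below 500 trees; both grids are arguments. Ties go to the simpler model.
* **Support-vector regression** (`train_svr()`): RBF-kernel
  epsilon-regression on z-scored bands, with `(gamma, cost)` grid-searched
  the same way. Predictions are the kernel expansion over the support
  vectors plus bias, which a test checks explicitly.
* **NDVI pixel dichotomy** (`dichotomy_fvc()`): linear unmixing
  $FVC = (NDVI - NDVI_s)/(NDVI_v - NDVI_s)$ between a soil and a
  full-canopy endmember. Endmembers come from percentiles of the NDVI
  raster (default 5th/95th) or literal overrides -- e.g. values calibrated
  against ground samples. The percentile rule assumes both pure classes are
  actually present in the scene; on a jointing-stage scene that never
  reaches full canopy it is biased, which is why the override path exists.
* **Half-Gaussian histogram** (`hagfvc()`): for RGB orthophoto tiles, the
  outer left flank of the vegetation a\* peak and the outer right flank of
  the background peak are each fitted with a half-Gaussian; the threshold
  is the equal-density point of the two reconstructed full Gaussians. Tiles
  without two genuinely separated modes (fewer than 30 populated flank
  bins, or no valley between the dominant peaks) are flagged degenerate.

On synthetic scenes built with the NDVI-linearity option (endmember red+NIR
sums equal, making NDVI exactly linear in cover) the dichotomy with true
endmembers recovers truth to 10^-6, which pins down the unmixing
arithmetic. When extra NIR variance is injected over dense canopy --
emulating the saturation of NDVI at high cover -- the dichotomy error at
FVC > 0.8 exceeds the forest's, which can lean on the unperturbed bands;
this ordering is asserted on seeded scenes.

## The satellite network

The retrieval network is deliberately small: 3 band inputs (green, red,
NIR), 6 logistic-sigmoid hidden nodes, linear output -- at most 31 weights.
(The published satellite preprocessing selects red/red-edge/NIR bands but
the retrieval itself is stated on green/red/NIR; the band list is an
argument with green/red/NIR as default.) Inputs are z-scored with
training-split statistics; targets stay on the cover scale and predictions
are clipped to [0, 1] with the clip count reported.

Training is full-batch Levenberg--Marquardt: solve
$(J^\top J + \lambda I)\,\delta = J^\top r$, accept the step if the
training SSE drops (then $\lambda \leftarrow \lambda/10$), otherwise raise
$\lambda$ tenfold and retry. $\lambda$ starts at 10^-3. Identity damping
was chosen over Marquardt's diagonal scaling after the latter proved
fragile here: when the output-layer weights are small the diagonal entries
for the input-layer columns collapse and the damped system stays
ill-conditioned, stalling training from some initialisations. Weights are
initialised uniform in (-0.5, 0.5) from the config seed; the data split is
8:1:1 train/validation/test.

Stopping combines a goal with a patience rule. The validation-RMSE goal is
0.06 -- the accuracy level at which a cover product is considered usable at
this scale -- and the patience rule stops after 15 iterations whose
validation RMSE changes by less than a relative 10^-5. The goal binds only
once the RMSE is at or below it *and* no longer improving materially: the
first LM step from a random initialisation is nearly an undamped
Gauss--Newton jump and can land anywhere below the goal, so stopping at the
first dip would freeze a half-converged network whose quality is a lottery
of the initialisation. On hard problems where 0.06 is barely attainable the
two formulations coincide (the goal is reached only near convergence); on
easy ones the combined rule trains the extra handful of iterations to the
plateau. A non-finite trial SSE is treated as a rejected step (damping
increases); training aborts only after 30 consecutive rejections, which at
convergence simply means no further improving step exists.

`data_volume_experiment()` quantifies accuracy versus training-set size: a
fixed held-out set is split off once, and for each size the network is
retrained on fresh subsamples, several repeats per size, reporting mean and
spread of the held-out RMSE.

## The synthetic scene generator

The generator emulates exactly the structure the workflow assumes, no more:

* **Cover field**: seeded white noise smoothed with a Gaussian kernel
  (standard deviation half the correlation length) and rescaled to the
  stage's cover range inside rectangular wheat plots; bare path corridors
  are zero cover. Defaults: jointing-stage cover 0.25--0.75, booting
  0.65--0.95 (dense canopy with the wheat rows closed), correlation length
  12 m -- management and soil variation in flat irrigated fields varies at
  the tens-of-metres scale.
* **Reflectance**: per pixel and band, linear vegetation/soil endmember
  mixing plus Gaussian sensor noise, clipped to [0, 1]. Default endmembers
  give canopy NDVI ~0.9 and soil NDVI ~0.1, typical for green wheat on
  loam; noise defaults to 0.01 reflectance units (~1%), a realistic
  surface-reflectance uncertainty. All spectra are arguments.
* **Satellite degradation**: block means over the fine grid (an idealised
  top-hat point-spread function). In the pipeline the 10 m reflectance is
  rendered from the block-averaged cover field with the sensor noise drawn
  at the 10 m scale -- by linearity of the mixing rule this equals
  averaging noiseless fine reflectance and adding noise at the sensor's own
  resolution, which is where satellite noise actually enters.
* **Photos**: a pixel fraction equal to the target cover is drawn as
  vegetation; a\* values follow the class Gaussians (defaults: vegetation
  -18 +/- 4, background +8 +/- 5), L\* and b\* are per-class constants so
  the a\* histogram is the only information channel; L\*a\*b\* converts to
  sRGB under D65 with out-of-gamut clipping reported.
* **Scene layout** (`default_scene()`): 400 m x 200 m with two large plots
  separated by a 4 m path, emulating contiguous production fields where
  plot interiors dominate but a sharp cover boundary exists for
  edge-effect analysis. The default fine grid for this large scene is
  0.5 m (16 fine pixels per 2 m cell); `scene_config()` itself defaults to
  0.05 m for photo-scale work. At 0.5 m the zonal statistics of linear
  mixing are unchanged while a 400 m scene stays ~0.3 M cells per band.

What the generator does *not* emulate -- and hence what passing tests do
not establish about real data: radiative-transfer canopy effects (BRDF, row
geometry, shadowing), atmospheric residuals, georegistration error, mixed
weed/residue classes, and non-Gaussian photo colour distributions. The
linear-mixing world is the friendliest possible one for the NDVI dichotomy
and for a 31-weight network; real-data accuracies will be worse, and
comparisons between estimators here only probe the structural effects
(scale gap, saturation, boundary mixing) that the generator does encode.

## Evaluation

`fvc_rmse()` and `fvc_r2()` implement RMSE and the prediction coefficient
of determination $1 - SS_{res}/SS_{tot}$ (the regression-SS form printed in
some method descriptions equals this only for an OLS fit with intercept,
so the residual form is used and said so).
`boundary_interior_eval()` samples a fixed number of cells (default 150)
within 5 m of a plot edge and deep inside plots, reporting per-stratum
accuracy -- the coarse sensor mixes wheat and path signal at edges, and
this stratification shows how much of the total error lives there.
`strategy_comparison()` tabulates RMSE for the upscaling--downscaling
pipeline against an upscale-only comparator (the same network trained on
native 10 m pairs) and reports the relative RMSE reduction.

## Problem sizes and reproducibility

The default pipeline scene yields 20,000 2 m training pairs (a 200 x 100
cell analysis grid from a 40 x 20 pixel satellite raster), 30 five-photo
ground sites, and trains in well under a minute on one core; the
data-volume experiment uses a 440 m x 220 m variant (24,200 pairs) so a
20,000-pair subsample leaves an untouched pool. These sizes were chosen to
keep a full multi-seed test suite comfortably interactive while matching
the published experiment's order of magnitude (~28k pairs). Every stage
takes an explicit seed and restores the caller's RNG state, so identical
configurations reproduce byte-identical tables; the pipeline manifest
records a hash of the configuration with every run.

## Known limitations

* The regression label models cannot extrapolate below the sampled cover
  range: bare paths, never visited by the five-point sites, are labelled at
  the lowest sampled cover rather than zero. The network inherits this
  bias in the path corridors; it is visible in the boundary stratum of the
  evaluation and is a faithful reproduction of a real limitation of
  sample-trained label models.
* Percentile endmember selection for the dichotomy assumes both pure
  classes occur in the scene; calibrate endmembers against ground samples
  (literal overrides) when they do not.
* The 2 m target grid is assumed co-registered across sensors;
  georegistration error is out of scope.
* `hagfvc()` requires a genuinely bimodal tile and refuses (degenerate
  flag) otherwise rather than guessing.
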