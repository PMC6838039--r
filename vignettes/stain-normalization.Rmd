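---
title: "Methods: stain normalization, color-constancy metrics, and segmentation evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stain normalization, color-constancy metrics, and segmentation evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hestain)
```

## The optical model

Brightfield transmission through a stained section follows the Beer–Lambert
law, `I = I0 * exp(-V S)`: absorbances add linearly in optical density
`OD = log(I0 / I)`, where the columns of the 3×2 matrix `V` are unit OD-space
color vectors of hematoxylin and eosin and `S` holds the per-pixel stain
concentrations. Everything stain-related in this package — deconvolution,
Macenko estimation, spectral-matching and quantile-mapping normalization, and
the synthetic renderer — is built on this model.

Assumptions worth stating explicitly:

* **Two stains.** `V` is 3×2. A two-stain model is the standard H&E reading;
  a third absorber (e.g. melanin, formalin pigment) is projected onto the
  H&E plane by the least-squares deconvolution `S = pinv(V) OD` and will
  surface as spurious concentration.
* **`V` is 3×2, so "inversion" means pseudo-inverse.** The deconvolution is
  the orthogonal projection of each pixel's OD vector onto the stain plane.
  Small negative concentrations are legitimate least-squares output; they are
  preserved in `ConcentrationMap`s and clipped only at recomposition.
* **Brightfield `I0` defaults to 255 per channel** and is overridable
  per call; the package does not estimate it from the image. Zero-intensity
  pixels are clamped to 1 before the log so OD stays finite, and pixels
  brighter than `I0` clamp to it so OD stays non-negative.

## Stain-vector estimation

`estimate_stain_matrix()` implements the SVD/percentile scheme: discard
pixels whose OD norm is below `od_threshold` (default **0.15** — the common
choice for separating tissue from brightfield), find the dominant plane of
the remaining OD cloud by SVD, and take the directions at the
`angular_percentile` (default **1%**) extremes of the in-plane angle
distribution. Both parameters are exposed because they are conventions, not
physics. Columns are clamped to non-negative OD, renormalized, and ordered
by the rule *hematoxylin = larger blue OD component* (tie-break: larger
green); the rule is stated because every downstream per-stain statistic
depends on a deterministic column identity.

Degenerate inputs raise classed errors rather than returning garbage: fewer
than 20 foreground pixels (`min_foreground`) or a second singular value below
`1e-6` of the first (an OD cloud collapsed onto one chromatic ray) give a
`he_degenerate_stain` condition.

On rendered synthetic scenes with OD noise 0.01, estimates land within
about 3 degrees per column of the generating matrix; the test suite requires
95 of 100 seeded renders within 5 degrees.

## The four normalizers

All four share one contract: `fit_reference(ref, method)` captures reference
statistics once; the returned model is a deterministic, JSON-serializable
function of the reference.

* **HS** — per-RGB-channel histogram specification. The lookup table maps
  each query level to the smallest reference level whose CDF reaches the
  query CDF. Exact self-identity on levels present in the image.
* **RH** — Reinhard color transfer: per-channel mean/sd matching in Ruderman
  lαβ. If a query channel has (numerically) zero variance the scale step is
  skipped and only the offset applied. Note the channel naming: **α is the
  red–green opponent** `(log L − log M)/√2` and **β the yellow–blue**
  `(log L + log M − 2 log S)/√6`. This follows the convention used by the
  color-error metrics in this field's CN-evaluation literature; Reinhard's
  original paper names the axes the other way around. The log is natural,
  and the LMS values are floored at 1e-6 before the log.
* **MC** — Macenko spectral matching: deconvolve the query with its *own*
  estimated matrix, rescale each stain channel so its robust maximum
  (default **99th percentile**, configurable — "maximum" alone would be
  hostage to a single pixel) matches the reference's, recompose with the
  *reference* matrix.
* **KH** — quantile-mapping stain-channel normalization, documented as
  *KH-style*: after deconvolution each stain channel is pushed onto the
  reference channel's distribution by a monotone quantile map
  (plotting-position ranks against a 1001-point reference quantile grid,
  linear interpolation). This keeps the defining property of stain-specific
  nonlinear color transfer — reference stain-channel statistics imposed on
  the query — while replacing the original classifier-driven spline
  formulation, which is out of scope here.

All methods round half-up and clamp to `[0, 255]`; half-up (rather than R's
round-half-even) is fixed so that reports are bit-reproducible across
platforms.

## Color-constancy metrics

NMI and NMH are self-normalized ratios, `median / 95th-percentile`, of the
channel-mean intensity and of the HSV hue respectively. Two consequences
shape their use:

* They are deliberately robust to global scaling — a uniformly darker image
  has nearly the same NMI. What they detect are changes in distribution
  *shape and position*, which is why they are summarized across a population
  by the CV (sample sd / mean; sample, because CN study populations are
  small).
* Hue is treated as a **linear** quantity in degrees `[0, 360)`, exactly as
  the plain median/percentile definition implies. For H&E this is safe —
  hematoxylin sits near 240°, eosin near 300–330°, far from the wrap point —
  but for stains whose hue straddles 0°/360° the metric would become
  unstable; the package does not attempt circular statistics because the
  metric is defined linearly.

Per-image hue statistics run over chromatic pixels only; hue is undefined at
zero saturation, so gray pixels are masked out rather than counted as red
(hue 0). A fully achromatic image raises `he_undefined_metric`, and
`population_report()` records such images as missing with a count instead of
poisoning the CV.

AMCE pools the means of non-overlapping 64×64 windows (configurable; partial
edge windows are discarded) of the α and β channels per image set and
reports the absolute difference of the pooled means. When the two sets have
unequal pooled lengths the means are taken over each *full* list rather than
truncating to the shorter one: truncation would make the statistic depend on
the arbitrary order in which images are listed and silently discard most of
the larger set. The two conventions coincide whenever the sets match in size,
which is the only case the windowed definition pins down.

CD is the window-averaged grayscale `sd/mean` of the normalized image minus
that of the un-normalized one; windows with zero mean in either image are
excluded from both sums so the statistic stays anti-symmetric. Its CV is
reported as-is but can be unstable when the mean CD is near zero.

Medians and percentiles everywhere use linear interpolation between order
statistics (R type 7), stated so that all worked examples are exactly
reproducible.

## Ensembling, binarization and post-processing

The ensemble combiner is the plain channel-wise arithmetic mean of N
probability maps — agreement reinforces, disagreement attenuates. Maps may
be softmax-style (channels sum to 1) or sigmoid-style (independent
channels); the combiner does not renormalize. Hard labels use per-pixel
argmax with ties broken toward the *lower* class index
(background < boundary < nuclei): deterministic and conservative, preferring
a missed nucleus over a hallucinated one.

Binarization of the nuclei channel offers Otsu (between-class variance
maximization on a 256-bin histogram; strictly-above convention) and a fixed
threshold (default 0.5; at-or-above convention). Otsu on a constant channel
is undefined and falls back to fixed 0.5 with a warning.

Post-processing applies, in order: a 3×3 binary median filter (for a binary
image the median is the 9-neighbor majority; the border is zero-padded),
morphological closing with a disk of radius `se_radius` (default **2 px**),
filling of enclosed holes (background regions with no 4-connected path to
the border), and removal of 8-connected components below `min_object_px`
(default **30 px**). The defaults suit nuclei at roughly 40× magnification
and are configurable. One subtlety: a single pass of a median filter over a
curved boundary is not a fixed point — convex corners keep eroding — so the
chain is iterated until the mask stabilizes (3–5 passes in practice, capped
at 25). That makes the operation idempotent and the postconditions (no
enclosed holes, no undersized components) checkable invariants rather than
aspirations. Connectivity is fixed at 8 for foreground components and 4 for
hole detection so all object counts are reproducible; small-object removal
applies to whichever class mask the caller passes.

## Segmentation scores

Dice, Jaccard, extra fraction, precision and recall are computed from exact
pixel confusion counts; evaluation is pixel-level throughout (object-matched
indices such as AJI are out of scope). An empty *label* makes the overlap
scores undefined and raises a condition; an empty *prediction* reports
precision 0 with an explicit flag, keeping population aggregation total.
Aggregation uses sample statistics with missing scores excluded and counted;
images are weighted equally.

## The synthetic multicenter generator

`generate_scene()` builds a ground-truth world: non-overlapping random
ellipses as nuclei (rejection sampling, bounded attempts, classed placement
error listing the achieved count), a 2 px boundary ring around each, and
concentration fields — hematoxylin ~0.9 in nuclei with an accentuated 0.7
rim, eosin ~0.35 in a smoothly textured stroma. Hematoxylin also bleeds into
the stroma with its own smooth texture (0.18 ± 0.18): real tissue shows a
continuum of stain mixing, and without it the hue distribution collapses to
a narrow band in which the ratio-based NMH cannot register any center
effect. Rendering is Beer–Lambert with Gaussian OD noise (sd **0.01**, a
quiet-camera level that leaves chromaticity clearly recoverable). Every
stage draws from a stream derived from `(seed, operation)`, so scenes,
renders and predictions are pure functions of their parameters.

`generate_multicenter()` layers center effects on top, emulating the classic
sources of inter-laboratory variability:

* stain-vector jitter up to `stain_jitter_deg` per column (draws that would
  leave eosin bluer than hematoxylin are resampled — such a matrix no longer
  depicts an H&E pair, and no method, including the ones under study, could
  identify the stains in it);
* overall staining intensity U(0.75, 1.25) and per-dye protocol factors
  U(0.85, 1.15);
* scanner tone curve: gamma in 0.8–1.25 applied to the rendered image;
* illumination color: a warm/cool white point (±24 levels of red–blue skew
  around a 235–243 white).

Gamma and warmth are drawn by stratified (Latin-hypercube-style) sampling
across centers: with only three centers, independent draws occasionally
produce near-identical scanners, which is no longer the multicenter problem
being simulated. All scanner draws precede the jitter draws so that cohorts
generated at different jitter levels under the same seed share identical
scanner conditions — this is what makes "jitter strictly increases pooled
hue variability" a clean, matched-pairs property.

What the generator does **not** emulate: real tissue architecture (glands,
lumina, necrosis), instrument blur and chromatic aberration, JPEG artifacts,
out-of-focus regions, or annotation noise in the ground truth. Passing tests
on this substrate therefore demonstrate the correctness and the qualitative
behavior of the algorithms — not performance figures transferable to any
real cohort.

`simulate_predictor()` stands in for trained segmentation networks: it flips
each pixel's true class with probability `flip_prob`, concentrates
probability mass `sharpness` (default 0.9) on the resulting class, adds
truncated Gaussian channel noise, and emits either softmax- or
sigmoid-style maps. Because its errors are independent across simulated
models, ensembling visibly denoises — on 20 scenes at flip 0.15 and six
models the fused Dice beats the median single model on every scene — which
is the property the combiner exists to exploit.

## What the population experiments show

On a 3-center, 10-images-per-center cohort at 15° jitter, each normalizer is
fitted to a single clean reference render and applied to the pooled cohort.
HS, MC and KH reduce the CV of both NMI and NMH by factors of 3–15 across
every development seed we examined; MC and KH also reduce AMCE α and β
against the reference, as expected from methods that re-express the image in
the reference's stain basis. RH reduces CV(NMI) reliably and CV(NMH) in most
cohorts, but *can* fail to reduce hue variability when the between-center
difference is dominated by stain rotation: a per-channel affine map in lαβ
cannot rotate hue. This is a genuine property of Reinhard-style transfer,
not an implementation artifact — published CN evaluations likewise report
datasets where RH increases a CV — and it is the reason the method
comparison in this package treats RH's hue behavior as cohort-dependent.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use scenes of 96–256 px, cohorts
of 30 images, 100-render estimation studies and 20-scene ensemble studies.
These sizes put every statistic comfortably into its asymptotic regime for
the properties being checked (CV ratios, angular errors, Dice orderings)
while keeping a full run in minutes on one core; all of them scale up by
changing `scene_params()` and the cohort arguments.

## Known limitations

* Reference quality is the user's problem: the toolkit deliberately does not
  select references, and a poor reference propagates into every normalized
  image.
* The KH-style normalizer preserves stain-channel *marginals*, not the joint
  H–E dependence structure.
* NMH's linear hue treatment is unsuitable for stains near the red wrap
  point.
* MC and KH inherit every failure mode of stain estimation; on images with a
  single effective stain they raise degenerate-stain errors by design.
* GAN-based normalization is supported only as a pass-through of externally
  normalized images.
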