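# hestain

Color normalization and segmentation evaluation for H&E histopathology, in R.

Hematoxylin-and-eosin (H&E) slides digitized at different laboratories differ
markedly in color: staining protocols, section thickness, scanner illumination
and tone curves all drift between sites. Deep segmentation models trained at
one center therefore degrade at another, and *color normalization* (CN) —
mapping every image onto the color distribution of a reference — is the
standard remedy. `hestain` provides the full quantitative machinery around
that workflow for researchers studying CN and its effect on nuclei
segmentation:

* **Stain model.** Beer–Lambert optical density transforms
  (`OD = -log(I/I0) = V S`), SVD-based (Macenko) estimation of the 3×2 unit
  stain matrix `V`, least-squares deconvolution into hematoxylin/eosin
  concentration maps `S`, and recomposition.
* **Four classical CN methods** behind one fit-reference/apply contract:
  histogram specification (HS), Reinhard color transfer in Ruderman lαβ space
  (RH), Macenko spectral matching (MC), and a quantile-mapping stain-channel
  method (KH-style). Externally normalized (e.g. GAN) images enter as a
  pre-normalized directory.
* **CN quality metrics**: normalized median intensity
  `NMI = median(A)/P95(A)` of the channel-mean image `A`, normalized median
  hue `NMH = median(H)/P95(H)` of the HSV hue channel (color rather than
  brightness constancy), window-averaged absolute mean color error (AMCE) in
  the lαβ opponent channels, and contrast difference (CD); all aggregated
  over an image population by the coefficient of variation `CV = sd/mean`.
* **Ternary segmentation utilities**: per-pixel
  (background, boundary, nuclei) probability maps, ensemble averaging
  `E = (1/N) Σ P_n`, Otsu or fixed-threshold binarization, and a
  median → closing → hole-fill → small-object-removal post-processing chain.
* **Overlap scores**: Dice `2TP/(2TP+FP+FN)`, Jaccard, extra fraction
  `FP/(TP+FN)`, precision, recall, with population aggregation.
* **Patch preparation**: 51×51/stride-7 center-labeled patches and 256×256
  non-overlapping one-hot tiles, right-angle rotation augmentation, and
  tile recombination.
* **A seeded synthetic multicenter H&E generator** with full ground truth
  (labels, concentrations, stain matrices) and a simulated ternary
  predictor, so the entire pipeline is testable end to end without any
  external dataset.

## Worked example

```r
library(hestain)

# a 3-center synthetic cohort, 5 ROIs per center, stain jitter up to 15 degrees
recs <- generate_multicenter(n_centers = 3, scenes_per_center = 5,
                             stain_jitter_deg = 15, seed = 42)
imgs <- lapply(recs, `[[`, "image")

# reference image and Macenko normalization
ref   <- render_scene(generate_scene(scene_params(), seed = 42 + 7919))
model <- fit_reference(ref, method = "mc")
normed <- lapply(imgs, normalize_image, model = model)

# population color-constancy report before/after
population_report(imgs,   target_set = list(ref))$summary
population_report(normed, target_set = list(ref))$summary
```

The same chain is available as one call, `run_pipeline(seed = 42, out = "out")`,
which also simulates a 6-model prediction ensemble per scene, post-processes
the fused mask and scores it against ground truth. Its `summary.csv` from the
run above reads:

```
quantity,value
cv_nmi_unnormalized,0.0238373
cv_nmi_normalized,0.00627949
cv_nmh_unnormalized,0.0270173
cv_nmh_normalized,0.00221924
mean_amce_alpha_unnormalized,0.00697927
mean_amce_alpha_normalized,0.00100261
mean_amce_beta_unnormalized,0.0824597
mean_amce_beta_normalized,0.00324653
mean_ensemble_dsc,0.997762
```

Reading: across the pooled 15-image cohort, Macenko normalization cut the
coefficient of variation of NMI from 2.4% to 0.6% and of NMH from 2.7% to
0.2% — the population became far more color-constant — while the mean color
error against the reference dropped an order of magnitude in both opponent
channels; the ensemble of six noisy simulated predictors segmented nuclei at
a mean Dice of 0.998 after post-processing.

A command-line wrapper is installed at `exec/hestain`:

```sh
hestain synth --centers 3 --per-center 10 --jitter 15 --seed 42 --out data/
hestain normalize --method mc --reference ref.png --in data/ --out normed/
hestain qc --in normed/ --unnormalized data/ --target refdir/ --out report.csv
hestain pipeline --seed 42 --out run1/
```

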