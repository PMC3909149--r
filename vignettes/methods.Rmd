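---
title: "Multiparametric MR diagnosis of breast masses: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric MR diagnosis of breast masses: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breast masses seen on MR imaging are characterised along several
complementary axes: how fast and in what shape they enhance after contrast
injection (dynamic contrast-enhanced MRI), how irregular their margins are
(morphology of the segmented lesion), how heterogeneous their internal
signal is (texture), and how restricted water diffusion is inside them
(diffusion-weighted imaging, summarised by the apparent diffusion
coefficient, ADC). Malignant masses typically show fast early enhancement
followed by washout, spiculated margins, heterogeneous texture and low ADC;
benign masses show persistent enhancement, smooth margins and high ADC.

`massdx` implements a complete diagnosis pipeline over these axes:
semi-automated lesion segmentation (fuzzy c-means initialisation refined by
a gradient-vector-flow snake), extraction of 28 per-lesion measurements in
five groups (1 pathology variable — patient age; 2 kinetic; 11
morphological; 13 GLCM texture; 1 diffusion), hybrid filter/wrapper/ablation
feature-subset selection, and cross-validated evaluation of single features,
feature groups and the combined subset with four classifiers. Because no
clinical images are distributed with the package, a phantom generator
produces cohorts with the statistical structure the pipeline assumes, with
known ground truth for every quantity the pipeline estimates.

## The phantom generator

`phantom_config()` / `generate_cohort()` simulate, per case:

* **Class label** — 234 cases with 149 malignant / 85 benign by default,
  matching the composition of the clinical cohort the defaults emulate.
* **Lesion geometry** — a star-shaped boundary
  $r(\theta) = R\,(1 + a\cos(k\theta + \phi))$ plus a smooth periodic
  perturbation. Spike count $k$ and amplitude $a$ are drawn per case from
  class-specific, deliberately overlapping distributions (malignant lesions
  are more spiculated on average). $R \approx 18$ px at 1 mm/px — a
  ~3.6 cm mass with millimetre-scale spiculations. This scale was chosen
  once so that boundary detail sits above the localisation limit of
  edge-based segmentation after Gaussian smoothing; at much smaller radii
  the spiculation wavelength approaches the pixel grid and no contour
  method can resolve it.
* **Kinetics** — a three-frame dynamic series (pre-contrast, first and last
  post-contrast), parameterised by an enhancement fraction $e$
  ($SI_{first} = SI_{pre}(1+e)$) and a washout fraction $w$
  ($SI_{last} = SI_{first}(1-w)$; negative $w$ = persistent rise).
  Malignant defaults put SER above 1 (washout), benign below 1. The
  washout draw is capped so that the late signal never comes within 30% of
  baseline: SER is a ratio with a singularity where
  $SI_{last} = SI_{pre}$, and without the cap occasional draws produce
  arbitrarily large SER values that have no clinical counterpart and make
  its sample variance meaningless. The enhancement fraction has a floor of
  0.3: an enhancing mass by definition enhances well above the
  ~10%-enhancing background parenchyma (and the segmentation's
  bright-cluster assumption depends on it).
* **Texture** — a multiplicative stationary Gaussian random field inside
  the lesion, shared across frames (it models a tissue property), with
  class-dependent amplitude and correlation length, both drawn per case
  from overlapping distributions. An earlier design with fixed per-class
  field parameters made texture a deterministic class marker — combinations
  of GLCM features could separate the classes perfectly, which no real
  cohort does — so every texture parameter now carries case-level spread.
* **Diffusion** — a b=0 / b=800 s/mm² pair satisfying
  $S_b = S_0 e^{-b\,\mathrm{ADC}}$ pixelwise before noise, with per-case
  true ADC drawn from class distributions centred at 1.0 (malignant) and
  1.7 (benign) ×10⁻³ mm²/s.
* **Age** — truncated normals on [18, 78] years with class means 41
  (benign) and 49.5 (malignant), giving a cohort mean of ~46 years.
* **Noise** — independent multiplicative Gaussian pixel noise (sd 5%) on
  every frame.

Class effect sizes were calibrated once so that single-feature diagnostic
accuracy lands in the 60–80% range and only the combination of groups
reaches ~90% — the regime reported for clinical cohorts — and then frozen.
Five feature groups carry planted signal: ADC, SER, slope, age and texture
heterogeneity.

What the phantoms do **not** emulate: coil inhomogeneity and bias fields,
motion and ghosting, partial-volume and slice-profile effects, non-mass-like
enhancement, multi-focal disease, and any correlation between age and
imaging phenotype. Passing the package's tests therefore shows that the
algorithms recover planted structure through the full imaging chain under
realistic noise — not that the clinical numbers would reproduce on real
patients.

## Segmentation

`segment_lesion()` composes:

1. **Fuzzy c-means** (`fcm_cluster()`) on the ROI intensities of the first
   post-contrast frame, $c = 2$ clusters, fuzzifier $m = 2$, centers
   initialised at the 10th/90th intensity percentiles (deterministic). The
   standard alternating updates are used and the objective history is
   recorded; it is non-increasing by construction and asserted in tests.
2. **Initial mask** (`initial_mask()`): hard assignment to the brighter
   cluster at membership > 0.5, largest connected component, holes filled.
3. **GVF snake** (`gvf_field()`, `evolve_snake()`): the edge map is
   $|\nabla(G_\sigma * I)|^2$ with $\sigma = 1$ px, normalised to [0, 1];
   the gradient-vector-flow field is the explicit-time-step solution of the
   usual diffusion equations with regularisation $\mu = 0.05$ over 40
   iterations (the time step is kept inside the stability bound
   automatically). The snake uses the semi-implicit pentadiagonal update
   with tension $\alpha = 0.05$, rigidity $\beta = 0.02$, step
   $\gamma = 1$, 160 vertices resampled to uniform arc length each
   iteration, and stops when the mean vertex displacement falls below
   0.05 px.
   A snake whose evolution tangles is first repaired by radial smoothing
   and, failing that, projected onto the nearest star-shaped polygon
   (radius as a single-valued function of angle about the centroid) —
   always simple, and faithful for the star-shaped masses this pipeline
   targets.
4. **Sub-pixel edge relocation**: after convergence each vertex is moved
   along its local normal to the maximum of a sharper edge profile
   ($\sigma = 0.75$ px, search ±2.5 px). Two systematic biases make this
   step necessary: a contour traced through boundary-pixel centers sits
   half a pixel inside the physical edge (re-rasterising it erodes a
   half-pixel ring, costing ~0.1 Dice on a 18-px lesion), and Gaussian
   smoothing displaces the edge ridge by roughly $\sigma^2\kappa$ at
   curvature $\kappa$ — inward at spiculation tips, outward in valleys.
   Relocation removes both at once.

The internal-energy weights are deliberately light. Stronger settings (e.g.
$\alpha = 0.2$, $\beta = 0.1$, $\mu = 0.2$, $\sigma = 1.5$) are common for
noisy natural images but systematically round spiculated boundaries here,
which destroys exactly the morphological detail the downstream features
measure; with the FCM mask already providing a near-perfect initialisation,
the snake's job is sub-pixel refinement, not long-range capture. All
parameters are exposed in `snake_params()`.

On default-noise phantoms the scheme reaches median Dice ≈ 0.98 over a
234-case cohort (≥ 0.98 noiseless for both classes); occasional failures
(Dice < 0.5) occur when heavy texture splits the FCM mask — they are the
price of a fully automatic second stage and are visible in the
`segmentation_dice.csv` output of the analysis workflow.

## Features

* **Kinetic** (lesion-mean intensities):
  slope $= (SI_{first} - SI_{pre})/SI_{pre}$ and
  SER $= (SI_{first} - SI_{pre})/(SI_{last} - SI_{pre})$. SER is flagged
  missing when the denominator is within machine tolerance of zero. Both
  are computed on lesion means rather than pixelwise, which is the stabler
  choice for small lesions. The slope variable is housed with the kinetic
  group; published tables sometimes list it under morphology, and the
  registry keeps aliases so either naming resolves
  (`canonical_feature_name()`).
* **Morphological** (11): area (mm²), circularity $4\pi A/P^2$,
  compactness $P^2/4\pi A$, extent, solidity, eccentricity and elongation
  from the second-central-moment ellipse, entropy (base 2, 10 equal-width
  bins) of max-normalised radial lengths, spiculation = zero crossings of
  the centred radial profile divided by vertex count (resampling
  invariant), box-counting fractal dimension of the rasterised boundary
  (box sizes 1–16 px, clamped to [1, 2]), heterogeneity = intra-mask
  sd/mean of the first post-contrast frame.
* **Texture** (13): the classical Haralick statistics of a 32-level,
  symmetric, distance-1, 4-direction GLCM built from intra-mask pixel
  pairs only. Logs are base 2 with $0\log 0 := 0$; sum/difference
  variances are taken about the sum/difference averages;
  $IMC_1 = (HXY - HXY_1)/\max(HX, HY)$,
  $IMC_2 = \sqrt{1 - e^{-2(HXY_2 - HXY)}}$. A brute-force double-sum
  oracle in the test suite pins all 13 to $10^{-10}$.
* **Diffusion**: pixelwise ADC $= \ln(S_0/S_b)/b$; the lesion ROI is
  dichotomised against the mean high-b signal of a 5-px annulus around the
  mask, the mean ADC is taken over the high-signal pixels, and results
  with high-signal area below 20 mm² are flagged invalid and the case
  excluded.

## Feature selection

`run_hybrid_fss()` chains three steps:

1. **Filter** — per-feature two-sample Welch t-test at $\alpha = 0.05$.
   The benign and malignant groups are independent samples of unequal
   size, so an unpaired, unequal-variance test is the only applicable
   form.
2. **GA-wrapped SVM search** — chromosomes are inclusion masks over the
   filter survivors; fitness is mean 5-fold cross-validated accuracy of an
   RBF SVM on the encoded subset (folds fixed per run; empty chromosomes
   score 0). Population 50 (topped up so every singleton chromosome is
   present initially — the search can then never end below the best single
   feature), tournament size 3, uniform crossover 0.8, bit-flip mutation
   0.02, elitism 2, at most 100 generations with early stopping after 15
   stagnant generations; the initial population also contains the
   all-survivors chromosome so the search can prune downward from the full
   set, and the GA optimum is polished by single-bit hill climbing (a
   memetic step that recovers features never sampled near convergence).
   Fitness values are cached per chromosome. The
   SVM's $C$ and $\gamma$ are tuned once per run by 5-fold CV on the full
   survivor set and then held fixed for all wrapper evaluations: tuning
   inside every fitness call multiplies the cost by the grid size while
   changing subset rankings only marginally, since the standardised
   features live on a common scale.
3. **Ablation** — greedy backward elimination: repeatedly drop the feature
   whose omission reduces wrapper CV accuracy the least, while that
   reduction is ≤ 0.005 (absolute accuracy). The accuracy deltas are
   averaged over three repeated fold assignments: single-split CV noise
   (1–2% accuracy) would otherwise dominate contributions near the
   threshold. Ties are broken by removing
   the feature with the larger filter p-value; never returns an empty
   subset. The 0.5% threshold operationalises "negligible contribution";
   it is configurable (`selection_config(ablation_epsilon = )`). The
   elimination is iterated rather than single-pass — a single pass leaves
   order-dependent redundancy behind.

The returned trace partitions the input features into
removed-at-step-2/3/4 and the final subset, and records per-generation best
fitness and per-removal accuracy deltas.

## Evaluation

* **Folds**: stratified k-fold (default 10) with per-class and overall
  sizes differing by at most one. Plain unstratified splitting risks folds
  without benign cases at a 64/36 imbalance; stratification is the
  standard remedy.
* **Univariate features** are evaluated by per-fold Youden-optimal
  thresholds (direction chosen by training AUC, so "low ADC calls
  malignant" emerges from the data); the center of the optimal-threshold
  interval is used when several cutoffs tie. The whole-data threshold is
  also reported, mirroring how diagnostic cutoffs are usually printed.
* **Multi-feature sets** are evaluated by four classifiers — RBF SVM
  ($C \in \{0.1, 1, 10, 100\}$, $\gamma \in \{0.01, 0.1, 1\}/d$ tuned by
  inner 5-fold CV inside each training fold), Gaussian naive Bayes, k-NN
  with $k = 6$, and logistic regression — with standardisation fitted on
  training folds only. AUC always comes from continuous decision scores
  (SVM decision values, posterior probabilities, k-NN vote fractions),
  never from hard labels. An "Averaged" row per feature set is the
  arithmetic mean of the four models' metrics.
* **Leakage control** is tested directly: rescaling a noise feature has no
  effect beyond CV noise, label permutation drives accuracy to chance, and
  a feature equal to the label yields exactly 1.0 under every model.

## Problem sizes

The test suite and the acceptance script run, by the package's own choice
of scale: 20-case cohorts for segmentation/ADC recovery spot checks, a
234-case cohort (the default) for each selection run, 20 seeded
cohort+selection replicates for the recovery study, 200 simulated cohorts
for filter calibration, and one fully segmented 234-case cohort for the
end-to-end evaluation. A full `run_all()` at defaults takes a few minutes
on one core; segmentation is ~0.15 s per case.

## Known limitations

* 2-D single-slice phantoms and features; no volumetric texture or shape.
* The three-frame dynamic series carries no acquisition timing — the
  kinetic features used here need none, but time-to-peak style features
  cannot be added without extending the generator.
* The GVF snake assumes one lesion per ROI and a star-shaped-ish boundary;
  the radial repair and relocation steps exploit that.
* The GA wrapper's fixed (once-per-run) SVM hyperparameters trade a small
  amount of selection fidelity for a ~12× cost reduction.
* Phantom realism bounds what green tests mean: the pipeline recovers
  planted structure under the stated noise model; clinical performance
  claims require clinical data.
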