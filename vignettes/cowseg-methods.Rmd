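---
title: "Methods: multitask CoW segmentation on synthetic CTA phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitask CoW segmentation on synthetic CTA phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

The Circle of Willis (CoW) is the arterial ring at the base of the brain
that connects the carotid and vertebrobasilar circulations. On CT
angiography (CTA), individual ring segments — the anterior communicating
artery (Aco), the precommunicating anterior and posterior cerebral segments
(A1, P1) and the posterior communicating arteries (Pco) — are classified as
*normal* or *variation* (not visualised, or more than 70% thinner than the
contralateral homologue), and the anterior part, posterior part and entire
ring are called complete when all their segments are normal. Stenosis of
the feeding and draining arteries is graded on the NASCET scale from the
relative lumen-diameter reduction: normal, mild (≤29%), moderate (30–69%),
severe (≥70%).

`cowseg` implements this assessment pipeline end to end, with three
ingredients:

1. a **synthetic CTA phantom generator** with exact vessel ground truth,
   standing in for clinical data that cannot be redistributed;
2. a **multitask convolutional encoder–decoder** that segments vessels on
   axial slices while simultaneously reconstructing the image as a
   probability-weighted blend of a foreground and a background image, plus
   a single-task baseline;
3. **classification and prevalence statistics**: the variant/completeness
   rules, NASCET grading from measured lumen profiles, reconstruction of
   event counts from printed `(n, %)` summaries and uncorrected chi-square
   group comparisons.

## The multitask model and its loss

Each axial slice `I` (windowed to [0, 1]) is mapped to three maps of the
same size: a segmentation probability map `O`, a foreground reconstruction
`F` and a background reconstruction `B`. The training loss is

```
J = mean( (I - (F*O + B*(1-O)))^2 )  +  1 - 2*sum(O*S) / (sum(O^2) + sum(S^2) + eps)
```

the per-pixel mean squared error between the image and its blend
reconstruction, plus the soft Dice loss between `O` and the binary ground
truth `S`. Spatial sums are per image; batches average per-image terms.
The two terms carry unit weights; `train_config(recon_weight=)` exposes the
balance because nothing fixes it a priori. A perfect prediction (`O = S`,
`F = I` on vessels, `B = I` elsewhere) gives `J = 0`.

Architecture: four encoder stages of 3×3 convolution + instance
normalization + ReLU with 2×2 max-pooling between stages; an atrous spatial
pyramid pooling (ASPP) bottleneck concatenating parallel 3×3 convolutions
at dilation rates 1, 2, 4, 8 with a global-average-pooling branch, fused by
a 1×1 convolution; a decoder of factor-2 bilinear upsampling, skip
concatenation and 3×3 convolution per level; and 1×1 output heads — sigmoid
for `O`, linear for `F` and `B` (the single-task baseline keeps only the
`O` head and the Dice term). Design choices the architecture description
leaves open, decided here once:

* **Normalization.** Per-conv-block normalization uses *per-image spatial
  statistics* (instance normalization). The training loop processes
  images individually, per-image statistics make single-slice inference
  identical to training, and without any normalization the Dice term
  demonstrably collapses to the empty segmentation at the small scales
  this package trains at.
* **Head activations.** `O` must be a probability, hence sigmoid; `F` and
  `B` live in windowed intensity units, hence linear.
* **Upsampling** is bilinear interpolation followed by convolution, the
  least-assuming reading of "upsampling".
* **Channel widths** default to 16 at the first level, doubling per level;
  every experiment here uses 4 to keep CPU training in minutes. Width is
  configurable and orthogonal to the multitask-vs-single-task question.
* **Both-empty Dice convention:** when `O` and `S` are both entirely zero
  the Dice term is 0 (perfect agreement), enforced by `eps = 1e-6` in
  numerator and denominator; the binary Dice *coefficient* correspondingly
  scores two empty masks as 1.
* **Slice handling.** Everything is 2D and axial; volumes are segmented
  slice by slice and restacked along z. Binarisation threshold 0.5,
  configurable.

The whole network and its backpropagation are implemented in this package
(im2col/col2im and pooling/resize kernels in C++, matrix products through
BLAS, explicit layer-by-layer gradients, Adam); correctness is established
by finite-difference gradient checks in the test suite rather than by
trusting a framework.

## The phantom generator

The generator emulates what matters for this method, not anatomy for its
own sake:

* **Geometry.** Centrelines are natural cubic splines through hand-designed
  waypoints of the full ring (2 ICA, BA, 2 VA, 2 A1, Aco, 2 P1, 2 Pco,
  2 M1, postcommunicating ACA/PCA stubs truncated at fixed length), scaled
  to the volume extent. World coordinates are in mm, axes (x, y, z) with
  axial slices along z, voxel centres at `origin + index * spacing`.
* **Radii.** Defaults (ICA 2.4 mm … Aco 0.5 mm) make Aco the thinnest ring
  segment, so the clinically reported difficulty ordering (P1 easiest, Aco
  hardest) has a geometric cause in the phantom.
* **Variants.** A segment is `normal`, `absent` (rasterises nothing) or
  `hypoplastic` — radius shrunk to 25% of the contralateral homologue,
  deliberately inside the ">70% thinner" band so the classification ground
  truth is unambiguous.
* **Stenoses.** A focal stenosis reduces the local radius to
  `(1 - severity/100)` of nominal over a plateau with cosine shoulders.
  Because tubes are rasterised as unions of spheres along the centreline,
  the plateau scales with the nominal radius (`max(2.5 r, 2 mm)`): a
  shorter throat would be partially filled in by shoulder spheres and the
  rendered severity would undershoot the requested one.
* **Intensities.** HU-scale classes — air −1000, soft tissue 40, vessels
  350, bone 1200 — blended by sub-voxel occupancy (supersampling factor 3
  per axis), so thin vessels show realistic partial-volume dimming; a
  smooth multiplicative low-order polynomial bias field (default ±10%) and
  additive Gaussian noise (default 20 HU) reproduce the inhomogeneity and
  noise that make vessel segmentation nontrivial. The binary ground-truth
  mask is exact: voxel centre within the local radius of a non-absent
  centreline.
* **Background.** A spherical head with a thin cranial bone shell and air
  outside. No hemodynamics, no realistic skull, no DICOM — deliberately.

What passing tests on phantoms do **not** show: performance on clinical
CTA. The phantom has no motion, no veins or enhancing soft tissue, no
pathology beyond the inserted variants/stenoses, and its noise is white.
Clinical Dice values reported for this family of models (≈78% multitask vs
≈74% single-task) are therefore *not* targets here; the package asserts
the *orderings* — multitask ≥ single-task held-out Dice, and detection
difficulty P1 ≥ Pco ≥ Aco — under its own study conditions.

## Preprocessing

Volumes are resampled to isotropic 0.5 mm by default (trilinear for
intensities, nearest-neighbour for masks), windowed to [0, 2000] HU by
clamping and rescaling to [0, 1] (clamping rather than voxel deletion keeps
the grid intact for the reconstruction task; the windowing map is
idempotent on its output scale via the unit window), and cut into one
centre-cropped/zero-padded square patch per axial slice. Augmentation is
the 8-element dihedral group (90° rotations + flips) applied jointly to
patch and mask — rigid by construction, so binary masks suffer no
interpolation. Whether vessel-free slices are dropped is a config flag
(default off in `extract_patches()`; the pipeline enables it, plus a
per-volume slice budget, to keep CPU budgets bounded).

## Study conditions for the scaled experiments

Training at clinical scale (288×288 slices, 50 epochs, batch 32, learning
rate 1e-4 — the package defaults) is not meaningful on one CPU core, so the
comparison experiments run a scaled design (`compare_baselines()`):
24 training / 6 validation phantoms of 64³ voxels at 1 mm; per-side variant
frequencies Aco 0.4, Pco 0.6, P1 0.15, A1 0.1 (roughly the prevalence
ballpark of published CoW cohorts); base 4 filters; 6 slices per training
volume; 16 epochs at batch 8 with learning rate 3e-3; three training seeds
on a fixed cohort so the multitask vs single-task comparison is paired. At
this scale one comparison takes 12–15 minutes on a single core. Three
aspects of the design deserve explanation:

* **Trained to convergence.** The claimed benefit of the reconstruction
  task concerns trained models. The multitask model converges more slowly
  at first — its early updates serve the reconstruction term — so a
  deliberately undertrained comparison would measure convergence speed
  instead. The runtime budget therefore goes into epochs (a small slice
  budget per volume, more passes) rather than into patches per epoch. The
  higher learning rate compensates for the far fewer updates than the
  clinical recipe; it was fixed from the single-phantom overfitting
  experiment (the Dice term needs a few hundred updates to leave its
  background-dominated plateau). Substantially smaller training cohorts
  were found to make training unstable at this learning rate — occasional
  runs collapse to near-empty segmentations — so the cohort size stays at
  24, matching the scale of a small clinical training set.
* **Detection cohort.** Per-segment detection accuracy is scored on a
  separate 16-phantom test cohort whose variants are drawn *absent-only*
  at one matched frequency (0.3) for Aco, Pco and P1, and averaged over
  the multitask models of all three seeds. Hypoplastic vessels are
  excluded there on purpose: a sub-resolution hypoplastic segment is
  "present" in the ground truth but physically invisible in the image, so
  mixing it in makes the accuracy track each segment's hypoplasia rate
  rather than the radius-driven difficulty the comparison is about; a
  matched frequency keeps the presence/absence base rates from favouring
  any segment; and averaging over seeds damps the binomial noise a single
  12–16 phantom cohort cannot escape.
* **The comparison may not favour the multitask model here.** On clean
  phantoms the vessels are the only mid-intensity structures, so the
  foreground/background decomposition that reconstruction enforces is
  nearly trivial, and its main effect is to spend model capacity and
  gradient budget; the generalization benefit reported on noisy clinical
  CTA with ambiguous enhancing structures has no obvious counterpart
  here. The experiment reports whatever the data show; the package does
  not tune its generator to manufacture the clinical ordering.

## Numerical and procedural choices

* **Chi-square without continuity correction**, df = 1, two-sided, no
  multiple-comparison correction: this is the convention under which the
  six printed prevalence p-values (0.046, 0.009, 0.024, 0.044, 0.072,
  0.087) are reproduced exactly at printed precision; Yates-corrected
  values do not reproduce them.
* **Count reconstruction** from printed `(n, %)` rows is `n*pct/100`
  rounded half-up (print-table convention; banker's rounding mis-inverts
  x.5 percentages), with a round-trip warning when the recovered count
  does not re-round to the printed percentage.
* **Per-patient prevalence** for bilateral segments is "variation on either
  side"; the generator draws sides independently.
* **The 70% rule** is strict: variation iff diameter < 0.3 × contralateral.
* **"Visualised"** in ground-truth classification means traceable — at
  least one rasterised voxel per 2 mm of centreline — *and* at least one
  voxel wide; a lumen thinner than the voxel is lost to partial volume no
  matter how many voxel centres it happens to graze, which is also how
  visual assessment behaves. Sub-resolution hypoplastic vessels are
  thereby not visualised and classify as variation even when the
  contralateral comparison is unavailable.
* **NASCET bands** leave (29, 30) undefined for fractional input;
  percentages there are rounded to the nearest integer before banding.
* **Stenosis measurement** estimates lumen diameters from cross-sectional
  areas in thin slabs perpendicular to the centreline, smooths the profile
  over ±0.5 mm against voxel quantisation, and uses the median profile
  diameter as the NASCET-style reference; the minimum interior diameter
  gives the severity. Ends (15% each) are excluded so junction voxels of
  connected segments do not bias the profile. Recovery is accurate to
  about one voxel of diameter; tests assert exactly that tolerance.
* **Segment detection** replaces expert visual review with a mechanical
  surrogate: a segment is called present when ≥50% of its ground-truth
  centreline sample points fall inside the predicted mask dilated by one
  voxel. This is documented as a surrogate; it is not a claim about expert
  agreement.
* **Determinism.** Every stochastic stage (phantom sampling, cohort draws,
  weight initialisation, shuffling, augmentation) derives child seeds from
  one master seed; identical config + seed reproduces volumes, histories
  and reports bit-for-bit.

## Known limitations

* The phantom's realism gap (above) means absolute Dice values here say
  nothing about clinical performance. In particular, the scaled comparison
  computed by the test suite and the acceptance script has so far shown the
  single-task baseline matching or exceeding the multitask model on
  phantoms — consistent with the reconstruction task having nothing to
  disambiguate in images whose only mid-intensity structures are the
  vessels themselves — so the clinically reported multitask advantage
  should not be expected to reproduce here.
* Bilateral hypoplasia is intrinsically ambiguous under a purely
  contralateral diameter rule; the visualisation criterion resolves it at
  typical CTA resolution, but at very fine grids a bilaterally hypoplastic
  pair that is genuinely traceable would classify as normal. That is a
  property of the rule, not of the implementation.
* Training is plain Adam on 2D slices with small nets; no semi-supervision,
  no pretraining, no 3D context.
* Surface-distance metrics, DICOM ingestion and rendering are out of scope.
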