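# cowseg

Segmentation of the Circle of Willis (CoW) and statistics of its anatomical
variants, built around a from-scratch multitask convolutional network and a
synthetic CT-angiography (CTA) phantom generator.

## The problem

The CoW is the arterial ring connecting the carotid and vertebrobasilar
circulations. Reading head–neck CTA for it is slow: delineating the
cerebral arteries by hand takes an expert about an hour per study, and the
assessment itself — calling each ring segment *normal* or *variation* (not
visualised, or >70% thinner than its contralateral homologue), deriving
anterior/posterior/entire-ring completeness, and grading stenosis on the
NASCET scale — is tedious and error-prone. `cowseg` is for researchers who
want to study that pipeline quantitatively: it provides the segmentation
model, the evaluation metrics, the classification rules and the group
statistics, exercised end to end on synthetic phantoms with exact ground
truth instead of clinical data.

## The model

Each axial slice `I` is mapped to three maps: a segmentation probability
map `O`, a foreground reconstruction `F` and a background reconstruction
`B`, produced by a shared encoder–decoder (four conv levels, atrous spatial
pyramid pooling bottleneck with dilation rates 1, 2, 4, 8 plus a
global-pooling branch, bilinear-upsampling decoder with skip connections)
with three 1×1 heads. Training minimises

    J = mean[ (I − (F·O + B·(1−O)))² ] + 1 − 2·Σ(O·S) / (Σ O² + Σ S²)

the mean squared error between the image and its probability-weighted
blend reconstruction, plus the soft Dice loss against the ground-truth
mask `S`. A single-task baseline (same backbone, `O` head and Dice term
only) isolates the contribution of the reconstruction task. Segmentation
quality is scored with the Dice coefficient `DC = 2|P∩T|/(|P|+|T|)`.

The network, its backpropagation and Adam are implemented in this package
(C++ kernels for im2col/pooling/resizing, BLAS matmuls, explicit
gradients); the test suite validates the gradients against finite
differences.

## Worked example

```r
library(cowseg)

# a 64^3 phantom at 1 mm with an absent Aco and a 70% ICA stenosis
spec <- phantom_spec(volume_shape = c(64, 64, 64), spacing_mm = 1,
                     segment_statuses = list(Aco = "absent"),
                     stenoses = list(list(segment = "ICA_L", position = 0.5,
                                          severity_pct = 70)),
                     seed = 7)
ph <- generate_phantom(spec)
ph
#> <cow_phantom> 64x64x64 voxels, 1615 vessel voxels, variants: Aco

# the ground-truth classification and completeness
cfg <- classify_phantom(ph)
classify_completeness(cfg)
#> $entire    [1] FALSE
#> $anterior  [1] FALSE
#> $posterior [1] TRUE

# measure the inserted stenosis back from the mask and grade it
pct <- measure_stenosis_pct(ph$mask, ph$tree$ICA_L)
round(pct)
#> [1] 76
as.character(grade_stenosis(pct)$grade)
#> [1] "severe"

# prevalence statistics from printed (n, %) group summaries
compare_groups(cow_table2(), "Aco", list(c("Yn", "Sn")))
#>   group1 group2 outcome    chi2 df          p significant
#> 1     Yn     Sn     Aco 3.98345  1 0.04594935        TRUE
```

Interpretation: the phantom's absent anterior communicating artery makes
the anterior ring incomplete; the inserted 70% stenosis is recovered to
one voxel of diameter accuracy at this coarse 1 mm grid (fine grids
recover it to within a percentage point) and grades *severe* under NASCET;
and reconstructing the event counts behind the printed young-vs-senior group
summaries yields an uncorrected chi-square p of 0.046 for the Aco
prevalence difference.

A full simulate → preprocess → train → predict → evaluate run is one call
(`run_pipeline()`), and `compare_baselines()` runs the multitask vs
single-task comparison across seeds on a fixed cohort. A thin command-line
wrapper with `simulate`, `preprocess`, `train`, `predict`, `evaluate`,
`stats` and `run-all` subcommands ships in `inst/scripts/cowseg.R`.

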