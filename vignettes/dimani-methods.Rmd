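---
title: "Methods: diffusion-averaged thalamic contrast, phantoms, and reproducibility metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-averaged thalamic contrast, phantoms, and reproducibility metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimani)
```

## The contrast and its physics

The core operation is deliberately simple: keep the diffusion-weighted
volumes of a 4D acquisition (strictly `b > bThreshold`, default
100 s/mm², so b0 and near-b0 volumes are dropped) and aggregate them
voxelwise. Under the single-tensor model

$$S(g) = S_0 \, e^{-b\, g^\top D g},$$

the direction-average of $S$ over a uniform scheme is governed by how the
attenuation spreads across directions. Two facts drive the anatomy seen
in the image:

1. **Diffusivity darkens.** Larger mean diffusivity (MD) lowers the
   average monotonically — CSF (MD ≈ 3.0e-3 mm²/s) ends up an order of
   magnitude darker than parenchyma (MD ≈ 0.7e-3).
2. **Anisotropy brightens.** At fixed MD and $S_0$, the average of the
   convex function $e^{-b\,\mathrm{adc}(g)}$ over directions is minimized
   when the ADC is the same in all directions (Jensen's inequality), so a
   high-FA tensor yields a strictly brighter average than an isotropic
   one. This is why white-matter laminae between subnuclei appear bright
   and why the alternating-anisotropy "zebra" lamination of the ventral
   group is visible at all.

Both facts are asserted numerically in the test suite, the first against
closed forms, the second by quadrature over the actual direction set for
FA ∈ {0, 0.4, 0.8} at MD 0.7e-3 and b = 1500 s/mm².

Isotropic voxels give the same signal in every direction, so their
average is independent of the direction scheme — computed exactly, two
different 48-direction schemes produce bit-near-identical contrast on a
purely isotropic phantom (≤ 1e-10). This is the mechanism behind the
observation that datasets acquired with entirely different gradient
tables show the same contrast.

### Aggregation variants

`mean`, `median`, `centromean`, `sum` and `l2norm` are provided. The
centromean discards the lowest ⌊n/4⌋ and highest ⌊n/4⌋ of the n sorted
values and averages the rest — for n not divisible by 4 this symmetric
trimming is the natural reading of "mean of the middle 50 %". Median ties
for even n average the two central values.

Each voxel's series is **sorted before aggregation**. This costs one
`order()` pass and buys an exact guarantee: every method, including
floating-point `mean` and `sum`, is bit-identical under any permutation
of the volumes (naive left-to-right summation is not associative in
floating point). The implementation is a single vectorized pass over a
voxels-by-volumes matrix; the test suite pins it to an independent
per-voxel loop oracle at ≤ 1e-10 relative error on 50 random datasets.

### Method agreement, and what ranks can and cannot show

Aggregation variants are expected to produce the *same contrast* (rank
structure), though different voxel values. On a structure-rich image this
is true with Spearman ρ > 0.95 for every variant. One statistical caveat
is worth recording: inside a large *homogeneous* region, voxel ranks are
pure noise, and the correlation between the mean and the median of the
same n-sample is only ≈ √(2/π) ≈ 0.80 (the median's asymptotic
efficiency). A phantom dominated by one flat region therefore caps the
median's global rank agreement near 0.90 *regardless of the noise level* —
a property of piecewise-constant fixtures, not of the methods. Method
agreement is accordingly evaluated on the graded-slab preset
(`presetGradedSlabs`), whose foreground spans the contrast's full
CSF-to-white-matter dynamic range in 16 distinct levels, so ranks are
structure-driven as they are in real anatomy; there all four variants
agree with the mean at ρ > 0.99. On the thalamus preset the same check is
asserted for centromean/sum/l2norm (> 0.95) while the median is asserted
above its 0.80 noise-only baseline.

### Adaptive histogram equalization

For display, a 3D CLAHE: tiles of `kernelShape` voxels (default: image
shape / 8 per axis, floor 4), per-tile histograms of `nBins` bins
(default 256) over the global range, counts clipped at
`clipLimit × tile voxel count` (default 0.01) with the excess
redistributed uniformly, per-tile CDF mappings, and trilinear
interpolation of the mappings between tile centers. Output is in [0, 1].
With a single tile and `clipLimit = 1` the operation reduces exactly to
global histogram equalization, which is how it is validated. A mask
restricts the histograms to foreground (otherwise air dominates) and the
background stays 0; masked-first is the default order. A constant input
(degenerate range) returns all zeros with a warning rather than an
error, so pipelines do not die on empty cases. The algorithm's
parameters are recorded in the image's provenance; no published
parameterization exists to match, so visual equivalence with any
particular figure is not a goal.

## The phantom generator

`PhantomSpec` describes a voxel grid, a list of regions (box, ellipsoid,
or slab-stack geometry; one SPD tensor and one S0 per region; later
regions win on overlap), an acquisition (n directions, b-value, n b0s,
direction seed), and a Rician noise sigma with its own seed. The forward
model is the single-tensor monoexponential — the simplest model that
exercises every claim the package tests; no multi-compartment or
kurtosis terms, no eddy/susceptibility distortion, no spatial smoothing.
Noise is Rician, `sqrt((S + n1)^2 + n2^2)` with n1, n2 ~ N(0, σ²),
applied to the magnitude — at S = 0 this is the Rayleigh floor with mean
σ√(π/2), which the tests check to 2 % at n = 1e5. All randomness flows
through the two named seeds; builds are bit-reproducible.

Two presets encode the study conditions:

* **`presetThalamus`** (48³ voxels at 1.25 mm, 48 directions at
  b = 1500 s/mm² + 4 b0, S0 = 100, σ = 2 % of S0 by default): CSF-like
  isotropic surround (3.0e-3 mm²/s), a zebra slab stack alternating
  FA 0.8 / FA 0.2 laminae at equal MD 0.7e-3 (4-voxel = 5 mm slabs), a
  dark isotropic MD-like ellipsoid, a CM-like ellipsoid (FA 0.4), and a
  bright internal-capsule-like slab (FA 0.85). Tissue tensors are
  literature-typical values (parenchymal MD ≈ 0.7e-3 mm²/s, WM FA
  0.8–0.85); no published per-nucleus tensors exist to fit.
* **`presetGradedSlabs`** (32³): sixteen slabs with MD log-spaced
  3.0e-3 → 0.5e-3 and FA 0 → 0.8, spanning the contrast's dynamic range
  in many distinct levels — the method-agreement fixture.

What the phantom deliberately does **not** emulate: real anatomy's
curved boundaries and partial-volume mixtures, spatially varying S0/T2,
EPI distortion, motion, and multi-shell acquisitions. Passing tests on
the phantom therefore validate the *mechanics* of the contrast
(selection, aggregation, noise behavior, ordering by diffusivity and
anisotropy) — not clinical image quality.

### Direction schemes

`makeDirections(n, seed)` minimizes the antipodally symmetrized
electrostatic energy $\sum_{i<j} 1/\|v_i-v_j\| + 1/\|v_i+v_j\|$
(diffusion is symmetric under $g \to -g$, so each point repels the
others and their antipodes) by projected tangential repulsion with an
adaptive step, from a seeded random start, until the relative energy
change is < 1e-8 or 10,000 iterations. For n = 3 the optimum is an
orthogonal triad (|dot| < 1e-3 in the tests); for n = 50 the minimum
folded angle (~20°) beats the median of 100 random sets (~2°) by an
order of magnitude.

`subsampleDirections` emulates a shorter acquisition drawn from the same
scheme: greedy growth from the widest pair, each step adding the
direction that minimizes the subset energy, followed by two deterministic
exchange-polishing stages — swaps that lower the energy, then swaps that
raise the subset's minimum folded angle. The polishing stages are needed
because plain greedy growth, while good, is a local heuristic: without
them it loses to the best of 1,000 random 6-subsets on minimum folded
angle in roughly half of trials, and with them it wins ≥ 95 % of trials
(59/60 across three Monte-Carlo batches). b0 volumes are always carried
through subsampling; only weighted directions are subsetted, and the CLI
writes 0-based volume indices so the 4D file can be sliced consistently.

### Noise scaling across direction counts

Averaging N directions reduces noise as 1/√N while the signal mean is
direction-scheme-independent for (near-)isotropic voxels — so fewer
directions yield the same contrast, only noisier. The acceptance
machinery measures, in a homogeneous region (FA 0.2, MD 0.7e-3, S0 100,
σ = 2), the SD of the mean contrast across 200 noise realizations at
N ∈ {6, 12, 24, 48} subsampled from one 48-direction parent; the
SD(6)/SD(48) ratio lands within a few percent of √8 ≈ 2.83.

## Dice reproducibility

`diceCoefficient` is 2|A∩B|/(|A|+|B|); `multilabelDice` evaluates it per
label over the union of labels in either map; `pairwiseDiceReport`
evaluates all C(k,2) unordered pairs (8 co-registered sessions → 28
comparisons per nucleus; 3 raters → 3) and summarizes per-label mean/SD.
Conventions, recorded in the report metadata: both masks empty → 1.0
(perfect agreement on absence), exactly one empty → 0.0. Inputs must
share a grid; the module refuses to resample, because hidden
interpolation of label maps silently corrupts overlap values —
registration belongs upstream.

`perturbLabels` generates synthetic rater variability: every foreground
boundary voxel (6-connectivity; volume faces border background) is
independently reassigned, with probability `rate`, to a uniformly chosen
differing neighbor label. It is seeded and deterministic. Two properties
connect it to practice: mean Dice decreases strictly with the flip rate,
and at equal rate smaller structures lose more Dice than larger ones
(surface-to-volume scaling) — the reason the smallest nuclei, such as
the habenula, are always the weakest entries in reproducibility tables.

## Numerical and design choices

* Strict inequality `b > 100` for volume selection, configurable; shell
  selection is `|b − shell| ≤ 50` s/mm² by default. Multi-shell data
  aggregate all weighted volumes unless a shell is requested.
* Voxel indexing is 0-based in all geometry parameters and CLI index
  files; world coordinates follow the NIfTI affine. Scalar images are
  written as 32-bit float, labels as 16-bit integers.
* bvecs are used as stored (FSL image-coordinate convention); no
  world-space rotation is applied, since the aggregation is invariant to
  a global rotation of the scheme. A transposed N×3 bvecs file is
  auto-detected by shape and accepted with a warning; silent misreads
  are the failure mode to avoid.
* Non-finite voxels on read are an error by default with an explicit
  zero-fill-and-warn flag.
* Gradient validation: unit norm within 1e-3 where b > 0 (optionally
  renormalized), zero vectors permitted at b = 0.
* Geometry agreement for region statistics and Dice requires affines to
  match within 1e-4.
* SPD validation of tensors is by symmetry check plus eigenvalue
  positivity; `tensorFromFAMD` solves the prolate eigenvalue problem by
  a monotone 1D root find and is exact to the root tolerance (1e-14).

## Problem sizes

The default test and acceptance runs use 48³ phantoms (52 volumes), 32³
graded phantoms, 6³ × 12 oracle datasets (50 of them), 200 noise
realizations × 400 voxels for the scaling experiment, and 100 random
direction sets for the uniformity baseline. The full suite completes in
about a minute on one CPU; the acceptance script in ~15 s.

## Limitations

The phantom's single-tensor, piecewise-constant world is a mechanism
test-bench, not a brain. No claim is made about segmentation accuracy on
real data, about the optimal CLAHE parameterization for display, or
about multi-shell direction schemes (single-shell uniformity only).
Registration, distortion correction and atlas inference are explicitly
out of scope; the Dice module assumes its inputs are already on one
grid.
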