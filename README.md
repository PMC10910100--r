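# dimani

Direct anatomical contrast of thalamic subnuclei from diffusion MRI.

The thalamic subnuclei — VLPv, VPL, VLa, MD, CM, Pul and their neighbors —
are targets for deep-brain stimulation (the Vim for essential tremor) but
are nearly invisible on conventional T1/T2 MRI. This package computes a
contrast in which they are directly visible: the voxelwise average of the
diffusion-weighted volumes of an ordinary dMRI acquisition,

```
C(x) = (1/N) * sum over volumes i with b_i > 100 s/mm^2 of S_i(x)
```

Under the tensor model `S = S0 * exp(-b * g' D g)`, the direction-averaged
signal is dark where water diffuses fast and isotropically (CSF,
fast-relaxing nuclei such as MD), bright where diffusion is restricted or
anisotropic (white matter, high-FA laminae), and intermediate in between —
which is what separates the subnuclei, including the alternating
dark/bright "zebra" lamination across VLa/VLPv/VPL seen sagittally.

The package is aimed at neuroimaging methods researchers and at anyone who
wants to evaluate this contrast without scanner data: alongside the
contrast itself it provides

* aggregation variants (`mean`, `median`, `centromean` = mean of the middle
  50 % of sorted values, `sum`, `l2norm`), a `b0_mean` companion, and shell
  selection for multi-shell data;
* 3D contrast-limited adaptive histogram equalization (CLAHE) for display;
* NIfTI-1 + FSL `bvals`/`bvecs` readers/writers with strict gradient
  validation (transposed bvecs auto-detected, unit norms enforced);
* a diffusion-tensor phantom generator — labeled multi-region geometry,
  per-region SPD tensors, Rician noise, electrostatically uniform gradient
  schemes — with a thalamus-like preset (CSF surround, zebra slab stack,
  MD/CM-like nuclei, internal-capsule slab) and a graded-slab preset
  spanning the full dynamic range;
* gradient-direction subsampling that preserves angular uniformity,
  emulating shorter acquisitions;
* per-nucleus Dice reproducibility reports over all pairs of co-registered
  segmentations (test-retest and inter-rater designs), plus a seeded
  boundary-perturbation generator for synthetic rater variability;
* a command-line tool (`inst/cli/dimani.R`) with `compute`, `b0mean`,
  `phantom`, `dice` and `subsample` subcommands and JSON provenance
  sidecars.

## Worked example

Build the thalamus-like phantom (48 uniform directions at b = 1500 s/mm²,
4 b0 volumes, 1.25 mm voxels, Rician sigma = 2 % of S0), compute the mean
contrast, and inspect the regions:

```r
library(dimani)

spec  <- presetThalamus(seed = 1, noiseSigma = 2)
built <- buildPhantom(spec)
ci    <- computeContrast(built$dwi, method = "mean", bThreshold = 100)
regionStats(ci, built$labels)
#>   label      name   mean     sd n_voxels
#> 1     1       CSF  2.697 0.2025    66460
#> 2     2 VL_bright 40.396 0.2855     6272
#> 3     3   VL_dark 35.257 0.2877     6272
#> 4     4        MD 35.048 0.2862      739
#> 5     5        CM 35.930 0.2839      257
#> 6     6        IC 41.724 0.2869     5184
```

The ordering is the physics of the contrast: the CSF-like surround
(MD = 3.0e-3 mm²/s, isotropic) is darkest; the isotropic gray-matter-like
MD nucleus (0.7e-3) sits in the middle; at the *same* mean diffusivity the
high-anisotropy laminae (VL_bright, FA 0.8) and capsule (IC, FA 0.85) are
brightest — Jensen's inequality on the convex exponential. The two zebra
laminae differ by ~5 intensity units against a within-slab SD of ~0.29,
i.e. the lamination is detectable at ~18 noise SDs.

Equalize for display and quantify segmentation reproducibility against a
synthetically perturbed "second rater":

```r
eq <- equalizeAdaptive(ci, clipLimit = 0.01, nBins = 256)   # values in [0, 1]
pairwiseDiceReport(list(s1 = built$labels,
                        s2 = perturbLabels(built$labels, 0.2, seed = 9)))
#> DiceReport: 6 comparison record(s), 6 label(s)
#>  label      name mean_dice sd_dice n_comparisons
#>      1       CSF     0.963       0             1
#>      2 VL_bright     0.885       0             1
#>      3   VL_dark     0.883       0             1
#>      4        MD     0.913       0             1
#>      5        CM     0.859       0             1
#>      6        IC     0.884       0             1
```

Smaller structures lose more Dice under the same boundary perturbation —
the behavior expected of small nuclei such as the habenula.

From the shell, the same pipeline:

```sh
Rscript inst/cli/dimani.R phantom --preset thalamus --seed 1 --out ph/
Rscript inst/cli/dimani.R compute --dwi ph/dwi.nii.gz --bval ph/bvals \
    --bvec ph/bvecs --method mean --equalize --out contrast.nii.gz
Rscript inst/cli/dimani.R dice --labels seg_a.nii.gz seg_b.nii.gz \
    --names ph/names.json --out report.csv
```

Every run writes a JSON provenance sidecar (tool version, parameters,
input digests, seeds).

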