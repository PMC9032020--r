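# resectseg

Semiautomated segmentation of **surgical resection cavities** on
postoperative T1-weighted brain MRI, with automated anatomical reporting.

After resective epilepsy surgery, the cavity left by the removed tissue is
the best available estimate of the epileptogenic zone, and studies of
surgical outcome biomarkers need it delineated voxel by voxel.  The cavity
is dark and homogeneous on T1 MRI — ideal for seeded region growing —
but its intensity resembles the image background, so naive growth leaks
out of the skull.  `resectseg` implements a hybrid pipeline for
neuroimaging researchers: region growing on the postoperative MRI,
confined by the patient's preoperative brain mask.

## The method

Given a co-registered postoperative volume, a preoperative brain mask and
one seed voxel inside the cavity:

1. **Standardize** the uint8-converted volume: contrast-stretch adjustment
   (`adj`) or min–max normalization (`norm`), globally or per axial slice
   (`adj-g`, `adj-l`, `norm-g`, `norm-l`).
2. **Preprocess the mask**: 3D Gaussian smoothing (σ in voxels) and
   re-binarization at > 0.01; optionally remove ventricle labels.
3. **Grow** from the seed, best-first over the in-mask 6-neighbour queue:
   at each step admit the queued voxel minimizing |I − mean(region)|, iff
   that difference is strictly below `tolerance × 255`; stop when the
   minimum reaches the tolerance or the queue empties.
4. **Finalize**: Gaussian-smooth the region and re-binarize at 10% of the
   smoothed maximum, yielding the logical resection model and its volume
   in cm³.

Models are scored against gold standards with the dice similarity
coefficient, DSC = 2|X∩Y| / (|X|+|Y|).  A factorial sweep over the tested
parameter values (504 pipelines per ADJ method, 84 per NORM) supports
optimization; `tuning_bounds()`/`mqd()` quantify how close
tolerance-only tuning (MaxS) comes to full tuning (MaxP) via the mean
quadratic discard Σ(MaxSᵢ−MaxPᵢ)²/N.  A 12-seed placement protocol
(four seeds per MRI view, slices two voxels apart) measures robustness to
seed choice.  Given a Desikan–Killiany-style parcellation, the package
maps labels onto seven anatomical areas (frontal, temporal, parietal,
occipital, cingulate, hippocampus, amygdala; sided), computes per-area
resection percentages by overlap or nearest-neighbour label propagation,
calls areas resected above a threshold, and selects that threshold by
leave-one-out cross-validation (concordance, accuracy, or ROC criterion).

Default parameters are the optimal local-adjustment settings: mask
smoothing 0.5, tolerance 0.05, saturation 10%, final smoothing 0.5.

## Worked example

No patient data ships with the package; the phantom generator builds
co-registered inputs with known ground truth:

```r
library(resectseg)

ph <- make_phantom(phantom_spec(noise_std = 5, rng_seed = 1))
ph
#> <resect_phantom> 72x72x72 voxels | cavity 18656 voxels (18.66 cm^3) | noise std 5

model <- segment(ph$post, ph$brain, ph$seed)   # defaults = optimal ADJ-L
model
#> <resection_model> 20310 voxels (20.31 cm^3), seed 41,41,36, method adj-l
dice(model$mask, ph$gold)
#> [1] 0.9574

areas <- map_areas(ph$labels, ph$lookup)
rep <- call_resected(knn_report(model$mask, areas), 1.76)
head(rep[rep$resected, c("area", "resection_pct")], 3)
#>           area resection_pct
#> 2 lh-cingulate         38.17
#> 3   lh-frontal          9.59
#> 6  lh-parietal          9.73
```

The 18.7 cm³ synthetic cavity is recovered with DSC 0.957 against the
exact ground truth (the ~2000 extra voxels are the one-voxel smoothing
halo of the finalization step), and the report lists every area the model
touches above the 1.76% threshold.  Re-running `segment` from any of the
12 protocol seeds (`perturb_seeds(ph$seed, dim(ph$post$data))`) returns a
bit-identical model: pairwise DSC and volume ratios of exactly 1.

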