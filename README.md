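# nwuct — automated net water uptake quantification from non-contrast CT

Ischemic brain edema lowers the X-ray attenuation of infarcted tissue on
non-contrast CT (NCCT). **Net water uptake (NWU)** quantifies this as the
percentage density deficit of a lesion relative to its mirrored
contralateral counterpart,

```
NWU = (1 − HU(A) / HU(B)) × 100
```

where `HU(A)` is the mean attenuation of the ischemic region and `HU(B)`
that of the corresponding contralateral normal tissue. NWU is a validated
early-stroke biomarker, but computing it normally requires a lesion mask
delineated on CT perfusion or diffusion MRI. `nwuct` implements a fully
automated, deep-learning-free pipeline that produces both the lesion mask
and its NWU **from the NCCT volume alone**, exploiting hemispheric
symmetry:

1. **Pre-processing** — resampling to 1 mm isotropic voxels, affine
   alignment to a left-right symmetric template, hemisphere splitting
   with mirroring of one side, and demons-style deformable registration
   between the hemispheres for voxel-wise contralateral correspondence.
2. **NWU map** — hemisphere parenchyma masks (positive HU, CSF/bone band,
   Sobel edge exclusion), masked 3D average pooling with an
   11 × 11 × 11 mm kernel and a 10% (133-voxel) minimum-coverage rule,
   then the NWU formula applied per voxel to corresponding window means.
3. **Lesion extraction** — Otsu thresholding above a noise cutoff,
   largest connected component, morphological opening, interior flood
   fill, and the final total NWU by the formula above over the extracted
   mask and its contralateral image.

The package also ships an **evaluation panel** (Dice, bounding-box IoU at
the 3D threshold 0.5^(3/2), detection rate, NWU error statistics) and a
**synthetic head-phantom generator** — skull shell, textured parenchyma,
ventricles, and a unilateral hypodense lesion of known uptake — so the
whole pipeline is testable end to end without clinical data. It is aimed
at researchers in stroke imaging who need a transparent, reproducible NWU
reference implementation or a test bed for their own variants.

## Worked example

```r
library(nwuct)

# symmetric template + a phantom with a 15%-uptake lesion and CT noise
template <- default_template()
spec <- phantom_spec(lesion_center_mm = c(-24, -10, 0),
                     lesion_radii_mm = c(16, 20, 14),
                     uptake_percent = 15, noise_sd = 2, seed = 7)
case <- generate_phantom(spec)
case
#> <phantom_case> 120 x 144 x 104 voxels, lesion 18.5 mL at 15% uptake (seed 7)

result <- run_case(case, template)
result
#> <nwu_case_result> side left, volume 13.4 mL, NWU 14.90 % (Otsu 9.17)
```

The report says the lesion was found in the left hemisphere, its refined
mask covers 13.4 mL, and the density deficit of that region relative to
its contralateral counterpart is 14.90% — the implanted ground truth was
15%. (The mask is deliberately interior-biased: sampling the lesion core
keeps the NWU estimate accurate even where the boundary is uncertain.) Benchmarking over a reproducible suite:

```r
suite <- phantom_suite(n = 20, uptake = c(5, 10, 15, 20),
                       volume_ml = c(10, 60), noise_sd = c(0, 4), seed = 11)
bench <- run_benchmark(suite, template)
bench
#> <benchmark_result> n = 20
#>   detection rate 1.00, mAP@0.354 1.00
#>   NWU MAE 0.18 %, ME -0.14 %, median AE 0.14 %
#>   Dice median 0.78 [0.72, 0.83]
```

Every lesion is detected, the NWU mean absolute error against the
implanted uptake is 0.18 percentage points, and the median Dice overlap
with the ground-truth masks is 0.78.

A thin command-line front end is installed with the package
(`system.file("cli", "nwu.R", package = "nwuct")`) with `run`, `phantom`
and `bench` subcommands for shell use on NIfTI files; all parameters are
exposed through a YAML config (see `nwu_config()`), and every report
embeds a hash of the exact configuration.

## Vignette

`vignettes/nwu-pipeline.Rmd` documents the model and its assumptions, all
tunable parameters with their defaults and units, what the phantom
emulates (and what it deliberately does not), and the package's numerical
design choices.
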