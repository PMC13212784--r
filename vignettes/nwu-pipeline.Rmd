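---
title: "Automated net water uptake from non-contrast CT: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated net water uptake from non-contrast CT: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nwuct)
```

## The model

Cytotoxic edema draws water into ischemic brain tissue, lowering its CT
attenuation by roughly 1.5–2.5% per percent of water uptake. Net water
uptake (NWU) operationalises this as a ratio of mean attenuations,

$$\mathrm{NWU} = \left(1 - \frac{\overline{HU}(A)}{\overline{HU}(B)}\right) \times 100,$$

with $A$ the ischemic region and $B$ its contralateral homologue. The
quantity is self-calibrating: scanner-level offsets that affect both
hemispheres equally cancel in the ratio, which is why the contralateral
mirror — rather than an absolute HU threshold — is the reference. The
assumptions this rests on are (i) approximate bilateral symmetry of the
healthy brain, (ii) a unilateral lesion, so the mirror region is
actually normal tissue, and (iii) comparable beam paths for mirrored
voxels. The pipeline automates the construction of $A$ without any
manually delineated mask:

1. resample the NCCT to 1 mm isotropic voxels;
2. align it by an affine registration to a left–right symmetric template
   so the mid-sagittal plane is a coordinate plane;
3. split the volume at that plane, mirror the right half, and register
   the mirrored half deformably onto the left to absorb normal
   anatomical asymmetry;
4. mask brain parenchyma in both hemisphere images;
5. compute, at every voxel, the mean HU of an 11×11×11 mm window in each
   hemisphere (masked average pooling) and apply the NWU formula to the
   pair of window means — a voxel-wise NWU map;
6. threshold the map (Otsu above a noise cutoff), keep the largest
   connected component, refine it morphologically, and report the NWU of
   the final mask by the same formula.

Window means rather than single voxels make the map robust to CT noise:
at a noise level of $\sigma$ HU, a full 1331-voxel window estimates the
local mean to $\sigma/\sqrt{1331} \approx 0.03\sigma$ HU.

## Tunable parameters

All parameters live in one nested configuration (`nwu_config()`), can be
overridden from YAML (`read_config()`), and are hashed into every run
report.

| group | key | default | meaning |
|---|---|---|---|
| resample | `target_spacing` | 1 mm | isotropic working resolution; the kernel and coverage constants assume it |
| registration | `metric` | `"mse"` | similarity metric; `"mi"` available |
| registration | `dof` | `"rigid"` | 6-parameter alignment; `"similarity"` adds isotropic scale |
| registration | `shrink`, `max_iter` | 8/4/2, 200/200/100 | multi-resolution pyramid and per-level optimiser caps |
| demons | `sigma_mm` | 2 mm | Gaussian regularisation of the displacement field |
| demons | `iterations`, `levels`, `tol` | 100, 2, 1e-4 | per-level iteration cap, pyramid depth, relative-MSE stop |
| demons | `max_disp_mm` | 10 mm | hard cap on displacement magnitude |
| mask | `csf_hu`, `bone_hu` | 14, 60 HU | parenchyma band; voxels at or outside are excluded |
| mask | `edge_threshold` | 120 | 3D Sobel magnitude (unnormalised weights) above which a voxel is excluded |
| pooling | `kernel_mm` | 11×11×11 mm | window size; 1331 voxels at 1 mm |
| pooling | `min_fraction` | 0.10 | coverage rule: windows with fewer than `floor(0.10·1331) = 133` in-mask voxels are invalid |
| nwu | `clip` | [−30, 30] % | clipping of the voxel-wise map against pathological ratios at mask borders |
| lesion | `lower_cutoff` | 2.5 % | noise floor below which map values never seed a lesion |
| lesion | `erosion_radius`, `dilation_radius` | 1, 1 voxel | morphological opening of the candidate |
| lesion | `connectivity` | 26 | 3D connectivity for component labelling |
| lesion | `min_volume_ml` | 1 mL | candidates below this report "no lesion" |

The HU band (14–60) is a common parenchyma window: CSF sits near 0–15 HU,
gray/white matter near 25–45 HU, and bone far above. The Sobel threshold
of 120 (in units of the unnormalised 3D Sobel response, roughly HU per
voxel) passes the gentle gray/white gradients but removes
skull/CSF interfaces, whose step edges respond at several hundred. The
2.5% lower cutoff sits about ten standard deviations above the pooled
noise floor at typical CT noise (2–4 HU), yet below any clinically
meaningful uptake.

## Design choices in the open parts

**Template.** A distributable symmetric CT atlas does not exist, so the
default template is the package's own noise-free symmetric phantom head
(`default_template()`); any user-supplied symmetric volume can replace
it. Alignment to a same-geometry template is deliberately easy — the
scientific content of the step is the standardised mid-sagittal plane,
not inter-subject normalisation.

**Registration metric.** NCCT-to-CT-template alignment is mono-modal, so
mean squared error is the default metric; mutual information is kept as
an option for robustness experiments. The optimiser is Nelder-Mead over
a 3-level pyramid with simplex restarts at the coarse levels; at the
stated caps, self-registration recovers identity to <0.001 mm and random
rigid displacements (≤10°, ≤10 mm) to ~0.3 mm mean landmark error.

**Hemisphere correspondence.** The mirrored right hemisphere is warped
onto the left by a demons-style scheme (symmetric force, Gaussian field
smoothing of σ = 2 mm, displacement cap 10 mm, best-iterate selection so
the metric never worsens versus the identity field) *before* pooling, so
window pairs compare deformation-corrected anatomy. A
`pair_by_mirror_only` flag disables the warp for ablation. On an exactly
symmetric input the scheme returns the zero field, which makes the null
control exact.

**Intensity normalisation.** An optional affine HU rescale
(`normalize_to_template()`, config key `nwu$normalize`) maps the aligned
volume's robust positive-intensity range onto the template's. It is off
by default: NWU is a within-image ratio, so a pure gain cancels exactly
and only the offset component could matter; the switch exists to ablate
that question, not as a recommended step.

**Otsu population.** The threshold separating lesion from background is
computed on the *positive* NWU values at or above the lower cutoff,
pooled from both sign conventions. Including the full positive
population would let the enormous near-zero noise class dominate the
histogram and drag the threshold deep into the lesion's pooled boundary
skirt, inflating the mask and diluting the reported NWU; restricted to
the supra-cutoff values the threshold self-scales to roughly half the
lesion's uptake, which places the candidate boundary at the half-overlap
surface of the pooling kernel — i.e. at the true lesion boundary. Ties
across empty histogram gaps resolve to the plateau midpoint.

**Morphology.** The candidate is opened with an equal-radius
erosion/dilation pair (1 voxel each). A net-dilating refinement was
rejected: every voxel of normal tissue added to the mask pulls the mean
of $A$ toward $B$ and biases NWU low by the added volume fraction. The
final mask is restricted to a single connected component and its
enclosed cavities are filled. The side (left/right) is the hemisphere
with the larger supra-threshold candidate.

**Right-sided masks on the full grid.** The pipeline's working frame is
the left-hemisphere grid; a right-sided lesion mask is carried back
through a first-order inverse of the deformation (nearest-neighbour warp
by the negated field) before un-mirroring. At the smooth, capped fields
the pipeline produces, the first-order inverse is accurate to well below
a voxel.

**Interpretation of the total NWU.** The reported `nwu_total` uses the
raw (unpooled) HU means over the final mask and its warped contralateral
correspondence. Because the mask construction is interior-biased by the
Otsu scaling above, the estimate stays close to the lesion's true uptake
even when the boundary is uncertain — undershooting the volume hurts
Dice slightly but not the NWU, which is the clinically reported number.

## The phantom: what it emulates, and what it does not

`phantom_spec()`/`generate_phantom()` build a digital head: an
ellipsoidal skull shell at 1200 HU, a thin 5 HU CSF gap, parenchyma at
35 HU modulated by a smooth ±5% multiplicative texture (a stand-in for
gray/white contrast that keeps pooling and Otsu non-degenerate), paired
8 HU ventricles, and optionally a unilateral ellipsoidal lesion whose
density is exactly $(1-w/100)$ times the local parenchyma before noise —
$w$ is therefore the ground-truth NWU by construction, and with no
noise, no asymmetry and a sharp boundary the formula applied to the
ground-truth mask recovers $w$ to machine precision. Texture is
symmetrised, so lesion-free phantoms are exactly mirror-symmetric.
Additive Gaussian HU noise, a smooth random asymmetry deformation, and a
Gaussian lesion-boundary blur are available per case; the blur default
is 0 (sharp) because any blur dilutes the implanted density ratio and
would break the exactness of the ground truth — it exists to emulate the
subtle-hypoattenuation regime, not for calibration.

Deliberately **not** modelled: CT physics (no sinogram/filtered
backprojection, so no streaks, beam hardening or cupping), gantry tilt,
anatomical detail (gyri, deep gray nuclei), bilateral or multiple
lesions, and partial-volume effects at the skull base. Passing the
phantom suite therefore demonstrates the correctness of the machinery
and the self-consistency of the method under its own assumptions — it
does not certify clinical accuracy, where confounds like leukoaraiosis,
old infarcts and asymmetric positioning dominate the error budget.

Suite sampling (`phantom_suite()`) draws uptake, nominal volume and
noise per case, places each lesion by rejection sampling (fully inside
the brain ellipsoid, strictly within one hemisphere, bounded retries),
and records achieved volumes; lesions overlapping a ventricle exclude
those voxels from the ground-truth mask, as real infarcts do not include
CSF. The standard validation suite is 20 cases, uptakes {5, 10, 15,
20}%, volumes 10–60 mL, noise 0–4 HU — conditions chosen to mirror the
lesion-size and edema range of early middle-cerebral-artery stroke while
staying strictly easier than clinical data (no modality gap between the
"reference" and the image).

## Numerical choices and degenerate inputs

* Trilinear interpolation for HU resampling (the resolution step's
  interpolation is not otherwise constrained; linear is the assumption),
  nearest-neighbour for every mask; positions up to half a voxel outside
  the grid clamp to the border, anything further is background
  (−1000 HU for CT, 0 for masks).
* Window sums use exact running-sum accumulation (no FFT), so pooled
  means match a brute-force oracle to 10⁻⁶ and are bounded by the masked
  input range; borders truncate the window but the coverage count is
  always measured against the full nominal 1331.
* Otsu uses 256 bins over the observed range; constant input is a
  degenerate histogram and raises an error at the operation level, while
  the lesion extractor treats it as "no lesion".
* Component labelling assigns labels in scan order, so size ties break
  toward the component containing the smallest linear voxel index.
* Odd-sized split axes exclude the single central slice from both
  hemispheres rather than assigning it arbitrarily.
* An empty lesion is a valid outcome everywhere downstream: side
  "none", volume 0, NWU reported as missing.
* All randomness (phantom noise, suite sampling) is seeded; pipelines
  and suites are bitwise reproducible per seed.

## Problem sizes used in the shipped validation

The test and acceptance runs use the default 120×144×104 phantom head at
1 mm for end-to-end studies (the size a real supratentorial volume
occupies after cropping), a 72×88×64 head for unit-level checks, 20³
volumes for pooling oracles, and 12³ masks for connected-component
oracles. On one CPU a full case takes roughly 10 s — about 6 s affine
alignment, 3 s demons, the rest masking, pooling and extraction — and
the 20-case suite about 4 minutes.

## Known limitations

* The affine step assumes the head is already roughly upright; rotations
  far beyond the tested ±10° may fall outside the Nelder-Mead basin.
* Bilateral or midline-crossing lesions violate the contralateral
  assumption and will bias both the map and the reported NWU; the
  pipeline reports a single unilateral component by design.
* The demons scheme absorbs smooth anatomical asymmetry but, by the same
  token, can absorb a small part of a lesion's contrast at its boundary;
  the regularisation and iteration caps bound this effect (it is
  invisible in the suite's error budget) but it is not zero.
* Core/penumbra differentiation is out of scope: NWU reflects
  hypoattenuation, not perfusion state.
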