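---
title: "Shading correction of narrow-FOV CBCT: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shading correction of narrow-FOV CBCT: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
simulation model and its assumptions, the network and training protocol,
the parameters that matter, and the choices made where the design was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The restoration problem

Narrow field-of-view (FOV) cone-beam CT suffers three intensity
distortions that make its Hounsfield units (HU) quantitatively
unreliable: scatter-induced *cupping* (the object center reconstructs
darker than its periphery), *truncation* artifacts when the body extends
beyond the 208-mm reconstructible FOV (bright bands at the rim and a
non-unique interior solution), and the global intensity *lowering*
introduced by extrapolation-based truncation correction. The package
treats HU restoration as supervised image-to-image translation on axial
slices: the input is a corrupted CBCT slice, the label the aligned CT
slice, both normalized to `[0, 1]`.

## Simulation model

`simulate_cbct()` chains five stages per axial slice.

**Attenuation conversion.** `mu = (clip(HU, -1000) + 1000) / 2^16` per
mm; air maps to exactly 0 and the inverse is applied after
reconstruction. Any monotone linear map would serve; this one keeps
projector inputs in the range a flat-panel reconstruction toolkit
expects.

**Fan-beam projection.** The axial problem is two-dimensional, and the
central plane of a cone beam *is* a fan beam, so a per-slice fan-beam
projector replaces a 3D cone-beam projector; cone-angle effects are out
of scope. Rays are integrated with bilinear interpolation at a half-pixel
step; the test suite holds the projector to 1% RMS against 10×
oversampled brute-force integration. The default geometry mirrors a
treatment-room C-arm: source-to-isocenter 1172 mm, source-to-detector
1672 mm, 220° arc, 500 views, detector pitch 0.388 mm. The detector is
collimated to 765 bins so the isocenter FOV is 208 mm — the printed FOV
of the clinical system rather than the ~278 mm a full 1024-bin panel
would imply; the full panel remains available via `detector_bins`.

**Projection-domain physics.** The corruption model is parametric — the
reference reconstruction platform's internal operators are not public —
and is chosen to produce the qualitative artifacts the network corrects:

* *Scatter* (`scatter_factor`, default 0.001): in intensity space
  `I = exp(-p)`, an additive term `f_sc * G(I)` where `G` is a
  Gaussian-weighted integral of the transmitted intensity along the
  detector row (kernel SD `scatter_kernel_width`, default 100 mm,
  integrated per mm of detector). Because `G` integrates rather than
  averages, a factor of 0.001 yields scatter-to-primary ratios near 1
  behind a wide pelvis — the regime in which cupping of tens of HU
  appears. Bins behind dense anatomy (small `I`) receive relatively more
  scatter, darkening the reconstructed center.
* *Beam hardening* (`beam_hardening_factor`, default 1.005): a
  compressive power law on post-log attenuation, `p -> p^(1/f)`, with
  fixed point at `p = 1`.
* *Noise* (`noise_factor`, default 0.001): Gaussian intensity noise of
  SD `f_n * I0`, clipped at `10^-6 * I0` before the log for numerical
  safety.

`(0, 1, 0)` is the exact identity and returns the input bit-for-bit.

**Truncation handling.** Rows whose edge value exceeds a small threshold
are extended on the truncated side by 30% of the detector width
(`extension_fraction = 0.30`): the row is mirrored about its edge bin and
weighted by a cosine that starts at 1 and reaches 0 at the extension end.
Mirroring about the edge bin itself keeps the extension continuous at the
detector edge to within the first cosine factor (< 1%). The extension
participates only in ramp filtering; backprojection uses the original bin
support. This extrapolation suppresses the bright rim band at the cost of
a global intensity lowering — precisely the residual shading the network
is trained to remove, so the simulator reproduces it deliberately.

**Short-scan FBP.** Cosine pre-weighting, redundancy weighting, Ram-Lak
ramp filtering (cosine-apodized by default), and distance-weighted
(`1/U^2`) backprojection. For the 220° arc the redundancy weights
generalize Parker weighting to over-scan: each ray's weight is
`f / (f + f_conjugate)` with `f` a `sin^2` taper of width equal to the
over-scan angle, so conjugate samples sum to exactly 1 and
singly-measured rays get weight 1 (this defining property is asserted to
`1e-6` in the tests). One orientation subtlety is worth recording: with
the detector axis oriented along `(-sin b, cos b)`, the conjugate of ray
`(b, g)` lies at `b + pi - 2g`, not the textbook `b + pi + 2g`; the sign
follows from the parallel-beam parameterization and using the wrong one
produces a position-linear HU tilt of tens of HU that a uniform-disk
reconstruction exposes immediately.

## Digital pelvis phantoms

`generate_phantom()` builds seeded HU volumes with tissue label maps:
an elliptical body (anterior-posterior axis 0.70 of the lateral width)
with subcutaneous fat and muscle layers, two femoral heads of spongy
bone in a cortical shell, a bladder ellipsoid, a clinical-target-volume
ellipsoid, and a muscle-walled rectum tube that can carry seeded air
pockets (per-slice probability 0.3, radii 5–15 mm) to synthesize the
air-mismatch scenarios the evaluation module excludes. Tissue HU means
(air −1000, fat −100, muscle +45, bladder +15, spongy bone +300,
cortical bone +700, CTV +50; Gaussian texture 10–20 HU) are standard
radiology ranges and fully configurable; none is asserted against
external data. The default 512×512 1-mm grid lets bodies up to 400 mm
exceed the 208-mm FOV, so truncation emerges naturally from geometry.

What the generator does *not* emulate: patient-realistic organ shapes,
deformation between paired scans, detector lag or ring artifacts, and —
importantly for one analysis — anatomy that is independent of body size.
Organ positions scale with the body width, so as the pelvis widens the
femoral heads migrate out of the FOV and the in-FOV Base error can
*fall* even though truncation worsens; the width-versus-error rank
correlation that holds for real patients is therefore confounded here,
and the tests assert the monotone driver (out-of-FOV body fraction grows
with width) instead. Passing tests on these phantoms demonstrate that
the pipeline's mechanics are correct, not that the trained weights
transfer to clinical anatomy.

## Network

The U-Net processing block is two 3×3 stride-1 convolutions with ReLU,
batch normalization after each convolution, and 10% dropout between them
("switching off" a random tenth of the activations during training).
Four contracting blocks of widths 16-32-64-128 are each followed by 2×2
max pooling; the expanding path mirrors them. Of the structural details
a width sequence does not pin down, the builder exposes three
(`transpose_kernel` 2/3, `final_kernel` 1/3, `bottleneck`
paired/pooled) and freezes one variant as the default: the deepest
contracting block pools into an equal-width (128) expanding block — the
"128-128" pair — transpose convolutions are channel-preserving 2×2
stride-2, every skip concatenation joins equal widths
(128+128, 64+64, 32+32, 16+16), and a 1×1 sigmoid convolution maps the
final 32 channels to one output. This is the only arrangement in which
the reference width sequence, the symmetric block pairing, and the
fine-tune scopes (one block = the 128-128 pair; two blocks =
64-128-128-64) are all simultaneously natural. Its full trainable count
is 919,777 parameters (convolution and transpose weights and biases plus
batch-norm scale/shift; moving statistics excluded), which
`enumerate_unet_variants()` shows is the closest of all enumerated
variants to the reference configuration's nominal count of 919,177. No variant
in the grid reproduces that figure exactly — a parity argument shows no
architecture with all widths multiples of 16, biased convolutions, and a
single 1-channel head can — so the nearest-variant default is frozen and
the discrepancy accepted rather than hidden behind an ad-hoc layer.

The engine (Rcpp/Armadillo kernels for convolution, transpose
convolution, and pooling; R for batch norm, dropout, and the optimizer)
supports arbitrary input sizes divisible by `2^n_blocks`, exact
finite-difference-verified gradients, and strict freezing: in a frozen
block neither weights nor batch-norm statistics change, and inference
statistics are used in its forward pass during fine-tuning.

## Training protocol

Mean absolute error on `[0, 1]` patches, ADAM with learning rate 0.001,
beta1 0.9, beta2 0.999. Runtime augmentation draws a fresh 128×128 crop,
a rotation by a multiple of 90°, and an optional horizontal flip for
every presentation, applied identically to input and label, so the
network never sees the same patch twice. Validation metrics are computed
each epoch on full, un-augmented slices (the deployment condition) and
the checkpoint with maximal validation SSIM is returned.

Unstated hyperparameters are artifact choices: batch size 8, 4–6 patch
draws per slice per epoch (an "epoch" is therefore several augmented
passes — necessary because desk-scale cohorts provide tens, not
thousands, of slices), 18 pretraining and 14 fine-tuning epochs in the
demonstration configuration, validation capped at 6 slices per epoch.
`noFT` trains a fresh network on target data only; `FTx` pretrains on
synthetic pairs end to end (the Synth model) and then retrains the `x`
deepest symmetric pairs — for `x = 2`, exactly the blocks of widths
64-128-128-64 plus their adjacent transpose convolutions; the 1×1 output
convolution stays trainable by default (`finetune_final`). The
leave-one-out harness (`run_loocv()`) builds one fold per scan pair,
fine-tunes on the rest, and reports per-fold median PSNR/SSIM/MAE for
Base, noFT, and FTx; its trainer is injectable so the fold structure can
be verified with a stub.

## Evaluation conventions

* PSNR uses peak 1 on the normalized scale (a fixed offset from HU-scale
  PSNR; comparable across runs).
* SSIM uses an 11×11 Gaussian window (SD 1.5), K1 = 0.01, K2 = 0.03,
  data range 1, averaged over positions where the full window fits, so
  no padding convention enters the value.
* MAE is reported in HU after exact denormalization
  (`HU = 4100 x - 1000`).
* The air-mismatch mask excludes voxels below −300 HU in exactly one of
  the two volumes (the threshold is configurable; the reference
  procedure's exact values are not specified).
* CNR is signed, `(mean_fg - mean_bg) / sqrt((var_fg + var_bg)/2)`;
  a background-only-SD variant is available.
* Cupping depth is center-minus-periphery mean HU with the periphery
  taken at 40–70 mm radius — inside the FOV but away from the rim band
  that truncation dominates; measured on uniform phantoms, since in
  heterogeneous anatomy radial means mix tissues.
* The network's correction is defined only inside the reconstructed FOV:
  `correct_slice()` composites the prediction with the input outside the
  FOV circle, and slice metrics are computed on the 220×220
  reconstruction grid after cropping the zero padding. With random-crop
  training on mostly-empty 256×256 frames, the frame corners are
  sampled too rarely at desk scale for the network to learn them; they
  carry no anatomy and no correction task, so they are excluded by
  construction rather than by more training.

## Problem sizes

The package's own study configuration (`run_demo()`): 12 synthetic
pretraining phantoms and 6 target phantoms of widths 250–310 mm, 3
slices each, on a 320-voxel grid; a reduced geometry of 180 views and
2×-binned detector pitch (FOV unchanged); a 2-block/8-filter network;
18 + 14 epochs. The acceptance checks in the test suite use the full
default geometry (500 views, 765 bins) for projector, FBP, cupping, and
truncation properties, and the reduced configuration for the end-to-end
efficacy study. These sizes are the package's chosen desk-scale study
conditions; the full-scale configuration (4 blocks, 16 filters, 220³
volumes, thousands of slices) is what the defaults of `build_unet()` and
`cbct_geometry()` describe.

## Known limitations

* The scatter/beam-hardening operators are parametric stand-ins with
  the right qualitative behavior (cupping that deepens with the scatter
  factor, compressive high-attenuation response); their constants are
  not calibrated against measured scatter.
* Batch normalization with batch size 8 on small cohorts couples
  training stability to crop statistics; the trainer mitigates this with
  several patch draws per slice but small-cohort runs remain noisier
  than full-scale training.
* Phantom anatomy scales with body width (see above), confounding
  width-versus-error analyses across wide ranges.
* The 2D fan-beam simulator cannot produce cone-angle artifacts, ring
  artifacts, or detector lag, and the synthetic pairs are perfectly
  aligned — residual-deformation robustness of the transfer protocol is
  untested here.
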