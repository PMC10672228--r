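---
title: "Synthetic MV CBCT generation for pacemaker visualization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic MV CBCT generation for pacemaker visualization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthmv)
```

## The problem

Cardiac implantable electronic devices (pacemakers, defibrillators) must be
contoured on radiotherapy planning images so their dose can be limited.
On kilovoltage (kV) CT and CBCT the metal can scatters X-rays and
preferentially absorbs the low-energy part of the beam, producing bright and
dark streaks that obscure the device outline. Megavoltage (MV) CBCT
interacts far less with high-atomic-number material: the device appears
streak-free, at the cost of poor soft-tissue contrast and higher noise.
`synthmv` implements an end-to-end pipeline for studying whether
image-to-image translation networks — a paired conditional GAN and an
unpaired-capable cycleGAN — can map kV images into MV-like images on which
the device contours as cleanly as on a real MV acquisition.

The pipeline runs entirely on synthetic thorax-phantom images, so every
stage is exercised with known ground truth: a parametric phantom renderer,
a sinogram-domain streak simulator, rigid mutual-information registration,
clipping/normalization/patch extraction, compact GAN trainers, and
contour-agreement evaluation (Dice, surface Dice at 1 mm, HD95, mean
surface distance) with a two-tailed rank-sum comparison of the model
routes. Real NIfTI triplets can be imported through the same case
structure, making every downstream stage source-agnostic.

## The synthetic study and what it emulates

The default study design mirrors a phantom experiment in which ten
pacemakers and four thorax phantoms form 40 possible pairings, of which 35
combinations are imaged in three modalities — kV CT, kV CBCT, MV CBCT —
for 105 images in total; 80% of cases (28) train the models and 20% (7)
are held out. Which five pairings go unimaged is not part of the design
being emulated, so the generator drops the last five in lexicographic
order, deterministically.

Each combination is rendered as a piecewise-constant attenuation map:
a body ellipse (soft tissue, 40 HU) containing two lung ellipses
(-700 HU) and a spine disc (700 HU), a 5 mm tissue-equivalent bolus sheet
over the anterior surface, and a device polygon (3000 HU, above the
12-bit kV ceiling once clipped) with a thin lead, placed flat on the
anterior chest under the bolus. The 3000 HU device value is a plausible
titanium-can attenuation; real values saturate the scanner scale, which
the [-1000, 2000] HU clip reproduces.

The three modalities differ in their observable physics, not in geometry:

* **kV CT / kV CBCT** — each slice is forward-projected to a parallel-beam
  sinogram (180 views over 180 degrees), every ray whose path crosses the
  device is corrupted multiplicatively, and the slice is reconstructed by
  filtered back-projection (band-limited discrete ramp filter). The
  corruption alternates over- and under-attenuation in two-detector-bin
  bands, flips sign between neighbouring angles, scales with the device
  path length, and carries a net under-attenuation component of 0.3 times
  the streak strength — beam hardening depresses measured line integrals
  through metal while scatter raises neighbouring rays. This produces
  bright/dark fans radiating through the device and a corrupted apparent
  device density, the two failure modes that make kV contouring hard.
  CT uses a weaker default streak strength (0.6) than kV CBCT (1.2),
  reflecting iterative metal-artifact reduction in the CT reconstruction.
  Zero-mean Gaussian noise is applied on the reconstructed HU scale
  (ct 15, kv_cbct 30 HU) — the design declares noise in image-domain HU,
  so applying it after FBP keeps the parameter directly interpretable —
  and the result is clipped to [-1000, 2000] HU.
* **MV CBCT** — streak-free by construction: the attenuation map is
  compressed into [-1000, 400] HU by a fixed monotone piecewise-linear map
  that keeps all tissue classes separable and sends the device to the
  range maximum, then 40 HU Gaussian noise is added (higher than the kV
  noise, reflecting poorer MV low-contrast quality). Thresholding the
  noiseless rendering at the soft-tissue/device midpoint (200 HU)
  reproduces the device mask exactly — the property the reference contour
  relies on.
* **CT misalignment** — the CT is resampled under a random in-plane rigid
  offset (sd 3 mm per translation axis, 2 degrees rotation), emulating the
  phantom transfer between imaging sessions; the aligning transform is
  recorded as ground truth for the registration stage. The kV CBCT and MV
  CBCT share one frame (acquired without moving the phantom), so the
  kV-to-MV route needs no registration.

These defaults were chosen once as the study conditions. At them, the
device contrast-to-noise ratio against adjacent soft tissue is higher on
simulated MV than on simulated kV — the premise of the whole approach —
and thresholded contours on raw kV images degrade to a mean Dice of
roughly 0.1-0.4 against the MV reference, while the device remains
partially visible, matching the qualitative description of devices that
are "hard to discern" rather than invisible.

What the generator does **not** emulate: cone-beam (divergent) geometry,
spectral beam-hardening physics, scatter kernels, anatomical variability
between slices (volumes are extruded 2D slices), detector lag or motion.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that the translation models repair this class of streak
corruption; they do not certify performance on clinical data.

## Registration

The CT is registered to the kV CBCT (both kV-energy images, so their
intensities are comparable and the CBCT frame is the one shared with MV)
by minimizing negated Mattes-style mutual information: a joint intensity
histogram over the overlap region, Parzen-smoothed with a linear kernel on
both axes, 50 bins per axis. Fewer than 10% of fixed voxels overlapping is
an error, never a silent extreme value. The optimizer is a regular-step
gradient descent on central-difference gradients with step halving, at
most 200 iterations per level, run coarse-to-fine over a shrink-factor
4/2/1 pyramid; rotation is scaled onto a millimetre-equivalent axis (one
degree at the typical body radius) so the three parameters descend
jointly. Because the phantom stack is extruded, transforms are in-plane
rigid (one angle, two translations) applied per slice; the rotation centre
is the fixed image's physical centre. Intensities resample linearly,
masks by nearest neighbour; out-of-field voxels become air (-1000 HU) and
are excluded from the validity mask that overlap cropping intersects.

At the package's test scale (64 x 64 at 4 mm), 20 random misalignments up
to 6 mm / 4 degrees are recovered with a median translation error around
0.1-0.2 mm at zero noise — far under the half-voxel criterion the test
suite asserts.

## Preprocessing

Registered triplets are clipped (kV [-1000, 2000] HU; MV [-1000, 400] HU),
cropped to the intersection of validity masks, and affinely normalized to
[-1, 1]. Body masks come from thresholding the MV image above -400 HU,
then per-slice largest connected component and hole filling. Training
patches are 2D squares cut at centres sampled uniformly from body-mask
voxels (restricting centres to the body maximizes body content per patch);
patches that would overhang the grid are shifted minimally inward, which
keeps every training pixel real image content while preserving the
centre-in-body guarantee. Input and target patches are always cut at
identical coordinates. Full scale uses 256 x 256 patches, 32 per case;
the test profile uses 32 x 32, 8 per case.

## Translation models

Both model families share one generator topology: a ResNet-style
fully-convolutional network with a three-convolution encoder (7x7 stem,
then two stride-2 3x3 convolutions), nine residual blocks at full scale,
and a three-transposed-convolution decoder (two stride-2 upsamplings and a
stride-1 7x7 final transposed convolution), instance normalization and
leaky-ReLU (slope 0.2) after internal layers, and a tanh output matching
the [-1, 1] normalization. Output spatial dimensions equal input
dimensions for inputs divisible by four; inference reflect-pads and crops
otherwise. Whether the three encoder convolutions include a stride-1 stem
is an open design point; the classic layout (stem + two downsamplings) is
used, and the stride-1 final transposed convolution keeps the decoder at
exactly three transposed layers.

The discriminator is a patch-level network: five 4x4 convolutions with
strides 2, 2, 2, 1, 1, leaky-ReLU between layers, final layer linear, so a
256 x 256 input yields a 30 x 30 map of sub-regional authenticity scores.
It judges the (synthetic) MV image alone, unconditioned on the kV input.

Training uses least-squares adversarial losses and Adam. The cGAN adds an
L1 term to the paired target with weight 100; the cycleGAN trains two
generator/discriminator pairs with cycle-consistency weight 10 and no
identity term (flag-free; the classic identity loss is omitted). These
weights, the optimizer (learning rate 2e-4, beta1 0.5 at full scale), and
the epoch/batch defaults come from the conditional-GAN/cycleGAN lineage;
they are configuration-exposed, not baked in. The entire training loop —
convolution kernels, instance-norm backprop, Adam — is implemented in the
package (RcppArmadillo kernels driven from R), which keeps runs
single-threaded-deterministic: a fixed seed fixes initialization and batch
order and reproduces final weights bit-identically, and checkpoints reload
with bit-identical forward outputs.

At test scale the networks are narrow (8 base channels, one residual
block) and train for about 500 steps with learning rate 1e-3 and beta1
0.9 — settings at which a tiny generator demonstrably fits an identity
task to L1 < 0.05, chosen because 200 steps at the full-scale learning
rate is too short for convergence in this compact engine.

## Evaluation

Manual delineation by multiple readers is not reproducible in software, so
contours are produced by thresholded auto-contouring (threshold, per-slice
largest component, hole fill) on both the synthetic and the reference MV
image; real reference masks can be imported for real-data runs. Metrics:

* **Dice**: `2|A∩B| / (|A|+|B|)`; undefined (an error) for two empty masks.
* **Surface distances**: surface voxels are foreground voxels with a
  face-neighbour background voxel; directed distances are exact
  nearest-surface-point Euclidean distances in physical mm, honouring
  anisotropic spacing, computed in 3D (a 2D-per-slice variant would change
  little for extruded stacks).
* **Surface Dice (1 mm)**: fraction of pooled surface points within
  tolerance of the opposite surface.
* **HD95**: 95th percentile, linear interpolation between order
  statistics, of the pooled symmetric distance multiset (pooling chosen
  over the max-of-directed-percentiles variant and documented here).
* **MSD**: directed mean from the reference contour to the evaluated one,
  as the metric is verbally defined; a symmetric flag exists because the
  literature often symmetrizes.

Model comparisons use a two-tailed Wilcoxon rank-sum test with midranks:
exact by full enumeration of rank assignments when the combined sample
size is at most 12 (a permutation null, which also handles ties and gives
p = 1 for identical samples), otherwise the normal approximation with tie
and continuity corrections. The implementation is the package's own and is
cross-checked in the tests against `stats::wilcox.test`.

## The reduced-scale experiment

`run_experiment()` drives the full chain from one configuration: simulate,
split 80/20, register (CT route only), preprocess, train the four routes
(cGAN/cycleGAN x CT-to-MV/kV-to-MV), translate the held-out cases, and
evaluate — emitting a four-route summary table (mean ± sd of the four
metrics) and the pairwise rank-sum p-values, plus a manifest with a config
snapshot and stage hashes for cache reuse. The test profile (64 x 64 grid,
12 combinations, three slices, narrow networks) completes in a few minutes
on one CPU; at that scale the experiment reproduces the *direction* of the
full-scale findings — contours on cGAN synthetic-MV images score a
substantially higher mean Dice than contours on raw kV inputs in every
seed tried, and the paired cGAN matches or beats the unpaired cycleGAN in
most seeds (their full-scale difference is itself not statistically
significant, so only the ordering is asserted, as a majority over seeds).
Absolute full-scale metric values are out of reach at desk scale: they
require the real phantom dataset, GPU-scale training and human contours.

## Numerical choices and degenerate inputs

* FBP uses the band-limited discrete ramp (Kak-Slaney) filter; the plain
  `|f|` filter leaves a DC bias. Reconstruction fidelity is asserted
  against a convergence tolerance measured at doubled angular sampling
  rather than a hard constant, since the residual is discretization, not
  angular undersampling.
* Mutual information on a constant image is undefined and errors
  explicitly (a degenerate joint histogram), never NaN.
* Dice of two empty masks and surface distances of an empty mask error.
* Percentile interpolation is the linear rule (R type 7).
* Patch centres exactly on the grid border clamp inward rather than
  zero-pad.
* All seeds derive from one global seed through a fixed affine map modulo
  a 32-bit prime, so every stage is reproducible in isolation.

## Limitations

Extruded 2D geometry, parallel-beam (not cone-beam) projection, a single
noise model per modality, and thresholded auto-contouring as the reader
stand-in all limit realism; conclusions about clinical images require the
real-data import route and full-scale training. The compact conv-net
engine is deliberately minimal (no GPU, no augmentation, no perceptual
losses) — sufficient for the reduced-scale experiment, not a general
training framework.
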