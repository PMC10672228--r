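# synthmv

Synthetic megavoltage (MV) CBCT generation for clearer pacemaker
contouring, as a fully testable R pipeline.

## The problem

Cardiac implantable devices must be contoured on radiotherapy planning
images. On kilovoltage (kV) CT/CBCT the metal can causes beam hardening
and scatter, so bright/dark streaks radiate through the device and obscure
its outline. MV imaging barely interacts with the metal — the device is
streak-free — but has poor soft-tissue contrast. The idea this package
operationalizes: train image-to-image translation models (a paired
conditional GAN and an unpaired-capable cycleGAN, both with ResNet
generators and patch-level discriminators) to map kV images into synthetic
MV (sMV) images, and quantify whether device contours drawn on sMV images
agree with contours on real MV images better than contours drawn on the
raw kV inputs.

Contour agreement uses the field's standard surface metrics between a
reference mask A (real MV) and an evaluated mask B (sMV):

- Dice similarity coefficient `DSC = 2|A∩B| / (|A|+|B|)`
- surface Dice at 1 mm (fraction of pooled surface points within 1 mm of
  the opposite surface)
- HD95, the 95th percentile of pooled surface distances (mm)
- MSD, the directed mean surface distance from reference to evaluated (mm)

with a two-tailed Wilcoxon rank-sum test (exact by enumeration for small
samples) comparing the model families.

Everything runs on seeded synthetic thorax phantoms — 35 device/phantom
combinations imaged as kV CT, kV CBCT and MV CBCT (105 images, 28/7
train/test split), with sinogram-domain streak simulation, a rigidly
misaligned CT, and exact ground-truth device masks — so every stage is
verifiable. Real NIfTI triplets can be imported into the same case
structure. See the vignette (`vignettes/synthetic-mv-cbct.Rmd`) for the
models, parameters and design decisions.

## Worked example

A reduced-scale end-to-end experiment (64 x 64 grid, 12 combinations,
narrow networks; a few minutes on one CPU):

```r
library(synthmv)

cfg <- experiment_config(profile = "test", seed = 1, routes = "kv2mv")
res <- run_experiment(cfg)
print(res$report)
#> <smv_report>
#>   4 per-case rows (2 cases x 2 route/model combinations)
#>   route    model mean_dsc mean_hd95_mm mean_msd_mm mean_sdsc_1mm sd_dsc
#> 1 kv2mv     cgan    0.882            4       0.667         0.843 0.0329
#> 2 kv2mv cyclegan    0.768            4       0.778         0.695 0.0193
#>   rank-sum model comparisons (two-tailed):
#>   route   metric model_a  model_b p_value
#> 1 kv2mv      dsc    cgan cyclegan   0.333
#> 2 kv2mv sdsc_1mm    cgan cyclegan   0.333
#> 3 kv2mv  hd95_mm    cgan cyclegan   1.000
#> 4 kv2mv   msd_mm    cgan cyclegan   0.667
mean(res$baseline$dsc)   # contours on the raw kV inputs
#> [1] 0.4274419
```

Reading: device contours on the cGAN's synthetic MV images reach a mean
Dice of 0.88 against the reference MV contours, the unpaired cycleGAN
0.77, while thresholding the raw streaked kV images manages only 0.43 —
the translation repairs the streak corruption that defeats direct kV
contouring. (At this tiny scale only the ordering is meaningful, not the
absolute values; the rank-sum p-values over two test cases are
uninformative by design.)

Individual stages are exported too: `generate_study()`,
`register_rigid()` / `resample()`, `clip_intensities()` /
`compute_body_mask()` / `extract_patches()`, `train_cgan()` /
`train_cyclegan()` / `translate()`, `auto_contour_device()` and the
metric functions, plus `autoplot()` methods for volumes and reports and
broom-style `tidy()` / `glance()` for reports. A thin command-line front
end lives at `inst/cli/synthmv.R` (`simulate`, `register`, `run-all`).

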