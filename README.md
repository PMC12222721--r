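# frexpan

Simulation and analysis of **fluorescence polarization microscopy (FPM)**
with **excitation polarization angle narrowing (ExPAN)** — including the
camera frame-separated pulse scheme (**FrExPAN**) used with negatively
switching fluorescent proteins.

## The problem

Rotating the excitation polarization makes a fluorophore's intensity
modulate as

    I(alpha) = y0 + A * cos^2(alpha - x)

where the phase `x` reads out the orientation of its transition dipole.
When fluorescent proteins are rigidly anchored (double membrane tags),
the phase maps membrane orientation with high contrast; a perpendicular
off-switching beam narrows the excited angle range further, turning the
cos² response into

    I(alpha) = y0 + A * cos^2(alpha - x) / (1 + f * sin^2(alpha - x))

whose **ExPAN factor `f`** quantifies the narrowing.  This package is a
tested toolkit for the whole workflow around that model, aimed at
microscopists and image analysts who want to prototype, validate or
reanalyse polarization-modulation experiments:

* a **forward simulator** — membrane geometries (vesicles, filaments,
  spineheads, whole-cell scenes), fluorophore fields with an order
  parameter for anchor rigidity, cos²-law excitation, photoswitching
  doses, lateral membrane diffusion, PSF blur and a Poisson/read-noise
  camera, with full per-frame ground truth;
* the **processing chain** — per-pixel stack mean normalization,
  switch/readout frame demultiplexing, periodic averaging, per-pixel FFT
  demodulation into offset/amplitude/phase maps, phase-coded rendering;
* **ExPAN statistics** — bounded model fitting, automated centre-out ROI
  picking with brightness/segmentation/fit-quality gates, Cohen's d and
  two-sample t comparison of ExPAN vs NoExPAN stacks;
* three **deconvolution paths** — per-frame Richardson–Lucy, a penalized
  space×phase deconvolution of polarization-demodulation (SPoD) data,
  and the per-pixel three-parameter ALPA model fitted through a PSF-blur
  forward model.

## Worked example

Simulate a FrExPAN acquisition of a vesicle, together with its reference
acquisition without the off-switch beam, and compare ExPAN factors:

```r
library(frexpan)

res <- run_pipeline(list(
  seed = 5,
  scene = list(kind = "circle",
               params = list(r = 450, center = c(1440, 1440)),
               density = 100, tag_mode = "double"),
  plan = list(n_frames = 130, frames_per_period_acq = 30,
              mode = "frexpan", n_lead_frames = 10),
  detector = list(shape = c(64, 64)),
  analysis = list(roi_size = 11, max_rois = 20),
  render_method = "splat"), quiet = TRUE)

res$stats
#> <expan_stats> n=8 ROIs
#>   f(ExPAN)   = 1.561 +/- 1.031
#>   f(NoExPAN) = 0.057 +/- 0.089
#>   Cohen's d = 2.056, t = 4.112, p = 0.00106 (Student)
```

Eight 11 × 11-pixel ROIs on the vesicle membrane pass all gates in both
stacks.  With the off-switch pulse the fitted narrowing factor averages
1.56; without it the same regions fit an essentially un-narrowed cos²
(f ≈ 0.06).  The effect size (d ≈ 2) and p-value quantify the angle
narrowing the pulse scheme produces.  `res$phase_map` holds the
per-pixel orientation maps, and `phase_color_render()` turns them into
the usual hue- or two-colour-coded images.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/frexpan.R simulate --geometry circle --tag double \
    --mode frexpan --frames 700 --frames-per-period 100 --leads 100 \
    --seed 7 --out stack.tif
Rscript inst/cli/frexpan.R demodulate --in stack.tif --cut 100 --out maps.tif
```

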