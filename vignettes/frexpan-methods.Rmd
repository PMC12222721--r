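---
title: "Models and methods behind frexpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind frexpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frexpan)
```

# The measurement this package models

In fluorescence polarization microscopy (FPM) the linear excitation
polarization is rotated continuously while a camera records frames.  A
fluorophore whose transition dipole moment (TDM) lies at axis angle
$\bar\varphi$ absorbs in proportion to $\cos^2(\alpha-\bar\varphi)$, where
$\alpha$ is the polarization angle, so a pixel's intensity trace over one
rotation period follows

$$I(\alpha) = y_0 + A\cos^2(\alpha - x),$$

with offset $y_0$, modulation amplitude $A$ and phase $x$ — the phase is a
direct readout of label orientation.  Because $\cos^2$ is $\pi$-periodic,
every orientation and phase in this package is an *axis* on $[0,\pi)$ and
all phase arithmetic is modulo $\pi$; one modulation period corresponds to
$\pi$ of polarization rotation, spread over `frames_per_period` camera
frames ($\alpha_k = \pi k/N$).

Membrane-anchored fluorescent proteins wobble about their anchor faster
than the camera frame time.  We summarise that wobble by an order
parameter $c\in[0,1]$ that scales the modulation depth:

$$E = B_0\left[\tfrac{1-c}{2} + c\cos^2(\alpha-\bar\varphi)\right].$$

A rigidly double-tagged protein (farnesyl + palmitoyl anchor) keeps
$c$ near 1 (default 0.95); a single-tagged protein rotates nearly freely
($c = 0.2$ by default).  We deliberately do not simulate the wobble
mechanistically (e.g. by per-frame von-Mises draws): the fluctuations
average out within a frame, so only their time-averaged second moment —
exactly $c$ — is observable.  A consequence the tests exploit: two
simulations that differ only in $c$ have FFT amplitude maps in the exact
ratio of their order parameters.

## Excitation polarization angle narrowing (ExPAN)

With reversibly switchable fluorescent proteins (rsFPs), a second beam
polarized perpendicular to the excitation switches off fluorophores whose
TDM is not parallel to the excitation.  The narrowed response is

$$I(\alpha) = y_0 + A\,\frac{\cos^2(\alpha-x)}{1 + f\,\sin^2(\alpha-x)},$$

where the ExPAN factor $f \ge 0$ quantifies the narrowing.  The peak
$y_0+A$ is independent of $f$, and the FWHM of the modulated term is
$\arccos\!\big(f/(2+f)\big)$: $90^\circ$ at $f=0$, $60^\circ$ at $f=2$.

For negatively switching rsFPs the off-switch beam would flood the
camera, so the pulse scheme separates frames: after `n_lead_frames`
frames without the off beam, frames alternate between a *switch* frame
(on-switch pulse at $\alpha$, then a perpendicular off pulse) and a
*readout* frame.  We model the switching photophysics with two
dimensionless doses: the on-switch pulse leaves a fluorophore on with
probability $1-e^{-a\cos^2\delta}$ and the perpendicular off pulse lets
it survive with probability $e^{-b\sin^2\delta}$ ($\delta$ the angle
between TDM and $\alpha$).  The paper gives no rate equations, so this
exponential-survival form is our modelling choice; $f$ is treated purely
as a fitted descriptor of the resulting narrowed trace, never derived
from $(a,b)$.  Fitted $f$ increases strictly with the off dose $b$
(0.11, 1.3, 4.4, 19.0 at $b = 0, 1, 3, 10$ with $a=6$, $c=0.95$,
15 angles), which is what the dose-response acceptance check asserts.

# The synthetic-data generator

No raw data are deposited for this kind of experiment, so the simulator
is a first-class, tested component.  It emulates:

* **Geometry** — contours in nm: circles (vesicles), segments and
  crossing filaments, double membranes at sub-PSF gaps, a spinehead, a
  vesicle field, and a `cell` scene (a large plasma-membrane circle with
  vesicles inside).  Tangent angles are defined along arc length; for a
  circle the tangent at polar angle $\theta$ is $\theta+\pi/2$.
* **Dipole fields** — Poisson-distributed fluorophore counts
  (`density` per µm of contour), uniform arc positions, a fixed
  `anchor_offset` between tangent and mean TDM (default $\pi/2$, dipole
  perpendicular to the membrane), brightness `B0` (default 200 expected
  photons per readout at perfect alignment) and 1-D lateral diffusion
  along the contour.  The diffusion default `D_lat = 135` nm²/ms is
  calibrated so the RMS displacement in 30 ms is 90 nm
  ($\langle x^2\rangle = 2Dt$), the reported mobility of a
  single-membrane-tagged GFP.
* **Camera** — expected photons are placed through a pixel-integrated
  Gaussian PSF (default $\sigma = 0.21\,\lambda/\mathrm{NA} \approx
  79$ nm for 525 nm emission at NA 1.4; pixel size 45 nm, matching
  11 × 11-pixel ROIs spanning 495 nm), then Poisson-sampled, multiplied
  by gain, and given Gaussian read noise (2 counts) and a baseline
  offset (100 counts).  The paper describes the EMCCD but no noise
  equation; this Poisson + Gaussian model is the standard sCMOS/EMCCD
  abstraction.  A fast rendering path (`"splat"`) deposits photons
  bilinearly and convolves once with the PSF; it differs from the exact
  per-emitter integral only by a sub-pixel blur and is used for the
  large statistical scenes.
* **Frame scheduling** — `simulate_stack()` renders lead, switch and
  readout frames per the plan; switch frames carry the bright
  perpendicular-driven fluorescence with a configurable
  `switch_brightness` (the paper only calls it "intense", so the
  magnitude is an exposed scalar, default 3).  All randomness derives
  from one integer seed via a documented per-frame stream split, so a
  (field, plan, detector) triple reproduces a stack bit for bit.

What the generator does **not** emulate — photobleaching fatigue,
3-D dipole orientation, defocus PSFs, drift, flat-field error, timing
jitter — bounds what passing tests show about real data: they validate
the analysis chain against its own forward model, not against every
nuisance of a live-cell acquisition.

# The processing chain

`mean_normalize()` divides each pixel's trace by its temporal mean (the
"stack mean normalization" background correction; traces become
dimensionless around 1, zero-mean pixels are zeroed and flagged).
`demux_frexpan()` drops the leads and keeps readout frames; the readout
sub-stack advances two acquisition angle steps per frame, so
`frames_per_period` halves — 700 frames with 100 leads yield exactly
300 readout frames, and 30 acquisition frames per period yield 15.
`periodic_average()` folds all complete periods (trailing partial
periods are dropped, matching the paper's trimming to whole multiples).

`fft_demodulate()` reads the fundamental DFT bin per pixel: for
$I_k = y_0 + A\cos^2(\pi k/N - x)$,
$C_1 = \sum_k I_k e^{-2\pi i k/N} = \frac{AN}{4}e^{-2ix}$, so
$A = 4|C_1|/N$ and $x = (-\arg C_1/2) \bmod \pi$ — exact on noiseless
traces because a squared cosine has energy only in the DC and
fundamental bins (this needs $N \ge 4$).  If the first frame was not
acquired at $\alpha=0$ the recovered phase is shifted by the stored
first-frame angle; demultiplexed stacks carry wrapped acquisition
angles, which the fitting layer re-sorts modulo $\pi$.  Zero-amplitude
pixels get phase 0 plus a mask, so NaNs never reach the colour renders
(hue = phase/$\pi$ on HSV with value ∝ amplitude, or two-colour
red/green about a phase threshold).

# ROI statistics

`pick_rois()` reproduces the automated selection: a grid of touching
`roi_size` × `roi_size` tiles walked from the image centre outwards
(Chebyshev rings, row-major within a ring), each candidate gated by
(1) mean brightness above the 80th percentile of a reference intensity
image, (2) overlap with an Otsu-threshold + small-object-removal
foreground mask (our lightweight stand-in for a full cell segmenter),
and (3) an $R^2$ gate on the narrowed-model fit of the tile's mean
trace.  The brightness/segmentation gates use the *raw* temporal mean
image: after per-pixel mean normalization the average image is flat by
construction, so an intensity gate on the normalized data would be
meaningless.  Gate defaults ($R^2 > 0.7$ for the ExPAN stack, $> 0.4$
for the weaker NoExPAN modulation, 80th-percentile brightness) are
stated choices — the source workflow mentions the thresholds but not
their values.

`compare_expan()` fits $f$ per ROI in both stacks, excludes an ROI from
both groups if either fit fails its gate, and reports Cohen's $d$ with
pooled SD and a two-sample independent $t$-test (Student's by default,
matching the wording "two-sample independent"; Welch is a switch).  The
NoExPAN reference can be simulated either as the paper acquires it
(same pulse scheme with the off beam shuttered, i.e. $b=0$ — the
default) or as plain FPM.

Model fitting (`fit_modulation()`) is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with $y_0, A, f \ge 0$, started from the
trace's second-harmonic regression (the DFT initialisation for evenly
spaced angles) with $f_0 = 1$; two additional starts (phase $+\pi/2$,
small $f$) make the phase identifiable modulo $\pi$ and guarantee the
eq2-nests-eq1 property within optimizer tolerance.  Non-convergent fits
return $R^2 = -\infty$ so quality gates exclude them.

# Deconvolution

Three paths operate on periodic-averaged stacks.

**Richardson–Lucy** — the standard multiplicative update per frame,
started from the data, with reflective boundary padding (flux
conservation for interior sources is boundary-sensitive; reflective
padding keeps it below 0.1 %).

**SPEED-style space × phase deconvolution** — the forward model mixes a
non-negative density over $P$ orientation channels with
$\cos^2(\alpha_k - x_p)$ weights and blurs with the PSF.  We minimise

$$\tfrac12\lVert \mathcal A\rho - d\rVert^2 + \lambda_1\lVert\rho\rVert_1
  + \tfrac{\lambda_2}{2}\lVert D_p \rho\rVert^2,\quad \rho \ge 0,$$

with $D_p$ the circular second difference along the phase axis, by
accelerated projected proximal gradient (FISTA) with a non-negative
soft-threshold step.  The published weights $\lambda_1 = 0.20$,
$\lambda_2 = 5.00$ and 500 iterations are the defaults.  Two numerical
choices matter and were made deliberately.  First, the exact functional
of the original SPEED publication is not restated in the source we
model, so this penalized least-squares form is our interpretation of
"penalized, iterative, non-negative".  Second, we tried the
multiplicative one-step-late (RL-type) update first; at
$\lambda_2 = 5$ its denominator $\mathcal A^T\mathbf 1 + \lambda_1 +
\lambda_2 D^TD\rho$ turns negative wherever the phase profile is
strongly curved, and any clamp either stalls or speckles the
reconstruction — the proximal-gradient solver has no such failure mode.
Input data are rescaled to unit mean internally (and the density scaled
back) so the $\lambda$ weights act identically at any intensity scale.
With $\lambda_1=\lambda_2=0$ the solver reduces to non-negative least
squares on the joint operator.  For scoring filament separation we
define the mask of a phase slice (channels within $\pm\pi/12$ of a
target orientation) as pixels above 10 % of the slice maximum, compared
to a 1-pixel-radius band around the true contour by
intersection-over-union.

**ALPA** — each pixel gets three parameters in
$I(t) = I_0 + A\cos t - B\sin t + \sqrt{A^2+B^2}$; the
$\sqrt{A^2+B^2}$ term pins the trace minimum at $I_0 \ge 0$.  We
interpret $t$ as the modulation phase variable, $t = 2\alpha$: the
model has a single-harmonic cosine while the physical signal modulates
at $2\alpha$, so one polarization period maps to one cosine cycle; a
plain trace $y_0 + A_1\cos^2(\alpha - x)$ corresponds to
$A = (A_1/2)\cos 2x$, $B = -(A_1/2)\sin 2x$ (hence the ALPA amplitude
map is half the FFT amplitude map, and the phase map
$\mathrm{atan2}(-B, A)/2$ matches it exactly).  Starting values come
from the per-pixel fundamental DFT bin, with negative provisional
offsets clamped to zero; the PSF-blurred least-squares functional over
all pixels is minimised with bound-constrained L-BFGS-B (the bound
$I_0 \ge 0$ realises the offset clamp as a projection), default 2400
iterations.  The $A/\sqrt{A^2+B^2}$ gradient is regularised at
$A=B=0$.  Note the offset semantics: because of the amplitude term,
$I_0$ is the trace *minimum*, not the temporal mean minus anything —
whether that equals "background" depends on the sample.

All three paths are deterministic; small cross-platform numerical
differences (FFT round-off, BLAS order) are expected and the tests use
tolerances, not bit-exactness.

# Problem sizes and runtime choices

The statistical experiments in the test-suite and acceptance script use
sizes chosen to keep a single-core run comfortable while preserving the
studied conditions: the ROI-statistics experiment uses a 256-pixel
(11.5 µm) cell scene, 700 frames at 30 frames/period with 100 leads
(300 readout frames, 20 periods of 15), density 100 fluorophores/µm —
yielding 150 accepted ROIs (the reference condition requires at least
99); the no-false-narrowing check uses 100 repeats of a paired
64-pixel, 190-frame vesicle acquisition; SPEED runs its published 500
iterations on a 64-pixel crossing-filament scene.  The cell scene's
geometry (one 4.8-µm membrane circle plus 26 vesicles of 300–480 nm)
was designed so that many tiles are simultaneously bright and
phase-coherent — large-radius arcs are locally straight — which is what
lets a fixed 80th-percentile brightness gate accept ≥ 99 tiles, as in
the cell images the method was demonstrated on.

# Known limitations

* 2-D orientations only; out-of-plane dipole tilt reduces real
  modulation in ways the order parameter absorbs but does not resolve.
* The switching model is a two-dose survival curve, not a kinetic
  scheme; absolute $f$ values are therefore descriptive, and only their
  ordering and statistics are meaningful across conditions.
* The SPEED functional is an interpretation (see above); reconstruction
  details near the crossing of two structures depend on it.
* `compare_expan()` assumes the two stacks are co-registered, as they
  are when acquired back-to-back; no registration is attempted.
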