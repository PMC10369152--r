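---
title: "Quantifying dopamine synthesis capacity from dynamic FDOPA PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dopamine synthesis capacity from dynamic FDOPA PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdopapet)
```

## The measurement problem

After a bolus injection of 6-[¹⁸F]fluoro-L-dopa (FDOPA), striatal neurons
take up the tracer and trap it as [¹⁸F]fluorodopamine; the trapping rate is
a proxy of presynaptic dopamine synthesis capacity. A typical acquisition is
a 90–95 minute dynamic scan without blood sampling, reconstructed into
frames of increasing duration (the default schedule here: 8×15 s, 3×60 s,
5×120 s, 16×300 s — 32 frames over 95 minutes). Between injection and the
last frame the subject's head moves, the count statistics vary by an order
of magnitude across frames, and the quantity of interest is a rate constant
of order 0.01 min⁻¹ that must be stable across scanners, sessions and
analysts. This package implements the full chain from raw 4D volume to
regional and voxelwise estimates, and — because the interesting failure
modes only reveal themselves under known ground truth — a compartmental
phantom generator that emulates the acquisition end to end.

## Kinetic model and graphical analysis

Tissue is modelled as an irreversible two-tissue compartment system driven
by metabolite-free plasma activity $C_p(t)$:

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)\,C_1, \qquad
  \frac{dC_2}{dt} = k_3 C_1,$$

with total tissue signal $C_T = C_1 + C_2$. $K_1$ (mL/g/min) is
blood–brain clearance, $k_2$ (min⁻¹) efflux, and $k_3$ (min⁻¹) the
decarboxylation (trapping) rate; the plasma-input net uptake is
$K_i = K_1 k_3/(k_2+k_3)$. A reference region without trapping
($k_3 = 0$; the cerebellum) substitutes for arterial sampling: the
Gjedde–Patlak plot of $y = C_T/C_\mathrm{ref}$ against the normalized time
$x = \int_0^t C_\mathrm{ref}\,d\tau / C_\mathrm{ref}(t)$ becomes linear
once the free compartments equilibrate, and its slope is the
reference-normalized influx constant `Ki^cer`. Across subjects the striatal
`Ki^cer` is about 0.0137 ± 0.0015 min⁻¹, so per-scan errors must be held
to a few percent.

Numerical choices, all exercised by the test-suite oracles:

* Integrals are trapezoidal on frame mid-times with an implicit (0, 0)
  sample at injection (activity is zero when the bolus is injected).
* The fit uses ordinary least squares on points with mid-time ≥ t\* and
  t\* fixed at 20 minutes, inclusive. Negative slopes are retained; the
  lowest-uptake cortical regions legitimately straddle zero.
* Points where the reference is at or below 10⁻⁶ of its maximum are
  dropped and counted, and fewer than three usable late points is an error
  rather than a guess.
* The voxelwise fit shares the abscissa across voxels, reducing the map to
  closed-form moment expressions; voxels with no signal give `NA`.
* SUVr averages activity over 60–75 minutes with frame-window overlap
  weights; under the default schedule three 300-s frames tile the window
  exactly.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes a desk-scale digital phantom: a 32×32×24 grid of
4 mm voxels holding a bilateral striatum (two ellipsoidal lobes under one
label), a cerebellar reference and a large occipital-like background shell,
each with its own kinetic parameters; a Feng-type plasma input; per-frame
Gaussian noise; and optional per-frame rigid motion.

Generator defaults, chosen once as a realistic operating point:

* **Plasma input.** Canonical Feng bolus coefficients with the peak placed
  at 1 min by a time shift, which preserves the physiological washout
  rates; amplitude scaled to a 25 kBq/mL peak. (Time-*scaling* the curve
  instead slows the late washout and visibly distorts the Patlak geometry.)
* **Striatum.** $K_1 = 0.05$, $k_2 = 0.04$, $k_3$ solved so that
  `Ki^cer` is exactly 0.0137 min⁻¹. The small $k_2$ follows the FDOPA
  literature and gives a free-compartment distribution volume close to the
  cerebellar one, hence a realistic Patlak intercept (≈0.9) and an SUVr
  (≈2.0) inside the reported population envelope (1.71–3.11).
* **Cerebellum.** $K_1 = k_2 = 0.06$, $k_3 = 0$. With $K_1/k_2 = 1$ the
  reference-normalized slope equals the plasma-input $K_i$, which keeps the
  ground truth interpretable.
* **Background.** $K_1 = 0.054$, $k_2 = 0.06$, tuned to
  `Ki^cer` = 0.0005 min⁻¹ (occipital-like). Matching its efflux to the
  reference cancels equilibration transients, so its Patlak slope sits
  within 10⁻⁴ of the target — important because the near-zero regions are
  where slope biases are easiest to see.
* **Noise.** Per-frame Gaussian with sd
  $\sigma_0\sqrt{\bar A_f/\Delta t_f}$: shorter, hotter frames are noisier,
  a stand-in for reconstruction noise. The default $\sigma_0 = 0.35$
  corresponds to clinical ~2 mm-grid noise volume-averaged onto the
  phantom's 4 mm voxels (per-voxel sd scales with the inverse square root
  of voxel volume, $1/\sqrt{8} \approx 0.35$). The true noise law of any
  given reconstruction differs; all tolerances in the tests are defined
  under this law.
* **Motion** is applied analytically: each moved frame is rasterized at its
  transformed pose with anti-aliased (supersampled) partial-volume edges.
  A moved head produces a *sharp* image; resampling an already-gridded
  frame would bake interpolation blur into the data and measurably bias
  any downstream registration experiment. `inject_motion()` retains plain
  trilinear resampling for transforming existing images.

The phantom does **not** model scanner point-spread, attenuation, scatter,
randoms, metabolite kinetics (the COMT and acid-metabolite pathways are
suppressed pharmacologically in the emulated protocol), or anatomical
realism beyond ellipsoids. Passing tests therefore demonstrate the
correctness and stability of the *analysis chain* under controlled
conditions, not clinical performance on real reconstructions.

## Motion correction and QC

Frames are realigned rigidly (6 DOF) to the frame whose mid-time is nearest
15 minutes — late enough for stable tracer distribution, early enough for
good counts. Three numerical points dominate the design at PET voxel sizes:

1. **Jittered sampling.** Trilinear interpolation is a small pose-dependent
   blur. If the cost compared interpolated moving samples with
   never-interpolated reference voxels, grid-aligned poses would look
   spuriously sharp and attract the optimizer (an effect worth ~1 mm /
   1–2° at 4 mm voxels). All costs therefore sample both images at a fixed
   set of sub-voxel jittered points, making the interpolation blur
   statistically identical on both sides at every pose.
2. **Contrast immunity.** Regional contrast evolves across frames (striatum
   rises, reference falls), which displaces the optimum of any
   single-reference intensity cost even without noise. A detector first
   fits each frame against the two-image basis spanned by the reference
   and an early-transit frame — the tracer's temporal contrast space is
   essentially two-dimensional — and accepts the pose if it is negligible.
   A frame is never registered against a basis containing itself.
3. **Precision under noise.** When real motion is detected, the pose is
   re-estimated by Levenberg–Marquardt on the residual vector with the
   intensity scale fixed at the starting pose, seeded by a coarse
   Nelder–Mead pass on an 8 mm-smoothed half-resolution grid, run from
   both the coarse seed and zero, keeping the better fit and preferring
   the smaller motion on near-ties.

On default-noise phantoms this recovers injected perturbations on frames of
≥60 s duration with median errors around 0.1 mm and 0.4°. The 15-s
early-transit frames have per-voxel SNR below one; no intensity-based
estimator can register them reliably at this scale, and recovery
experiments draw their perturbations from the longer frames. Pre-arrival
frames (no signal) keep identity transforms and are listed in the QC
output.

Framewise displacement combines the parameter steps as
$\mathrm{fd} = \lVert\Delta t\rVert + r\,\lVert\Delta\theta\rVert$ with
$r = 50$ mm (head-radius convention); the source never states how
translations and rotations are combined, so the radius is exposed in the
configuration. Spikes are steps strictly above 5 mm; one spike flags the
scan; the scan-level gate fails at a maximum displacement of 8 mm. Spike
counting uses consecutive-frame differences by default; the
frame-to-reference alternative is available via
`framewise_displacement(mode = "to_reference")`.

## TV denoising

Voxelwise maps are preceded by per-frame Chambolle total-variation
denoising (dual projection, step 1/(2·ndim), forward-difference gradients,
energy-based stopping at a relative tolerance of 2×10⁻⁴ or 200
iterations). The weight semantics minimize
$\lVert u - f\rVert^2/(2w) + TV(u)$, so larger weights smooth more. The
default weight is 0.02× the volume's robust maximum: strong enough to cut
voxel noise, weak enough that the mean Ki over a small high-uptake
structure moves by under 2% — at 0.1× the robust maximum the striatal
blob of the desk-scale phantom erodes and its mean parametric value drops
by ~8%, which is why that more aggressive default was rejected. The
iteration preserves the volume mean exactly and can only reduce total
variation; both properties are asserted in the tests.

## Reliability statistics

Two-way mixed-model, single-measure ICC is reported in its consistency
form ICC(3,1) by default — invariant to per-session additive shifts, which
suits between-pipeline comparisons — with the absolute-agreement form
ICC(2,1) available via `type = "agreement"`; the source terminology
("2-way mixed model", SPSS wording) does not distinguish the two, so the
choice is explicit here. %VAR is the mean over subjects of
$100\,|t - r| / \bar{x}_{tr}$ with the within-pair mean as denominator
(configurable to a session-1 denominator). Bland–Altman limits are
bias ± 1.96 sd of the paired differences. F-distribution confidence
intervals for the ICC are provided (`conf_level =`) but have no external
check. The two-session phantom experiment in the acceptance suite runs six
subjects per noise level with between-subject `Ki^cer` spread drawn from
N(0.0137, 0.0015²); it uses the region-wise quantification path without
motion correction, since the sessions are generated motion-free and
realignment correctness is established by its own experiments.

## Problem sizes and degenerate inputs

Routine tests use 16×16×12 phantoms (6 mm voxels); quantification and
registration experiments use the default 32×32×24 grid. The acceptance
experiments use 8–20 seeded phantoms for motion recovery, 500 replicates
for the ICC sampling distribution, and 36 phantom builds for the
reliability-versus-noise curve. Degenerate inputs fail loudly rather than
silently: overlapping phantom regions, schedules with overlapping frames,
double decay-correction, empty regions, all-dropped Patlak points,
zero-variance ICC tables and reference regions without activity all raise
errors with explicit messages; all-zero voxels inside a fitting mask
produce `NA` map entries.

## Known limitations

* Atlas construction and nonlinear template registration are out of scope;
  label volumes must already live on the image grid.
* The noise model is Gaussian and spatially white; reconstruction noise in
  real scanners is correlated and non-stationary.
* Rotation recovery on very noisy short frames is statistically limited;
  QC numbers for 15-s frames reflect a noise floor, not head motion.
* The plasma input is a parametric bolus; infusion protocols would need a
  different input model.
* Voxelwise fits are unweighted OLS by default, matching the region-wise
  estimator; `weight_frames = TRUE` switches to frame-duration weights,
  which is a no-op under the default schedule because all post-t\* frames
  share one duration.
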