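# fdopapet

Automated quantification of dynamic 6-[¹⁸F]fluoro-L-dopa (FDOPA) brain PET.

Striatal FDOPA trapping reflects presynaptic dopamine synthesis capacity, a
neuroimaging biomarker studied in psychosis, Parkinson's disease and
neuro-oncology. Quantifying it from a 90–95 min dynamic scan requires a chain
of processing steps — frame-to-frame head-motion correction with quality
control, regional time-activity-curve (TAC) extraction, graphical kinetic
analysis against a reference region, denoising for voxel-level parametric
maps, and test–retest reliability statistics when pipelines or sessions are
compared. `fdopapet` implements that chain as a tested R library with a thin
command-line front end, together with a compartmental digital phantom
generator so every stage can be validated against known ground truth without
access to clinical archives.

## The model

The tracer is described by an irreversible two-tissue compartment model:
plasma FDOPA enters tissue with clearance `K1` (mL/g/min), washes out at
`k2` (1/min), and is trapped (decarboxylated to [¹⁸F]fluorodopamine) at `k3`
(1/min), giving a net uptake rate `Ki = K1·k3/(k2+k3)`. Because the
acquisitions are blood-free, quantification uses the Gjedde–Patlak plot with
a cerebellar reference region (negligible trapping): with
`x(t) = ∫₀ᵗ C_ref dτ / C_ref(t)` and `y(t) = C_T(t)/C_ref(t)`, the plot is
linear beyond an equilibrium time `t* = 20` min and its slope is `Ki^cer`
(1/min), the reference-normalized net influx constant. A late-window
(60–75 min) standardized uptake value ratio (SUVr) is computed alongside.
Motion QC counts between-frame displacements above 5 mm ("spikes") and fails
scans whose maximum displacement reaches 8 mm. Test–retest agreement is
summarized by the two-way mixed single-measure ICC, within-subject %VAR,
Bland–Altman limits of agreement, Pearson r and mean absolute percent
difference.

## Worked example

```r
library(fdopapet)

# a 95-min bolus FDOPA phantom: bilateral striatum (Ki^cer = 0.0137/min),
# cerebellar reference, occipital-like background, realistic frame noise
ph  <- build_phantom(phantom_spec(seed = 42))

fit <- patlak_region(ph$image, ph$labels, "whole_striatum")
fit
#> Patlak fit [whole_striatum]: Ki = 0.01392 1/min, intercept = 0.8709,
#>   R^2 = 0.9997 (15 points, t* = 20 min)

suvr(ph$image, ph$labels, "whole_striatum")
#> SUVr [whole_striatum / cerebellum, 60-75 min]: 1.987
```

The fitted slope, 0.0139 1/min, is the phantom's striatal dopamine synthesis
proxy and sits within 2% of the generative ground truth (0.0137 1/min); the
SUVr of 1.98 lies in the population range reported for striatal FDOPA. The
full per-scan pipeline — decay correction, realignment to the 15-min
reference frame, motion QC, TV-denoised voxelwise Ki maps, and a JSON
summary report — runs via:

```r
rep <- run_pipeline(pipeline_config(image = ph$image, labels = ph$labels,
                                    scan_id = "phantom42", out_dir = "out/"))
rep
#> Scan report 'phantom42' [ok]
#>   QC: max FD 4.60 mm, 0 spike(s), pass
#>   Kinetics:
#>          region   ki_per_min intercept        r2      suvr
#>  whole_striatum 0.0138114628 0.8760929 0.9996168 1.9832539
#>      background 0.0004302874 0.8964645 0.9173346 0.9268705
```

A command-line front end (`inst/cli/fdopa`) exposes the same functionality
as `fdopa simulate | qc | quantify | reliability | report` with exit codes
0/1/2 (ok / QC fail / error).

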