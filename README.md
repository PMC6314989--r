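# datSBR

Count-based quantification of striatal dopamine-transporter binding for
[123I]FP-CIT (DaT) SPECT.

Visual reading of DaT scans is observer-dependent, so clinical practice leans
on the **specific binding ratio (SBR)** — the striatal count concentration due
to specific tracer binding, expressed relative to the nonspecific background:

```
SBR = (C_st − C_bg) / C_bg
```

with `C_st` the striatal and `C_bg` the occipital (reference) count
concentration per mL. `datSBR` implements a count-based estimator of this
quantity for people who work on SPECT semi-quantification — physicists,
methods researchers, and anyone who needs a transparent, scriptable
alternative to black-box vendor tools.

## The method

1. **Voxel budget.** The average striatal volume is taken as a fixed standard,
   `V_s = 11.2 mL`. On a grid with voxel volume `v` mm³ this is
   `n = round(11200 / v)` voxels — **1052** voxels per side at 2.2 mm
   isotropic spacing.
2. **Search region.** A trapezoid VOI (`VOI_t`) drawn on the central striatal
   slice and extruded over the slices covering the striata only *locates* the
   striata; it never enters the SBR arithmetic. Any mask file works in its
   place.
3. **Fixed-volume extraction.** `VOI_t` is split at its midline; the peak
   voxel of the right half seeds a greedy best-first growth that adds the
   highest-valued neighbouring voxel (26-connectivity by default) until
   exactly `n` voxels are included — a connected high-intensity cluster of
   standard striatal volume (`VOI_st`). The left side follows. All ties break
   lexicographically, so two operators running the tool get bit-identical
   masks.
4. **SBR.** `C_st` = total `VOI_st` count / 11.2 mL; `C_bg` = mean occipital
   count per voxel / voxel volume. The mask's *size* is fixed by design, so
   low residual uptake cannot shrink the denominator.

A reference **Tossici-Bolt** estimator is included for comparison: with a
large fixed-geometry VOI (44 mm axial thickness) enclosing the striatum,

```
SBR_Bolt = (Q_voi / C_r − V_voi) / V_s = R · (C_voi / C_r − 1),  R = V_voi / V_s
```

The package also ships a digital phantom generator (ellipsoidal striata of
11.2 mL per side over a uniform background, Gaussian PSF, Poisson noise,
known ground-truth SBR) and evaluation statistics (CV, variance-ratio test,
ROC/AUC with Youden cutoff, method agreement), so the entire pipeline is
testable without clinical data.

## Worked example

```r
library(datSBR)
report <- runPipeline(system.file("extdata", "demo-config.yaml", package = "datSBR"))
```

The demo config simulates a moderately abnormal study (true SBR 2.0 both
sides, 10 mm FWHM PSF, Poisson noise) and quantifies it with both methods.
The report it printed:

```
n_voxels: 1052
count_based:   right 1.2907, left 1.2728, bilateral_mean 1.2817, dominant 1.2728
tossici_bolt:  right 1.9020, left 1.8976   (V_voi = 127.8 mL, R = 11.4)
true_sbr: 2.0
```

Reading the numbers: the extracted 1052-voxel masks sit on the striata, but
at 10 mm resolution counts spill out of the small fixed VOI, so the
count-based SBR (≈1.28) underestimates the true 2.0 — a stable, monotone
compression. The Tossici-Bolt estimate (≈1.90) recovers nearly all counts by
construction, at the price of an amplification constant `R ≈ 11`: every
fluctuation of the reference concentration is multiplied by it, which is why
its values scatter several-fold more across noise realizations (compare
`cv_count_based` with `cv_tossici_bolt` below). On noiseless, unblurred
phantoms both methods agree with the ground truth to better than 0.05%.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/datSBR.R pipeline --config inst/extdata/demo-config.yaml
Rscript inst/cli/datSBR.R phantom  --spec spec.yaml --out-dir out/
Rscript inst/cli/datSBR.R extract  --image vol.nii.gz --voi-t voit.nii.gz \
    --out-right r.nii.gz --out-left l.nii.gz --report extract.json
Rscript inst/cli/datSBR.R sbr      --image vol.nii.gz --method both \
    --voi-st-right r.nii.gz --voi-st-left l.nii.gz --voi-bg bg.nii.gz --out sbr.json
Rscript inst/cli/datSBR.R evaluate --cohort cohort.csv --out report.json
```

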