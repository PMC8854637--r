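# clotvh — virtual histology of blood clots from propagation-based X-ray microCT

Clots retrieved from stroke patients by mechanical thrombectomy are
conventionally classified from stained 2D histology slices, which cannot
capture volumetric composition. Propagation-based X-ray microtomography
(PB microCT) images the intact clot in 3D without contrast agent: after
phase retrieval and reconstruction, red-blood-cell (RBC) masses appear
hyperintense, fibrin/platelet matrix at moderate gray values, pores at air
level, and sub-resolution hydroxyapatite nano-calcifications as a "glassy
opacity" in between. `clotvh` implements this analysis chain as a tested R
package, together with a ground-truthed synthetic clot generator so the
whole pipeline is verifiable without any proprietary scan:

* **Simulation** — clot-in-Kapton-tube phantom with ordered composition
  classes (P < L F/Pl < C F/Pl < Ca < RBC), parallel-beam projection,
  propagation edge enhancement (inverse Paganin filter, amplitude
  `1 + alpha f^2`) and Poisson noise.
* **Reconstruction** — Paganin-style single-material retrieval
  `-log(F^-1[F(I) H(f)])` with `H(f) = 1/(1 + alpha f^2)`, parametrised by
  its −6 dB point as a fraction of Nyquist (default 0.16, giving
  `alpha = (10^0.3 − 1)/(0.08)^2 ≈ 155.5`), then slice-wise filtered back
  projection.
* **Calibration** — Hounsfield-like two-point map sending the mean of air
  to 500 and of the polystyrene tube to 1500.
* **Virtual histology** — automatic sample masking, reproducible
  multi-class thresholds (histogram-valley default, multi-Otsu option),
  per-class volume fractions and calibrated mean intensities (MI), porosity
  sizing with the ~2-voxel resolvability floor.
* **RBC detection** — multiscale 3D Frangi filter (scales 1–3 voxels,
  bright polarity, lower-10 % noise suppression) yielding blob centroids,
  sizes and 4–7 µm single-cell candidates.
* **XRD** — Williamson–Hall fit `beta cos(theta) = K lambda / D +
  4 eps sin(theta)` with Si instrumental-broadening correction, giving the
  crystallite size `D` and microstrain `eps` with uncertainties.

## Worked example

```r
library(clotvh)

run <- run_pipeline(pipeline_config(seed = 7))
print(run)
#> <vh_run> virtual-histology pipeline result
#>   calibration: a = 1.225e+06, b = 492.3
#>   thresholds: 732.36, 1169.1, 1497, 1754
#>   composition:
#>  class                     name n_voxels   vol_pct mean_intensity
#>      P                 porosity    55098 10.337200       531.7901
#>    LFP   loose fibrin/platelets   206879 38.813562       961.3123
#>    CFP compact fibrin/platelets   208768 39.167966      1362.3252
#>     CA            calcification    18033  3.383258      1623.2621
#>    RBC          red blood cells    44229  8.298015      1881.5694
```

The phantom was composed as P 10, LFP 38, CFP 40, CA 2, RBC 10 % of the
clot volume; the pipeline — projection, propagation + noise, retrieval,
FBP, automatic air/tube calibration, masking, valley thresholds —
recovers each fraction to within ~2 percentage points, and the calibrated
MI column reproduces the expected ordering (air-level porosity just above
500, loose < compact fibrin, calcification between compact fibrin and the
hyperintense RBC masses). `autoplot(run$composition)` draws the
composition bar chart and `plot_slice(run$calibrated, labels = run$labels)`
a labelled slice.

Crystallite sizing from an XRD peak list:

```r
peaks <- simulate_wh_peaks(c(20, 30, 40, 55, 70), size_nm = 17, strain = 8e-4)
fit <- williamson_hall_fit(peaks)   # Cu-K-alpha, K = 0.9
print(fit)
#> <wh_fit> Williamson-Hall size/strain analysis
#>   crystallite size D = 17.00 +/- 0.00 nm (K = 0.9, lambda = 1.5406 A)
#>   microstrain = 8.000e-04 +/- 5.022e-19
#>   5 peaks, residual SE 6.391e-19
tidy(fit); glance(fit); autoplot(fit)
```

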