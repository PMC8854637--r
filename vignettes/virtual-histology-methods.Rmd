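---
title: "Methods: synthetic virtual histology of blood clots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic virtual histology of blood clots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`clotvh` implements a complete, testable pipeline for non-contrast 3D
"virtual histology" of retrieved blood clots imaged by propagation-based
X-ray microtomography (PB microCT). Because no patient scan is publicly
deposited for this kind of study, the package ships a ground-truthed
synthetic data generator so every downstream stage — phase retrieval,
reconstruction, calibration, segmentation, quantification, blob detection —
can be validated end to end on a desk machine.

The pipeline stages are:

1. **Phantom** (`generate_clot_phantom()`): a ~2 mm clot inside a Kapton
   (polystyrene) tube in air, with five ordered composition classes:
   porosity (P), loose fibrin/platelets (LFP), compact fibrin/platelets
   (CFP), nano-calcification "glassy opacity" (CA) and red-blood-cell
   masses (RBC).
2. **Acquisition** (`forward_project()`, `apply_propagation_and_noise()`):
   parallel-beam line integrals, propagation edge enhancement, Poisson
   noise.
3. **Retrieval + reconstruction** (`paganin_retrieve()`,
   `fbp_reconstruct()`): single-material low-pass phase retrieval
   parametrised by its −6 dB point, then filtered back projection.
4. **Calibration** (`fit_two_point()`, `apply_calibration()`):
   Hounsfield-like two-point scaling, air → 500 and polystyrene → 1500.
5. **Virtual histology** (`extract_sample_mask()`, `auto_thresholds()`,
   `segment_composition()`, `quantify_composition()`,
   `quantify_porosity()`): ordered multi-class thresholding and the
   per-class volume-fraction / mean-intensity report.
6. **RBC detection** (`multiscale_detect()`): 3D Frangi filtering at scales
   1–3 voxels with bright polarity.
7. **XRD** (`correct_instrumental()`, `williamson_hall_fit()`):
   Williamson–Hall crystallite-size/microstrain analysis of peak lists.

# The phase-retrieval model

Single-material phase retrieval is lumped into one isotropic low-pass
filter applied to each normalized-intensity projection:

$$H(f) = \frac{1}{1 + \alpha f^2}, \qquad
  R(p) = -\ln\,\mathcal{F}^{-1}\!\left[\mathcal{F}[I]\,H(f)\right]$$

with $f$ the radial spatial frequency in cycles/pixel. Rather than exposing
the physical $\delta/\mu$ ratio and propagation distance, $\alpha$ is
derived from the frequency at which the amplitude response has fallen by
6 dB, expressed as a fraction $c$ of the Nyquist frequency
($f_N = 0.5$ cycles/pixel):

$$\alpha = \frac{10^{6/20} - 1}{(c\, f_N)^2}.$$

The default $c = 0.16$ gives $\alpha \approx 155.5$. The −6 dB point is read
as an *amplitude* ratio $10^{-6/20} \approx 0.501$ (the filter-response
convention), not a power ratio; `measure_cutoff_fraction()` verifies the
crossing numerically through the public retrieval path.

Propagation is modelled as the exact frequency-domain inverse of the
retrieval filter (gain $1 + \alpha f^2$) acting on $I = e^{-p}$, rather
than as full Fresnel wave optics. This keeps the forward/inverse pair
self-consistent and testable: with matched $\alpha$ and noise off, the
round trip reproduces the projections to a relative RMS well below 1 %.
Retrieval is applied per projection before reconstruction (the standard
order; the alternative post-reconstruction filtering is not implemented).
Projections are padded to the next power of two with edge replication
before filtering to curb wrap-around.

# Reconstruction

Slice-wise parallel-beam filtered back projection: the ramp filter is built
in the spatial domain (the band-limited kernel with $h(0)=1/4$,
$h(n) = -1/(\pi n)^2$ for odd $n$), which avoids the DC bias of sampling
$|f|$ directly, then apodized and applied via FFT with zero padding to
twice the next power of two; back projection uses linear interpolation and
the $\pi/N_\theta$ quadrature weight. A uniform-disk oracle reconstructs
the interior mean to well within 2 %.

The default apodization window is Shepp–Logan (sinc). Hann at Nyquist is
provided as an option, but at desk-scale grids — where a whole clot spans
only ~100 voxels and internal structures tens of voxels — the wider Hann
point spread measurably inflates partial-volume mixing between composition
classes, which is the dominant error source in fraction recovery. Cone-beam
geometry is deliberately out of scope: at desk scale only the effective
voxel size matters, so magnification is folded into `voxel_size` and the
parallel-beam transform stays exactly oracle-checkable.

# The synthetic clot phantom

The generator's defaults describe the study conditions:

* geometry: 128³ voxels at 16 µm (a 2.05 mm field), clot radius 800 µm,
  tube annulus 900–1000 µm; projections at
  $\max(180, \lceil\sqrt{2}\,n\rceil)$ angles over 180°;
* class mix: P 10, LFP 38, CFP 40, CA 2, RBC 10 % of the clot volume;
* raw attenuations (µm⁻¹): P 5·10⁻⁶, LFP 3.8·10⁻⁴, CFP 7.2·10⁻⁴,
  CA 9.2·10⁻⁴, RBC 1.14·10⁻³, tube 8·10⁻⁴. These are free parameters chosen
  once so that after the air → 500 / PS → 1500 calibration the class means
  land near the values reported for real reconstructed clots
  (P ≈ 507, LFP ≈ 975, CFP ≈ 1404, RBC ≈ 1925, with the calcification level
  between compact fibrin and RBC), preserving the strict ordering
  P < LFP < CFP < CA < RBC. Raw (pre-calibration) contrast is not
  quantitatively constrained by any published figure, so only the ordering
  and the calibrated anchors are meaningful.
* photon budget: 10⁵ mean counts per projection pixel. The desk simulation
  uses ~181 angles, roughly 8.5× fewer than a long laboratory scan; the
  per-projection dose is raised correspondingly so the reconstruction noise
  budget is comparable to a multi-hour acquisition (dose equivalence). At
  this level the interior reconstruction noise is ~15 calibrated units —
  small against class separations of 250–450 units, as it must be for a
  histogram that a human could threshold manually.

**Morphology.** Pores and calcifications are random ellipsoidal blobs; RBC
content is placed as large smooth ellipsoidal aggregates (hundreds of µm)
wrapped in a thin low-intensity "porous boundary" shell labelled LFP, plus
small clusters for the non-aggregated remainder; the remaining matrix is
split loose/compact along a smooth Gaussian random field. Three rules
matter, all consequences of simulating at 16 µm voxels rather than the
instrument's ~1.2 µm:

1. *Feature sizes are desk-scaled.* The reconstruction point spread is
   ~1.5–2 voxels (~30 µm). Real scans resolve pores, calcified patches and
   aggregate boundaries over hundreds of voxels; a faithful desk-scale
   phantom must therefore keep each feature several PSF widths across
   (pores 100–300 µm, calcifications 150–280 µm, aggregates 600–800 µm,
   loose/compact texture correlation 450 µm). Features at or below the PSF
   would consist almost entirely of partial-volume voxels, a regime the
   real data are not in.
2. *Sub-resolution cells are represented as the smallest resolvable
   clusters.* A 4–7 µm single RBC is far below a 16 µm voxel; its volume is
   carried by ~4-voxel-radius clusters of tightly packed cells. (At fine
   voxel sizes, `generate_rbc_phantom()` rasterises individual oblate
   cells.)
3. *Pores are seeded inside loose regions* — porosity belongs to the loose,
   porous fibrin matrix — which keeps pore boundary transitions inside the
   P/LFP intensity bands instead of spraying partial-volume mass across all
   classes.

Realized class fractions track the requested mix to within ±1 percentage
point (blob radii are capped to the remaining class budget, so a single
large blob cannot overshoot). The generator is fully deterministic given
`seed`.

What the phantom does **not** emulate: Fresnel fringes beyond the lumped
inverse-filter model, beam hardening, detector point spread and scintillator
blur, ring artifacts, cone-beam distortion, fibrillary anisotropy, and the
biconcave fine shape of single cells at coarse voxels. Passing tests
therefore demonstrate the correctness and internal consistency of the
algorithms under controlled conditions — not performance on artifacts the
real instrument may add.

# Masking and calibration references

The sample mask is a coarse air/material threshold (the first threshold of
a 3-class Otsu over the whole volume — a plain 2-class Otsu tends to split
inside the multimodal material range instead of at the air level), followed
by 26-connected labelling, morphological opening (blur tails can bridge the
thin air gap between clot and tube), selection of the clot component,
closing, and hole filling so internal pores belong to the sample. The clot
and tube components are told apart by ring geometry — the tube's voxels sit
much farther from the central axis — rather than by size, which is
ambiguous at this geometry.

Calibration references are located automatically: the tube annulus (eroded
by one voxel against partial-volume rims) and in-FOV air — voxels inside the
inscribed reconstruction cylinder, below the air threshold and at least two
voxels from any material. Grid corners are deliberately *not* used: they lie
outside the inscribed circle where parallel-beam FBP is quantitatively
biased. Manual mask overrides are accepted everywhere. The two-point map
$g = a\,v + b$ with $a = 1000/(m_{PS} - m_{air})$ is exact by construction
on its reference means; calibrated volumes are stored as unclamped floats
since hyperintense classes exceed the 1500 anchor.

# Segmentation thresholds

The published workflow thresholds gray levels manually. The automatic
surrogate must be reproducible, and we provide two:

* `method = "valley"` (default): smooth the within-mask histogram, rank its
  modes by topological persistence, keep the `k` strongest, and cut at the
  midpoint between adjacent mode positions. Two deliberate choices: (a)
  persistence (peak height above the highest saddle toward a higher peak)
  selects small-but-real modes such as a 2 % calcification class while
  ignoring noise wiggles; (b) the midpoint-of-modes cut, rather than the
  raw density minimum, because with symmetric blur the midpoint between two
  class means is the volume-unbiased boundary — partial-volume tails drag
  the density minimum toward the smaller mode and systematically starve it.
* `method = "otsu"`: exact multi-level Otsu via dynamic programming over a
  256-bin histogram (verified against exhaustive search). Between-class
  variance is *not* a valley criterion: with strongly unbalanced weights it
  can prefer splitting a heavy mode over isolating a small one — on
  five-class clot histograms it reproducibly absorbs the 2 % calcification
  class — which is why it is not the default.

User-supplied thresholds always take precedence. Ties go to the upper class
(half-open intervals $[t_i, t_{i+1})$), voxel indexing is 0-based with axis
order (z, y, x) in the stored stacks.

# Porosity and blob detection

Pores are 26-connected components of class P; each is sized by its
equivalent-sphere diameter $(6n/\pi)^{1/3}$ voxels. The retained-porosity
figure excludes pores below 2 voxel units — the technique's practical floor
— while still listing them for diagnostics.

RBC detection computes the Frangi measure from the $\sigma^2$-normalized
Gaussian Hessian at scales {1, 2, 3} voxels, bright polarity
($V = 0$ where $\lambda_2 > 0$ or $\lambda_3 > 0$), with
$R_A = |\lambda_2|/|\lambda_3|$, $R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$
and structureness $S$; the per-voxel response is the maximum over scales.
Defaults: $\alpha_F = \beta_F = 0.5$; $c$ set per scale to half the maximum
Frobenius Hessian norm; the $R_B$ gate accepts both tubular and spherical
bright structures (the pointwise maximum of the classical tube gate and its
blob complement). The "lower 10 %" noise rule is implemented as zeroing
responses below 10 % of the maximum response (the percentile reading is
available via `noise_mode = "percentile"`); surviving voxels are grouped by
26-connectivity, specks below 2 µm equivalent diameter are discarded, and
blobs with diameters in 4–7 µm are flagged as single-cell candidates.

Because both $c$ and the 10 %-of-max threshold adapt to the volume at hand,
a control (specificity) run must reuse the calibration of the detection
run: pass the returned `c_used` and `threshold_used` to
`multiscale_detect()` on the control volume. Re-deriving them on a
structure-free volume would simply re-normalise its own noise. Watershed
splitting of touching cells is out of scope; the seeded test phantom places
cells far enough apart that their response regions stay separate.

# Williamson–Hall analysis

Peak widths (FWHM, degrees) are corrected for instrumental broadening
against a polycrystalline-Si reference by Gaussian quadrature subtraction
$\beta = \sqrt{\beta_{obs}^2 - \beta_{instr}^2}$ (Lorentzian linear
subtraction available), with the instrumental width linearly interpolated in
$2\theta$. The fit is ordinary least squares through

$$\beta\cos\theta = \frac{K\lambda}{D} + 4\varepsilon\sin\theta$$

with $\beta$ in radians; $D = K\lambda/\text{intercept}$ (nm),
$\varepsilon$ the slope, uncertainties from the regression covariance.
Defaults $K = 0.9$ and the FWHM convention are common practice and are
documented as package choices, not as the instrument vendor's. A
non-positive intercept flags the size as undefined (strain-only
broadening). Noiseless synthetic peak lists invert exactly; with 2 %
multiplicative width noise on 6 peaks the size is recovered within ±15 %
over 100 replicates. Reproducing any particular published crystallite size
would require the raw diffractogram, which is not deposited; parameter
recovery on synthetic peaks is the validation surface.

# Problem sizes and determinism

The package's own validation uses: 128³ phantoms with ~181 angles for the
ten-seed fraction-recovery study (about a minute per run on one CPU), 96³
phantoms for unit tests, 96³ fine-voxel (1.23 µm) phantoms with 50 seeded
cells for detection tests, and 100-replicate Monte-Carlo for the
Williamson–Hall noise study. Every stochastic step takes an explicit seed;
identical configurations reproduce reports bit-for-bit, and the pipeline
writes a provenance record (config hash, seed, calibration coefficients,
thresholds, package version) next to its outputs.

Recovery accuracy is assessed as the per-class mean absolute error across
the ten seeds (≤ 2 percentage points), with the calibrated mean-intensity
ordering required on every run. Individual seed-and-class errors can graze
~2.2 points for RBC: hard thresholds at desk-scale resolution lose the
outer partial-volume shell of the brightest class to the classes below —
a structural effect of the resolution ratio, not of the estimator.

# Known limitations

* The lumped propagation model cannot produce true Fresnel fringes; it is
  the exact inverse of the retrieval filter by construction.
* Fraction recovery is biased by partial volume wherever features approach
  the reconstruction PSF; the end classes of the intensity ordering (P,
  RBC) lose their outer shells with no compensating gain.
* The valley thresholder assumes the in-mask histogram has at least `k`
  persistent modes; degenerate histograms fall back to multi-Otsu, and
  constant volumes are rejected.
* TIFF float storage is defined on [0, 1]; volumes are affine-mapped with
  the range recorded in the JSON sidecar, so float grids round-trip at
  single precision (integer grids exactly).
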