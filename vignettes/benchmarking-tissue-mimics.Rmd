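---
title: "Benchmarking light-sheet imaging of tissue mimics: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking light-sheet imaging of tissue mimics: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbench)
```

`tmbench` quantifies how well a 3D fluorescence microscope — typically a
light-sheet instrument — images tissue mimics (TMs): spherical multicellular
aggregates of 100–500 µm such as tumour spheroids, cardiospheres and
neurospheres. This vignette is the package's methods reference: the forward
model behind the synthetic phantom, the exact definition and numerical
conventions of every metric, the parameters that matter, and the limits of
what the synthetic validation shows.

## Geometry and units

One convention is enforced everywhere and is not configurable per call:

* voxel arrays are indexed `(z, y, x)`, with a leading `t` for time series;
* the illumination sheet enters the sample at the **+x** face and propagates
  toward −x;
* the detection objective is on the **+z** side;
* space is in micrometres, time in seconds, mean free paths in millimetres;
* the physical centre of voxel `i` along an axis with pitch `d` is
  `(i − 0.5)·d`.

Fixing the axes removes the most common source of sign errors in
penetration-depth work: every CoM component, quadrant label and attenuation
direction below means the same thing in every module. On the equatorial z–x
section, quadrant Q1 is (+z, +x) — near the objective *and* near the sheet
entry; Q2 = (−z, +x); Q3 = (−z, −x); Q4 = (+z, −x). Q1/Q4 therefore probe
the detection path and Q2/Q3 the illumination path.

## The phantom's forward model

`render_phantom()` builds a synthetic TM in six ordered steps:

1. **Objects.** Spherical nuclei (hard spheres, rejection-sampled, diameter
   ~ N(mean, sd)) and point-like beads are placed uniformly inside the TM
   sphere. Rejection sampling is capped at 10,000 consecutive failures;
   densities near close packing are out of scope. Beads keep a minimum
   pairwise separation (default 3 µm), emulating dilute bead loading and
   making the bead count usable ground truth for detector tests.
2. **Ballistic attenuation.** Each object's emission is scaled by
   `exp(−d_ill/MFP_ill)·exp(−d_det/MFP_det)`, where `d_ill` is the chord
   length from the +x surface of the TM sphere to the object and `d_det` the
   chord from the object to the +z surface. This is a purely ballistic
   model: scattered light is not propagated, it is summarized by the
   constant background level. An optional diffuse in-sample signal
   (`tm_base_fraction`, default 0.15 of the peak) paints the whole TM sphere
   with per-voxel attenuated intensity — the cytoplasmic
   stain/autofluorescence that makes real stained spheroids a connected
   bright body; without it a sparse-nuclei phantom is not segmentable as one
   object, and with it attenuation profiles can be read off the tissue
   itself. `attenuation_volume()` exposes the per-voxel factors.
3. **PSF.** Separable anisotropic Gaussian blur with sigmas `psf_sigma`
   (µm). When `bessel_sidelobe_fraction = f > 0` the axial kernel becomes
   the mixture `(1−f)·G(σz) + f·G(3σz)`: a fraction of axial energy in a 3×
   wider lobe, the surrogate for Bessel-beam side lobes. A true J0² profile
   is deliberately not modelled — the consequences being tested (axial FWHM
   inflation, contrast loss from out-of-plane light) are reproduced by the
   mixture while keeping the kernel separable, and `f` is a single
   interpretable knob. All kernels are normalized to sum 1, so noise-free
   rendering conserves integrated intensity away from borders.
4. **Background.** A constant offset (default 10 counts) over the whole
   stack.
5. **Noise.** `poisson` (default), `gaussian(σ)`, `mixed`,
   `multiplicative(frac)`, or `none`. Multiplicative noise
   (`I·(1 + N(0, frac))`) is the model used for the bleaching series, where
   the dominant fluctuation at high signal is gain-like.
6. **Bleaching (4D only).** Frame n is the noise-free signal times
   `exp(−t_n/τ)` plus the (non-bleaching) background, with fresh noise per
   frame.

All randomness comes from one seed (`rng_seed`); two renders with the same
configuration are bit-identical.

### Default parameters

The defaults describe a 400 µm spheroid imaged on a digitally scanned
light-sheet system: voxel pitch (1, 0.65, 0.65) µm; PSF sigmas
(2.3, 0.6, 0.6) µm, i.e. ~5.4 µm axial and ~1.4 µm lateral FWHM (a 5–6 µm
optical section); mean free path 0.2 mm on both optical paths (visible
excitation — 0.19 mm at 532 nm and 0.40 mm at 1040 nm bracket the
visible-to-NIR range in fixed spheroids); nuclei 12 ± 2 µm; peak signal
10,000 counts over a background of 10 (≈30 dB, the level at which matched
multi-modality acquisitions are practical); bleaching decay time 27.6 s
sampled every 10 s (the faster, two-photon-regime decay; the one-photon
reference value is 63.6 s). Tests and examples override the *grid* (voxel
size, TM diameter) to keep desk runtimes in seconds; they do not change the
physics defaults.

## Metrics

### SNR

`snr_db(stack, signal_region, background_region)` =
`10·log10(q0.999(signal) / mean(background))`. The 99.9th percentile stands
in for the maximum to resist hot pixels. The decibel convention treats
intensity as power-like (10·log10); since conventions vary across
instruments, `db_factor = 20` is available. Regions must be non-empty and
disjoint; a non-positive background is an error, not a warning, because the
ratio is meaningless. Default regions in the orchestrator: inside the TM
mask vs. outside its dilation.

### NCI

`nci(x, mask)` is the mean absolute intensity difference over all
6-connected voxel pairs with both ends in the region, divided by the
region's dynamic range (max − min). It is dimensionless, lies in [0, 1] for
face-connected data, equals 0 for a constant region (by convention) and 1
for a perfect checkerboard, and is exactly invariant under affine intensity
maps `I → aI + b`, `a > 0`. Each unordered pair is counted once. The
normalization by dynamic range is a package convention (the field has no
single standard); it is isolated in this one function so it can be swapped.

On phantoms, NCI behaves as a local-contrast measure should: it strictly
decreases under wider PSF blur, and — evaluated **inside the sample** — it
decreases monotonically as the Bessel side-lobe fraction grows, in the
regime where nuclei (~8 µm) are comparable to the side-lobe axial extent.
Two caveats discovered during validation are worth recording. First,
whole-stack NCI (background included) can *increase* with side-lobe haze,
because the dynamic range (the denominator) falls faster than the mean
difference (the numerator); contrast comparisons should be made on the
sample region. Second, the same self-normalization is why the CIV's local
contrast map is *not* normalized per window (next section).

### CIV, CoM and quadrants

`segment_tm()` finds the TM: Gaussian smoothing (default σ 4 µm), Otsu
threshold **on log1p intensities**, largest 6-connected component, hole
filling, morphological closing. The log matters: ballistic attenuation
spreads in-sample intensities over two decades, and a raw-histogram Otsu
splits dim tissue from bright tissue rather than background from tissue. On
phantoms the recovered centre is within a voxel, the equivalent radius
within ~3%, and the Jaccard sphericity ≈ 0.99.

`equatorial_section()` takes the z–x plane at the TM centre's y index
(averaged over a 3-slice slab). `civ()` then:

1. computes a local contrast map: windowed (default 10 µm square) mean
   |adjacent difference| of in-mask 4-connected pairs, divided by the
   **global** in-mask dynamic range. A per-window range was tried and
   rejected: in noise-dominated windows the numerator and the denominator
   both scale with the noise amplitude, so deeply attenuated regions score
   as high as structured ones and the CIV covers the whole TM regardless of
   attenuation — exactly what the metric must detect. With global
   normalization the map inherits affine invariance through the relative
   threshold below;
2. thresholds it at `contrast_threshold` (default 0.3) × the 95th
   percentile of the in-mask map — relative, so the CIV is comparable
   across exposure levels;
3. reports the CIV mask, its unweighted centroid relative to the TM centre
   (signed (Δz, Δx)), the per-quadrant coverage fractions (CIV area in the
   quadrant ÷ TM section area in the quadrant) and the combined Q1∪Q2
   coverage.

The quadrant fractions satisfy exact accounting
(Σ fraction·quadrant-area = CIV area), the CoM flips sign under section
mirroring, sits at the origin (±2 voxels) for an unattenuated phantom, and
moves monotonically toward +x as the illumination MFP shrinks. On the 4 µm
desk grid used in the tests, a both-paths-0.2 mm phantom yields a Q1∪Q2
coverage of ~0.17; the same analysis at 2 µm sampling of a smaller TM gives
~0.36. Published values for real matched acquisitions fall in 0.3–0.6; the
coverage depends on sampling, window size and TM size, so the tests log
this number rather than assert a band.

### 3D PSF

`detect_beads()`: 26-connected local maxima above an intensity percentile
(default 99.5), greedy non-maximum suppression at `min_separation` in
physical distance, sub-voxel refinement by centre of mass in a 3-voxel
radius, and exclusion of candidates within `border_margin` (default
`min_separation`) of a stack face. `measure_fwhm()` fits a 1D Gaussian to
the background-subtracted profile along each axis (background = median of
the profile ends; window half-width default 8 µm) and converts
`FWHM = 2√(2 ln 2)·σ`. A record is accepted only if R² ≥ 0.8 on *every*
axis (threshold exposed); a window that would leave the stack rejects the
record rather than erroring. `fit_psf_population()` fits a lognormal to
each axis' accepted FWHMs by maximum likelihood — resolution distributions
are positive and right-skewed, and the lognormal is the canonical choice —
alongside the sample mean ± sd; at least 5 accepted records are required,
otherwise the population is flagged unavailable. The raw records are always
returned so multi-modal behaviour (e.g. partially filtered side lobes,
which produce a bimodal axial FWHM distribution) can be assessed
downstream; the package intentionally fits a single lognormal, not a
mixture.

Validation: a noise-free rendered bead returns `2.3548·σ` per axis within
2%; on a 50-bead Poisson-noise phantom the population median per axis is
within 10% of truth; lognormal parameters from 200 known draws are
recovered to ±0.05 in both log-parameters; FWHM is invariant under
intensity scaling; a side-lobe fraction of 0.5 measurably inflates the
axial FWHM at identical σz.

### Photobleaching

`normalize_bleach()` computes per-frame ROI means `I_n`, the pooled
background `I_BKG`, and `PB_n = (I_n − I_BKG)/(I_1 − I_BKG)` (so `PB_1 ≡ 1`
exactly). A first frame at or below background is an error — there is no
signal to normalize. `fit_decay()` fits `PB(t) = A·exp(−t/τ)` (optionally
+ offset) with `minpack.lm::nlsLM`, initialized from a log-linear
regression; for the offset model the initialization first subtracts a
floor, since otherwise a plateau drives the initial τ toward infinity and
the Jacobian of (A, offset) is singular. A series with no measurable decay
returns the sentinel `τ = Inf` with note `"no_bleach"`; a non-converging
fit is returned flagged with diagnostics, never silently replaced. PB
normalization makes τ exactly scale-invariant in the raw intensities.
Mono-exponential is the default because continuous-illumination bleaching
of a single fluorophore is well described by one decay time; the offset
variant covers a non-bleaching pool.

### Mean free path

`extract_attenuation_profile()` reads intensity versus depth along one
optical path, restricted to a central column (default radius = TM
radius / 4) around the beam axis through the TM centre — the geometry of a
beam-through-the-equator measurement. The restriction is essential, not
cosmetic: near the TM rim the chord from the entry surface shrinks to zero,
so plane-wide robust quantiles mix path lengths and flatten the decay (on a
0.2 mm phantom the plane-wide estimate came out at 0.7 mm with R² 0.14; the
column estimate is 0.19 mm with R² 0.91). Per plane the 90th percentile of
in-column intensity is taken and the out-of-mask plane mean is subtracted
as background. `fit_mfp()` regresses `ln(I)` on depth with weights ∝ I
(countering log-space heteroscedasticity); `MFP = −1/slope`, in mm. A
non-negative slope is flagged as "no measurable attenuation" rather than
reported as a value.

One physical caveat: in a fluorescence image both paths attenuate, so an
illumination-axis profile from a both-paths-attenuated stack is biased by
the detection term (which varies as `√(R² − x²)` along the column). MFP
estimation phantoms therefore attenuate one path at a time, as transmission
measurements do; on such phantoms the estimator recovers 0.19–0.40 mm
within 10%, and the simulated-profile route (`simulate_attenuation_profile`)
recovers them within ~1% at 2% noise.

### Morphometry

`segment_nuclei()` seeds local maxima of the smoothed stack
(σ = seed_radius/2) separated by ≥ seed_radius, then floods the foreground
from the seeds in descending smoothed intensity (a level-set seeded
watershed on the inverted image, 32 bands), so touching nuclei split near
the intensity valley. The foreground mask comes from Otsu **on the raw
intensities**: thresholding the smoothed image would dilate every nucleus by
about one smoothing sigma and inflate volumes roughly two-fold. Volumes are
voxel counts × voxel volume; the equivalent 2D cross-section per nucleus is
`π·(3V/4π)^(2/3)` — derived from the measured volume because that is how a
2D nuclear surface is obtained from a volumetric measurement when no
independent 2D segmentation exists. `cell_density(n, mean2d, roi)` =
`n·mean2d·100/roi` (default ROI 80×80 µm = 6400 µm²), the percentage of ROI
area covered by nuclear cross-sections; values above 100% warn about
overlap but are still returned.

## Orchestration

`run_benchmark()` maps stack roles to metrics (beads → PSF population + SNR
+ NCI; nuclear → SNR, NCI, TM mask, CIV/CoM, optional morphometry;
timeseries → τ), records per-metric failures without aborting, and writes a
long-format CSV plus JSON summary stamped with an MD5 hash of the
configuration. Re-running the same configuration reproduces the CSV
bit-exactly. `compare_groups()` is a thin Welch t-test wrapper for
between-modality comparisons. The `benchkit.R` script in `inst/cli/` exposes
the same operations from a shell.

## Problem sizes used in the validation suite

The test suite renders phantoms at desk scale: 400 µm TMs on a 4 µm grid
(~10⁶ voxels) for segmentation/penetration, 30–40 µm bead fields at
(0.5, 0.3, 0.3) µm for PSF work, 60 µm TMs at 4 µm for bleach series, and
100 µm TMs at 2 µm for morphometry. The recovery scripts use 20 replicate
seeds per quantity. These sizes were chosen so the full suite runs in a few
minutes on one CPU; all recovery tolerances (τ and MFP within 5–10%, FWHM
within 2–10%) were set from the estimator properties, not from the grid.

## What the synthetic validation does and does not show

The phantom demonstrates that every estimator recovers its generating
parameter under the stated model: exponential ballistic attenuation,
separable Gaussian (+ wide-lobe) PSF, Poisson/Gaussian camera noise,
mono-exponential bleaching, spherical nuclei. Real acquisitions violate all
of these to some degree — stripe and shadow artifacts from side
illumination, depth-dependent PSF aberration, diffuse (not constant)
scattered background, non-spherical touching nuclei, fluorophore
photophysics beyond one decay constant. None of those effects are
simulated, so passing this suite says the *analysis* is correct, not that a
given instrument will reach any particular metric value. Published
per-modality values measured on real stacks (e.g. NCI ≈ 0.009–0.025, SNR
17–30+ dB) are plausibility references for the same code paths, not
reproduction targets: the phantoms produce numbers of the same order, and
the parameter-recovery results (27.6 s / 63.6 s decay times; 0.19 / 0.40 mm
MFPs, two-fold apart) are exact-model recoveries by construction.

## Known limitations

* The side-lobe surrogate is a two-Gaussian mixture; it reproduces FWHMz
  inflation and in-sample contrast loss but not Bessel ring structure.
* The CIV is computed on the 2D equatorial section (as the penetration
  figures in the field are); a full-3D extension would be a straightforward
  loop over sections but is not implemented.
* `segment_nuclei` assumes a nuclear-label channel; on a channel with
  strong diffuse cytoplasmic signal the raw Otsu mask includes that signal
  and volumes inflate.
* The MFP estimator assumes single-exponential ballistic decay; it does not
  separate scattering from absorption or estimate anisotropy.
* Hard-sphere packing by rejection sampling fails (by design, with an
  error) near close packing.
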