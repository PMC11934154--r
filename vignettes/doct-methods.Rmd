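---
title: "Mapping spheroid viability with dynamic OCT power spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spheroid viability with dynamic OCT power spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doct)
```

## The measurement

Dynamic optical coherence tomography (D-OCT) repeatedly images one
cross-section of a living sample and treats the temporal fluctuation of each
pixel's backscattered intensity as an endogenous contrast agent for cellular
activity. In 3D cell spheroids — the use case this package targets — the
outer, nutrient-supplied shell contains highly viable cells whose motion
produces strong, narrowband, low-frequency intensity fluctuations, while the
nutrient-starved core degenerates into low-activity or necrotic tissue whose
residual fluctuation is weaker and shifted to higher frequencies. Mapping a
frequency summary of each pixel's fluctuation spectrum therefore maps
site-dependent viability without stains, at depths fluorescence microscopy
cannot reach.

The pipeline operates on a time series of B-scan intensity images
$I(t, z, x)$, canonically 512 frames at 56 frames/s with 2.53 µm isotropic
pixels. Each frame is first normalized by its own spatial mean to suppress
frame-to-frame illumination instability. For every pixel the one-sided power
spectral density $P$ of the intensity time series is estimated by Welch's
averaged-periodogram method, and three summaries are computed:

* the **mean frequency** (spectral centroid)
  $f_{\mathrm{mean}} = \sum_i \frac{P_i}{\sum_j P_j} f_i$,
* the **bandwidth** $f_{\mathrm{std}}$, the PSD-weighted standard deviation
  of frequency, and
* the **amplitude** $\mathrm{STD}$, the per-pixel temporal standard
  deviation of intensity (population convention, $1/N$).

Viable tissue concentrates at $f_{\mathrm{mean}} \approx 8\text{–}9.5$ Hz,
necrotic tissue at $\approx 11.5\text{–}13$ Hz; the midpoint of the two band
limits, 10.5 Hz, splits the spheroid mask into viable and necrotic classes,
and the fraction of spheroid pixels classified viable is the cross-section's
viability. A sampling rate above 40 frames/s is required for sub-20 Hz cell
motion (Shannon); at 56 frames/s the detectable band is 0–28 Hz.

## Estimator choices

**Welch parameters.** Segment length 256, 50 % overlap, Hann taper,
one-sided density scaling. These are the estimator's defaults, chosen as the
standard compromise: a 512-frame acquisition yields three averaged segments
(PSD methods want well over 100 frames for stable estimates) at a frequency
resolution of $56/256 \approx 0.22$ Hz across 0–28 Hz. All four knobs are
user-settable through `welch_params()`. With `segment_length` equal to the
series length and a rectangular taper the estimator reduces exactly to the
plain periodogram, which the test suite exploits as an oracle equivalence.

**DC handling.** A raw intensity series has an overwhelming zero-frequency
component (its mean level); folded into the centroid it would drag every
$f_{\mathrm{mean}}$ toward 0 and destroy the viability contrast. The
estimator therefore subtracts each pixel's temporal mean before
segmentation (`detrend = TRUE`, the default), equivalent to zeroing the DC
bin. Frame normalization alone cannot do this — it fixes each frame's
spatial mean, not each pixel's temporal mean.

**Degenerate pixels.** A pixel with zero total fluctuation power (constant
series) has no defined centroid; it is assigned
$f_{\mathrm{mean}} = f_{\mathrm{std}} = 0$. This keeps the maps total, and
such pixels carry zero amplitude so they render black and fall outside any
intensity-based mask. A radicand of the bandwidth that dips below zero by
less than $10^{-9}$ (floating-point rounding) is clamped to zero; anything
larger is treated as a genuine error.

**Smoothing.** The mean-frequency raster — and only it — is smoothed after
the per-pixel computation with a 3×3 Gaussian kernel of σ = 3 px,
replicate-padded at the borders. A σ of 3 inside a 3×3 support is heavily
truncated and nearly uniform; the filter is applied literally in this form
rather than "corrected" to a wider support, because its role is only to
knock down aberrant single-pixel values. Replicate padding avoids edge
darkening; the border convention is otherwise immaterial at σ = 3.

**Chunking.** `compute_dynamics_maps()` accepts a spatial tiling contract
(`n_chunks` of 1, 4 or 9) mirroring how a parallel implementation quarters
the data cube. Per-pixel reductions are performed serially in a fixed
order, so any tiling produces bitwise-identical maps — asserted in the
tests — making the tiling safe to parallelize without changing results.

## Segmentation

The spheroid (total-tissue) mask is the largest connected component of a
thresholded reference image — by default Otsu's threshold on the amplitude
raster, with holes filled; an absolute threshold is available because any
such cut is ultimately empirical. Components are 8-connected. The viable /
necrotic split at 10.5 Hz sends ties to the necrotic side; the threshold
sits strictly between the two observed bands, so real data is unaffected by
the convention.

**Edge-ring artifact.** The refractive-index step between spheroid and
medium produces specular, broadband fluctuation in a thin rim at the
boundary, which the frequency threshold misclassifies as necrotic. The
correction examines each necrotic-labeled connected component: components
that touch the spheroid boundary *and* lie entirely within 5 px (Euclidean
distance transform) of it are relabeled as edge artifact; interior
components — genuine necrosis — are untouched, as are boundary-touching
components thicker than the rim. The published description of this rule is
ambiguous about its exact mask arithmetic; the implemented reading is the
one consistent with its stated purpose (removing a thin interface-reflection
ring whose tissue is in fact highly viable). Reclassified pixels join the
viable mask by default (`reassign = "viable"`), since the rim tissue is
viable; an `exclude` mode drops them from both classes instead, which
lowers the quantitative viability — both behaviours are legitimate
readings, so both are exposed. The operation is idempotent.

## Pseudo-color rendering

The three maps combine into an HSV composite: hue is
$f_{\mathrm{mean}}$ clamped to 8–13 Hz and scaled linearly to 0–0.66 (red →
blue), saturation is the reciprocal bandwidth $1/f_{\mathrm{std}}$, value is
the amplitude. Viable tissue thus renders red-yellow (low frequency, strong
narrowband fluctuation), necrotic tissue blue-green, and broadband noise
desaturates toward black. No published normalization exists for the
saturation and value channels, so the package scales each robustly by its
99th percentile (configurable) with clipping — a fixed scale would be
equally arbitrary and fragile against hot pixels. Degenerate pixels with
$f_{\mathrm{std}} = 0$ get saturation 0 (gray) rather than an infinite
reciprocal.

## The phantom generator

No public D-OCT spheroid recordings exist, so the package ships a synthetic
generator that stands in for the instrument. A layered ellipsoid (outer
shell, optional concentric core, optional 3-px boundary ring) is rasterized
at the acquisition pixel pitch; each layer's pixels receive a static
reflectivity (layer base value × a per-pixel lognormal speckle texture,
σ_log = 0.25) multiplied by a temporal fluctuation process, plus additive
white detector noise:

* viable shell — band-limited tones spanning 8–9.5 Hz, relative amplitude
  0.35 (strong, low-frequency, narrowband);
* necrotic core — tones spanning 11.5–13 Hz, amplitude 0.2 over a 0.6×
  dimmer base (weaker, higher-frequency);
* edge ring — white broadband fluctuation, reproducing the specular
  artifact;
* background — dim static reflectivity plus noise.

The `band_tones` process sums equal-amplitude, random-phase cosines at
every acquisition-grid frequency inside the band, so its spectrum is exactly
band-limited and its expected centroid is computable in closed form
(`expected_fmean()`); an `ar1_plus_white` alternative provides a smoother,
Lorentzian-shaped spectrum when a less idealized signal is wanted. Defaults
mirror the acquisition the package targets: 660×660 px at 2.53 µm, 512
frames at 56 Hz, a 450 µm-diameter spheroid; the core defaults to half the
outer radius, a typical mid-culture state chosen once as a representative
geometry. A fixed seed reproduces a phantom bitwise, and generation leaves
the caller's RNG stream untouched.

What the phantom deliberately does **not** model: coherent speckle
formation and decorrelation, depth attenuation, refraction, or any
biophysical claim about the true motility spectrum of hepatocytes — the
contrast is statistical, matching exactly what the pipeline measures.
Passing recovery tests on phantoms therefore demonstrates that the
estimator chain is correct and self-consistent, not that the biological
bands themselves are right; those come from the observed data the method
was built on.

## Numerical and I/O conventions

Stacks are exchanged as multi-page grayscale TIFF. The available TIFF
writer stores samples on a fixed-point grid of $[0,1]$, so values are
affinely rescaled and quantized to a 24-bit grid (single-precision mantissa
resolution) with the scale recorded in a JSON sidecar; integer data
round-trips bitwise, floating data to within $6\times10^{-8}$ of its range.
Volumetric (4D) acquisitions are a directory of per-y stacks with a
manifest, matching how repeated-B-scan volumes are actually acquired and
keeping memory bounded. The acquisition frame rate is treated as the
authoritative clock everywhere (a 512-frame series at 56 fps spans
512/56 ≈ 9.14 s).

Depth profiles measure depth from the first slice whose spheroid mask is
non-empty, in steps of the y spacing; per-slice class means are omitted
where a class is empty. Replicate depth profiles combine into mean ±
1.96 SE bands.

## Problem sizes

The test suite and the acceptance script run entirely on generated
phantoms, sized for quick, deterministic verification while preserving the
acquisition's sampling physics (56 Hz frame rate, real pixel pitch):
recovery checks use 128×128 px × 256 frames, geometry and artifact checks
64×64 × 128, growth series 96×96 × 128 over five time points, volumetric
checks 7–9 slices of 24–48 px. At these sizes the class-mean
$f_{\mathrm{mean}}$ is recovered within 0.15 Hz of the analytic
expectation, class masks overlap ground truth with Jaccard ≥ 0.99, and
viability is within 0.1 % of the true area fraction — comfortably inside
the 0.3 Hz / 0.9 / 3 % bounds the checks assert.

## Known limitations

* The viability threshold (10.5 Hz) and hue range (8–13 Hz) are properties
  of the observed cell line and instrument; other samples will need
  recalibration.
* Per-frame mean normalization removes common-mode intensity drift only; no
  inter-frame registration is attempted, so bulk sample motion would blur
  spectra.
* Viability is a per-cross-section area ratio, not a whole-volume cell
  count.
* The edge-ring rule assumes the artifact forms thin boundary-hugging
  components; an artifact merging with a boundary-reaching necrotic region
  would not be separated.
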