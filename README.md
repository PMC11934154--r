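# doct — dynamic OCT viability mapping for 3D spheroids

`doct` quantifies site-dependent cell viability inside 3D cell spheroids
(e.g. hepatocyte spheroids) from **dynamic optical coherence tomography**
(D-OCT) time series: repeated B-scans of one cross-section whose per-pixel
intensity fluctuations encode cellular activity. It is written for
tissue-engineering and drug-screening labs that image spheroids with OCT
and want label-free, depth-resolved viability maps, and for method
developers who need a fully synthetic, ground-truthed test bed for
fluctuation-spectroscopy pipelines.

## Method

For a stack $I(t, z, x)$ (canonically 512 frames at 56 frames/s, 2.53 µm
pixels), each frame is normalized by its spatial mean, then every pixel's
one-sided power spectral density $P$ is estimated by Welch's method and
reduced to:

- mean frequency (spectral centroid):
  $f_{\mathrm{mean}} = \sum_{i} \left( P_i \middle/ \sum_j P_j \right) f_i$
- bandwidth: $f_{\mathrm{std}} = \sqrt{\sum_i w_i f_i^2 - \left(\sum_i w_i f_i\right)^2}$, with $w_i = P_i / \sum_j P_j$
- amplitude: $\mathrm{STD} = \sqrt{\tfrac{1}{N}\sum_t (I(t) - \bar I)^2}$ per pixel

Viable tissue fluctuates strongly at low frequency
($f_{\mathrm{mean}} \approx 8\text{–}9.5$ Hz), necrotic tissue weakly at
high frequency ($\approx 11.5\text{–}13$ Hz). Thresholding the
mean-frequency map at 10.5 Hz inside the spheroid mask — after
reclassifying the thin specular edge-ring artifact at the spheroid/medium
boundary — yields viable and necrotic masks, and

$$\text{viability} = \frac{|\text{viable pixels}|}{|\text{spheroid pixels}|}.$$

The maps also combine into an HSV pseudo-color image (hue =
$f_{\mathrm{mean}}$ over 8–13 Hz → 0–0.66, saturation = $1/f_{\mathrm{std}}$,
value = STD): viable tissue renders red-yellow, necrotic tissue blue-green.

Because no public D-OCT spheroid recordings exist, the package includes a
layered-ellipsoid phantom generator with known per-layer temporal spectra,
analytic expected $f_{\mathrm{mean}}$ per layer, and ground-truth labels, so
the whole pipeline is testable end to end without an instrument.

## Worked example

```r
library(doct)

# Synthetic spheroid: 140 µm outer radius, 70 µm necrotic core,
# 256 frames at 56 Hz, 128 x 128 px at 2.53 µm
spec <- phantom_spec(shape = c(128, 128), outer_radii_um = 140,
                     core_radii_um = 70, n_frames = 256,
                     edge_ring = list(enabled = FALSE), seed = 7)
phantom <- generate_phantom(spec)
print(phantom)
#> Synthetic spheroid phantom (128 x 128 px, 256 frames @ 56 Hz, seed 7)
#>   pixels: background 6772, viable 7196, necrotic 2416, edge 0
#>   expected fmean: viable 8.75 Hz, necrotic 12.25 Hz

result <- doct_process(phantom$stack,
                       params = welch_params(segment_length = 256))
print(result)
#> D-OCT dynamics maps (128 x 128 px)
#>   fmean: [8.61, 15.31] Hz (smoothed)
#>   fstd : [0.42, 9.59] Hz
#>   STD  : [0.03054, 1.522]
#> D-OCT segmentation (threshold 10.50 Hz)
#>   spheroid 9604 px | viable 7188 px | necrotic 2416 px | edge 149 px
#>   viability = 0.748

mean_fmean_over_mask(result$maps$fmean, phantom$labels == 1)
#> [1] 8.885502   # viable shell, vs 8.75 Hz analytic expectation
mean_fmean_over_mask(result$maps$fmean, phantom$labels == 2)
#> [1] 12.22468   # necrotic core, vs 12.25 Hz
```

The recovered viability (0.748) matches the phantom's true area fraction
(1 − 2416/9612 = 0.749): the spheroid has a 70 µm core inside a 140 µm
shell, so about a quarter of the central cross-section is necrotic.
`plot(result$maps, mask = result$segmentation$spheroid)` shows the
pseudo-color composite; `write_result(result, "out/")` saves maps, masks,
the rendered image and a summary CSV.

A command-line interface wraps the same functions
(`inst/cli/doct.R`): `doct simulate`, `doct process`, `doct segment`,
`doct render`, `doct quantify`, `doct profile`.

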