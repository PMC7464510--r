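---
title: "Methods: accumulation mapping, functionality classification and concentration estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accumulation mapping, functionality classification and concentration estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermcasa)
```

spermcasa implements three computer-assisted sperm analysis (CASA)
read-outs that share one segmentation stage, plus a synthetic
microscopy generator that provides planted ground truth for all of
them. This vignette explains the models and procedures, the parameters
that matter, the numerical choices at the edges, and what the
synthetic validation does and does not establish.

## Segmentation: the shared particle-analysis stage

Every pipeline starts from the same chain: grayscale conversion
(Rec. 601 luminance, `0.299 R + 0.587 G + 0.114 B`), optional global
histogram equalisation, thresholding, and connected-component
extraction with physical size filtering.

**Thresholding.** The default is Otsu's method, computed by an
exhaustive scan of all 256 candidate levels maximising the
between-class variance of the intensity histogram. A level `t` splits
the histogram into `{v < t}` and `{v >= t}`; the foreground is
`v >= t` for bright-on-dark imagery (fluorescence) and `v < t` for
dark-on-bright negative phase contrast — polarity is an explicit
parameter because both kinds of optics occur in practice. Ties in the
variance objective are broken toward the lowest level, which makes the
chosen level deterministic and, on a well-separated bimodal image,
places it strictly between the modes. A constant image has no valid
split; it yields an empty mask and a warning rather than an error.

**Equalisation is per-pipeline.** Contrast stretching helps
phase-contrast-like imagery but is harmful in two situations this
package deals with: on fluorescence colour fields it distorts hue, and
on sparse dark-background fields it spreads background noise across
the full intensity range until Otsu splits the background rather than
the cells. Equalisation is therefore on by default in the accumulation
and concentration chains and off in the functionality chain, and every
entry point exposes the flag.

**Components and sizes.** Connected components are labelled at
8-connectivity by default (sperm heads are compact blobs; 4 is
available), centroids are arithmetic means of member pixel coordinates
in a 0-based, pixel-centre convention, and components are kept only if
`pixel_count * scale^2` lies within `[min_area_um2, max_area_um2]`.
Filtering in µm² rather than pixels makes parameter files transfer
between magnifications. The defaults (10–80 µm²) bracket a bull sperm
head of about 32 µm²; they are species-dependent settings, not
constants. An oversized aggregate of collided cells is *dropped* by
the upper bound — the documented failure mode of accumulation assays
at very high local density, which is why `roi_timeseries()` reports
per-frame totals that let such drops be noticed.

## Accumulation maps

For one frame with detected centroids, the accumulation signal at
pixel `(x, y)` is the number of centroids within Euclidean distance
`R` of the pixel centre (boundary inclusive). `R` is the one genuinely
scientific tunable: it sets the smoothing bandwidth of the density
estimate and the spatial scale at which accumulation is judged. It can
be given in pixels or µm.

**Boundary correction.** Near the image border a disc of radius `R`
is partly outside the field, which would bias counts low. Each pixel's
count is divided by the fraction of its rasterised disc (offsets with
`dx^2 + dy^2 <= R^2`) lying in-bounds. Using the same rasterisation
for counting and for the fraction makes interior fractions exactly 1,
so correction touches only the border band. The rasterised fraction at
a corner exceeds the continuous quarter-disk value by up to
`(2R + 2) / (pi R^2)` (the disc's axis row and column stay in-bounds);
tests budget exactly that.

**Display scaling.** Corrected values are mapped linearly so the
frame minimum hits 0 and the maximum 255, rounding half-up; a constant
map (the degenerate case with no range) maps to all zeros. Scaling is
per frame by default, matching the single-image definition; a
`global_scale` option normalises a whole video by its global range so
colours are comparable across time. The scaled value indexes a frozen
256-entry Jet look-up table generated from piecewise-linear channel
ramps (`clamp(1.5 - |4t - c|)` with offsets 3/2/1 for R/G/B), so
rendering is bit-exact across platforms.

**Video acceleration.** Two parameters trade resolution for speed
exactly as in the interactive tool this mirrors: a sampling factor `f`
computes full maps every `f` frames and fills intermediate frames by
per-pixel linear interpolation of the two flanking computed maps (the
form of interpolation is a design choice; linear is the simplest
monotone option), and an odd window `W` evaluates counts only at the
centre of each `W x W` block, painting the block with that value. The
last frame is always computed, never extrapolated. With `f = 1`,
`W = 1` the video path is identical to the still path — a tested
invariant.

**ROI time series.** Counts inside a circle of radius `r` around the
attractant source, and inside the concentric `2r` and `3r` circles,
are reported per frame in absolute form and relative to that frame's
total detected particles. The per-frame denominator is deliberate: the
number of cells in the field changes during an assay, and a relative
measure against the current total is the one that stays interpretable.
Frames with zero detections report missing relative values rather
than 0.

## Functionality classification

The triple-stain read-out distinguishes five subpopulations by colour:
a membrane-impermeant DNA dye marks membrane-damaged cells red, a
membrane-permeant DNA dye marks membrane-intact cells blue, and an
esterase substrate marks an intact acrosome green (or the whole head
and tail, in the high-esterase IFI phenotype).

**Hue scale and bands.** Classification works on the HSV hue channel
expressed on a 0–255 scale (the 8-bit convention: 360° map to 256
levels, pure green 120° → 85, pure blue 240° → 170). Band defaults:
red when `H > 200` or `H < 20`, green when `50 < H < 125`, blue when
`130 < H < 185`, all strict; everything else is unclassified. The gaps
between bands are useful, not accidental: blurred transition pixels
between a green cap and a blue body mix to cyan (~127), which falls in
the 125–130 gap and is ignored instead of voting for either class.
Achromatic pixels have no defined hue, and pixels darker than value 30
or less saturated than 30 (0–255 scales) are unclassified to keep
background-adjacent noise out of the ratios.

**Ratios and the decision tree.** For each segmented cell the red,
green and blue ratios divide the band counts by the *total* pixel
count of the cell (unclassified pixels stay in the denominator, so the
ratios are absolute fractions, not renormalised shares). The tree is:

1. `green_ratio >= 0.75` → IFI (whole cell green);
2. otherwise, acrosome intact iff `green_ratio >= 0.10` (a green cap
   covers roughly a quarter to a third of the head);
3. membrane status by majority between the body dyes: damaged iff
   `red_ratio > blue_ratio`, intact iff `blue_ratio > red_ratio`;
4. `red_ratio == blue_ratio` (including both zero) → UNCLASSIFIED —
   there is no usable membrane signal and guessing would bias the
   subpopulation percentages.

The two internal thresholds are configurable; their defaults were
fixed once, from the geometry of the staining patterns (a cap is well
above 10% of head area, a fully green cell well above 75%), and they
must — and do — reproduce the five verbal colour patterns exactly.
Segmentation for this pipeline runs on the value (brightness) channel,
never on equalised data, for the hue-fidelity reason above.

**Summaries.** Per-subtype counts and percentages (summing to 100
within rounding), plus acrosome-intact % = IAIM + IADM and
membrane-intact % = IAIM + DAIM + IFI. IFI counts as membrane-intact
by default on the biochemical argument that retaining the esterase
substrate requires an intact membrane; a flag excludes it for
laboratories that report otherwise.

## Concentration

With the chamber depth known, the imaged field samples a volume
`field_width_um * field_height_um * depth_um`; by default the field
dimensions come from the image size times the µm/pixel scale (that is
the reading under which the scale input is needed at all), and both
can be overridden for grid-based conventions. Then

```
concentration (M cells / mL) = n * dilution_factor * 1e6 / volume_um3
```

since 1 mL = 1e12 µm³. The estimate is exactly linear in the count and
the dilution factor, and halves when the depth doubles — all tested as
invariants. Cells whose centroid is in-bounds are counted, a
deterministic stand-in for manual two-edge counting rules. Per-field
results aggregate to mean ± sample SD across fields.

## The synthetic generator

The generator is the package's validation instrument; its defaults are
the study conditions of the tests and the acceptance script, chosen
once to emulate the assays' optics and then left alone.

* **Fields** (`make_field()`): 512×512 px at 0.5 µm/px, bright
  elliptical heads (9 × 4.5 µm, about 32 µm²) at intensity 200 on a
  background of 20, placed by rejection sampling with no overlaps and
  full in-bounds margins, softened by a σ = 1 px Gaussian so Otsu has
  a stable edge; optional additive Gaussian noise. Placement failure at
  excessive density is an error suggesting a lower density, not a
  silent degradation.
* **Motion videos** (`make_motion_video()`): 200 cells, 150 frames,
  Rayleigh step lengths (scale 4 px ≈ 100 µm/s at 25 fps and 0.5
  µm/px), directions drawn from a circular mixture — with probability
  κ toward the attractant (±0.3 rad wobble), otherwise uniform — and
  boundary reflection. κ = 0 is the control (the source is inert);
  κ = 0.5 the case; κ = 1 drives every cell to the source. The planted
  per-frame positions feed the ROI machinery directly, so the
  accumulation statistic is validated separately from detection.
* **Stained fields** (`make_stained_field()`): 150 cells at 768×768
  px, rendered per subtype with hues strictly inside the bands (red 8,
  green 85, blue 170), a green anterior cap of ~30% of head area for
  IAIM/IADM, a green tail for IFI, per-pixel wrapped-Gaussian hue
  jitter as chromatic noise, and the same σ = 1 px softening.

**What passing these tests shows — and does not.** Synthetic recovery
(exact counts on clean fields, 100% subtype recovery at zero jitter,
≥95% at jitter SD 10, exact concentration round-trips, clean
case/control separation) establishes that the *algorithms* implement
their definitions and are robust to the modelled noise. It does not
establish performance on real micrographs: the generator has no
point-spread function, no phase-contrast halos, no uneven
illumination, no staining variability beyond hue jitter, no
out-of-focus or overlapping cells, and no debris other than what tests
plant deliberately. Real-data thresholds (size bounds, hue bands,
tree cut-offs) remain empirical settings.

## Statistical notes

The agreement utility reports the correlation (Pearson or Spearman)
between two measurement series and the Bland–Altman bias
`mean(x - y)` with 95% limits of agreement; constant series report a
missing correlation rather than failing.

One testing choice deserves its own paragraph. The control arm of the
accumulation assay is "flat" in the sense of having no drift, but the
ROI count of diffusing cells is strongly serially dependent: a naive
per-series rank-correlation trend test assumes independent
observations and false-triggers on roughly half of genuinely unbiased
controls. The flatness check therefore uses the independent replicates
instead: a Wilcoxon signed-rank test on the per-replicate change
(final minus initial relative count) across 10 seeded control runs,
which is a valid rank test of monotone change and cleanly separates
the arms (control p ≈ 1, case p < 0.01 at the study conditions).

## Problem sizes and determinism

All validation runs at desk scale, chosen as conditions of the
synthetic study: 512² px fields with 40–200 cells, 150-frame motion
videos, 768² px stained fields with 150 cells, oracle comparisons on
≤128² px instances with ≤200 particles. Every generator consumes an
explicit integer seed and is bit-reproducible; every pipeline writes
its resolved configuration next to its outputs, so any run can be
reproduced from that file alone.

## Known limitations

* Videos are frame-sequence directories; compressed containers (AVI)
  are not decoded and raise an error pointing at the frame-directory
  route. Analysis is per-frame, so nothing scientific is lost.
* There is no trajectory linking: the accumulation module measures
  collective density, not individual paths, and the concentration
  module assumes immobilised cells.
* Aggregated clusters beyond the size bound are dropped, which
  understates accumulation at very high density — visible as a drop in
  the per-frame total `N` alongside the relative series.
* The hue-band and tree defaults encode one staining kit's empirical
  ranges; other fluorochrome panels need their own bands.
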