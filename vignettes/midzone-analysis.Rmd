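---
title: "Models and methods behind midzoner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind midzoner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midzoner)
```

`midzoner` quantifies the architecture and dynamics of the anaphase
spindle midzone from four kinds of data: traced 3D microtubule networks,
paired SHG/two-photon polarity images, two-channel embryo movies, and
single-molecule track tables. This vignette is the package's account of
the underlying models: what is assumed, which parameters matter, how the
synthetic generators relate to real data, and where the numerical
choices were genuinely open.

## Filament networks and the interaction analysis

Traced microtubules are ordered 3D polylines in nm. Two conventions are
applied before any statistic: tracings shorter than 100 nm are excluded
(`filter_short()`), because tracings below the minimal reliable tracing
length are dominated by detection error; and the bounding volume used for
density defaults to the tight axis-aligned box of all points, because raw
tracing files rarely delimit an analysis volume. When a study delimits a
midzone sub-volume, pass it explicitly — density is only as meaningful as
its denominator.

An **interaction** is a contiguous stretch of a *source* microtubule that
stays within a center-to-center distance `d_max` of a *target*
microtubule for at least `l_min` of arc length. Defaults are
`d_max = 100` nm (the reach of the relevant cross-linkers and motors) and
`l_min = 100` nm (the tracing detection limit). No angle restriction is
applied. The numerical procedure is:

1. resample each filament at a uniform arc step (`resample_step`, default
   20 nm, well below both 100 nm thresholds);
2. compute, for each sample, the exact point-to-segment distance to every
   other filament (closed-form, in C++);
3. take maximal runs of in-threshold samples as candidate interactions,
   refining each run boundary by linear interpolation between the last
   in-threshold and first out-of-threshold samples (the distance along the
   arc is 1-Lipschitz, so the neighbouring sample is always within
   `d_max + resample_step` and its distance is available exactly);
4. discard runs shorter than `l_min`; report length, minimum distance and
   the angle between the end-to-end lines of the two filaments (robust to
   local tracing distortion; 0° = parallel, 180° = antiparallel, with a
   folded [0, 90°] option for orientation-agnostic summaries).

A **single out-of-threshold sample splits a run** — there is no gap
bridging. This is the strict reading of "maintained over a minimum
length"; bridging would silently merge distinct contact sites.

Interactions are **ordered-pair records** (part of source near target),
and the interaction count `n` counts ordered runs. Whether such counts
should be deduplicated across the two directions is genuinely ambiguous,
so a `mode = "symmetric"` option reports one record per unordered pair
(mean of the two directions' total lengths, minimum of their minimum
distances). A true geometric union of runs across directions is not
well-defined — the two runs live on different filaments' arc
parameterisations — which is why the symmetric mode is a summary, not a
merge.

Statistics (`network_stats()`) use the population SD (divisor *N*), and
distance-bin fractions default to upper edges spanning 25–100 nm in 15
steps plus an open overflow bin, mirroring the conventional color scale
for interaction distances.

A uniform 3D grid over segments (`grid_index()`) accelerates both
interaction detection and nearest-neighbour searches. Cells are at least
as large as the query reach, so the 27-neighbourhood of a cell certifies
every segment within the reach: the accelerated results are *identical*
to the brute-force scan, which the tests assert against an independent
1-nm-sampling oracle written in plain R.

One property worth stating precisely: *existence* of an interaction is
symmetric between the two directions only when `l_min = 0` (both reduce
to "minimum pair distance ≤ `d_max`"). With the length filter, a straight
filament passing a target's endpoint obliquely can carry a run longer
than `l_min` while the reverse run is shorter. The tests therefore check
symmetry at `l_min = 0` and for clearly interacting pairs.

## Polarity and the SHG/TP forward model

For oriented microtubules, polarity is
$P = |n^+ - n^-|/(n^+ + n^-) \in [0, 1]$: 1 when all plus ends point the
same way, 0 for balanced antiparallel overlap. On filament networks this
is computed directly from plus-end annotations; a region with no
filaments is undefined (`NA`), never 0 — zero is a physical value meaning
"balanced", not "no data".

Image-based polarity uses a **declared forward model**: two-photon
fluorescence reads microtubule density, $TP = \alpha\rho$, while the
coherent second-harmonic signal depends on both density and polarity,
$SHG = \beta(\rho P)^2$. This is the minimal model consistent with SHG
physics (coherent summation over a focal volume: antiparallel pairs
cancel, amplitude scales with net oriented density, intensity with its
square). The true calibration of a given microscope may differ; the model
is isolated in `shg_tp_forward()` / `polarity_from_images()` so a
different law can be substituted, and the calibration constant
$\kappa = \beta/\alpha^2$ can be estimated from a reference region assumed
fully parallel (`calibrate_kappa()`, median of $SHG/TP^2$ — robust to
outliers). The inversion masks pixels whose TP signal is at the noise
floor rather than zero-filling them: low density makes polarity
unidentifiable, and zeros would fake antiparallel signal.

Axial profiles average the polarity map over slabs perpendicular to the
spindle axis, positions measured from the spindle center. The
**overlap width** is the full width of the central dip at a depth
fraction (default 0.5) between the flanking plateau (the smaller of the
two flank maxima) and the minimum, with linear interpolation between
samples. "Width of the polarity curve" has no canonical definition;
full width at half depth is standard, robust, and the level is exposed.
The metric is defined on the dip of $P$ itself (not of $1-P$); it is
invariant under uniform scaling of the values and translation of the
positions, so either display convention measures the same width.

## Spindle tracking

The tracking pipeline fixes its thresholds in absolute 8-bit units, which
forces one early decision: movies are converted to 8-bit with **global
per-channel min–max scaling** (not per frame), otherwise the fixed bands
would be non-stationary in time. The bands are `top_fraction_band(p)`
= `(floor((1 - p) * 255), 255)`: top 25% → (191, 255) for poles, top 50%
→ (127, 255) for chromatin. The pre-threshold blur is a 3×3 discrete
Gaussian; the kernel size is a pipeline convention, the σ (default
0.8 px) is not, so it is a parameter.

Embryos are segmented from a temporal median projection of the tubulin
channel (smoothed, Otsu-thresholded, holes filled, touching embryos split
by watershed on the distance map); the mask zeroes all signal outside the
embryo. Poles are the two largest thresholded components
(intensity-weighted centroids); anterior is the smaller coordinate along
the reference axis, overridable since slide orientation is arbitrary.
Chromatid leading edges are the outermost thresholded chromatin positions
projected on the pole–pole axis, measured from the midzone (the pole
midpoint). Frames where detection fails are flagged invalid and never
interpolated.

**Anaphase onset** follows the "last frame before visible segregation"
convention, operationalised as the frame before the first run of
`persist = 3` consecutive frames in which the chromatin has split into
components whose axial gap exceeds `gap_min = 1` µm. Both parameters are
exposed — "visible" is qualitative, and the defaults simply make the
call robust to single-frame noise. **Rates** are displacements over the
first 40 s after onset divided by 40 s, for chromatid-edge separation
(segregation) and pole–pole distance (elongation).

Kymographs rotate each frame about the pole midpoint so the pole axis is
horizontal (bilinear interpolation, out-of-bounds → 0) and sum the rows
within ±5 px of the axis. Rotating about the midpoint keeps both poles in
frame; pixel coordinates are 0-based centers, converted to µm only at
reporting boundaries. Enhancement applies local-mean adaptive
thresholding followed by Zhang–Suen thinning (implemented in the package)
to reduce trajectories to 1-px curves.

## Intensity, comets, FRAP

Midzone intensities are background-ratio normalized:
`(mean(roi) − mean(bg)) / mean(bg)`. The normalization used for published
"normalized intensity" values is rarely stated; the background ratio is
declared as this package's convention. Protein profiles are column means
of an ROI box across the spindle, and their half-intensity width is the
full width at half of (peak − background) with interpolated crossings —
invariant under gain/offset changes.

Comet events are counted on a kymograph segment (default 4.5 µm × 100 s)
binarized at `background + 0.10 × (max − background)`. A "10% threshold"
could mean percent-of-max, percent-of-range or a percentile; the
background-subtracted-maximum reading is declared and configurable.
Events are 8-connected components of ≥ 2 px (single-pixel noise is not an
event; the area floor is a parameter). Crossing comets merge into one
component — a documented limitation of component counting.

FRAP curves are fitted with the single-exponential recovery
$F(t) = F_0 + (F_\infty - F_0)(1 - e^{-kt})$, the simplest standard
model when only a recovery fraction is reported; the mobile fraction is
$(F_\infty - F_0)/(F_{pre} - F_0)$. The fit is Levenberg–Marquardt with
data-driven starting values; an exactly flat post-bleach curve short-cuts
to fraction 0 (the model is degenerate there). Reaction–diffusion FRAP
modelling is out of scope.

## Single molecules

Track speed is **path length / elapsed time** — for a processive motor
the path-based estimate is the natural one — while the net start-to-end
displacement is reported separately as the run length; both appear in
`summarize_tracks()` so no information is lost. The brightness–speed
association uses per-track median intensity vs speed among particles above
a velocity floor (default 0.075 µm/s, the conventional display filter for
"moving" particles); the floor is applied only to this association, never
to raw summaries. Co-appearance fractions are returned at full precision;
display rounding is the caller's concern.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded, bit-identical under regeneration, and returns
ground truth sufficient to predict its paired analysis in closed form:

- `make_filament_network()` lays straight, axis-parallel filament *pairs*
  on a jittered lattice. Both members of a pair share one axial span, so
  the designed overlap equals the filament length and each ordered pair
  yields exactly one interaction of that length at exactly the designed
  spacing. (Extending the filaments beyond a partial overlap would add
  $\sqrt{d_{max}^2 - s^2}$ of run beyond the overlap zone — ~92 nm at
  40 nm spacing — making "designed overlap" ill-posed at the ±40 nm level
  the recovery tests require.) Plus-end orientations are antiparallel for
  an exact count of the in-zone filaments. What it does not emulate:
  curvature, tracing noise, missing-wedge artefacts, partial overlaps, or
  realistic length mixtures — so passing recovery tests validates the
  measurement chain, not any biological claim.
- `make_mitosis_movie()` renders two Gaussian poles and Gaussian chromatin
  masses inside a dim elliptical embryo, with piecewise-linear kinematics:
  constant metaphase pole distance, then elongation at the preset rate;
  a single chromatin plate, then two masses separating at the preset rate
  from an abrupt ~2 µm initial separation (anaphase onset is
  morphologically abrupt, and EM staging of early anaphase starts near
  1.5 µm chromosome distance). Antiphase transverse pole oscillation,
  signal-proportional plus read noise. Not emulated: rotating or drifting
  spindles, photobleaching, lagging chromosomes, spindle rupture, uneven
  illumination.
- `make_shg_tp_pair()` builds a spindle-shaped density map and a polarity
  map with a designed central dip (Gaussian of a given FWHM, or
  rectangular), rendered through the forward model.
- `make_comet_kymograph()` draws diagonal comet traces with an enforced
  minimum separation; its default canvas spans exactly the standard
  4.5 µm × 100 s counting window so the designed count is the counted
  count. It errors when the requested count cannot be placed.
- `make_frap_curve()`, `make_track_table()`, `make_coappearance_log()`
  invert trivially by construction.

Default kinematic and architectural scales follow the documented condition
presets (`midzone_presets()`): e.g. control segregation 0.13 µm/s,
elongation 0.09 µm/s, FRAP fraction 0.34. These are simulation presets;
recovering them from synthetic data says nothing about real embryos.

## Problem sizes and numerical conventions

The test-suite defaults are sized for a laptop-scale run: oracle
equivalence uses 50 random networks of 10–30 straight filaments checked
against a 1-nm dense-sampling oracle; tracking recovery uses 20 movies of
80 frames at 280 × 160 px; width and FRAP recoveries use 50 seeded
replicates each. Tie-breaks and degenerate inputs are fixed as follows:
nearest-neighbour ties go to the smaller filament id; a region or profile
with no data is `NA`/error, never silently 0; constant image channels are
flagged and mapped to 0; degenerate (flat) bounding boxes are padded by
0.5 nm per side so a planar test network still has a volume; closed-loop
filaments have no defined angle and raise an error.

## Known limitations

- The SHG→polarity law is a declared model, not a microscope calibration;
  absolute widths from real images depend on κ and the TP floor.
- Interaction counts are resampling-dependent in principle; results
  should be reported with the `resample_step` used (the default 20 nm
  changes lengths by at most ±2 steps relative to 1 nm sampling on
  straight-filament networks).
- Component-based comet counting undercounts crossing events.
- The tracker assumes two poles and one/two chromatin masses per embryo;
  multipolar spindles and severe segregation defects are out of scope.
- 2D tracking only; no drift correction beyond rigid-rotation utilities.
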