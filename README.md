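# midzoner

Quantitative analysis of microtubule overlap and spindle dynamics in the
anaphase midzone of the early *C. elegans* embryo.

During anaphase, the spindle midzone — the array of antiparallel
microtubules between the segregating chromosomes — both drives and brakes
chromosome segregation. Assessing how its architecture is regulated
requires very different measurements to be brought together: 3D geometry
of traced microtubules from electron tomography, optical polarity mapping
of the whole spindle, pole/chromosome tracking in time-lapse movies,
midzone intensity and turnover readouts, and single-molecule motility
statistics. `midzoner` implements this analysis chain as a tidyverse-style
R package for cell biologists and image analysts, together with seeded
synthetic-data generators that attach exact ground truth to every input, so
each stage is testable end to end without any raw microscopy data.

## What it computes

**Filament interactions (electron tomography).** Traced microtubules are
polylines in nm (Amira SpatialGraph ASCII or CSV). After excluding
tracings shorter than 100 nm, an *interaction* is a contiguous stretch of
one microtubule that stays within a maximum center-to-center distance
*d*<sub>max</sub> = 100 nm of another for at least *l*<sub>min</sub> =
100 nm of arc length. Distances are exact segment–segment minima; each
filament is resampled at a uniform 20 nm arc step, in-threshold runs are
refined by linear interpolation at the threshold crossing, and a uniform
3D grid accelerates the search without changing any result. Network
summaries report density (MT/µm³), length and nearest-neighbour statistics
(population SD), and the fraction of interactions per distance bin.

**Microtubule polarity (SHG/TP imaging).** For an array of oriented
microtubules, polarity is

> P = |n⁺ − n⁻| / (n⁺ + n⁻),

1 for parallel arrays, 0 for balanced antiparallel overlap. On networks it
is counted from plus-end annotations; on images it is recovered from
simultaneous second-harmonic-generation (SHG) and two-photon (TP) signals
through a declared forward model (TP = αρ, SHG = β(ρP)²) inverted as
P = √(SHG / (κ·TP²)) with κ = β/α², masked where the TP density signal is
at floor. Axial profiles of P show the antiparallel overlap as a central
dip whose full width at half depth is the overlap-width statistic.

**Spindle tracking.** Two-channel movies are converted to 8-bit (global
per-channel min–max), embryos are segmented by watershed on a temporal
median projection, poles are detected in the top-25% band (191–255) and
chromatin in the top-50% band (127–255) after a 3×3 Gaussian blur.
The package derives pole–pole distance, chromatid leading edges relative
to the midzone, anaphase onset (last frame before a persistent ≥1 µm
chromatin gap), segregation/elongation rates over the first 40 s of
anaphase, pole oscillations, and rotation-aligned kymographs (±5 px sum
projection) with adaptive-threshold skeleton enhancement.

**Midzone intensity, comets, FRAP, single molecules.**
Background-normalized ROI intensities; full width at half intensity of
protein profiles; EB-comet counting on a 4.5 µm kymograph segment with 10%
thresholding; single-exponential FRAP fits
F(t) = F₀ + (F∞ − F₀)(1 − e^(−kt)) with mobile fraction
(F∞ − F₀)/(F_pre − F₀); and track-table summaries (path-length speed, net
run length, brightness–speed association, bait–prey co-appearance
percentages).

## Worked example

Generate a synthetic midzone-like network of 20 microtubules (10
antiparallel pairs at 71 nm spacing, lengths ~880 ± 140 nm), then run the
interaction analysis:

```r
library(midzoner)

gen <- make_filament_network(n = 20, length_dist = c(880, 140),
                             spacing = 71, antiparallel_fraction = 0.5,
                             seed = 42)
net  <- filter_short(gen$network, 100)
ints <- detect_interactions(net, d_max = 100, l_min = 100,
                            resample_step = 20, index = TRUE)
network_stats(net, ints)
#> <network_stats> 20 filaments, 7.85 MT/um^3 in 2.55 um^3
#>   length: 957 +/- 111 nm; nn distance: 71.0 +/- 0.0 nm
#>   interactions: n = 20, length 957 +/- 111 nm
network_polarity(net)
#> [1] 0
```

Every designed quantity is recovered: each filament's nearest neighbour
sits at exactly the designed 71 nm spacing, every ordered pair yields one
interaction whose length equals the pair's overlap, and the balanced
antiparallel orientation gives polarity 0. A noisy FRAP curve generated at
fraction 0.34 and k = 0.05 s⁻¹ is fitted by
`frap_recovery_fraction()`:

```r
g <- make_frap_curve(fraction = 0.34, k = 0.05, noise_sd = 0.02, seed = 42)
frap_recovery_fraction(g$curve)
#> <frap_fit> recovery fraction 0.339, k = 0.04977 /s (t1/2 = 13.9 s)
```

`run_pipeline(pipeline_config(seed = 1))` chains the synthetic network,
tracking and FRAP stages into one deterministic report; see the methods
vignette (`vignettes/midzone-analysis.Rmd`) for the models, parameter
conventions and limitations.

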