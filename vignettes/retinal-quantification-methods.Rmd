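---
title: "Quantifying subretinal nanoparticle therapy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subretinal nanoparticle therapy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retquant)
```

## What this package quantifies

Photovoltaic organic nanoparticles injected into the subretinal space of a
retinitis-pigmentosa mouse can substitute for lost photoreceptors: they sit
against the surviving outer retina, are partly phagocytized by the retinal
pigment epithelium (RPE), and — if they neither disperse nor trigger
inflammation — restore light-evoked cortical activity and visual behavior.
Evaluating such a therapy requires four quantitative pillars, and
`retquant` implements all of them as tested, reusable operations:

1. **Particle distribution imaging.** Segmentation of sub-micron
   fluorescent clusters in confocal Z-stacks, their diameter distribution
   in 250-nm bins, nearest-neighbor distances (granularity), areal
   coverage by a concave boundary, internalization by the RPE, and
   Manders overlap with microglial immunoreactivity.
2. **Cell morphometry.** Sholl profiles of microglia with a log-normal
   fit whose half-width gives the maximal branching span; the circularity
   index `4*pi*area/perimeter^2`; and RPE mosaic geometry (area,
   perimeter, ellipse axes, neighbor counts, density).
3. **Electrophysiology.** Flash and pattern visually evoked potentials
   (VEPs) on averaged sweeps with a 2-standard-deviation detection
   criterion; visual acuity as the X-axis intercept of amplitude versus
   log spatial frequency; short-time spectral Z-maps; and single-unit
   PSTHs with smoothed firing-rate Z-scores.
4. **Behavior.** The optomotor concordance/discordance ratio (score 1.0 =
   perception threshold) and freezing percentages in light-cued classical
   conditioning.

Because the underlying animal data are not publicly deposited, the package
ships a first-class synthetic-data module that generates every input class
with exact ground truth, so each stage is verifiable end-to-end.

## The synthetic-data model

### Nanoparticle stacks

`generate_np_stack()` renders fluorescent clusters as solid spheres with
log-normally distributed diameters; `diameter_mode` (default 0.85 um) is
the *mode* of that distribution (`meanlog = log(mode) + sdlog^2`,
`sdlog = 0.2`), matching a particle-aggregate population whose size
histogram peaks just below 1 um with essentially all clusters under 2 um.
Spheres are rasterized by centre-sampling (a voxel belongs to the sphere
iff its centre is inside the radius), giving an unambiguous discrete
ground truth, and are placed by dart throwing with centre separation of at
least the sum of radii plus one voxel diagonal — the margin that provably
prevents two rasterized spheres from ever becoming 26-connected. A
requested fraction of centres (`round(fraction * n)`, exactly testable)
falls in the epithelial z-band, the rest in the outer-retina band.

The optical model is deliberately minimal: an isotropic Gaussian PSF
(default sigma 0.05 um) followed by photon-counting (Poisson) noise at 1
count per intensity unit and Gaussian read noise (SD 2, peak signal 100).
These defaults emulate super-resolution (deconvolved) confocal acquisition
at 0.05 x 0.05 x 0.10 um voxels on a 384 x 384 x 48 grid with 100
clusters; at these conditions the full pipeline (moments threshold,
26-connected components, Feret diameter + one mean voxel pitch) recovers
the cluster count exactly on noiseless stacks and keeps the modal
histogram bin at [0.75, 1.0) um under default noise. Two things the model
does **not** emulate: pigment autofluorescence and tissue scattering, so
passing tests demonstrate correctness of the measurement chain, not
robustness to every real-world background.

A note on the diameter convention: the major diameter is the 3D maximum
Feret distance over member-voxel centres *plus one mean voxel pitch*, so a
single-voxel cluster reports a physical size rather than zero. For
multi-voxel clusters the centre-to-centre Feret barely shrinks below the
true diameter (diagonal pairs nearly achieve it), so the convention biases
diameters upward by roughly one voxel pitch. This is why the generator
defaults use fine sampling: at coarser pitches the bias would move the
modal bin of an 0.85-um population into the next 250-nm bin.

### Cells, recordings, behavior

*Microglia*: ramified cells are a soma disk plus a random binary tree of
1-pixel processes (`span` ground truth = max root-to-tip Euclidean
distance); ameboid cells are smoothly perturbed circles whose circularity
is computed exactly from the generating polygon. *RPE mosaics* are
Voronoi tessellations of a jittered hexagonal lattice (or uniform random
seeds); ground-truth adjacency is computed geometrically by dense sampling
of each pair's perpendicular bisector, independent of the rasterized
label image. *Evoked potentials* are a Gaussian-shaped deflection of set
amplitude and latency on 1/f-amplitude-spectrum background noise (white
noise spectrally shaped, the canonical LFP statistic); pattern-series
amplitudes follow `A(f) = -slope*(log10 f - log10 acuity)` clipped at
zero. *Spikes* are piecewise-constant-rate Poisson processes with a
multiplicative gain inside the response window. *Behavior traces* are
run-length state series whose per-state durations equal the request
exactly (durations must be multiples of the 0.1-s sample period).

All generators draw from one seeded generator per call and restore the
caller's RNG state; identical seed means bit-identical output.

## Numerical and design choices

**Moments auto-threshold.** The threshold preserves the first three
gray-level moments of the image. We evaluate the criterion exhaustively:
for every candidate level the below-threshold fraction `p0` fixes the two
representative levels that match the first and second moments exactly,
and the score is the third-moment mismatch; the best level wins, and ties
(empty histogram valleys) resolve to the middle of the tying run so a
symmetric bimodal histogram thresholds mid-valley. The test suite checks
this against an independent per-level root-finding oracle.

**Connected components** default to 26-connectivity (blurred blobs in
diagonal contact are one physical cluster), configurable to 6 or 18.
Thresholding is global over the stack volume, matching how volumes are
binarized; a per-slice variant exists behind a flag.

**Compartment membership** is decided by the cluster's centroid voxel, so
internalized plus non-internalized counts always sum to 100%.

**Coverage boundary.** The concave boundary is a k-nearest-neighbor
concave hull: a gift-wrapping walk restricted to the k nearest unused
points, with k escalated until the walk closes around every point.
`shrink` in [0, 1] maps log-linearly from k = n-1 (shrink 0, exactly the
convex hull) to k = 3 (tightest); the default 0.5 mirrors common boundary
routines whose shrink factor is rarely reported. Coverage is the hull
area as a percentage of the ROI area.

**Sholl counting** follows the published pipeline: binarize, skeletonize
(Zhang-Suen), dilate by one pixel, then count, for each radius, the
maximal contiguous foreground arcs of the sampling circle. The count is
computed *exactly* by angular-interval arithmetic over pixel cells rather
than by sampling the circle: sampled counting at any finite arc step
mis-resolves arc slivers narrower than the step near tangencies. Radius
steps are 1 um starting at the soma minor diameter (a flag halves the
step for the reading of "1 um diameter increments" as circle diameter).
The profile is fitted with `N(r) = A exp(-(ln r - mu)^2 / (2 sigma^2))`
by Levenberg-Marquardt least squares; the branching span is the distal
50%-of-peak crossing `exp(mu + sigma sqrt(2 ln 2))`. The proximal
crossing and full width are also reported because "half-width" is
ambiguous; the distal crossing is the reading consistent with a *maximal*
branching extent.

**Circularity of masks** polygonizes the outer contour (marching squares
at the half level after a light 3x3 box smoothing) instead of counting
pixel edges; raw pixel-edge perimeters are ~6% long for a disk, which
would bias circularity low by ~12%. With the contour convention a
rasterized disk of radius 50 px measures within 1% of 1.0.

**RPE neighbor counts** use 4-connected boundary contact; diagonal-only
contact does not make neighbors. Cells touching the field edge are
flagged and excluded from neighbor statistics and density. Note that
Voronoi edges shorter than one pixel cannot be seen by any rasterized
adjacency, so measured neighbor counts are validated against the
geometric ground truth as "equal for >85% of interior cells, never off by
more than 1" rather than exact equality.

**Filtering** uses Butterworth designs (0.1-100 Hz band-pass for VEPs;
300 Hz low-pass plus 48-52 Hz band-stop before probe analyses;
300 Hz-5 kHz for spikes) applied forward-backward, so group delay is zero
and latencies are unbiased. The combined `|H|^2` response is applied in
the frequency domain on a reflection-padded trace: time-domain IIR
recursion at the extreme 0.1 Hz corner (normalized cutoff 1e-4) loses
~7 digits to rounding-error amplification, while the spectral route is
exactly linear in the input. The mean is removed before the band-pass
because the 0.1-Hz corner's impulse response outlasts typical sweeps.

**VEP detection** takes the signed extremum of largest absolute deviation
from the baseline mean inside the 75-150 ms post-stimulus window (both
polarities detectable; cortical responses at depth are negative), and
declares a response when the amplitude exceeds `k = 2` times the noise
SD. What counts as "the noise" matters: on an averaged trace of
correlated 1/f background, the baseline SD underestimates slow drift and
the criterion would fire on most null traces. `vep_from_trials()`
therefore estimates the noise SD from the pre-stimulus baseline of the
*individual sweeps* (pooled), which makes the 2-SD rule a physiological
gate: the null detection rate is then below 10%, and a 50-uV response on
a 20-uV-noise recording is detected with latency accurate to a few
milliseconds. `detect_vep()` retains the trace-local baseline SD as the
default for single-trace use, with `noise_sd` as an override.

**Acuity extrapolation** regresses detected amplitudes on log10 spatial
frequency and reports `10^(-intercept/slope)`; non-detected frequencies
are dropped (not entered as zeros), and a non-negative slope is an
explicit no-decay error rather than a nonsense acuity.

**Spectral Z-maps** use a short-time periodogram (Hann window, 60-ms
segments, 5-ms hops) over the -0.1 to 0.4 s peristimulus window, with
each frequency row Z-scored against its pre-stimulus bins. Rows with zero
baseline SD are flagged undefined rather than silently infinite — this
includes the degenerate case of a signal exactly periodic at the hop.

**Spiking analysis**: PSTHs with 10-ms bins across 50 trials; firing-rate
Z-scores after a centred 50-ms boxcar whose window shrinks at the edges
(no padding); the response statistic is the maximum Z in 150-500 ms;
units under 0.2 Hz mean rate are excluded, with the boundary retained
(exclusion is strictly below threshold).

**Optomotor scoring** excludes untracked ("neither") time from both
numerator and denominator; repeats of a frequency are aggregated as the
arithmetic mean of per-repeat scores (a flag switches to pooled
durations). A trace with zero discordant time raises a censored-high
error instead of returning infinity.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen to finish in
minutes while preserving the statistical structure of each check: stacks
of 384 x 384 x 48 voxels with 100 clusters (the 30-of-100 internalization
construction); oracle-equivalence checks on 50 seeded instances per
operation at up to 64^3 voxels and 200-voxel clusters; 100-200 seeds for
the acuity and branching-span noise recoveries; 10^4 points for the
Poisson nearest-neighbor limit (border edge correction, 3% band around
`0.5/sqrt(lambda)`); 500 cells for the random-Voronoi neighbor limit.

## Known limitations

- The concave hull is a single polygon: it cannot represent holes, so
  coverage of an annular distribution reports the filled area.
- Rasterized neighbor counts miss sub-pixel Voronoi edges (see above).
- The spectral estimator's defaults (60-ms Hann segments) trade frequency
  resolution (~17 Hz) for temporal locality; both are configurable.
- Skeletonization is directional at the pixel level, so Sholl counts on
  *raw* masks are only approximately rotation-invariant; the counting
  core itself is exactly invariant under 90-degree rotations.
- The generator does not model autofluorescence, motion, or optical
  scattering; conclusions about robustness to those belong to real data.
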