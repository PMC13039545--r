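# retquant

Quantification pipeline for evaluating subretinal photovoltaic
nanoparticle therapy in retinal degeneration: imaging morphometry of the
injected particle distribution and of retinal cell types,
visually-evoked-potential and spiking analysis of the restored cortical
responses, and behavioral scoring of visual perception. It is written for
researchers who need the measurement chain of such a study as tested,
scriptable operations rather than a collection of one-off ImageJ/MATLAB
steps — and who need to validate every stage without access to the
original animal data, which is why a synthetic-data generator with exact
ground truth is a first-class part of the package.

## What it computes

**Particle distribution** (confocal Z-stacks, µm voxel spacing):
moment-preserving ("Moments") auto-thresholding; 26-connected 3D
components; per-cluster major diameter (3D max Feret over voxel centres
plus one mean voxel pitch); frequency histograms in 250-nm bins;
nearest-neighbor distances (mean NND, optional border edge correction);
areal coverage by a concave boundary polygon (shrink 0 = convex hull);
internalization percentage by centroid-in-compartment counting; Manders
split coefficients M1 = |A∩B|/|A|, M2 = |A∩B|/|B| (area or intensity
weighted); integrated density over ROIs on sum projections.

**Morphometry**: Sholl intersection profiles (1-µm radius steps from the
soma minor diameter, exact arc-run counting on the skeletonized, dilated
mask), log-normal profile fit N(r) = A·exp(−(ln r − µ)²/2σ²) with
branching span exp(µ + σ√(2 ln 2)); circularity 4π·area/perimeter²;
epithelial-mosaic geometry (area, perimeter, ellipse axes, 4-connected
neighbor counts, density).

**Electrophysiology**: zero-phase Butterworth filtering (0.1–100 Hz
band-pass; 300 Hz low-pass + 50 Hz notch; 300 Hz–5 kHz); sweep averaging;
VEP peak detection in the 75–150 ms window at >2× the noise SD with
onset-to-peak latency; visual acuity as the X-intercept of amplitude vs
log₁₀ spatial frequency; short-time spectral Z-maps
((f(t) − F₀)/sd(F₀), 5-ms bins, −0.1–0.4 s); PSTHs (10-ms bins, 50
trials); smoothed (50 ms) firing-rate Z-scores with the response
statistic max Z in 150–500 ms; exclusion of units under 0.2 Hz.

**Behavior**: optomotor score = concordant/discordant time ratio (1.0 =
perception threshold); freezing percentage per conditioning phase with
the paired dark-vs-CS difference.

## Worked example

Simulate a confocal-like stack with 40 clusters (30% internalized by the
pigment-epithelium band), then run the particle pipeline:

```r
library(retquant)
spec <- stack_spec(shape_xyz = c(192L, 192L, 32L), n_clusters = 40L,
                   layer_band_z = c(10L, 32L), rpe_band_z = c(0L, 10L), seed = 7L)
sim <- generate_np_stack(spec)
clusters <- segment_particles(sim$stack)
print(clusters)
#> <cluster_set> 40 clusters (connectivity 26, threshold 46.82854)

h <- diameter_histogram(clusters$table$diameter_um)
cat(sprintf("modal bin [%.2f, %.2f) um, %.0f%% below 2 um\n",
            h$modal_bin[1], h$modal_bin[2], 100 * h$fraction_below_cutoff))
#> modal bin [0.75, 1.00) um, 100% below 2 um

nn <- nearest_neighbor_distances(as.matrix(clusters$table[, c("cx_um","cy_um","cz_um")]))
cat(sprintf("mean NND %.2f um\n", nn$mean))
#> mean NND 1.41 um

ir <- internalization_fraction(clusters, sim$masks$rpe)
cat(sprintf("internalized: %.1f%% (%d of %d; ground truth %.0f%%)\n",
            ir$percent, ir$n_inside, ir$n_total,
            100 * mean(sim$truth$compartment == "RPE")))
#> internalized: 30.0% (12 of 40; ground truth 30%)
```

All 40 generated clusters are recovered, the diameter histogram peaks in
the 0.75–1 µm bin as constructed, and the centroid-based internalization
count reproduces the generator's 30% exactly.

## Analysis workflow

The study-scale analyses live as numbered drivers under `analysis/`,
each a thin script over the package functions that prints what it found
and writes tidy tables beneath `results/`:

```sh
Rscript analysis/01_simulate.R      # all synthetic inputs + ground truth
Rscript analysis/02_particles.R     # segmentation, histogram, NND, coverage, internalization
Rscript analysis/03_morphometry.R   # Sholl spans, circularity, mosaic geometry
Rscript analysis/04_ephys.R         # fVEP, acuity, spectral map, unit Z-scores
Rscript analysis/05_behavior.R      # OMR curve, conditioning summary
Rscript analysis/06_report.R        # group mean ± sem tables
```

Stage outputs carry JSON run manifests (parameters, input checksums,
package version, seed); identical config + seed re-runs are
byte-identical.

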