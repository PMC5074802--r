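---
title: "Methods: quantifying interareal excitation, inhibition and hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying interareal excitation, inhibition and hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scracmap)
```

## Scope and model

`scracmap` implements the quantification machinery used to ask how the
inhibition/excitation balance of cortico-cortical pathways depends on the
hierarchical positions of the source and target areas in mouse visual
cortex. Three measurement modalities are covered:

1. **sCRACM input maps.** Channelrhodopsin-expressing interareal axons are
   photostimulated one spot at a time on an 8 x 16 grid (75 µm pitch,
   long axis perpendicular to the pia) while a PV interneuron or a
   pyramidal (Pyr) cell is held at -70 mV. Each grid pixel is quantified
   as the mean EPSC over the 75 ms following the stimulus, averaged over
   3-5 repetitions, and retained only if it exceeds 4x the baseline SD.
   Total input is the sum of significant pixels; the cohort statistic for
   a pathway is the geometric mean of per-pair EPSC_PV/EPSC_Pyr fold
   ratios between cells recorded within ~100 µm of each other in the same
   layer and slice.
2. **Laminar density ratios.** A grayscale image of anterogradely labelled
   axons in a target area is smoothed with a circular averaging filter,
   normalized to peak, and the density ratio DR = mean OD in the L2-4
   top-70% contour / mean OD in the L1 top-70% contour is formed.
   Feedforward-like projections have DR > 1, feedback-like DR < 1; source
   areas ordered by mean DR over their targets give the area hierarchy,
   with pairwise Mann-Whitney U tests.
3. **Paired recordings.** Current steps (100-400 pA, 50 ms) injected into
   a PV cell evoke spikes; IPSCs in a neighboring Pyr cell held at 0 mV
   are quantified as windowed means over 75 ms after step onset. A pair is
   called connected if the response at the largest spiking step exceeds
   4x baseline SD; the IPSC-vs-excitation relation is tested by one-way
   ANOVA across steps.

No raw recordings or images from the original study are distributed, so a
synthetic-data module generates all three modalities with planted ground
truth, and the test suite establishes that every estimator recovers what
was planted under stated noise.

## Synthetic world: what is stated, what was chosen

Parameters fixed by the acquisition protocol are used verbatim: grid
8 x 16 at 75 µm, 3-5 repetitions, 75 ms response window, 4-SD pixel
threshold, -70 mV / 0 mV holding potentials, 100-400 pA steps of 50 ms,
~100 µm pairing distance. The protocol does not state noise levels,
unitary amplitudes, footprint geometry or inter-pair variability; those
were chosen once, for realism and testability, and are not revisited:

- **EPSC kernel.** Difference of exponentials
  \(A\,(e^{-t/\tau_d} - e^{-t/\tau_r})\), rescaled so that its *discrete*
  windowed mean equals the target amplitude exactly — this gives the
  conservation oracle (ground-truth amplitude == windowed mean of the
  noiseless sweep) to machine precision, and an analytic time to peak
  \(t^* = \ln(\tau_d/\tau_r)\tau_d\tau_r/(\tau_d-\tau_r)\) for kinetics
  tests. Defaults: \(\tau_r\) = 0.5 ms (PV), 2 ms (Pyr), \(\tau_d\) = 6 ms,
  consistent with the observation that PV-cell EPSCs rise faster.
- **Sign convention.** Sweeps store physical currents (inward EPSCs
  negative at -70 mV, outward IPSCs positive at 0 mV); all analysis
  outputs report magnitudes in pA, so maps are non-negative.
- **Amplitudes and noise.** Pyr peak windowed-mean amplitude 20 pA, raw
  sweep noise SD 2 pA (peak SNR 10). The input footprint is Gaussian
  along depth (SD 2 rows ≈ 150 µm, centred near the bottom of L2/3) and
  uniform across columns — a laminar slab; no lateral structure or
  dendritic cable filtering is modelled (attenuation enters only through
  the amplitude field).
- **Fold heterogeneity.** Per-pair PV:Pyr folds are log-normal with
  geometric mean equal to the planted fold (matching the geometric-mean
  cohort statistic) and log-SD 0.15. Real cohorts are far more dispersed
  (reported SEMs imply coefficients of variation near 1), so the fold
  recovery test characterizes estimator error, not biological variance.
- **Projection images.** Per-layer base intensities (L2-4 : L1 set to the
  planted DR) modulated by a multiplicative disk-smoothed log-normal
  texture renormalized to mean 1 within each band (so planted band means
  are exact before noise), plus 5% additive Gaussian noise. Real images
  additionally contain section borders, blood vessels, injection-site
  bleed-over and nonuniform illumination; a green recovery test does not
  establish robustness to any of those.
- **Paired recordings.** Spike waveforms are stereotyped 100 mV
  transients; each spike evokes (if connected) one unitary IPSC
  (peak 20 pA, \(\tau_r\) 0.3 ms / \(\tau_d\) 3 ms, 1 ms delay). Spikes
  are spaced 10 ms apart so unitary responses do not overlap, making the
  windowed mean proportional to spike count — the closed-form oracle.

## Numerical and design choices

- **Averaging before thresholding.** Repetitions are averaged first, and
  the 4-SD test uses the baseline SD of the averaged trace (the published
  order of operations is ambiguous). The baseline is the 100 ms
  immediately preceding stimulus onset (no baseline window is published).
- **Threshold censoring bias.** Zeroing sub-threshold pixels removes more
  mass from the weaker (Pyr) map than from the PV map, so the cohort fold
  is biased upward by roughly 5-9% at peak SNR 10 (larger for larger
  folds). This is a property of the published estimator, not of the
  implementation; recovery tolerances (15%) absorb it.
- **Row-layer assignment.** A grid row resides in a layer iff its centre
  depth (pia offset + (row-1) x 75 µm) lies in the band; the per-layer
  input fraction is the *mean* of the row percentages in the band,
  matching how L1 input was summarized.
- **Conductance normalization.** It is unclear whether published
  normalization divided by each cell's own conductance or the cohort mean;
  per-cell division is the reproducible reading and is what `fold_norm`
  implements (the unnormalized fold is always reported alongside).
- **Time to peak** is averaged over all significant pixels (the
  alternative — strongest pixel only — is not published either; averaging
  uses more data and is stabler).
- **70% contour.** "Highest 70% of optical densities" is read as pixels
  with OD ≥ 30% of the band maximum (the contour bounding the top 70% of
  the intensity range), computed within each band separately; the
  rank-based reading (top 70% of pixels) is available via
  `band_density(method = "rank")`.
- **Edge handling.** The circular averaging filter uses normalized
  convolution (each pixel is the mean over in-image disk offsets), so a
  uniform image is unchanged and borders carry no padding artifact. Band
  statistics erode each band by the filter radius before measuring,
  excluding pixels whose smoothing neighbourhood straddles a layer
  boundary; without this, bleed from a bright L2-4 into the thin L1 band
  inflates the L1 contour threshold and can bias DR by tens of percent.
  The filter radius defaults to 10 px and is exposed as a flag; synthetic
  recovery runs use radius 4 on 5 µm pixels (20 µm smoothing), matched to
  the image resolution.
- **Per-pathway DR** is the mean over the (typically 3) slice DRs;
  too-weak slices (all-zero band) are excluded and counted, mirroring the
  grey "too weak to analyze" entries of the connection matrix.
- **FF/FB boundary.** `classify_pathway` uses a strict `dr > 1` rule, so
  DR exactly 1 is called FB; the threshold is configurable.
- **Interpolation.** Cohort heat maps are upsampled bilinearly on a
  node-aligned fine raster: coarse grid nodes are a subset of the fine
  ones, so peak values survive interpolation exactly and the trapezoidal
  integral of the surface is preserved to machine precision.
- **Pairing rule.** Nearest eligible neighbour within 100 µm, same layer
  and slice; ties broken by distance then lowest cell id. A pair whose
  Pyr total is zero is flagged excluded (classed warning), never silently
  dropped.
- **Containers.** The sweep container is a plain-text directory (JSON
  manifest with schema version and units, one CSV per cell at full
  round-trip precision via `%.17g`); density images are CSV matrices with
  JSON sidecars. The target environment ships no R HDF5/TIFF bindings,
  and the logical schema and round-trip contracts are format-independent.

## Test-budget scaling

Simulation-heavy tests run at 2 kHz sampling with a 50 ms baseline
instead of the 10 kHz / 100 ms defaults; every assertion is expressed in
ms and pA and is rate-agnostic. Monte-Carlo sizes follow the acceptance
criteria (50/20/200/100/1000 seeds as stated); a reduced-n variant of the
false-positive calibration also runs in the unit suite.

## Known limitations

- No biophysical dendrite/cable model, ChR2 desensitization, laser-power
  saturation, spontaneous events or series-resistance artifacts are
  simulated; estimates of distal (L1) input share the published caveat of
  dendritic attenuation.
- The connection criterion for paired recordings (4 SD at the largest
  spiking step) is this package's operational definition; the original
  count (11/13, 7/15) was reported without one.
- Areal parcellation, slice registration and layer delineation are
  treated as given annotations, not computed.
- The synthetic-data defaults aim at testability, not at reproducing the
  published effect sizes; headline cohort numbers (e.g. 12.85-fold V1→PM
  PV:Pyr excitation) derive from unreleased recordings and are not
  reproduced here.
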