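---
title: "Spectral activity mapping of stimulation-locked cortical reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral activity mapping of stimulation-locked cortical reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its model

Intraoperative optical imaging records the exposed cortex through the
operating microscope while a sensory stimulus alternates in a block design:
`cycles` repetitions of `restDuration` seconds of rest followed by
`stimDuration` seconds of stimulation. Neuronal activation raises local
cerebral blood volume, which raises haemoglobin absorption and therefore
*lowers* reflectance at 568 nm (and in the green channel of an RGB camera).
The evoked signal is thus a small periodic reflectance modulation at the
block frequency

$$f_{stim} = \frac{1}{T_{rest} + T_{stim}}$$

(1/60 Hz for the standard 30 s + 30 s blocks), superimposed on spontaneous
vasomotion — slow oscillations of vascular tone below roughly 0.04 Hz —
broadband noise and slow drift.

The mapping statistic exploits the known frequency. Per pixel, the package
computes a one-sided DFT power spectrum and forms

$$\mathrm{ratio} = \frac{P_s}{P_{VLF}}$$

where $P_s$ is the power at the stimulation bin and $P_{VLF}$ the summed
power over the very-low-frequency band $0 < f < 0.04$ Hz. A pixel driven by
the stimulus concentrates power at $f_{stim}$ and stands out against the
vasomotor background; a pixel fluctuating for vascular reasons does not.

Two conditions make the statistic exact rather than approximate:

* the record spans an integer number of stimulation cycles, so $f_{stim}$
  falls exactly on DFT bin number `cycles` and no window function is needed
  (`computeActivityMap()` refuses records where this fails and suggests the
  nearest bin-aligned lengths);
* the ratio cancels global gain, so 8-bit, 12-bit and float acquisitions
  need no intensity rescaling.

## Spectral conventions

The implementation fixes the following conventions; each is a parameter
where a legitimate alternative exists.

* **Normalization.** Power at bin $k$ is $|X_k|^2/N$, with interior bins
  doubled (one-sided). The sum of non-DC one-sided power then equals
  $\sum_n (x_n - \bar{x})^2$, i.e. $N$ times the population variance — the
  Parseval identity the tests assert.
* **Power vs amplitude.** The ratio uses power by default; the
  `measure = "amplitude"` switch uses $|X_k|$ instead, for both numerator
  and band sum. Power is the default because the mapped quantities are
  power-spectral densities; the amplitude option exists because the two
  produce identically located but differently scaled maps.
* **Band edges.** The VLF band is the half-open interval $(0, 0.04)$ Hz: the
  DC bin (mean brightness, not vasomotion) is always excluded, and a bin at
  exactly 0.04 Hz is out.
* **Stimulation-bin guard.** $f_{stim} \approx 0.017$ Hz lies *inside* the
  VLF band. Including it in the denominator would let a true activation
  suppress its own ratio, so the stimulation bin ± 1 guard bin is excluded
  from $P_{VLF}$ by default (`excludeStimBinFromVlf`, `guardBins`). The
  guard absorbs leakage from the slight asymmetry the haemodynamic lag
  imposes on the block waveform.
* **Windowing.** None by default (bin-aligned record); an optional Hann
  window is provided for exploratory use on non-aligned records, with the
  caveat that it smears each spectral line across neighbouring bins and
  breaks the exactness arguments above.
* **Zero denominators.** A pixel with no band power (e.g. a constant trace)
  gets ratio 0 and is counted in a diagnostic rather than producing NaN.

## Preprocessing

* **Green channel.** RGB recordings are reduced to channel 2. In the green
  band both haemoglobin species absorb strongly, so the channel tracks
  blood-volume changes; the mixture of oxy-/deoxy-haemoglobin weightings is
  a physiological interpretation issue, not a mapping issue.
* **Detrending.** Each pixel's least-squares linear trend is removed before
  spectral analysis (default on, disable via the pipeline's `preprocess`
  block). Drift otherwise leaks into the VLF band and biases the
  denominator. A bin-aligned cosine is *almost* invariant under discrete
  detrending — the residual distortion is bounded by $3a/N$ at the record
  ends because the discrete projection of a cosine on a straight line is
  $-6a/N^2$ per frame, not zero; the tests assert exactly this bound rather
  than pretending orthogonality is exact.
* **Motion.** Intraoperative motion is compensated by integer-pixel global
  translation: each frame is aligned to a reference frame (frame 1 by
  default) at the peak of their FFT cross-correlation, ties resolved toward
  the smallest shift so constant frames stay put, exposed borders filled
  with the frame median. This is deliberately the simplest registration
  consistent with the data model — a documented extension point, not a
  claim that cortical motion is rigid. Deformable registration is out of
  scope because no specific algorithm is part of the analysis being
  reproduced.

## Segmentation

The activation segmentation chain is, in order:

1. **Threshold** at $z_{thresh} = \bar{A} + k_{sd}\, s_A$, mean and SD of
   the activity map over the *trepanation* pixels only — the craniotomy
   window is the only cortex the camera sees, so all statistics are
   restricted to it. The SD is the population SD (the sample/population
   difference is negligible at realistic pixel counts; the choice is fixed
   and documented). The inequality is strict, so a constant map yields an
   empty activation rather than a full one. $k_{sd}$ defaults to 1 and is
   exposed because awake measurements are noisier and may need a higher
   threshold for a well-delineated activation.
2. **Area opening**: connected components with fewer than 10 pixels are
   removed ("smaller than 10" is strict — a 10-pixel component survives).
   This realizes small-object removal by its effect, not by
   erosion–dilation with a structuring element, which would also round
   large components.
3. **Largest components**: the union of the 3 largest components is the
   activation area; fewer than 3 are all kept. Size ties break by the
   smallest row-major pixel index — deterministic across platforms.
4. **Convex hull** of the activation, rasterized as every pixel whose
   centre lies in the hull of the activation pixel centres. Collinear
   degenerate sets rasterize to the lattice points of their extreme
   segment. With integer vertex coordinates all in-hull tests are exact
   integer arithmetic, which is what makes hull idempotence an identity
   rather than a tolerance.

Connectivity is 8 by default (diagonal neighbours touch, the standard for
blob detection on cortical maps) and configurable to 4. Because
mean-plus-SD thresholding is affine-equivariant and everything downstream
is set arithmetic, the entire segmentation is invariant under positive
affine rescaling of the map — asserted directly in the tests.

## Comparison

* **DICE.** $DSC = 2|A \cap B|/(|A| + |B|)$, reported as the triplet
  (activation, convex hull, complete thresholded map) against the reference
  mask clipped to the trepanation. $DSC(\emptyset, \emptyset)$ is
  undefined; the implementation returns 0 with a warning — a silent 1 would
  fabricate agreement between two empty masks.
* **Region statistics.** The trepanation is partitioned into reference
  activation, PSC outside the reference, and the surrounding area; each
  region's raw ratio values are summarized as median/Q1/Q3 with
  linear-interpolation quantiles (`stats::quantile` type 7, configurable).
  Masks are first restricted to the expected nesting so the three regions
  always partition the trepanation exactly; empty regions report n = 0 with
  undefined statistics instead of erroring.
* **Topography.** Segmentations of several stimulation sites compose into
  an integer label map. Pixels claimed by several sites go to the
  earliest-listed site; the untouched per-site masks and a pairwise
  site-overlap DICE matrix are kept alongside, so the policy loses no
  information.

## The synthetic scene

No intraoperative recordings of this kind are deposited publicly, so the
package ships a generator whose defaults define the reference scenario used
in all end-to-end tests:

| parameter | default | meaning |
|---|---|---|
| grid | 128 × 128 px | camera view of the trepanation |
| paradigm | 9 × (30 s rest + 30 s stim), 2 fps | 1080 frames, $f_{stim}$ = 1/60 Hz |
| `activationAmplitude` | −0.02 | 2 % reflectance decrease at plateau |
| `responseDelay`, `responseTau` | 2 s, 5 s | haemodynamic onset lag and exponential rise/decay |
| `vasomotion` | 0.008/0.015/0.03 Hz at 0.005 | global sub-0.04 Hz sinusoids |
| `noiseSd` | 0.005 | i.i.d. fractional Gaussian noise |
| `driftSlope` | 0.002/min | slow illumination/physiology drift |
| `motionMaxShift` | 0 | optional integer-pixel frame translations |

The haemodynamic response is the paradigm box-car delayed by
`responseDelay` and passed through a first-order exponential lag — the
simplest shape with realistic latency; with a 5 s time constant the
response reaches 99.6 % of its plateau within a 30 s block, so the
injected plateau amplitude is recoverable to within 1 %. The frame rate is
a declared choice (2 fps), not an inferred one: acquisition hardware
exposure times do not determine it, and any rate that divides the cycle
into whole frames is accepted. The drift default of 0.2 %/min is a
realistic slow illumination drift; it exercises the detrending stage
without dominating the scene. Amplitude, noise and vasomotion defaults were
chosen once so that the default scenario is recoverable but not trivial:
the stimulation line carries roughly 30× the per-bin noise power, while
thresholding still has to separate a 270-pixel ellipse from a 9000-pixel
trepanation.

Ground-truth geometry: the trepanation is a centred disc (radius 0.42 of
the short grid side), the PSC a straight oblique band crossing it, the
activation an ellipse on the band axis, optionally offset along the band —
three offsets give three disjoint "body part" sites for somatotopy tests.
All sizes scale with the grid so small test grids keep the same scene.

What the generator deliberately does **not** model: vascular anatomy and
spatially structured vasomotion, heartbeat/respiration aliasing, specular
reflections, non-rigid tissue deformation, and spatially varying response
amplitude. Passing the recovery tests therefore shows the pipeline is
correct and well-calibrated for stimulation-locked signals in realistic
noise — it does not show robustness to every artifact of a real operating
room, which only patient data could.

## Determinism and file formats

A single integer seed drives one RNG stream through all draws, so a fixed
configuration reproduces stacks bit for bit; the end-to-end runner writes a
manifest with an MD5 checksum per artifact, and two runs with the same
config and seed produce byte-identical files. Stacks are stored as
multi-page 32-bit-float TIFF; since the TIFF writer stores values in
[0, 1], frames are mapped linearly into that range with the affine mapping
recorded in a JSON sidecar, giving float32-precision round-trips. Masks are
single-page 0/255 PNG or TIFF (any nonzero pixel reads as foreground);
activity maps are TIFF + JSON bundles; configs are YAML or JSON with
unknown keys rejected. Images are (row, column) with the origin top-left;
stacks put time first.

## Problem sizes in the test suite

Unit tests run on small grids (8–32 px) where brute-force oracles — an
$O(N^2)$ DFT, recursive flood fill, separating-line hull tests,
sort-and-interpolate quantiles — are affordable. The end-to-end recovery,
null-rejection, somatotopy and determinism checks run the full default
scenario (128 × 128 × 1080 frames) across 10, 10, 5 and 2 seeded runs
respectively; the in-mask-versus-background ratio property is additionally
exercised at 32 × 32 with 3 cycles, where it is cheap enough to run per
commit.

## Known limitations

* Translation-only motion compensation; deformable registration is an
  extension point.
* The VLF band sum treats all vasomotion bins equally; no 1/f weighting.
* Reference (fMRI) masks must arrive already registered into camera space;
  the package performs no cross-modality registration.
* The 8-bit RGB path quantizes with a fixed full scale of twice the
  baseline; saturated cameras (baseline near full scale) would clip.
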