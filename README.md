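# ioimap

Spectral activity mapping for intraoperative optical imaging (IOI) of the
human cortex.

## The problem

During tumour surgery near the primary sensory cortex (PSC), a camera on
the operating microscope can record the exposed cortex while a body part is
stimulated in alternating rest/stimulation blocks (typically 9 cycles of
30 s rest + 30 s stimulation). Stimulation-evoked changes in cerebral blood
volume modulate tissue reflectance — strongly at 568 nm or in the green
channel of an RGB camera — at the known block frequency. Mapping where that
stimulation-locked modulation stands out against spontaneous slow vasomotion
yields a functional map of the cortical surface that can be compared with
preoperative fMRI and used for topographic mapping of body parts along the
PSC.

`ioimap` implements that analysis as a tested, reproducible pipeline:

1. **simulate** — a seeded synthetic cortical-reflectance generator with
   ground-truth trepanation/PSC/activation masks, so every stage is testable
   without patient data (none are publicly available for this kind of
   recording);
2. **preprocess** — green-channel extraction, rigid (translation) motion
   compensation, pixelwise linear detrending;
3. **spectral** — pixelwise FFT and the activity map;
4. **segment** — mean-plus-SD thresholding, small-component removal,
   largest-component selection, convex hull;
5. **compare** — DICE coefficients, region-restricted quartile statistics,
   multi-site topographic composition;
6. **pipeline/IO** — TIFF/PNG/JSON readers and writers, YAML configs, and a
   deterministic end-to-end runner with a checksummed manifest.

## The statistic

For each pixel's temporal trace (N frames, frame interval Δt), the one-sided
DFT power spectrum is computed as P_k = |X_k|² / N (interior bins doubled).
With f_stim = 1/(T_rest + T_stim) falling exactly on a DFT bin (the record
holds an integer number of cycles), the activity map is

    ratio = P_s / P_VLF

where **P_s** is the one-sided power at the stimulation bin and **P_VLF**
the summed one-sided power over the very-low-frequency vasomotion band
0 < f < 0.04 Hz, excluding the DC bin and (by default) the stimulation bin
± 1 guard bin. The ratio expresses stimulation-locked power relative to the
vasomotor background; it is invariant to global gain and, after detrending,
to additive offsets.

Segmentation thresholds the map at z_thresh = mean + SD over the trepanation
window, removes connected components smaller than 10 pixels, and keeps the
three largest components as the activation area. Agreement with a reference
mask (e.g. fMRI-derived) is reported as a DICE triplet: activation vs
reference, convex hull vs reference, and the complete thresholded map vs
reference.

## Worked example

```r
library(ioimap)

cfg <- simulationConfig(gridRows = 48, gridCols = 48,
                        paradigm = stimulusParadigm(cycles = 6), seed = 42)
sim <- simulateSequence(cfg)
sim$truth
#> SimulationTruth: 48 x 48 grid; trepanation 1280 px, PSC 308 px, activation 36 px

am <- computeActivityMap(detrendPixelwise(sim$sequence), cfg@paradigm)
am
#> ActivityMap: 48 x 48 pixels
#>   f_stim = 0.016667 Hz, VLF band (0, 0.04) Hz, 4 bins excluded
#>   ratio range [0.08452, 4.284]; 0 zero-denominator pixels

seg <- segmentActivation(am, sim$truth@trepanationMask)
seg
#> ActivationSegmentation: z_thresh = 0.82; 36 supra-threshold px -> 36 after opening -> 36 in activation (1 component)

compareToReference(am, seg, asRegionMaskSet(sim$truth))
#> ComparisonReport
#>   DICE activation/hull/full: 1.000 / 1.000 / 1.000
#>   region statistics (median [Q1, Q3], n):
#>     reference_activation   3.42 [3.26, 3.56], n = 36
#>     psc_minus_reference    0.183 [0.16, 0.207], n = 272
#>     surrounding            0.182 [0.158, 0.205], n = 972
```

Reading the output: the stimulation-locked 2 % reflectance change raises the
activity ratio inside the injected activation ellipse (median 3.42) an order
of magnitude above the vasomotion-plus-noise background (≈ 0.18), so the
mean + SD threshold (z_thresh = 0.82) recovers the injected mask exactly —
all three DICE values are 1. On real recordings, where the reference comes
from a different modality (fMRI) and the activation is diffuse, the triplet
is informative rather than saturated.

The same chain runs end to end, with every artifact written and checksummed:

```r
res <- runPipeline(list(simulation = list(), seed = 0,
                        outputDir = "run0"))
```

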