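# sarcospace

Striation-spacing measurement for fluorescence microscopy of cardiac
myocytes: sarcomere length (SL) from labeled Z-disks, or the T-tubular
distance from membrane staining, estimated from line-ROI intensity profiles
by multipeak Gaussian fitting.

## Who this is for

Groups measuring SL or T-tubule periodicity in confocal images of (arrested)
hearts or isolated myocytes typically draw a line ROI along the myocyte
axis in ImageJ, take the width-averaged plot profile, fit a sum of Gaussians
over a linear offset, and report the distances between adjacent peak
centers. `sarcospace` packages that exact workflow as tested, scriptable R
functions, together with the group-comparison statistics used with such
data (Welch's t-test, including from printed mean ± SD summaries, and the
Steel-Dwass all-pairs test) and a synthetic striated-image generator with
known ground truth so the whole chain is verifiable.

## The model

An intensity profile Y sampled at positions X (µm) along the ROI is fitted
with

    Y = aX + b + Σᵢ Aᵢ · exp(−(X − μᵢ)² / (2σᵢ²))

by bounded Levenberg-Marquardt: a linear background plus one Gaussian per
striation band. Spacing is the set of adjacent-center differences
μᵢ₊₁ − μᵢ, reported as mean ± sample SD over the distances whose flanking
peaks pass an insufficient-intensity filter (amplitude ≥ 20% of the median
fitted amplitude by default; distances next to an excluded peak are dropped,
never bridged). Frame stacks can be superposed (pixelwise mean, optional
integer registration) before analysis to raise SNR. Out-of-plane tilt θ
inflates in-plane spacings by 1/cos θ with sin θ = t/L_min (optical section
thickness over in-focus length); the factor is reported, not silently
applied.

## Worked example

```r
library(sarcospace)

# a synthetic myocyte: 10 bands at 1.92 um, SNR ~ 10, known ground truth
scene <- striationScene(trueSpacing = 1.92, nBands = 10, snr = 10, seed = 42)
sim <- generateStriationImage(scene)
sim$image
#> FluorImage: 40 x 128 px at 0.27 um/px (10.8 x 34.6 um)
#>   intensity range [-4.758, 137.4] AU

# line ROI along the myocyte axis, 5 px wide; then profile -> fit -> spacing
roi <- axisROI(scene, width = 5)
res <- analyzeImage(sim$image, roi)
res$spacing
#> SpacingResult: 1.921 +/- 0.031 um (n = 9 kept of 9 distances) [ROI (25.9,19.5)->(101.1,19.5) w5]
res$fit
#> MultiPeakFit: 10 peak(s) + linear offset (a = 0.4359 AU/um, b = 25.32 AU)
#>   RSS 442.8, R^2 0.99310, converged: TRUE (8 iterations)
```

The ten fitted centers give nine adjacent-peak distances; their mean
1.921 µm recovers the simulated 1.92 µm spacing, and the SD (0.031 µm)
reflects fit noise at this SNR. Comparing against a published-style summary
(mean 1.80, SD 0.08, n = 9) needs no raw data:

```r
welchT(res$spacing, summaryStats(1.80, 0.08, 9),
       labels = c("measured", "reference"))
#> Welch two-sample t-test: measured vs reference
#>   statistic = 4.233, df = 10.36, p = 0.001605

# projection bias for a myocyte in focus over 70 um with a ~13.8 um slice
tiltOverestimation(tiltGeometry(70))
#> [1] 1.020018     # spacings overestimated by ~2%
```

`generateFrameStack()` + `superpose()` reproduce the frame-averaging
workflow; `steelDwass()` compares three or more groups with familywise
error control; `readFluorImage()` / `writeSpacingResult()` handle TIFF
input and CSV/JSON reports. A thin command-line wrapper with `simulate`,
`analyze`, `superpose` and `compare` subcommands is installed at
`inst/scripts/sarcospace-cli.R`.

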