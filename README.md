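# hepaticMRI

Quantitative, non-invasive MR biomarkers of the three most common diffuse
liver diseases — fibrosis, steatosis and hepatic iron overload — from
ROI-based analysis of magnitude MR images. The package is aimed at imaging
scientists who want a tested, scriptable alternative to interactive viewers
for these measurements, together with a synthetic phantom generator so every
stage can be validated end-to-end without patient data.

## The three biomarker arms

**Fibrosis (T1 / HSA calibration).** Human serum albumin (HSA) is
synthesised exclusively by the liver and its concentration falls in advanced
fibrosis, which makes it a candidate fibrosis surrogate. The package fits an
ordinary least-squares calibration of phantom T1 (ms) on HSA concentration
(%),

> T1 = β₀ + β₁ · HSA,  β₁ < 0,

reports Pearson *r* (carrying the slope's sign) and *R²*, and
inverse-predicts HSA% from a subject's liver T1 (mean of three elliptical
ROIs in Couinaud segments IV, VIII, VII). Predictions outside the calibrated
0–20% range are flagged, not clamped.

**Steatosis (two-point Dixon).** From an in-phase / opposed-phase pair,
fat-only and water-only images are reconstructed as (IP − OOP)/2 and
(IP + OOP)/2, and the fat fraction is

> FF (%) = 100 · S_F / (S_F + S_W),

graded NONE / MILD / MODERATE / SEVERE at breakpoints 6.4, 17.4 and 22.1%.
The liver-to-paravertebral-muscle signal intensity ratio
SIR = S_Liver / S_Muscle on the fat-only image provides a qualitative
cross-check (muscle is the reference tissue: it neither accumulates fat nor
stores iron).

**Iron overload (T2\* relaxometry).** Multi-echo gradient-echo liver signal
is fitted with the offset mono-exponential

> S(TE) = S₀ · exp(−TE/T2\*) + C,

by damped (Levenberg–Marquardt) least squares, after excluding echoes at or
below the background noise floor (measured in a NOISE ROI). R2\* = 1000/T2\*
(s⁻¹) is converted to liver iron concentration with Gandon's 3 T formula
LIC (µmol/g) = 0.314 · R2\* − 0.96; at 1.5 T the decay is first mapped to
its 3 T equivalent by halving T2\* (an approximation, flagged as such).
Grades: < 36 µmol/g none, 36–80 mild, > 80 severe.

## Worked example

A synthetic 3 T subject with no steatosis (true FF 3.1%) and no iron
overload (true liver T2\* 16.1 ms), analysed with the standard ROI set:

```r
library(hepaticMRI)

spec <- defaultPhantomSpec(field_t = 3.0, liver_t2star_ms = 16.1, noise_sd = 10)
gen  <- makeMultiechoSeries(spec, seed = 42, noise_model = "rician")
rois <- defaultROIs(spec)

dxspec <- defaultPhantomSpec(field_t = 3.0, liver_ff_percent = 3.1, noise_sd = 10)
dxspec@layout$t2star_ms[] <- 1e6        # negligible decay between the two echoes
dx <- makeDixonPair(dxspec, seed = 42)

runPipeline("patient3", 3.0, rois, dixon = dx$pair, series = gen$series)
#> BiomarkerReport 'patient3' (3 T)
#>   steatosis: FF = 3.1%, grade NONE
#>   iron: T2* = 16.1 ms, LIC = 19 umol/g, grade NONE
```

The fat fraction is recovered at 3.1% (below the 6.4% steatosis threshold),
and the fitted T2\* of 16.1 ms converts to R2\* = 62.1 s⁻¹ and
LIC = 0.314 · 62.1 − 0.96 = 18.5 µmol/g, printed as the rounded 19 µmol/g —
well below the 36 µmol/g overload threshold. No cross-contamination warnings
fire because both fat and iron are in their no-disease ranges.

## Package tour

| Area | Functions |
|---|---|
| Data model | `ImageFrame`, `EchoSeries`, `EllipseROI`, `DixonPair`, `readSeries`/`writeSeries`, `readROIs`/`writeROIs`, `classifyPhase` |
| ROI statistics | `roiStats`, `roiTable`, `liverSummary` |
| Fibrosis arm | `fitCalibration`, `predictHSA`, `compareT1` |
| Steatosis arm | `reconstructFatWater`, `fatFraction`, `gradeSteatosis`, `signalIntensityRatio`, `steatosisFromPair` |
| Iron arm | `fitDecay`, `decaySamples`, `licFromT2star`, `gradeIron`, `tissueDecayComparison`, `ironFromSeries` |
| Synthetic phantoms | `defaultPhantomSpec`, `defaultROIs`, `makeHSAPhantomT1Map`, `makeDixonPair`, `makeMultiechoSeries`, `phantomMeasurements` |
| Reporting | `runPipeline`, `crossContaminationWarnings`, `writeReport`/`readReport` |

The methods vignette (`vignettes/hepaticMRI-methods.Rmd`) documents the
signal models, parameter choices, numerical details and known limitations.
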