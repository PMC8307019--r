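---
title: "Models and methods behind hepaticMRI"
author: "hepaticMRI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hepaticMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaticMRI)
```

# Scope and data model

`hepaticMRI` quantifies three liver biomarkers from 2-D **magnitude** MR
images: liver T1 calibrated against human-serum-albumin (HSA) phantoms
(fibrosis arm), the two-point Dixon fat fraction and liver/muscle signal
intensity ratio (steatosis arm), and multi-echo T2\* relaxometry converted
to liver iron concentration (iron arm). Complex or phase data are never
represented: every input is an `ImageFrame` holding a non-negative pixel
matrix plus the metadata the analysis needs (echo time TE in ms, field
strength 1.5 or 3 T, sequence role). A multi-echo acquisition is an
`EchoSeries` of frames sharing geometry with strictly increasing TE.

Coordinates are 1-based `(row, col)` in R's native matrix convention, used
identically for pixel indexing and ROI geometry. A pixel belongs to an
`EllipseROI` when its center satisfies
$((r-r_0)/a)^2 + ((c-c_0)/b)^2 \le 1$, boundary included — a deterministic
rule matching common viewer behaviour. ROI placement is user input
throughout: the protocol requires three liver ROIs (Couinaud segments IV,
VIII, VII), two paravertebral-muscle ROIs, spleen, abdominal fat, and a
background NOISE ROI, all drawn to avoid vessels and artifacts, and the
package deliberately does not auto-place or segment.

Standard-format I/O goes through NIfTI (`RNifti`) plus a JSON sidecar
carrying `te_ms`, `field_t` and optional per-frame roles; the writer stores
64-bit floats so a write/read round trip is bit-exact. DICOM directories are
not read directly (no DICOM reader is part of the package's dependency set);
converters such as dcm2niix produce exactly the supported layout.

## In-phase / opposed-phase classification

Water and fat protons precess at different rates, so their transverse
magnetisations periodically align (in-phase, IP) and oppose (opposed-phase,
OOP). At 1.5 T the period corresponds to a base echo spacing of 2.4 ms: odd
multiples of 2.4 ms are OOP, even multiples IP. At 3 T chemical-shift
evolution is twice as fast and the base spacing halves to 1.2 ms.
`classifyPhase()` matches a TE to the nearest multiple of the base spacing
within ±0.1 ms (absorbing DICOM header rounding) and errors on off-grid TEs
rather than guessing.

# Fibrosis arm: T1 vs HSA

The liver synthesises albumin, and serum albumin falls substantially in
advanced fibrosis; across phantoms of increasing HSA concentration, T1
falls. `fitCalibration()` regresses T1 (ms, response) on concentration
(%, predictor) — the direction in which such calibrations are plotted — and
`predictHSA()` solves the fitted line rather than regressing concentration
on T1. Design choices:

* At least 3 distinct concentrations are required; identical concentrations
  are a degenerate design and error out.
* Pearson *r* carries the sign of the slope and `r_squared` is exactly
  `r_pearson^2`; on an exact line *r* is ±1 by construction.
* A non-negative slope triggers a warning: it is not a physically valid HSA
  calibration.
* No fat/iron correction of T1 is attempted, but `runPipeline()` raises
  `T1_CONFOUNDED_BY_FAT_OR_IRON` when the same subject's fat fraction or LIC
  exceeds its no-disease threshold, since both alter T1.
* HSA prediction is an exploratory biomarker: no validated T1-to-stage or
  HSA-to-stage rule exists, so out-of-range predictions (outside 0–20%) are
  flagged, never clamped, and no fibrosis staging is offered.

The liver value of a subject is the unweighted mean of the three liver-ROI
means (`liverSummary()`), reported with the sample SD of those three means.
Reference reports of this protocol quote a much smaller across-ROI "±"
figure than the sample SD of their own printed ROI means; since the formula
behind that figure is not stated, this package reports the plain sample SD
and makes no claim of reproducing the published dispersion.

# Steatosis arm: two-point Dixon

With water signal $W$ and fat signal $F$ per voxel, the ideal two-point
model gives $IP = W + F$ and $OOP = |W - F|$. `reconstructFatWater()` uses
the halved convention $fat = (IP - OOP)/2$, $water = (IP + OOP)/2$, chosen
so that the conservation identity $fat + water = IP$ holds exactly; because
the fat fraction

$$FF\,(\%) = 100\,\frac{S_F}{S_F + S_W}$$

is scale-invariant, the halved and unhalved conventions yield identical FF.
The printed form of this ratio is typographically ambiguous in places in the
literature; the reading implemented here is the only one bounded in
[0, 100]. Negative fat pixels (noise around zero fat) are clipped to zero in
the returned frame; the raw subtraction is also returned so the conservation
identity remains checkable.

Grading uses breakpoints 6.4 / 17.4 / 22.1%. Interior thresholds are
left-closed (6.4 grades MILD, 17.4 MODERATE); the severe bound follows the
strict inequality in which it is quoted (FF > 22.1%), so 22.1 itself grades
MODERATE. `gradeSteatosis()` is a pure step function with exactly these
three breakpoints.

Magnitude-only two-point Dixon cannot distinguish $FF$ from $100 - FF$
(fat–water dominance swap), so estimates live in [0, 50]; estimates within
5 percentage points of the 50% cancellation limit carry an
`FF_DOMINANCE_AMBIGUOUS` flag. Clinically reported fat fractions in this
protocol are all well below 50%.

The SIR method divides the mean of the three liver-ROI means by the mean of
the two muscle-ROI means on the same frame. On fat-only images SIR rises
with steatosis; on IP images it falls with iron overload. Paravertebral
muscle is the reference because it neither accumulates fat nor stores iron.

# Iron arm: offset-exponential T2\* relaxometry

Paramagnetic iron shortens T2\*, so the liver ROI mean across echoes is
fitted with

$$S(TE) = S_0\,e^{-TE/T2^*} + C,$$

where $C$ models the magnitude-image noise floor. Numerical choices in
`fitDecay()`:

* **Truncation rule.** Echoes whose signal is at or below the measured
  noise floor (NOISE-ROI mean) are excluded before fitting: once the curve
  sinks into the floor, later echoes carry no decay information and bias
  T2\* upward, which in turn underestimates iron. At least 4 usable echoes
  must remain; otherwise the error message advises shorter echo times or a
  lower field. Because $C$ is part of the model, keeping sub-floor echoes is
  not catastrophic — the test suite verifies in simulation that the full fit
  is no worse than the truncated one — but truncation is the default
  behaviour and matches how the floor hazard is described in the field.
* **Optimizer.** Levenberg–Marquardt damped least squares
  (`minpack.lm::nls.lm`) with analytic residuals and Jacobian, at most 200
  iterations, relative tolerance $10^{-8}$ — deterministic given inputs.
  Three deterministic starts are tried and the lowest-RSS solution kept: a
  log-linear regression of $\log(S - \text{floor})$ on TE with $C$ started
  at the floor; a two-point T2\* estimate from the first two echoes with
  $C = 0$; and the log-linear start with $C$ at half the minimum signal.
  Multiple starts protect against the flat $S_0$–$T2^*$–$C$ valley that a
  single poor start cannot escape.
* **Bounds.** $S_0 \ge 0$, $T2^* > 0$, and $0 \le C \le \min(S)$: the
  offset physically sits below every retained sample. The bound on $C$ is
  how "initialised at, and bounded near, the measured noise level" is made
  concrete.
* **Degenerate inputs.** Constant signal, or a fitted T2\* beyond 100× the
  longest TE (no measurable decay over the sampled echoes), is an error,
  not a number.
* **Fatty livers.** When the subject's FF exceeds the 6.4% steatosis
  threshold, the fat–water oscillation between IP and OOP echoes corrupts
  the mono-exponential; `use_phases = "IP"` restricts the fit to in-phase
  echoes, and `runPipeline()` applies this automatically when the steatosis
  arm measured FF ≥ 6.4%.

## LIC conversion and its 1.5 T approximation

At 3 T, LIC (µmol/g dry weight) $= 0.314 \cdot R2^* - 0.96$ with
$R2^* = 1000/T2^*$ (s⁻¹). The published conversion is stated for 3 T; T2\*
is approximately double at 1.5 T, so the 1.5 T path first halves T2\*
(doubles R2\*) and then applies the same formula. This reproduces published
low-iron 1.5 T cases to within rounding (17.5 ms → 34.9 vs a printed 34
µmol/g) but overshoots at severe overload (6.2 ms → 100.3 vs a printed 95
µmol/g), because the original 1.5 T calibration is tabulated software
internals not derivable from the published text. The package therefore
flags every 1.5 T conversion `APPROXIMATE_LIC_1P5T` and does not attempt to
reverse-engineer the exact 1.5 T table. Raw LIC is reported as a float and
clamped at zero (flagged) where very long T2\* drives the formula negative;
integer half-up rounding happens only in the report layer, since reference
values are printed as integers. Grading: `< 36` none, `36–80` mild, `> 80`
severe, applied to the raw (unrounded) LIC.

# Synthetic phantom generator

The generator exists so that every pipeline stage is testable against known
ground truth with no scanner data; each generator returns its truth
alongside the images, and a fixed seed gives bit-identical output.

* `makeHSAPhantomT1Map()` emulates a T1 map of an HSA vial rack: circular
  regions whose pixel values follow the true line
  $T1 = \beta_0 + \beta_1 \cdot \text{conc}$ plus Gaussian noise. The
  default concentrations (7 vials over 0–20%) match the modelled phantom
  set; vial overlap is a hard error.
* `makeDixonPair()` and `makeMultiechoSeries()` rasterise a `PhantomSpec` —
  non-overlapping labelled ellipses with per-region T1, T2\*, fat fraction
  and proton density — under the two-point model: $W = pd(1 - FF/100)$,
  $F = pd \cdot FF/100$, IP signal $(W+F)e^{-TE/T2^*}$, OOP signal
  $|W-F|e^{-TE/T2^*}$, with phases assigned per TE by `classifyPhase()`.
  Defaults per field follow the modelled acquisitions: 10 echoes every
  2.4 ms at 1.5 T, 12 echoes every 1.2 ms at 3 T, on a 128×128 matrix.
* **Noise.** Gaussian noise added to the magnitude and clipped at zero
  (adequate at ROI-mean level for SNR ≥ 10), or exact Rician noise
  ($\sqrt{(S+n_1)^2 + n_2^2}$), which produces the magnitude noise floor
  organically — the Rician model is what the T2\* recovery tests use. The
  default `noise_sd = 20` against a liver proton density of 1000 is SNR 50.
* The default abdomen layout gives muscle a 5% fat fraction — the small
  myocellular lipid content real muscle has — which also keeps the muscle
  reference signal strictly positive on fat-only images (the SIR
  denominator). Fat chemical shift is represented only through the IP/OOP
  dichotomy (two-point model), matching the modelled acquisition, not
  continuous dephasing. T1 maps are generated directly as parameter images;
  no inversion-recovery simulation is attempted because scanners supply
  reconstructed T1 maps.

**What passing tests do and do not show.** The phantoms are piecewise-
constant ellipses with ideal two-point signal behaviour: no anatomy, no B1
inhomogeneity, no motion, no multi-peak fat spectrum, no T1 weighting of the
echo train. Recovery results on them validate the estimators' arithmetic
and noise behaviour, not robustness to those real-world effects. In
particular, Dixon FF recovery is validated in the long-T2\* regime
(regional T2\* set to $10^6$ ms) to isolate the Dixon arithmetic: with
realistic T2\* the decay between the OOP and IP echo times biases magnitude
FF downward — that bias is inherent to uncorrected two-point Dixon (it is
why T2\*-corrected PDFF methods exist) and is surfaced by the fat–iron
cross-contamination warnings rather than corrected.

# Problem sizes in the test suite

The statistical tests run, per fixed seed: 1000 seven-point calibration
replicates at noise SD 5% of the 600 ms dynamic range (negative slope
recovered in ≥ 99%); 200 ten-echo 1.5 T series at SNR 50 with Rician noise
and true T2\* spanning 3–30 ms (median relative T2\* error ≤ 5%); Dixon
recovery at true FF {3, 10, 17, 25}% with noise SD 2% of signal (each
within 1 percentage point, strictly increasing); and ten fixed decay
instances on which the Levenberg–Marquardt fit is checked against an
exhaustive lattice search over $(T2^*, S_0, C)$ at 0.1 ms resolution in
T2\*. These sizes were chosen as the smallest that make the statistical
claims meaningful.

# Warning rules

All thresholds live in the grading functions with the standard defaults
(6.4 / 17.4 / 22.1% FF; 36 / 80 µmol/g LIC) and are overridable.
`crossContaminationWarnings()` encodes the mutual interference of the arms:
`FAT_AFFECTS_T2STAR` at FF ≥ 6.4%, `IRON_AFFECTS_FF` at LIC ≥ 36 µmol/g,
and `OMIT_FF` at LIC > 80 µmol/g (under severe iron overload the fat
calculation is best omitted). Every warning is reproducible from the
numeric fields of the report.

# Known limitations

* Single-slice, ROI-level analysis only: no pixel-wise T2\* maps, no 3-D
  handling beyond selecting a slice, no automatic slice selection (an
  explicit index is required because no selection criterion is defined in
  the protocol).
* The 1.5 T LIC path is approximate (see above).
* No multi-peak fat modelling or T2\*-corrected PDFF; magnitude-only Dixon
  caps estimable FF at 50%.
* No fibrosis staging: the T1–HSA relation is exploratory.
* R2 (spin-echo) iron methods, scanner-side B1-corrected T1 reconstruction,
  and vendor harmonisation are out of scope.
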