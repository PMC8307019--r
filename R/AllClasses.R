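#' @import methods
NULL

## Canonical vocabularies ----------------------------------------------------

#' Image roles and ROI labels
#'
#' `imageRoles()` returns the sequence roles an [ImageFrame] may carry;
#' `roiLabels()` returns the canonical ROI labels of the acquisition protocol
#' (three liver ROIs in Couinaud segments IV, VIII and VII, left/right
#' paravertebral muscle, spleen, abdominal fat, and a background-noise ROI).
#' Arbitrary labels are permitted on an [EllipseROI]; the canonical ones are
#' what the pipeline helpers look up by name.
#'
#' @return Character vector of role or label names.
#' @export
imageRoles <- function() {
  c("T1_MAP", "IN_PHASE", "OPPOSED_PHASE", "FAT_ONLY", "WATER_ONLY")
}

#' @rdname imageRoles
#' @export
roiLabels <- function() {
  c("LIVER_IV", "LIVER_VIII", "LIVER_VII", "MUSCLE_L", "MUSCLE_R",
    "SPLEEN", "ABDOMINAL_FAT", "NOISE")
}

.LIVER_LABELS  <- c("LIVER_IV", "LIVER_VIII", "LIVER_VII")
.MUSCLE_LABELS <- c("MUSCLE_L", "MUSCLE_R")

## ImageFrame ----------------------------------------------------------------

#' ImageFrame: one 2-D magnitude MR image with acquisition metadata
#'
#' The elementary container of the package: a single magnitude image (pixel
#' values in arbitrary units, all non-negative) together with the metadata the
#' analysis needs — echo time (ms), main magnetic field (tesla, 1.5 or 3.0),
#' the sequence role of the image, and the pixel spacing.
#'
#' Coordinates throughout the package are 1-based `(row, col)` in R's native
#' matrix convention; ROI geometry uses the same convention.
#'
#' @slot pixels numeric matrix, non-negative (magnitude image).
#' @slot te_ms echo time in ms; `NA` for parameter maps (role `T1_MAP`) where
#'   pixel values are themselves relaxation times.
#' @slot field_t main field in tesla, 1.5 or 3.0.
#' @slot role one of [imageRoles()].
#' @slot pixel_spacing_mm `(row, col)` spacing in mm.
#'
#' @param pixels,te_ms,field_t,role,pixel_spacing_mm see slots.
#' @return An `ImageFrame` object.
#' @examples
#' f <- ImageFrame(matrix(100, 8, 8), te_ms = 2.4, field_t = 1.5,
#'                 role = "OPPOSED_PHASE")
#' echoTime(f)
#' @export ImageFrame
#' @exportClass ImageFrame
ImageFrame <- function(pixels, te_ms = NA_real_, field_t = 1.5,
                       role = "T1_MAP", pixel_spacing_mm = c(1, 1)) {
  new("ImageFrame", pixels = pixels, te_ms = te_ms, field_t = field_t,
      role = role, pixel_spacing_mm = pixel_spacing_mm)
}

setClass("ImageFrame",
  representation(
    pixels           = "matrix",
    te_ms            = "numeric",
    field_t          = "numeric",
    role             = "character",
    pixel_spacing_mm = "numeric"
  ),
  prototype(
    te_ms            = NA_real_,
    field_t          = 1.5,
    role             = "T1_MAP",
    pixel_spacing_mm = c(1, 1)
  )
)

setValidity("ImageFrame", function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.numeric(px)) msg <- c(msg, "'pixels' must be a numeric matrix")
  if (anyNA(px) || any(!is.finite(px)))
    msg <- c(msg, "'pixels' must be finite (magnitude image)")
  else if (any(px < 0))
    msg <- c(msg, "'pixels' must be non-negative (magnitude image)")
  if (length(object@role) != 1L || !object@role %in% imageRoles())
    msg <- c(msg, sprintf("'role' must be one of: %s",
                          paste(imageRoles(), collapse = ", ")))
  if (length(object@field_t) != 1L || !object@field_t %in% c(1.5, 3.0))
    msg <- c(msg, "'field_t' must be 1.5 or 3.0")
  if (length(object@te_ms) != 1L)
    msg <- c(msg, "'te_ms' must be a single value (NA allowed for maps)")
  else if (object@role %in% c("IN_PHASE", "OPPOSED_PHASE") &&
           (is.na(object@te_ms) || object@te_ms <= 0))
    msg <- c(msg, "'te_ms' must be > 0 for IN_PHASE/OPPOSED_PHASE frames")
  if (length(object@pixel_spacing_mm) != 2L || any(object@pixel_spacing_mm <= 0))
    msg <- c(msg, "'pixel_spacing_mm' must be two positive values")
  if (length(msg)) msg else TRUE
})

## EchoSeries ----------------------------------------------------------------

#' EchoSeries: an ordered multi-echo collection of ImageFrames
#'
#' Frames share matrix geometry and field strength and are ordered by strictly
#' increasing echo time, as produced by a multi-echo gradient-echo acquisition
#' (10 echoes every 2.4 ms at 1.5 T, 12 echoes every 1.2 ms at 3 T in the
#' protocol this package models).
#'
#' @slot frames list of [ImageFrame] with strictly increasing `te_ms`.
#' @slot field_t tesla.
#' @slot echo_spacing_ms nominal inter-echo gap in ms (`NA` if irregular).
#'
#' @param frames,field_t,echo_spacing_ms see slots; `field_t` defaults to the
#'   frames' common field.
#' @return An `EchoSeries` object.
#' @export EchoSeries
#' @exportClass EchoSeries
EchoSeries <- function(frames, field_t = NULL, echo_spacing_ms = NA_real_) {
  if (is.null(field_t)) {
    ft <- unique(vapply(frames, function(f) f@field_t, numeric(1)))
    field_t <- ft[1]
  }
  new("EchoSeries", frames = frames, field_t = field_t,
      echo_spacing_ms = echo_spacing_ms)
}

setClass("EchoSeries",
  representation(
    frames          = "list",
    field_t         = "numeric",
    echo_spacing_ms = "numeric"
  ),
  prototype(echo_spacing_ms = NA_real_)
)

setValidity("EchoSeries", function(object) {
  msg <- character()
  fr <- object@frames
  if (length(fr) < 1L) msg <- c(msg, "need at least one frame")
  if (!all(vapply(fr, is, logical(1), "ImageFrame")))
    return("all 'frames' must be ImageFrame objects")
  dims <- vapply(fr, function(f) dim(f@pixels), integer(2))
  if (length(fr) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    msg <- c(msg, "all frames must share matrix dimensions")
  te <- vapply(fr, function(f) f@te_ms, numeric(1))
  if (!anyNA(te) && length(te) > 1L && any(diff(te) <= 0))
    msg <- c(msg, "'te_ms' must be strictly increasing across frames")
  ft <- vapply(fr, function(f) f@field_t, numeric(1))
  if (any(ft != object@field_t))
    msg <- c(msg, "all frames must share the series field strength")
  if (length(msg)) msg else TRUE
})

## ROI geometry and statistics ------------------------------------------------

#' EllipseROI: an elliptical region of interest
#'
#' Elliptical ROI in image coordinates: 1-based `(row, col)` center and
#' `(a, b)` semi-axes in pixels, where `a` applies along rows and `b` along
#' columns. A pixel belongs to the ROI when its center satisfies
#' \eqn{((r - r_0)/a)^2 + ((c - c_0)/b)^2 \le 1} (boundary included).
#'
#' @slot center numeric `(row, col)`, pixels.
#' @slot semi_axes numeric `(a, b)`, pixels, both `> 0`.
#' @slot label character label; see [roiLabels()] for the canonical set.
#'
#' @param center,semi_axes,label see slots.
#' @return An `EllipseROI` object.
#' @examples
#' EllipseROI(center = c(20, 30), semi_axes = c(5, 8), label = "LIVER_IV")
#' @export EllipseROI
#' @exportClass EllipseROI
EllipseROI <- function(center, semi_axes, label = "LIVER_IV") {
  new("EllipseROI", center = center, semi_axes = semi_axes, label = label)
}

setClass("EllipseROI",
  representation(center = "numeric", semi_axes = "numeric", label = "character"),
  prototype(label = "LIVER_IV")
)

setValidity("EllipseROI", function(object) {
  msg <- character()
  if (length(object@center) != 2L || anyNA(object@center))
    msg <- c(msg, "'center' must be (row, col)")
  if (length(object@semi_axes) != 2L || any(object@semi_axes <= 0))
    msg <- c(msg, "'semi_axes' must be two positive values")
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "'label' must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' ROIStats: summary statistics of one ROI on one image
#'
#' @slot label ROI label.
#' @slot mean mean signal over the enclosed pixels (a.u.).
#' @slot sd sample standard deviation (n - 1 denominator; 0 for a single
#'   pixel).
#' @slot n_pixels number of enclosed pixels.
#'
#' @param label,mean,sd,n_pixels see slots.
#' @return An `ROIStats` object.
#' @export ROIStats
#' @exportClass ROIStats
ROIStats <- setClass("ROIStats",
  representation(label = "character", mean = "numeric", sd = "numeric",
                 n_pixels = "integer")
)

setValidity("ROIStats", function(object) {
  msg <- character()
  if (object@n_pixels < 1L) msg <- c(msg, "'n_pixels' must be >= 1")
  if (is.na(object@sd) || object@sd < 0) msg <- c(msg, "'sd' must be >= 0")
  if (length(msg)) msg else TRUE
})

## Dixon pair ----------------------------------------------------------------

#' DixonPair: matched in-phase / opposed-phase frames
#'
#' @slot ip [ImageFrame] with role `IN_PHASE`.
#' @slot oop [ImageFrame] with role `OPPOSED_PHASE`.
#'
#' @param ip,oop see slots.
#' @return A `DixonPair` object.
#' @export DixonPair
#' @exportClass DixonPair
DixonPair <- setClass("DixonPair",
  representation(ip = "ImageFrame", oop = "ImageFrame")
)

setValidity("DixonPair", function(object) {
  msg <- character()
  if (object@ip@role != "IN_PHASE") msg <- c(msg, "'ip' must have role IN_PHASE")
  if (object@oop@role != "OPPOSED_PHASE")
    msg <- c(msg, "'oop' must have role OPPOSED_PHASE")
  if (!identical(dim(object@ip@pixels), dim(object@oop@pixels)))
    msg <- c(msg, "IP and OOP frames must have matching dimensions")
  if (object@ip@field_t != object@oop@field_t)
    msg <- c(msg, "IP and OOP frames must share field strength")
  if (length(msg)) msg else TRUE
})

## Model / result classes -----------------------------------------------------

#' CalibrationModel: fitted linear T1-vs-HSA relation
#'
#' Ordinary least squares of T1 (ms) on HSA concentration (%), with Pearson
#' correlation (carrying the sign of the slope) and coefficient of
#' determination. For a physically sensible HSA calibration the slope is
#' negative: T1 falls as protein concentration rises.
#'
#' @slot slope ms per percentage point.
#' @slot intercept ms (T1 at 0% HSA).
#' @slot r_pearson Pearson correlation between concentration and T1.
#' @slot r_squared `r_pearson^2`.
#' @slot slope_se standard error of the slope (ms/%).
#' @slot n number of calibration points.
#' @export
#' @exportClass CalibrationModel
CalibrationModel <- setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric",
                 r_pearson = "numeric", r_squared = "numeric",
                 slope_se = "numeric", n = "integer")
)

setValidity("CalibrationModel", function(object) {
  if (abs(object@r_squared - object@r_pearson^2) > 1e-9)
    return("'r_squared' must equal r_pearson^2")
  TRUE
})

#' DecayFit: fitted offset mono-exponential T2* decay
#'
#' Result of fitting \eqn{S(TE) = S_0 \exp(-TE/T2^*) + C} to multi-echo ROI
#' means, after truncating echoes at or below the background-noise floor.
#'
#' @slot s0 extrapolated signal at TE = 0 (a.u.).
#' @slot t2star_ms effective transverse relaxation time, ms.
#' @slot noise_offset fitted constant offset C (a.u.), `>= 0`.
#' @slot rss residual sum of squares of the fit.
#' @slot n_used echoes retained after noise-floor truncation.
#' @slot n_excluded echoes dropped by the truncation rule.
#' @slot te_ms,signal the retained samples (for plotting/diagnostics).
#' @export
#' @exportClass DecayFit
DecayFit <- setClass("DecayFit",
  representation(s0 = "numeric", t2star_ms = "numeric", noise_offset = "numeric",
                 rss = "numeric", n_used = "integer", n_excluded = "integer",
                 te_ms = "numeric", signal = "numeric")
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@t2star_ms <= 0) msg <- c(msg, "'t2star_ms' must be > 0")
  if (object@noise_offset < 0) msg <- c(msg, "'noise_offset' must be >= 0")
  if (object@n_used < 3L) msg <- c(msg, "'n_used' must be >= 3")
  if (length(msg)) msg else TRUE
})

#' SteatosisResult: fat-fraction and SIR summary for one subject
#'
#' @slot ff_percent fat fraction in percent (mean over the three liver ROIs).
#' @slot ff_sd sample SD of the per-ROI fat fractions (percentage points).
#' @slot sir liver / paravertebral-muscle signal intensity ratio.
#' @slot grade one of NONE, MILD, MODERATE, SEVERE.
#' @slot flags character flags (e.g. fat/water dominance ambiguity).
#' @export
#' @exportClass SteatosisResult
SteatosisResult <- setClass("SteatosisResult",
  representation(ff_percent = "numeric", ff_sd = "numeric", sir = "numeric",
                 grade = "character", flags = "character"),
  prototype(flags = character())
)

setValidity("SteatosisResult", function(object) {
  msg <- character()
  if (object@ff_percent < 0 || object@ff_percent > 100)
    msg <- c(msg, "'ff_percent' must be in [0, 100]")
  if (!is.na(object@sir) && object@sir <= 0) msg <- c(msg, "'sir' must be > 0")
  if (!object@grade %in% c("NONE", "MILD", "MODERATE", "SEVERE"))
    msg <- c(msg, "invalid steatosis grade")
  if (length(msg)) msg else TRUE
})

#' IronResult: T2*, R2*, LIC and iron-overload grade
#'
#' R2* is reported in 1/s (`R2* = 1000/T2*` with T2* in ms); LIC in µmol/g dry
#' weight via Gandon's conversion. At 1.5 T the conversion is approximate (the
#' published formula is stated for 3 T and mapped across field by the
#' T2*-halving rule), which the `approximate` slot records.
#'
#' @slot t2star_ms fitted T2*, ms.
#' @slot r2star_s R2* in 1/s.
#' @slot lic_umol_g liver iron concentration, raw value.
#' @slot lic_rounded LIC rounded half-up to the nearest integer.
#' @slot grade one of NONE, MILD, SEVERE.
#' @slot field_t tesla.
#' @slot approximate TRUE for the 1.5 T conversion path.
#' @slot flags character flags.
#' @export
#' @exportClass IronResult
IronResult <- setClass("IronResult",
  representation(t2star_ms = "numeric", r2star_s = "numeric",
                 lic_umol_g = "numeric", lic_rounded = "numeric",
                 grade = "character", field_t = "numeric",
                 approximate = "logical", flags = "character"),
  prototype(flags = character(), approximate = FALSE)
)

setValidity("IronResult", function(object) {
  msg <- character()
  if (abs(object@r2star_s * object@t2star_ms - 1000) > 1e-6 * 1000)
    msg <- c(msg, "'r2star_s' must equal 1000/t2star_ms")
  if (!object@grade %in% c("NONE", "MILD", "SEVERE"))
    msg <- c(msg, "invalid iron grade")
  if (!object@field_t %in% c(1.5, 3.0))
    msg <- c(msg, "'field_t' must be 1.5 or 3.0")
  if (length(msg)) msg else TRUE
})

setClassUnion("SteatosisResultOrNULL", c("SteatosisResult", "NULL"))
setClassUnion("IronResultOrNULL", c("IronResult", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' BiomarkerReport: per-subject summary across the three biomarker arms
#'
#' Collects whatever arms were run for one subject: liver T1 summary with an
#' optional HSA% estimate (fibrosis arm), the steatosis result, the iron
#' result, and the cross-contamination warnings derived from the numeric
#' fields.
#'
#' @slot subject_id character.
#' @slot field_t tesla.
#' @slot t1 `NULL` or list with `mean_ms`, `sd_ms`, and optionally
#'   `hsa_percent`, `hsa_out_of_range`.
#' @slot steatosis `NULL` or [SteatosisResult].
#' @slot iron `NULL` or [IronResult].
#' @slot warnings character vector of warning codes.
#' @export
#' @exportClass BiomarkerReport
BiomarkerReport <- setClass("BiomarkerReport",
  representation(subject_id = "character", field_t = "numeric",
                 t1 = "listOrNULL", steatosis = "SteatosisResultOrNULL",
                 iron = "IronResultOrNULL", warnings = "character"),
  prototype(t1 = NULL, steatosis = NULL, iron = NULL, warnings = character())
)

## PhantomSpec ----------------------------------------------------------------

#' PhantomSpec: layout and tissue parameters of a synthetic phantom
#'
#' Describes a digital phantom as a set of labelled, non-overlapping elliptical
#' regions on a background, each with its own true tissue parameters: T1 (ms),
#' T2* (ms), fat fraction (%) and proton density (a.u.). The generators in
#' this package rasterise the layout into [ImageFrame]s under the two-point
#' Dixon signal model with additive noise.
#'
#' @slot layout data.frame with columns `label, row, col, a, b, t1_ms,
#'   t2star_ms, ff_percent, pd`.
#' @slot dim image dimensions `(nrow, ncol)`.
#' @slot field_t tesla.
#' @slot noise_sd Gaussian noise SD (a.u.).
#' @export
#' @exportClass PhantomSpec
PhantomSpec <- setClass("PhantomSpec",
  representation(layout = "data.frame", dim = "integer", field_t = "numeric",
                 noise_sd = "numeric")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  need <- c("label", "row", "col", "a", "b", "t1_ms", "t2star_ms",
            "ff_percent", "pd")
  if (!all(need %in% names(object@layout)))
    return(sprintf("layout must have columns: %s", paste(need, collapse = ", ")))
  if (object@noise_sd < 0) msg <- c(msg, "'noise_sd' must be >= 0")
  if (!object@field_t %in% c(1.5, 3.0))
    msg <- c(msg, "'field_t' must be 1.5 or 3.0")
  if (any(object@layout$ff_percent < 0 | object@layout$ff_percent > 100))
    msg <- c(msg, "'ff_percent' must be in [0, 100]")
  if (any(object@layout$pd < 0)) msg <- c(msg, "'pd' must be >= 0")
  ## exact overlap check on the pixel raster
  if (nrow(object@layout) > 1L) {
    cover <- matrix(0L, object@dim[1], object@dim[2])
    for (i in seq_len(nrow(object@layout))) {
      m <- .ellipseMask(object@dim, c(object@layout$row[i], object@layout$col[i]),
                        c(object@layout$a[i], object@layout$b[i]))
      cover <- cover + m
    }
    if (any(cover > 1L)) msg <- c(msg, "layout regions overlap on the pixel grid")
  }
  if (length(msg)) msg else TRUE
})
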