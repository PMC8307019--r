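#' Reconstruct fat-only and water-only images from an IP/OOP pair
#'
#' Two-point Dixon arithmetic: the in-phase image carries water + fat signal
#' and the opposed-phase image water - fat, so
#' `fat = (IP - OOP)/2` and `water = (IP + OOP)/2`. The factor 1/2 makes the
#' conservation identity `fat_raw + water = IP` hold exactly; fat fraction is
#' scale-invariant, so either halved or unhalved convention yields identical
#' FF. Negative fat pixels (noise around zero fat) are clipped to 0 in the
#' `fat_only` frame; the unclipped subtraction is returned as the plain
#' matrix `fat_raw` so the conservation identity can be verified.
#'
#' @param pair a [DixonPair], or an IP [ImageFrame] when `oop` is given.
#' @param oop opposed-phase [ImageFrame] (signature 2).
#' @return list with `fat_only` and `water_only` [ImageFrame]s (roles
#'   `FAT_ONLY`, `WATER_ONLY`) and `fat_raw` (pre-clipping matrix).
#' @export
setGeneric("reconstructFatWater",
           function(pair, oop) standardGeneric("reconstructFatWater"))

#' @rdname reconstructFatWater
setMethod("reconstructFatWater", signature("DixonPair", "missing"),
  function(pair, oop) {
    .reconFW(pair@ip, pair@oop)
  })

#' @rdname reconstructFatWater
setMethod("reconstructFatWater", signature("ImageFrame", "ImageFrame"),
  function(pair, oop) {
    .reconFW(pair, oop)
  })

.reconFW <- function(ip, oop) {
  if (!identical(dim(ip@pixels), dim(oop@pixels)))
    .stopf("IP and OOP frames have mismatched dimensions (%s vs %s)",
           paste(dim(ip@pixels), collapse = "x"),
           paste(dim(oop@pixels), collapse = "x"))
  fat_raw <- (ip@pixels - oop@pixels) / 2
  water <- (ip@pixels + oop@pixels) / 2
  list(
    fat_only = ImageFrame(pixels = pmax(fat_raw, 0), te_ms = NA_real_,
                          field_t = ip@field_t, role = "FAT_ONLY",
                          pixel_spacing_mm = ip@pixel_spacing_mm),
    water_only = ImageFrame(pixels = water, te_ms = NA_real_,
                            field_t = ip@field_t, role = "WATER_ONLY",
                            pixel_spacing_mm = ip@pixel_spacing_mm),
    fat_raw = fat_raw
  )
}

#' Fat fraction from fat and water signal
#'
#' \deqn{FF\,(\%) = 100 \cdot S_F / (S_F + S_W)}
#' the percentage of fat signal over total (fat + water) liver signal,
#' measured on fat-only and water-only images. Scale-invariant in the common
#' signal units.
#'
#' @param s_fat fat signal (a.u.), `>= 0`.
#' @param s_water water signal (a.u.), `>= 0`.
#' @return fat fraction in percent.
#' @examples
#' fatFraction(1, 1)  # 50
#' @export
fatFraction <- function(s_fat, s_water) {
  if (any(s_fat < 0) || any(s_water < 0))
    .stopf("fat and water signals must be non-negative")
  tot <- s_fat + s_water
  if (any(tot == 0)) .stopf("zero total (fat + water) signal")
  100 * s_fat / tot
}

#' Grade steatosis from fat fraction
#'
#' Four-grade classification on the fat-fraction scale: below 6.4% no
#' steatosis, 6.4–17.4% mild, 17.4–22.1% moderate, above 22.1% severe.
#' Interior thresholds are left-closed (6.4 itself grades MILD, 17.4
#' MODERATE); the severe bound is strict, so 22.1 itself grades MODERATE.
#'
#' @param ff_percent fat fraction(s) in percent, `[0, 100]`.
#' @param thresholds the three breakpoints, overridable.
#' @return character vector of grades in
#'   `{"NONE", "MILD", "MODERATE", "SEVERE"}`.
#' @examples
#' gradeSteatosis(c(3.1, 16.8, 17.5, 24.8))
#' @export
gradeSteatosis <- function(ff_percent, thresholds = c(6.4, 17.4, 22.1)) {
  if (any(ff_percent < 0 | ff_percent > 100))
    .stopf("'ff_percent' must be in [0, 100]")
  ifelse(ff_percent < thresholds[1], "NONE",
  ifelse(ff_percent < thresholds[2], "MILD",
  ifelse(ff_percent <= thresholds[3], "MODERATE", "SEVERE")))
}

#' Liver / paravertebral-muscle signal intensity ratio
#'
#' \deqn{SIR = S_{Liver} / S_{Paravertebral\ muscles}}
#' with the liver signal the mean of the three liver-ROI means and the muscle
#' signal the mean of the two paravertebral-muscle ROI means, all measured on
#' the same frame. Paravertebral muscle is the reference tissue: it neither
#' accumulates fat in steatosis nor stores iron, so SIR rises with steatosis
#' on fat-only images and falls with iron overload on in-phase images.
#'
#' @param liver three liver [ROIStats] (list) or their means (numeric).
#' @param muscles two muscle [ROIStats] (list) or their means (numeric).
#' @return the ratio (dimensionless).
#' @export
signalIntensityRatio <- function(liver, muscles) {
  lm_ <- if (is.numeric(liver)) liver
         else vapply(liver, function(s) s@mean, numeric(1))
  mm <- if (is.numeric(muscles)) muscles
        else vapply(muscles, function(s) s@mean, numeric(1))
  if (length(lm_) != 3L) .stopf("expected 3 liver ROIs, got %d", length(lm_))
  if (length(mm) != 2L) .stopf("expected 2 muscle ROIs, got %d", length(mm))
  denom <- mean(mm)
  if (denom <= 0) .stopf("zero or negative muscle reference signal")
  mean(lm_) / denom
}

#' Full steatosis analysis of a Dixon pair
#'
#' Reconstructs fat-only / water-only images, measures the three liver ROIs on
#' each, forms a per-ROI fat fraction, and summarises as mean +/- sample SD
#' across ROIs; SIR is computed on the fat-only image against the two muscle
#' ROIs. Scanner-provided fat-only/water-only frames can be passed directly
#' via `fat_water`.
#'
#' Magnitude-only two-point Dixon cannot distinguish fat fractions above 50%
#' (fat-water dominance swap), so estimates live in `[0, 50]`; values within
#' 5 percentage points of the 50% cancellation limit are flagged
#' `FF_DOMINANCE_AMBIGUOUS`.
#'
#' @param pair a [DixonPair] (ignored when `fat_water` is supplied).
#' @param rois named list of [EllipseROI] containing the three liver labels
#'   and, for SIR, `MUSCLE_L`/`MUSCLE_R`.
#' @param fat_water optional list with `fat_only` and `water_only`
#'   [ImageFrame]s.
#' @return A [SteatosisResult].
#' @export
steatosisFromPair <- function(pair, rois, fat_water = NULL) {
  if (is.null(fat_water)) fat_water <- reconstructFatWater(pair)
  liver_labels <- .LIVER_LABELS
  missing_l <- setdiff(liver_labels, names(rois))
  if (length(missing_l))
    .stopf("missing liver ROI(s): %s", paste(missing_l, collapse = ", "))
  ff_roi <- vapply(liver_labels, function(lab) {
    f <- roiStats(fat_water$fat_only, rois[[lab]])@mean
    w <- roiStats(fat_water$water_only, rois[[lab]])@mean
    fatFraction(f, w)
  }, numeric(1))
  ff <- mean(ff_roi)
  flags <- character()
  if (ff >= 45) flags <- c(flags, "FF_DOMINANCE_AMBIGUOUS")
  sir <- NA_real_
  if (all(.MUSCLE_LABELS %in% names(rois))) {
    liver_st <- lapply(liver_labels, function(l) roiStats(fat_water$fat_only, rois[[l]]))
    muscle_st <- lapply(.MUSCLE_LABELS, function(l) roiStats(fat_water$fat_only, rois[[l]]))
    sir <- signalIntensityRatio(liver_st, muscle_st)
  }
  SteatosisResult(ff_percent = ff, ff_sd = .sampleSD(ff_roi), sir = sir,
                  grade = gradeSteatosis(ff), flags = flags)
}

#' @export
setMethod("show", "SteatosisResult", function(object) {
  cat(sprintf("Steatosis: FF = %.1f +/- %.1f %%  (grade %s)\n",
              object@ff_percent, object@ff_sd, object@grade))
  if (!is.na(object@sir)) cat(sprintf("  SIR (fat-only image) = %.3g\n", object@sir))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
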