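#' Read a multi-echo series from disk
#'
#' Reads a NIfTI volume (`.nii` / `.nii.gz`) whose third dimension indexes
#' echoes (a 2-D image is a single-echo series), together with a JSON sidecar
#' carrying the acquisition metadata the NIfTI header cannot:
#'
#' ```
#' {"te_ms": [2.4, 4.8, ...], "field_t": 1.5, "roles": ["OPPOSED_PHASE", ...]}
#' ```
#'
#' The sidecar is `<stem>.json` next to the image. `roles` is optional: when
#' absent, in-/opposed-phase roles are derived from each TE via
#' [classifyPhase()]. Frames are returned sorted by ascending TE with pixel
#' data unmodified.
#'
#' DICOM input is not supported by this package; convert series to
#' NIfTI + sidecar first (e.g. with dcm2niix, which writes exactly this
#' layout).
#'
#' @param path path to the NIfTI file.
#' @param format `"NIFTI"` (the only supported reader) or `"DICOM_DIR"`
#'   (raises an informative error).
#' @param slice for 4-D volumes, which slice of the 4th dimension to take
#'   (the protocol analyses a single slice; there is no automatic selection).
#' @return An [EchoSeries].
#' @seealso [writeSeries()]
#' @export
readSeries <- function(path, format = c("NIFTI", "DICOM_DIR"), slice = NULL) {
  format <- match.arg(format)
  if (format == "DICOM_DIR")
    .stopf(paste0("DICOM reading is not supported; convert '%s' to NIfTI with ",
                  "a JSON sidecar (te_ms, field_t) first"), path)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sidecar <- .sidecarPath(path)
  if (!file.exists(sidecar))
    .stopf("missing TE metadata: sidecar file '%s' not found for image '%s'",
           sidecar, path)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$te_ms))
    .stopf("sidecar '%s' carries no 'te_ms' entry", sidecar)
  if (is.null(meta$field_t))
    .stopf("sidecar '%s' carries no 'field_t' entry", sidecar)

  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) == 4L) {
    if (is.null(slice))
      .stopf("'%s' is 4-D; supply 'slice' to select one slice", path)
    arr <- arr[, , , slice, drop = FALSE]
    dim(arr) <- dim(arr)[1:3]
  }
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    .stopf("unsupported NIfTI dimensionality in '%s'", path)

  n <- dim(arr)[3]
  te <- as.numeric(meta$te_ms)
  if (length(te) != n)
    .stopf("sidecar '%s' lists %d TEs but image '%s' holds %d frames",
           sidecar, length(te), path, n)
  field_t <- as.numeric(meta$field_t)
  roles <- if (!is.null(meta$roles)) as.character(meta$roles)
           else classifyPhase(te, field_t)
  spacing <- if (!is.null(meta$pixel_spacing_mm))
    as.numeric(meta$pixel_spacing_mm) else c(1, 1)

  ord <- order(te)
  frames <- lapply(ord, function(i) {
    ImageFrame(pixels = arr[, , i], te_ms = te[i], field_t = field_t,
               role = roles[i], pixel_spacing_mm = spacing)
  })
  esp <- if (!is.null(meta$echo_spacing_ms)) as.numeric(meta$echo_spacing_ms)
         else if (n > 1L) unique(round(diff(sort(te)), 6))[1] else NA_real_
  EchoSeries(frames, field_t = field_t, echo_spacing_ms = esp)
}

#' Write a series as NIfTI + JSON sidecar
#'
#' Pixel data are written as 64-bit floats so the round trip
#' `readSeries(writeSeries(s))` is bit-exact.
#'
#' @param series an [EchoSeries].
#' @param path output NIfTI path (`.nii` or `.nii.gz`); the sidecar is written
#'   next to it as `<stem>.json`.
#' @return Invisibly, `c(image = path, sidecar = sidecarpath)`.
#' @export
writeSeries <- function(series, path) {
  frames <- series@frames
  arr <- array(0, dim = c(dim(frames[[1]]@pixels), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]@pixels
  RNifti::writeNifti(arr, path, datatype = "double")
  sidecar <- .sidecarPath(path)
  meta <- list(
    te_ms = vapply(frames, function(f) f@te_ms, numeric(1)),
    field_t = series@field_t,
    roles = vapply(frames, function(f) f@role, character(1)),
    echo_spacing_ms = series@echo_spacing_ms,
    pixel_spacing_mm = frames[[1]]@pixel_spacing_mm
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(image = path, sidecar = sidecar))
}

.sidecarPath <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(stem, ".json")
}

#' Read / write ROI definitions as JSON
#'
#' ROI files are JSON arrays of objects
#' `{"label": "...", "center": [r, c], "semi_axes": [a, b]}` with 1-based
#' pixel coordinates.
#'
#' @param path JSON file path.
#' @return `readROIs`: a named list of [EllipseROI] (names are labels).
#' @export
readROIs <- function(path) {
  if (!file.exists(path)) .stopf("ROI file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rois <- lapply(raw, function(x) {
    EllipseROI(center = as.numeric(x$center),
               semi_axes = as.numeric(x$semi_axes),
               label = as.character(x$label))
  })
  names(rois) <- vapply(rois, function(r) r@label, character(1))
  rois
}

#' @rdname readROIs
#' @param rois list of [EllipseROI].
#' @export
writeROIs <- function(rois, path) {
  out <- lapply(rois, function(r) {
    list(label = r@label, center = r@center, semi_axes = r@semi_axes)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
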