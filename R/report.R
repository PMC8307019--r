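#' Fat-iron cross-contamination warnings
#'
#' Fat and iron each perturb the other arm's signal model: fat-water
#' oscillation corrupts the mono-exponential T2* decay once steatosis is
#' present (FF at or above the 6.4% steatosis threshold), and iron shortens
#' T2* enough to depress the in-phase signal that the fat fraction relies on
#' (LIC at or above the 36 µmol/g overload threshold). Under severe iron
#' overload (LIC above 80 µmol/g) the fat calculation is best omitted
#' entirely.
#'
#' @param ff_percent fat fraction, %.
#' @param lic_umol_g liver iron concentration, µmol/g.
#' @return character vector drawn from `FAT_AFFECTS_T2STAR`,
#'   `IRON_AFFECTS_FF`, `OMIT_FF` (possibly empty).
#' @examples
#' crossContaminationWarnings(3.1, 19)    # none
#' crossContaminationWarnings(17.5, 95)   # all three
#' @export
crossContaminationWarnings <- function(ff_percent, lic_umol_g) {
  w <- character()
  if (ff_percent >= 6.4) w <- c(w, "FAT_AFFECTS_T2STAR")
  if (lic_umol_g >= 36) w <- c(w, "IRON_AFFECTS_FF")
  if (lic_umol_g > 80) w <- c(w, "OMIT_FF")
  w
}

#' Run the full biomarker pipeline for one subject
#'
#' Executes whichever arms have inputs: the fibrosis arm from a liver T1 map
#' (three liver ROI means, optional HSA inverse prediction through a
#' calibration model), the steatosis arm from a Dixon IP/OOP pair, and the
#' iron arm from a multi-echo series. Results are assembled into a
#' [BiomarkerReport] with all warning rules applied; when both steatosis and
#' iron arms ran and the fat fraction exceeds the steatosis threshold, the
#' iron fit is repeated on in-phase echoes only.
#'
#' @param subject_id character identifier.
#' @param field_t tesla (1.5 or 3.0).
#' @param rois named list of [EllipseROI] (see [readROIs()]); required label
#'   sets are checked per requested arm.
#' @param t1_frame optional [ImageFrame] of role `T1_MAP` (or `NULL`).
#' @param t1_means alternative to `t1_frame`: the three liver ROI means, ms.
#' @param calibration optional [CalibrationModel] for HSA inverse prediction.
#' @param dixon optional [DixonPair].
#' @param series optional [EchoSeries].
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, `roi_stats.csv` (per available frame) and
#'   `decay_curve.csv`.
#' @return A [BiomarkerReport].
#' @export
runPipeline <- function(subject_id = "subject", field_t, rois,
                        t1_frame = NULL, t1_means = NULL, calibration = NULL,
                        dixon = NULL, series = NULL, out_dir = NULL) {
  if (is.null(t1_frame) && is.null(t1_means) && is.null(dixon) && is.null(series))
    .stopf("no inputs: supply at least one arm (t1_frame/t1_means, dixon, series)")

  t1 <- NULL
  if (!is.null(t1_frame) || !is.null(t1_means)) {
    if (!is.null(t1_frame)) {
      miss <- setdiff(.LIVER_LABELS, names(rois))
      if (length(miss))
        .stopf("fibrosis arm: missing ROI label(s) %s", paste(miss, collapse = ", "))
      st <- lapply(.LIVER_LABELS, function(l) roiStats(t1_frame, rois[[l]]))
      t1 <- liverSummary(st)
    } else {
      t1 <- liverSummary(t1_means)
    }
    t1 <- list(mean_ms = t1$mean, sd_ms = t1$sd)
    if (!is.null(calibration)) {
      p <- predictHSA(calibration, t1$mean_ms)
      t1$hsa_percent <- p$hsa_percent
      t1$hsa_out_of_range <- p$out_of_range
    }
  }

  steat <- NULL
  if (!is.null(dixon)) {
    miss <- setdiff(.LIVER_LABELS, names(rois))
    if (length(miss))
      .stopf("steatosis arm: missing ROI label(s) %s", paste(miss, collapse = ", "))
    steat <- steatosisFromPair(dixon, rois)
  }

  iron <- NULL
  if (!is.null(series)) {
    use_phases <- if (!is.null(steat) && steat@ff_percent >= 6.4) "IP" else "all"
    iron <- ironFromSeries(series, rois, use_phases = use_phases)
  }

  warnings <- character()
  if (!is.null(steat) && !is.null(iron))
    warnings <- c(warnings,
                  crossContaminationWarnings(steat@ff_percent, iron@lic_umol_g))
  if (!is.null(t1)) {
    confounded <- (!is.null(steat) && steat@ff_percent >= 6.4) ||
                  (!is.null(iron) && iron@lic_umol_g >= 36)
    if (confounded) warnings <- c(warnings, "T1_CONFOUNDED_BY_FAT_OR_IRON")
    if (isTRUE(t1$hsa_out_of_range)) warnings <- c(warnings, "HSA_OUT_OF_RANGE")
  }
  if (!is.null(iron)) warnings <- c(warnings, iron@flags)
  if (!is.null(steat)) warnings <- c(warnings, steat@flags)
  warnings <- unique(warnings)

  report <- BiomarkerReport(subject_id = subject_id, field_t = field_t,
                            t1 = t1, steatosis = steat, iron = iron,
                            warnings = warnings)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeReport(report, file.path(out_dir, "report.json"))
    if (!is.null(series)) {
      curve <- decaySamples(series, rois[[.LIVER_LABELS[1]]])
      utils::write.csv(curve, file.path(out_dir, "decay_curve.csv"),
                       row.names = FALSE)
    }
    if (!is.null(dixon)) {
      fw <- reconstructFatWater(dixon)
      utils::write.csv(roiTable(fw$fat_only, rois),
                       file.path(out_dir, "roi_stats.csv"), row.names = FALSE)
    }
  }
  report
}

#' Serialise / restore a biomarker report
#'
#' `reportAsList()` converts a [BiomarkerReport] to a plain list;
#' `writeReport()` stores it as JSON at full numeric precision, and
#' `readReport()` restores the list, so the round trip is lossless.
#'
#' @param report a [BiomarkerReport].
#' @return `reportAsList`/`readReport`: a named list.
#' @export
reportAsList <- function(report) {
  out <- list(subject_id = report@subject_id, field_t = report@field_t)
  out$t1 <- report@t1
  if (!is.null(report@steatosis)) {
    s <- report@steatosis
    out$steatosis <- list(ff_percent = s@ff_percent, ff_sd = s@ff_sd,
                          sir = s@sir, grade = s@grade,
                          flags = as.list(s@flags))
  }
  if (!is.null(report@iron)) {
    i <- report@iron
    out$iron <- list(t2star_ms = i@t2star_ms, r2star_s = i@r2star_s,
                     lic_umol_g = i@lic_umol_g, lic_rounded = i@lic_rounded,
                     grade = i@grade, field_t = i@field_t,
                     approximate = i@approximate, flags = as.list(i@flags))
  }
  out$warnings <- as.list(report@warnings)
  out
}

#' @rdname reportAsList
#' @param path JSON file path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname reportAsList
#' @export
readReport <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' @export
setMethod("show", "BiomarkerReport", function(object) {
  cat(sprintf("BiomarkerReport '%s' (%g T)\n", object@subject_id, object@field_t))
  if (!is.null(object@t1)) {
    cat(sprintf("  liver T1: %.2f +/- %.2f ms", object@t1$mean_ms, object@t1$sd_ms))
    if (!is.null(object@t1$hsa_percent))
      cat(sprintf("  (HSA est. %.1f%%%s)", object@t1$hsa_percent,
                  if (isTRUE(object@t1$hsa_out_of_range)) ", out of range" else ""))
    cat("\n")
  }
  if (!is.null(object@steatosis))
    cat(sprintf("  steatosis: FF = %.1f%%, grade %s\n",
                object@steatosis@ff_percent, object@steatosis@grade))
  if (!is.null(object@iron))
    cat(sprintf("  iron: T2* = %.3g ms, LIC = %d umol/g, grade %s\n",
                object@iron@t2star_ms, as.integer(object@iron@lic_rounded),
                object@iron@grade))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = ", "), "\n")
})
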