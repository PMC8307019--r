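#' Fit the linear T1-vs-HSA calibration
#'
#' Ordinary least squares of measured T1 (ms, response) on human-serum-albumin
#' concentration (%, predictor), matching the direction in which phantom
#' calibrations are plotted: T1 as a function of concentration. HSA is used as
#' a fibrosis surrogate because the liver synthesises it and its concentration
#' falls in advanced fibrosis; across phantoms T1 rises as HSA concentration
#' falls, so a valid calibration has a negative slope (a warning is raised
#' otherwise).
#'
#' @param points data.frame with columns `hsa_percent` and `t1_ms` (the
#'   phantom-measurement CSV layout; `sd_ms` is tolerated and ignored), or a
#'   numeric vector of concentrations when `t1_ms` is given separately.
#' @param t1_ms optional numeric vector of T1 values, ms.
#' @return A [CalibrationModel].
#' @examples
#' x <- c(0, 2.5, 5, 8, 11, 16, 20)
#' fitCalibration(x, -30 * x + 1500)   # slope -30, intercept 1500, r = -1
#' @export
fitCalibration <- function(points, t1_ms = NULL) {
  if (is.data.frame(points)) {
    x <- points$hsa_percent
    y <- points$t1_ms
  } else {
    x <- as.numeric(points)
    y <- as.numeric(t1_ms)
  }
  if (length(x) != length(y) || length(x) < 3L)
    .stopf("need >= 3 calibration points; got %d", length(x))
  if (length(unique(x)) < 2L)
    .stopf("degenerate design: all HSA concentrations identical")
  if (length(unique(x)) < 3L)
    .stopf("need >= 3 distinct HSA concentrations; got %d", length(unique(x)))

  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ## r carries the sign of the slope; on an exact line cor() returns +/-1
  r <- if (stats::sd(y) == 0) sign(slope) * 1 else stats::cor(x, y)
  ## direct SE (summary.lm warns on exact-line fits)
  sigma2 <- sum(stats::resid(fit)^2) / (length(x) - 2)
  se <- sqrt(sigma2 / sum((x - mean(x))^2))
  if (slope >= 0)
    .warnf("fitted slope is non-negative (%.4g ms/%%); not a valid HSA calibration (T1 should fall with concentration)",
           slope)
  CalibrationModel(slope = slope, intercept = intercept, r_pearson = r,
                   r_squared = r^2, slope_se = se, n = length(x))
}

#' Inverse-predict HSA concentration from liver T1
#'
#' Solves the fitted calibration line for concentration:
#' `(t1_ms - intercept)/slope`. This is an exploratory biomarker only — no
#' validated T1-to-fibrosis-stage mapping exists — so predictions outside the
#' calibrated 0–20% range are returned as-is with an out-of-range flag rather
#' than clamped.
#'
#' @param model a [CalibrationModel].
#' @param t1_ms liver T1 value(s), ms.
#' @return list with `hsa_percent` (numeric) and `out_of_range` (logical),
#'   both vectorised over `t1_ms`.
#' @export
predictHSA <- function(model, t1_ms) {
  if (model@slope == 0) .stopf("calibration slope is zero; cannot invert")
  hsa <- (t1_ms - model@intercept) / model@slope
  list(hsa_percent = hsa, out_of_range = hsa < 0 | hsa > 20)
}

#' Compare liver T1 between two subjects
#'
#' @param subject_a,subject_b [liverSummary()] results (or single mean T1
#'   values in ms).
#' @param labels names used in the report (default `"A"`, `"B"`).
#' @return list with `higher` (label of the higher-T1 subject, or `"equal"`)
#'   and `difference_ms` (non-negative magnitude of the difference).
#' @examples
#' p1 <- liverSummary(c(797.48, 766.20, 688.96))
#' p2 <- liverSummary(c(889.09, 829.30, 930.37))
#' compareT1(p1, p2, labels = c("patient1", "patient2"))
#' @export
compareT1 <- function(subject_a, subject_b, labels = c("A", "B")) {
  ma <- if (is.list(subject_a)) subject_a$mean else as.numeric(subject_a)
  mb <- if (is.list(subject_b)) subject_b$mean else as.numeric(subject_b)
  d <- mb - ma
  list(
    higher = if (d > 0) labels[2] else if (d < 0) labels[1] else "equal",
    difference_ms = abs(d)
  )
}

#' @export
setMethod("show", "CalibrationModel", function(object) {
  cat("T1-vs-HSA calibration (OLS)\n")
  cat(sprintf("  T1 [ms] = %.4g %+.4g * HSA[%%]   (n = %d)\n",
              object@intercept, object@slope, object@n))
  cat(sprintf("  r = %.4f, R^2 = %.4f, SE(slope) = %.3g\n",
              object@r_pearson, object@r_squared, object@slope_se))
})
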