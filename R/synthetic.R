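## Synthetic phantom generators.
##
## Every generator returns its ground truth alongside the images, so the whole
## pipeline (ROI statistics -> calibration / Dixon / relaxometry -> grading)
## can be exercised end-to-end against known parameters with no patient data.
## A fixed seed gives bit-identical output.

#' Default digital abdomen phantom
#'
#' A non-overlapping elliptical layout on a 128 x 128 grid (the matrix size of
#' the multi-echo acquisition this package models): one large liver region,
#' two paravertebral-muscle regions, spleen and abdominal fat, on a
#' zero-signal background. Tissue parameters are plausible abdominal values at
#' the given field; liver T2* and fat fraction are the dials an experiment
#' varies.
#'
#' @param field_t 1.5 or 3.0.
#' @param liver_t2star_ms true liver T2*, ms (default 25, a no-iron liver).
#' @param liver_ff_percent true liver fat fraction, % (default 0).
#' @param noise_sd Gaussian noise SD in a.u. against a liver proton density of
#'   1000 (default 20, i.e. SNR 50).
#' @param dim image dimensions (default `c(128, 128)`).
#' @return A [PhantomSpec].
#' @export
defaultPhantomSpec <- function(field_t = 1.5, liver_t2star_ms = 25,
                               liver_ff_percent = 0, noise_sd = 20,
                               dim = c(128L, 128L)) {
  layout <- data.frame(
    label = c("LIVER", "SPLEEN", "MUSCLE_L", "MUSCLE_R", "ABDOMINAL_FAT"),
    row   = c(55, 60, 110, 110, 15),
    col   = c(45, 105, 45, 75, 64),
    a     = c(30, 12, 8, 8, 8),
    b     = c(32, 10, 10, 10, 30),
    t1_ms = c(800, 1100, 900, 900, 350),
    t2star_ms = c(liver_t2star_ms, 60, 30, 30, 40),
    ## muscle carries ~5% myocellular lipid; this keeps the muscle reference
    ## signal positive on fat-only images (SIR denominator)
    ff_percent = c(liver_ff_percent, 0, 5, 5, 90),
    pd    = c(1000, 900, 800, 800, 950),
    stringsAsFactors = FALSE
  )
  PhantomSpec(layout = layout, dim = as.integer(dim), field_t = field_t,
              noise_sd = noise_sd)
}

#' Standard ROI set for the default phantom
#'
#' Three liver ROIs (labelled by Couinaud segment as in the acquisition
#' protocol), two muscle ROIs, spleen, abdominal fat, and a background NOISE
#' ROI, all placed inside the [defaultPhantomSpec()] regions.
#'
#' @param spec a [PhantomSpec] (only the geometry convention matters; ROIs are
#'   positioned for the default layout).
#' @return Named list of [EllipseROI].
#' @export
defaultROIs <- function(spec = defaultPhantomSpec()) {
  mk <- function(label, r, c, a, b) EllipseROI(center = c(r, c),
                                               semi_axes = c(a, b),
                                               label = label)
  rois <- list(
    mk("LIVER_IV",   45, 35, 7, 7),
    mk("LIVER_VIII", 45, 55, 7, 7),
    mk("LIVER_VII",  65, 45, 7, 7),
    mk("MUSCLE_L",  110, 45, 5, 7),
    mk("MUSCLE_R",  110, 75, 5, 7),
    mk("SPLEEN",     60, 105, 8, 7),
    mk("ABDOMINAL_FAT", 15, 64, 5, 20),
    mk("NOISE",     110, 15, 6, 8)
  )
  names(rois) <- vapply(rois, function(r) r@label, character(1))
  rois
}

## per-pixel water / fat / T2* parameter maps from a layout
.rasterise <- function(spec) {
  d <- spec@dim
  w <- matrix(0, d[1], d[2])
  f <- matrix(0, d[1], d[2])
  t2 <- matrix(Inf, d[1], d[2])
  for (i in seq_len(nrow(spec@layout))) {
    li <- spec@layout[i, ]
    m <- .ellipseMask(d, c(li$row, li$col), c(li$a, li$b))
    w[m] <- li$pd * (1 - li$ff_percent / 100)
    f[m] <- li$pd * li$ff_percent / 100
    t2[m] <- li$t2star_ms
  }
  list(w = w, f = f, t2 = t2)
}

## additive noise on a magnitude image
.addNoise <- function(img, sd, model = c("gaussian", "rician")) {
  model <- match.arg(model)
  if (sd <= 0) return(img)
  if (model == "gaussian") {
    pmax(img + stats::rnorm(length(img), 0, sd), 0)
  } else {
    sqrt((img + stats::rnorm(length(img), 0, sd))^2 +
           stats::rnorm(length(img), 0, sd)^2)
  }
}

#' Synthetic HSA-phantom T1 map
#'
#' Emulates a T1 map of a rack of human-serum-albumin vials: one circular
#' region per concentration, pixel values drawn from the true linear relation
#' `t1 = true_intercept + true_slope * concentration` plus Gaussian noise.
#' T1 falls as protein concentration rises, so `true_slope` must be negative.
#'
#' @param concentrations HSA concentrations in percent, each in `[0, 20]`
#'   (default: seven vials spanning the 0–20% range).
#' @param true_slope ms per percentage point, `< 0`.
#' @param true_intercept T1 at 0% HSA, ms.
#' @param noise_sd per-pixel Gaussian T1 noise, ms.
#' @param seed integer seed for reproducibility (`NULL`: leave RNG state).
#' @param radius vial radius in pixels.
#' @return list with `frame` (an [ImageFrame], role `T1_MAP`), `truth`
#'   (data.frame of per-vial ground truth), and `rois` (per-vial
#'   [EllipseROI]s, shrunk to 70% of the vial radius to avoid edge pixels).
#' @export
makeHSAPhantomT1Map <- function(concentrations = c(0, 2.5, 5, 8, 11, 16, 20),
                                true_slope = -30, true_intercept = 1500,
                                noise_sd = 0, seed = NULL, radius = 8) {
  if (any(concentrations < 0 | concentrations > 20))
    .stopf("concentrations must lie in [0, 20] %%")
  if (true_slope >= 0)
    .stopf("'true_slope' must be negative (T1 falls with HSA concentration)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(concentrations)
  per_row <- 4L
  rows <- 20 + 30 * ((seq_len(n) - 1) %/% per_row)
  cols <- 15 + 25 * ((seq_len(n) - 1) %% per_row)
  d <- c(max(rows) + 2 * radius + 4, max(cols) + 2 * radius + 4)
  ## circles: overlap iff center distance < 2 * radius
  if (n > 1L) {
    dc <- as.matrix(stats::dist(cbind(rows, cols)))
    diag(dc) <- Inf
    if (any(dc < 2 * radius)) .stopf("phantom circles overlap; reduce 'radius'")
  }
  t1_true <- true_intercept + true_slope * concentrations
  px <- matrix(0, d[1], d[2])
  for (i in seq_len(n)) {
    m <- .ellipseMask(d, c(rows[i], cols[i]), c(radius, radius))
    px[m] <- pmax(t1_true[i] + stats::rnorm(sum(m), 0, noise_sd), 0)
  }
  rois <- lapply(seq_len(n), function(i) {
    EllipseROI(center = c(rows[i], cols[i]),
               semi_axes = c(radius, radius) * 0.7,
               label = sprintf("HSA_%g", concentrations[i]))
  })
  names(rois) <- vapply(rois, function(r) r@label, character(1))
  list(
    frame = ImageFrame(pixels = px, te_ms = NA_real_, field_t = 3.0,
                       role = "T1_MAP"),
    truth = data.frame(label = names(rois), hsa_percent = concentrations,
                       t1_true_ms = t1_true, row = rows, col = cols,
                       radius = radius, stringsAsFactors = FALSE),
    rois = rois
  )
}

#' Measure a synthetic HSA phantom
#'
#' Applies [roiStats()] to each vial ROI of a [makeHSAPhantomT1Map()] result,
#' producing the phantom-measurement table that feeds [fitCalibration()].
#'
#' @param phantom the list returned by [makeHSAPhantomT1Map()].
#' @return data.frame with columns `hsa_percent, t1_ms, sd_ms`.
#' @export
phantomMeasurements <- function(phantom) {
  st <- lapply(phantom$rois, function(r) roiStats(phantom$frame, r))
  data.frame(
    hsa_percent = phantom$truth$hsa_percent,
    t1_ms = vapply(st, function(s) s@mean, numeric(1)),
    sd_ms = vapply(st, function(s) s@sd, numeric(1)),
    row.names = NULL
  )
}

## noiseless magnitude signal of one echo under the two-point Dixon model:
## water and fat add in-phase and subtract opposed-phase, then decay with the
## regional T2*.
.echoSignal <- function(maps, te_ms, phase) {
  base <- if (phase == "IN_PHASE") maps$w + maps$f else abs(maps$w - maps$f)
  base * exp(-te_ms / maps$t2)
}

#' Synthetic Dixon in-phase / opposed-phase pair
#'
#' Rasterises a [PhantomSpec] into an IP/OOP frame pair under the two-point
#' Dixon signal model: per region, water signal `W = pd (1 - FF/100)` and fat
#' signal `F = pd FF/100`; the in-phase image is `(W + F) exp(-TE/T2*)` and
#' the opposed-phase image `|W - F| exp(-TE/T2*)`, with additive noise applied
#' to the magnitude and clipped at zero.
#'
#' @param spec a [PhantomSpec].
#' @param te_ip,te_oop echo times in ms; they must classify as IN_PHASE and
#'   OPPOSED_PHASE respectively at the spec's field (see [classifyPhase()]).
#' @param seed integer seed (`NULL`: leave RNG state).
#' @param noise_model `"gaussian"` (added then clipped) or `"rician"`.
#' @return list with `pair` (a [DixonPair]) and `truth` (layout plus the
#'   noiseless water/fat maps and per-echo noiseless images).
#' @export
makeDixonPair <- function(spec, te_ip = NULL, te_oop = NULL, seed = NULL,
                          noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  base <- if (spec@field_t == 1.5) 2.4 else 1.2
  if (is.null(te_ip)) te_ip <- 2 * base
  if (is.null(te_oop)) te_oop <- base
  if (classifyPhase(te_ip, spec@field_t) != "IN_PHASE")
    .stopf("te_ip = %g ms classifies as opposed-phase at %g T", te_ip, spec@field_t)
  if (classifyPhase(te_oop, spec@field_t) != "OPPOSED_PHASE")
    .stopf("te_oop = %g ms classifies as in-phase at %g T", te_oop, spec@field_t)
  if (!is.null(seed)) set.seed(seed)
  maps <- .rasterise(spec)
  ip0 <- .echoSignal(maps, te_ip, "IN_PHASE")
  oop0 <- .echoSignal(maps, te_oop, "OPPOSED_PHASE")
  ip <- .addNoise(ip0, spec@noise_sd, noise_model)
  oop <- .addNoise(oop0, spec@noise_sd, noise_model)
  list(
    pair = DixonPair(
      ip = ImageFrame(pixels = ip, te_ms = te_ip, field_t = spec@field_t,
                      role = "IN_PHASE"),
      oop = ImageFrame(pixels = oop, te_ms = te_oop, field_t = spec@field_t,
                       role = "OPPOSED_PHASE")
    ),
    truth = list(layout = spec@layout, w_map = maps$w, f_map = maps$f,
                 ip_noiseless = ip0, oop_noiseless = oop0)
  )
}

#' Synthetic multi-echo gradient-echo series
#'
#' Frames at `TE = k * echo_spacing_ms`, `k = 1..n_echoes`, each echo's phase
#' set by [classifyPhase()] (so IP and OOP alternate, as in the modelled
#' acquisition: 10 echoes every 2.4 ms at 1.5 T, 12 every 1.2 ms at 3 T —
#' those are the defaults per field). Per-pixel signal follows the same
#' two-point Dixon + T2* decay model as [makeDixonPair()], with an optional
#' constant background offset (`noise_floor`) plus random noise; the
#' `"rician"` noise model produces the magnitude noise floor organically.
#'
#' @param spec a [PhantomSpec].
#' @param n_echoes number of echoes (default 10 at 1.5 T, 12 at 3 T).
#' @param echo_spacing_ms inter-echo gap (default 2.4 at 1.5 T, 1.2 at 3 T).
#' @param seed integer seed (`NULL`: leave RNG state).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param noise_floor constant background offset added to every pixel (a.u.).
#' @return list with `series` (an [EchoSeries]) and `truth` (layout, true
#'   liver T2*, noise floor, water/fat maps).
#' @export
makeMultiechoSeries <- function(spec, n_echoes = NULL, echo_spacing_ms = NULL,
                                seed = NULL,
                                noise_model = c("gaussian", "rician"),
                                noise_floor = 0) {
  noise_model <- match.arg(noise_model)
  if (is.null(n_echoes)) n_echoes <- if (spec@field_t == 1.5) 10L else 12L
  if (is.null(echo_spacing_ms))
    echo_spacing_ms <- if (spec@field_t == 1.5) 2.4 else 1.2
  if (n_echoes < 4L) .stopf("'n_echoes' must be >= 4 for decay fitting")
  if (!is.null(seed)) set.seed(seed)
  maps <- .rasterise(spec)
  te <- seq_len(n_echoes) * echo_spacing_ms
  phases <- classifyPhase(te, spec@field_t)
  frames <- lapply(seq_len(n_echoes), function(k) {
    img <- .echoSignal(maps, te[k], phases[k]) + noise_floor
    ImageFrame(pixels = .addNoise(img, spec@noise_sd, noise_model),
               te_ms = te[k], field_t = spec@field_t, role = phases[k])
  })
  list(
    series = EchoSeries(frames, field_t = spec@field_t,
                        echo_spacing_ms = echo_spacing_ms),
    truth = list(layout = spec@layout,
                 liver_t2star_ms = spec@layout$t2star_ms[spec@layout$label == "LIVER"],
                 noise_floor = noise_floor, noise_sd = spec@noise_sd,
                 w_map = maps$w, f_map = maps$f, te_ms = te, phases = phases)
  )
}
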