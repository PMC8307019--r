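## Accessors and display methods for the core containers.

#' Accessors for ImageFrame and EchoSeries
#'
#' `pixels()` returns the pixel matrix; `echoTime()` the echo time in ms;
#' `fieldStrength()` the main field in tesla; `imageRole()` the sequence role;
#' `teTimes()` the vector of echo times of a series. `length()` and `[[`
#' work on an [EchoSeries] as on a list of frames.
#'
#' @param x an [ImageFrame] or [EchoSeries].
#' @return See each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
setMethod("pixels", "ImageFrame", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("echoTime", function(x) standardGeneric("echoTime"))

#' @rdname accessors
setMethod("echoTime", "ImageFrame", function(x) x@te_ms)

#' @rdname accessors
#' @export
setGeneric("fieldStrength", function(x) standardGeneric("fieldStrength"))

#' @rdname accessors
setMethod("fieldStrength", "ImageFrame", function(x) x@field_t)

#' @rdname accessors
setMethod("fieldStrength", "EchoSeries", function(x) x@field_t)

#' @rdname accessors
#' @export
setGeneric("imageRole", function(x) standardGeneric("imageRole"))

#' @rdname accessors
setMethod("imageRole", "ImageFrame", function(x) x@role)

#' @rdname accessors
#' @export
setGeneric("teTimes", function(x) standardGeneric("teTimes"))

#' @rdname accessors
setMethod("teTimes", "EchoSeries", function(x)
  vapply(x@frames, function(f) f@te_ms, numeric(1)))

#' @rdname accessors
#' @export
setMethod("length", "EchoSeries", function(x) length(x@frames))

#' @rdname accessors
#' @param i frame index.
#' @param j,... unused.
#' @export
setMethod("[[", "EchoSeries", function(x, i, j, ...) x@frames[[i]])

#' @export
setMethod("show", "ImageFrame", function(object) {
  cat(sprintf("ImageFrame %dx%d [%s]  TE = %s ms, %g T\n",
              nrow(object@pixels), ncol(object@pixels), object@role,
              if (is.na(object@te_ms)) "-" else format(object@te_ms),
              object@field_t))
})

#' @export
setMethod("show", "EchoSeries", function(object) {
  te <- teTimes(object)
  cat(sprintf("EchoSeries: %d echoes at %g T, TE = %s ms\n",
              length(object), object@field_t,
              paste(format(te, trim = TRUE), collapse = ", ")))
})

#' @export
setMethod("show", "EllipseROI", function(object) {
  cat(sprintf("EllipseROI '%s': center (%g, %g), semi-axes (%g, %g) px\n",
              object@label, object@center[1], object@center[2],
              object@semi_axes[1], object@semi_axes[2]))
})

#' @export
setMethod("show", "DixonPair", function(object) {
  cat(sprintf("DixonPair at %g T: IP TE = %g ms, OOP TE = %g ms, %dx%d\n",
              object@ip@field_t, object@ip@te_ms, object@oop@te_ms,
              nrow(object@ip@pixels), ncol(object@ip@pixels)))
})

#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%d at %g T, noise SD %g, %d regions:\n",
              object@dim[1], object@dim[2], object@field_t, object@noise_sd,
              nrow(object@layout)))
  print(object@layout, row.names = FALSE)
})
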