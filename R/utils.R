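## Internal helpers shared across modules.

## Logical mask of pixels whose centers fall inside the ellipse
## ((r - r0)/a)^2 + ((c - c0)/b)^2 <= 1, boundary included. 1-based (row, col).
.ellipseMask <- function(dim, center, semi_axes) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((r - center[1]) / semi_axes[1])^2 + ((c - center[2]) / semi_axes[2])^2 <= 1
}

#' Round half away from zero
#'
#' Deterministic half-up rounding (2.5 -> 3), unlike [base::round()]'s
#' round-half-to-even. Used wherever integer values are reported, since the
#' reference LIC tables print integers.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(18.5)   # 19
#' round(18.5)         # 18 (banker's rounding)
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## sample SD that is 0 (not NA) for a single observation
.sampleSD <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
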