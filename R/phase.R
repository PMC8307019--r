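#' Classify an echo time as in-phase or opposed-phase
#'
#' At 1.5 T water and fat protons are opposed-phase at odd multiples of
#' 2.4 ms and in-phase at even multiples; at 3 T the base spacing halves to
#' 1.2 ms (chemical-shift evolution is twice as fast), so opposed-phase falls
#' on odd multiples of 1.2 ms and in-phase on even multiples. Echo times are
#' matched to the nearest multiple of the base spacing within a tolerance that
#' absorbs header rounding.
#'
#' @param te_ms echo time(s) in ms.
#' @param field_t main field in tesla, 1.5 or 3.0.
#' @param tolerance_ms how far `te_ms` may sit from an exact multiple of the
#'   base spacing (default 0.1 ms).
#' @return Character vector of `"IN_PHASE"` / `"OPPOSED_PHASE"`.
#' @examples
#' classifyPhase(4.8, 1.5)  # IN_PHASE
#' classifyPhase(2.4, 1.5)  # OPPOSED_PHASE
#' classifyPhase(2.4, 3.0)  # IN_PHASE
#' @export
classifyPhase <- function(te_ms, field_t, tolerance_ms = 0.1) {
  if (length(field_t) != 1L || !field_t %in% c(1.5, 3.0))
    .stopf("'field_t' must be 1.5 or 3.0, got %s", paste(field_t, collapse = ","))
  base <- if (field_t == 1.5) 2.4 else 1.2
  vapply(te_ms, function(te) {
    k <- round(te / base)
    if (k < 1 || abs(te - k * base) > tolerance_ms)
      .stopf("TE = %g ms is not a multiple of the %g ms base echo spacing at %g T (tolerance %g ms)",
             te, base, field_t, tolerance_ms)
    if (k %% 2 == 1) "OPPOSED_PHASE" else "IN_PHASE"
  }, character(1))
}
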