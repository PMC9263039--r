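## Two-dimensional phase unwrapping.

#' Unwrap a 2D phase map
#'
#' Reliability-sorted region-growing unwrapper: pixels are merged along
#' 4-neighbour edges in order of decreasing reliability (inverse local
#' second-difference magnitude), adding the multiple of 2*pi that keeps the
#' merged groups continuous.  The result equals the input modulo 2*pi at
#' every valid pixel; invalid pixels keep their input value.
#'
#' @param wrapped numeric matrix of wrapped phase, values in (-pi, pi].
#' @param mask logical matrix of valid pixels (default: all valid).
#' @return numeric matrix of unwrapped phase.
#' @export
unwrapPhase <- function(wrapped, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(wrapped), ncol(wrapped))
  .unwrap_reliability(wrapped, mask)
}
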