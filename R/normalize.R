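#' Per-slice min-max normalization to 8 bit
#'
#' Rescales every slice independently so that its minimum maps to 0 and its
#' maximum to 255 ("zero saturation": the full observed range is used, no
#' percentile clipping), rounding half-up to integers. This compensates the
#' progressive photobleaching signal loss across sequentially acquired
#' slices: a per-slice multiplicative drift leaves the normalized stack
#' unchanged. A degenerate constant slice maps to all zeros (empty
#' background).
#'
#' The operation is idempotent: normalizing an already-normalized stack
#' reproduces it exactly.
#'
#' @param stack an \code{\linkS4class{ImageStack}}.
#' @return an 8-bit \code{ImageStack} with integral values in [0, 255].
#' @examples
#' s <- ImageStack(array(c(10, 60, 110, 35), c(2, 2, 1)))
#' voxels(normalizeSlicewise(s))[, , 1]
#' @export
normalizeSlicewise <- function(stack) {
  v <- voxels(stack)
  for (z in seq_len(dim(v)[3])) {
    sl <- v[, , z]
    lo <- min(sl); hi <- max(sl)
    v[, , z] <- if (hi > lo) floor((sl - lo) * 255 / (hi - lo) + 0.5) else 0
  }
  ImageStack(v, calibration = calibration(stack), bitDepth = 8,
             channelCount = stack@channelCount)
}
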