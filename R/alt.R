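#' Windowed auto-local thresholding (ALT)
#'
#' Binarizes an 8-bit image by comparing each pixel \code{p} against a
#' statistic \code{S} of the grey values inside the circular domain of
#' radius \code{r} centred on it (the domain is clipped at image borders; no
#' padding is invented): the pixel is an object iff \code{p > S - c}. The
#' three operators are the local \code{mean}, the mid-gray
#' \code{(max + min)/2} and the \code{median} (lower middle order statistic
#' for even-sized clipped windows). The strict inequality is deliberate: on
#' a constant image with \code{c = 0} nothing is an object.
#'
#' @param img integer-valued matrix with values in [0, 255].
#' @param method one of \code{"mean"}, \code{"midgray"}, \code{"median"}.
#' @param r domain radius in pixels (>= 1).
#' @param c offset subtracted from the local statistic (grey levels);
#'   increasing \code{c} can only grow the object set.
#' @return logical matrix, \code{TRUE} = object.
#' @examples
#' img <- matrix(0L, 9, 9); img[5, 5] <- 255L
#' which(autoLocalThreshold(img, "mean", r = 1))
#' @export
autoLocalThreshold <- function(img, method = c("mean", "midgray", "median"),
                               r, c = 0) {
  method <- match.arg(method)
  .check8bit(img)
  r <- as.integer(r)
  if (r < 1L) stop("domain radius r must be >= 1")
  storage.mode(img) <- "integer"
  alt_cpp(img, match(method, c("mean", "midgray", "median")), r, c)
}

.check8bit <- function(x) {
  if (anyNA(x) || min(x) < 0 || max(x) > 255 || any(x != floor(x)))
    stop("ALT input must be 8-bit (integral values in [0, 255])")
  invisible(TRUE)
}

#' Slice-wise ALT of a stack
#'
#' Applies \code{\link{autoLocalThreshold}} independently to every z slice.
#'
#' @param stack an 8-bit \code{\linkS4class{ImageStack}} or a 3D array.
#' @inheritParams autoLocalThreshold
#' @return 3D logical array of the same shape, \code{TRUE} = object.
#' @export
altStack <- function(stack, method = c("mean", "midgray", "median"), r,
                     c = 0) {
  method <- match.arg(method)
  v <- if (is(stack, "ImageStack")) voxels(stack) else stack
  .check8bit(v)
  out <- array(FALSE, dim(v))
  for (z in seq_len(dim(v)[3]))
    out[, , z] <- autoLocalThreshold(v[, , z], method, r, c)
  out
}
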