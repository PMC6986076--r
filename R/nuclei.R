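#' Nucleus-detection parameters from a calibration
#'
#' Derives the defaults of the stain-free nucleus recognition chain from the
#' expected mean nucleus diameter: the ALT domain radius is one nucleus
#' radius in pixels (the window must span from inside a nucleus into the
#' surrounding cytosol for the local statistic to separate the two), the
#' blur sigma is 10\% of the nucleus diameter, and the particle filter
#' retains areas between 0.25x and 4x the area of a disc of that diameter
#' with circularity at least \code{roundnessMin}.
#'
#' @param cal a \code{\linkS4class{Calibration}}.
#' @param rNuc ALT domain radius (px); default
#'   \code{round(0.5 * nucleusDiameter / dx)}.
#' @param sigmaBlur Gaussian sigma (px); default
#'   \code{0.1 * nucleusDiameter / dx}.
#' @param basalCutoff basal slices excluded from the z-projection (default 0;
#'   set to the glass-artifact depth of the acquisition).
#' @param watershedTolerance 2D watershed minima-suppression tolerance (px).
#' @param areaMin,areaMax particle area bounds (um^2).
#' @param roundnessMin minimum circularity.
#' @param excludeEdges drop nuclei touching the image border.
#' @return a \code{\linkS4class{NucleusParams}} object.
#' @export
nucleusParams <- function(cal = Calibration(), rNuc = NULL, sigmaBlur = NULL,
                          basalCutoff = 0L, watershedTolerance = 2,
                          areaMin = NULL, areaMax = NULL, roundnessMin = 0.3,
                          excludeEdges = TRUE) {
  ndPx <- cal@nucleusDiameter / cal@dx
  if (is.null(rNuc)) rNuc <- round(0.5 * ndPx)
  if (is.null(sigmaBlur)) sigmaBlur <- 0.1 * ndPx
  discArea <- pi * (cal@nucleusDiameter / 2)^2
  if (is.null(areaMin)) areaMin <- 0.25 * discArea
  if (is.null(areaMax)) areaMax <- 4 * discArea
  new("NucleusParams", rNuc = as.integer(rNuc), sigmaBlur = sigmaBlur,
      basalCutoff = as.integer(basalCutoff),
      watershedTolerance = watershedTolerance, areaMin = areaMin,
      areaMax = areaMax, roundnessMin = roundnessMin,
      excludeEdges = excludeEdges)
}

#' Gradual signal separation
#'
#' First half of the stain-free nucleus recognition: the slice-wise mean ALT
#' turns the dim nuclear autofluorescence into a binary estimate
#' (object = 255), which a Gaussian blur then smears into a grayscale stack
#' in which nuclear, cytosolic and extracellular areas occupy distinct grey
#' bands.
#'
#' @param normStack the per-slice normalized 8-bit stack.
#' @param params a \code{\linkS4class{NucleusParams}}.
#' @return an 8-bit \code{\linkS4class{ImageStack}} of separated signal.
#' @export
separateSignal <- function(normStack, params = nucleusParams(calibration(normStack))) {
  m <- altStack(normStack, "mean", r = params@rNuc)
  v <- array(0, dim(m))
  for (z in seq_len(dim(m)[3])) {
    sl <- EBImage::gblur(matrix(as.numeric(m[, , z]) * 255, dim(m)[1]),
                         sigma = params@sigmaBlur)
    v[, , z] <- pmin(pmax(floor(sl + 0.5), 0), 255)
  }
  ImageStack(v, calibration = calibration(normStack), bitDepth = 8,
             channelCount = normStack@channelCount)
}

#' Candidate nuclear voxels from the separated stack
#'
#' Applies the slice-wise mid-gray ALT to the gradually separated stack; the
#' highest grey band (nuclei) survives while cytosolic and exterior signal
#' is discarded.
#'
#' @param sepStack output of \code{\link{separateSignal}}.
#' @param params a \code{\linkS4class{NucleusParams}}.
#' @return 3D logical array of candidate nuclear voxels.
#' @export
nucleusMask <- function(sepStack, params = nucleusParams(calibration(sepStack))) {
  altStack(sepStack, "midgray", r = params@rNuc)
}

#' Z-projection of the nuclear mask with basal cutoff
#'
#' Logical-OR projection over slices above the basal cutoff; the excluded
#' basal slices keep glass-surface artifacts out of the footprint while the
#' projected area, dominated by the nuclear midsection, is unaffected.
#'
#' @param mask 3D logical array (slice 1 = basal).
#' @param basalCutoff number of basal slices to exclude.
#' @return 2D logical footprint mask.
#' @export
projectNuclei <- function(mask, basalCutoff = 0L) {
  nz <- dim(mask)[3]
  if (basalCutoff >= nz) stop("basalCutoff must be smaller than the slice count")
  keep <- seq.int(basalCutoff + 1L, nz)
  out <- matrix(FALSE, dim(mask)[1], dim(mask)[2])
  for (z in keep) out <- out | mask[, , z]
  out
}

#' Watershed separation of converging nuclei
#'
#' Euclidean-distance-transform watershed of the 2D footprint mask. Seeds
#' are distance-map maxima surviving suppression of maxima shallower than
#' \code{tolerance}; every foreground pixel is assigned to exactly one
#' label.
#'
#' @param mask2d 2D logical footprint mask.
#' @param tolerance minima-suppression tolerance (px of distance).
#' @return 2D integer label map with consecutive labels 1..K.
#' @export
nucleiWatershed <- function(mask2d, tolerance = 2) {
  if (!any(mask2d)) return(matrix(0L, nrow(mask2d), ncol(mask2d)))
  w <- EBImage::watershed(EBImage::distmap(mask2d), tolerance = tolerance)
  .relabelRaster(matrix(as.integer(w), nrow(mask2d)))
}

# consecutive labels 1..K in order of first (column-major) occurrence
.relabelRaster <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (length(u) == 0L) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Particle filtering of candidate nuclei
#'
#' Measures area, perimeter and circularity of every labelled footprint and
#' retains those inside the area bounds with circularity at least
#' \code{roundnessMin}; nuclei in contact with the image edge are discarded
#' when \code{excludeEdges} is on (partially imaged nuclei would bias the
#' foci counts). Survivors are relabelled 1..K.
#'
#' The perimeter is the 8-connected contour chain length (unit steps and
#' \code{sqrt(2)} diagonal steps), under which a digital disc of radius
#' 20 px has circularity about 0.91.
#'
#' @param labels 2D integer label map.
#' @param cal a \code{\linkS4class{Calibration}}.
#' @param params a \code{\linkS4class{NucleusParams}}.
#' @return a \code{\linkS4class{NucleusSet}}.
#' @export
filterNuclei <- function(labels, cal, params = nucleusParams(cal)) {
  K <- max(labels)
  pxArea <- cal@dx * cal@dy
  if (K == 0L) {
    return(new("NucleusSet", labels = labels,
               rois = .emptyRois(), calibration = cal))
  }
  areaPx <- tabulate(labels[labels > 0L], nbins = K)
  per <- .chainPerimeters(labels, K)
  circ <- 4 * pi * areaPx / pmax(per, 1)^2
  ny <- nrow(labels); nx <- ncol(labels)
  edgeLabels <- unique(c(labels[1, ], labels[ny, ], labels[, 1], labels[, nx]))
  touches <- seq_len(K) %in% edgeLabels[edgeLabels > 0L]
  areaUm2 <- areaPx * pxArea
  keep <- areaUm2 >= params@areaMin & areaUm2 <= params@areaMax &
    circ >= params@roundnessMin & !(params@excludeEdges & touches)
  newLab <- matrix(0L, ny, nx)
  map <- integer(K)
  map[which(keep)] <- seq_len(sum(keep))
  pos <- labels > 0L
  newLab[pos] <- map[labels[pos]]
  idx <- which(keep)
  rois <- .emptyRois()
  if (length(idx) > 0) {
    cy <- vapply(idx, function(k) mean(row(labels)[labels == k]), 0)
    cx <- vapply(idx, function(k) mean(col(labels)[labels == k]), 0)
    rois <- data.frame(label = seq_along(idx),
                       areaUm2 = areaUm2[idx],
                       xUm = (cx - 0.5) * cal@dx,
                       yUm = (cy - 0.5) * cal@dy,
                       circularity = circ[idx],
                       touchesEdge = touches[idx])
  }
  new("NucleusSet", labels = newLab, rois = rois, calibration = cal)
}

.emptyRois <- function() {
  data.frame(label = integer(), areaUm2 = numeric(), xUm = numeric(),
             yUm = numeric(), circularity = numeric(),
             touchesEdge = logical())
}

# 8-connected outer-contour chain length per label
.chainPerimeters <- function(labels, K) {
  oc <- EBImage::ocontour(labels)
  per <- numeric(K)
  for (k in seq_len(K)) {
    ct <- oc[[k]]
    if (is.null(ct) || nrow(ct) < 2L) { per[k] <- 4; next }
    d <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])
    per[k] <- sum(sqrt(rowSums(d^2)))
  }
  per
}

#' Full stain-free nucleus detection
#'
#' Composition of the whole nucleus-identification chain: per-slice
#' normalization, gradual signal separation (mean ALT + Gaussian blur),
#' mid-gray ALT, basal-cutoff z-projection, tolerance watershed and particle
#' filtering.
#'
#' @param stack a raw or normalized \code{\linkS4class{ImageStack}}.
#' @param params a \code{\linkS4class{NucleusParams}}.
#' @return a \code{\linkS4class{NucleusSet}}.
#' @examples
#' \donttest{
#' sc <- renderScene(fociFieldScene(5, seed = 1))
#' nuc <- detectNuclei(sc$stack)
#' nucleusROIs(nuc)
#' }
#' @export
detectNuclei <- function(stack, params = nucleusParams(calibration(stack))) {
  norm <- normalizeSlicewise(stack)
  sep <- separateSignal(norm, params)
  mask <- nucleusMask(sep, params)
  fp <- projectNuclei(mask, params@basalCutoff)
  lab <- nucleiWatershed(fp, params@watershedTolerance)
  filterNuclei(lab, calibration(stack), params)
}
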