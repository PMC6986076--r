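#' Foci-detection parameters from a calibration
#'
#' The median-ALT domain radius defaults to twice the effective focus
#' diameter in pixels (30 px at 0.1 um pixels and a 1.5 um effective focus
#' extent). The minimum object size defaults to the voxel volume of a sphere
#' a quarter of the effective focus diameter wide (floored, at least 2
#' voxels), suppressing single-voxel noise.
#'
#' @param cal a \code{\linkS4class{Calibration}}.
#' @param rFoci median ALT domain radius (px); default
#'   \code{round(2 * fociDiameter / dx)}.
#' @param cFoci ALT offset (grey levels, default 0).
#' @param preBlurSigma optional Gaussian pre-blur sigma (px; 0 = off). Extra
#'   blurring is usually unnecessary for clean stacks; it is intended for
#'   poor-quality, low-signal acquisitions.
#' @param use3dws activate the seeded 3D watershed to split touching foci
#'   (computationally heavier; worthwhile at high foci densities).
#' @param maximaTolerance prominence threshold (grey levels) of the 3D seed
#'   finder.
#' @param minFocusVoxels minimum retained object size (voxels).
#' @param maxFocusVoxels maximum retained object size (voxels); defaults to
#'   the voxel volume of a sphere twice the effective focus diameter wide,
#'   discarding threshold artifacts far larger than any plausible focus.
#' @return a \code{\linkS4class{FociParams}} object.
#' @export
fociParams <- function(cal = Calibration(), rFoci = NULL, cFoci = 0,
                       preBlurSigma = 0, use3dws = FALSE,
                       maximaTolerance = 10, minFocusVoxels = NULL,
                       maxFocusVoxels = NULL) {
  if (is.null(rFoci)) rFoci <- round(2 * cal@fociDiameter / cal@dx)
  if (is.null(minFocusVoxels)) {
    rUm <- 0.25 * cal@fociDiameter / 2
    minFocusVoxels <- max(2L, as.integer(floor(4 / 3 * pi * rUm^3 /
                                                 voxelVolume(cal))))
  }
  if (is.null(maxFocusVoxels)) {
    rUm <- cal@fociDiameter
    maxFocusVoxels <- as.integer(ceiling(4 / 3 * pi * rUm^3 /
                                           voxelVolume(cal)))
  }
  new("FociParams", rFoci = as.integer(rFoci), cFoci = cFoci,
      preBlurSigma = preBlurSigma, use3dws = use3dws,
      maximaTolerance = maximaTolerance,
      minFocusVoxels = as.integer(minFocusVoxels),
      maxFocusVoxels = as.integer(maxFocusVoxels))
}

#' 3D binary foci mask
#'
#' Optional slice-wise Gaussian pre-blur followed by the slice-wise median
#' ALT with the focus-scale radius; bright puncta rise above the robust
#' local background estimate and form one 3D binary blob per focus.
#'
#' @param normStack per-slice normalized 8-bit stack.
#' @param params a \code{\linkS4class{FociParams}}.
#' @return 3D logical array, \code{TRUE} = focus voxel.
#' @export
fociMask <- function(normStack, params = fociParams(calibration(normStack))) {
  v <- voxels(normStack)
  if (params@preBlurSigma > 0) {
    for (z in seq_len(dim(v)[3]))
      v[, , z] <- pmin(pmax(floor(EBImage::gblur(v[, , z],
                                                 params@preBlurSigma) + 0.5),
                            0), 255)
  }
  altStack(v, "median", r = params@rFoci, c = params@cFoci)
}

#' 3D intensity maxima with prominence suppression
#'
#' Finds 26-neighbourhood local maxima of the normalized stack whose
#' prominence (height above the saddle connecting them to a higher maximum)
#' exceeds \code{tolerance}. An intensity plateau yields one seed at its
#' centroid, rounded to the nearest voxel. Used to seed the 3D watershed.
#'
#' @param normStack an \code{\linkS4class{ImageStack}} (any grey scale).
#' @param tolerance prominence threshold (grey levels).
#' @return integer matrix of 1-based voxel coordinates, columns
#'   \code{y}, \code{x}, \code{z}; ordered by decreasing peak intensity.
#' @export
findMaxima3D <- function(normStack, tolerance = 10) {
  v <- if (is(normStack, "ImageStack")) voxels(normStack) else normStack
  m <- maxima3d_cpp(as.numeric(v), dim(v), tolerance) + 1L
  colnames(m) <- c("y", "x", "z")
  m
}

#' Seeded 3D watershed of a foci mask
#'
#' Splits every foreground component holding two or more seeds along the
#' ridge lines of its (anisotropic) Euclidean distance transform, flooding
#' from the seeds in order of decreasing distance to the background.
#' Components with at most one seed are kept whole; an unseeded component
#' still counts once (a focus whose maximum fell below the seed tolerance
#' should not vanish). Seeds outside the foreground are dropped with a
#' warning.
#'
#' @param mask 3D logical array.
#' @param seeds integer matrix of 1-based voxel coordinates
#'   (\code{y}, \code{x}, \code{z}), e.g. from \code{\link{findMaxima3D}}.
#' @param cal a \code{\linkS4class{Calibration}} (for the anisotropic
#'   distance transform).
#' @return 3D integer label array with consecutive labels 1..K.
#' @export
fociWatershed3D <- function(mask, seeds, cal = Calibration()) {
  d <- dim(mask)
  if (!any(mask)) return(array(0L, d))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  idx <- (seeds[, 3] - 1) * d[1] * d[2] + (seeds[, 2] - 1) * d[1] + seeds[, 1]
  inFg <- as.logical(mask[cbind(seeds[, 1], seeds[, 2], seeds[, 3])])
  if (any(!inFg)) {
    warning(sum(!inFg), " seed(s) outside the foreground were dropped")
    idx <- idx[inFg]
  }
  comps <- label3d_cpp(as.logical(mask), d)
  edt <- edt3d_cpp(as.logical(mask), d, cal@dy, cal@dx, cal@dz)
  lab <- ws3d_cpp(as.logical(mask), d, comps, as.integer(idx - 1), edt)
  out <- array(.relabelRaster(matrix(lab, nrow = 1))[1, ], d)
  storage.mode(out) <- "integer"
  out
}

#' 26-connected labeling of a 3D mask
#'
#' @param mask 3D logical array.
#' @return 3D integer label array, labels 1..K in raster discovery order.
#' @export
labelFoci3D <- function(mask) {
  lab <- label3d_cpp(as.logical(mask), dim(mask))
  array(lab, dim(mask))
}

#' Count and measure foci per nucleus
#'
#' Labels the foci mask (26-connected components, or the seeded 3D watershed
#' labels when \code{params@use3dws} is on and \code{x} already carries
#' them), removes objects smaller than \code{minFocusVoxels}, measures each
#' focus (volume = voxels x voxel volume; surface area by exposed-face
#' counting with anisotropic face areas; centroid in um; mean/max intensity
#' on the normalized stack) and assigns it to the nucleus whose 2D footprint
#' contains its (x, y) centroid. Foci landing outside every footprint are
#' not reported.
#'
#' @param x 3D logical foci mask or a 3D integer label array.
#' @param nuclei a \code{\linkS4class{NucleusSet}}.
#' @param normStack the normalized stack intensities are measured on.
#' @param params a \code{\linkS4class{FociParams}}.
#' @return a \code{\linkS4class{FociResult}}; the summary has one row per
#'   retained nucleus (zero counts included).
#' @export
countFoci <- function(x, nuclei, normStack,
                      params = fociParams(calibration(normStack))) {
  cal <- calibration(normStack)
  if (is.logical(x)) {
    labels <- if (params@use3dws) {
      seeds <- findMaxima3D(normStack, params@maximaTolerance)
      fociWatershed3D(x, seeds, cal)
    } else labelFoci3D(x)
  } else labels <- x
  st <- region_stats3d_cpp(as.integer(labels), dim(labels),
                           as.numeric(voxels(normStack)))
  st <- st[st$nvox >= params@minFocusVoxels &
             st$nvox <= params@maxFocusVoxels, , drop = FALSE]
  fp <- labelMap(nuclei)
  rois <- nucleusROIs(nuclei)
  foci <- .emptyFoci()
  if (nrow(st) > 0) {
    # voxel-centre centroid -> um; then the footprint pixel containing it
    xUm <- (st$cx + 0.5) * cal@dx
    yUm <- (st$cy + 0.5) * cal@dy
    zUm <- (st$cz + 0.5) * cal@dz
    px <- pmin(pmax(floor(xUm / cal@dx) + 1, 1), ncol(fp))
    py <- pmin(pmax(floor(yUm / cal@dy) + 1, 1), nrow(fp))
    nucLab <- fp[cbind(py, px)]
    keep <- nucLab > 0L
    st <- st[keep, , drop = FALSE]
    if (nrow(st) > 0) {
      surf <- st$facesY * cal@dx * cal@dz + st$facesX * cal@dy * cal@dz +
        st$facesZ * cal@dx * cal@dy
      ord <- order(nucLab[keep], st$label)
      st <- st[ord, , drop = FALSE]
      foci <- data.frame(
        focusId = seq_len(nrow(st)),
        nucleusLabel = nucLab[keep][ord],
        voxelCount = st$nvox,
        volumeUm3 = st$nvox * voxelVolume(cal),
        surfaceUm2 = surf[ord],
        xUm = xUm[keep][ord], yUm = yUm[keep][ord], zUm = zUm[keep][ord],
        meanIntensity = st$meanInt, maxIntensity = st$maxInt)
    }
  }
  fn3d <- vapply(rois$label, function(l) sum(foci$nucleusLabel == l), 0L)
  summary <- data.frame(nucleusLabel = rois$label, fn3d = fn3d)
  keepLab <- array(0L, dim(labels))
  if (nrow(foci) > 0) {
    keepMask <- labels %in% st$label
    keepLab[keepMask] <- labels[keepMask]
    keepLab <- array(.relabelRaster(matrix(keepLab, nrow = 1))[1, ],
                     dim(labels))
    storage.mode(keepLab) <- "integer"
  }
  new("FociResult", foci = foci, nucleusSummary = summary, labels = keepLab)
}

.emptyFoci <- function() {
  data.frame(focusId = integer(), nucleusLabel = integer(),
             voxelCount = integer(), volumeUm3 = numeric(),
             surfaceUm2 = numeric(), xUm = numeric(), yUm = numeric(),
             zUm = numeric(), meanIntensity = numeric(),
             maxIntensity = numeric())
}

#' Default midsection slice
#'
#' The 2D counting mode operates on the slice located about 3 um above the
#' glass surface. With slice 1 basal and \code{dz} um between slices, the
#' 1-based index is \code{round(3 / dz) + 1}; at dz = 0.25 um this is slice
#' 13 (0-based index 12).
#'
#' @param dz axial voxel size (um/slice).
#' @return 1-based slice index.
#' @export
midsectionSlice <- function(dz) as.integer(round(3 / dz)) + 1L

#' 2D foci counting in a midsection slice
#'
#' The same detection chain restricted to one slice: median ALT,
#' 8-connected labeling, optional seeded watershed splitting, size
#' exclusion (the 2D analogue of the voxel minimum: the pixel area of a
#' disc a quarter of the effective focus diameter wide, at least 2 px) and
#' per-nucleus assignment by centroid.
#'
#' @param normStack normalized 8-bit stack.
#' @param nuclei a \code{\linkS4class{NucleusSet}}.
#' @param params a \code{\linkS4class{FociParams}}.
#' @param midsection 1-based slice index; default
#'   \code{midsectionSlice(dz)}.
#' @return data.frame with \code{nucleusLabel} and \code{fn2d}.
#' @export
countFoci2D <- function(normStack, nuclei,
                        params = fociParams(calibration(normStack)),
                        midsection = NULL) {
  cal <- calibration(normStack)
  if (is.null(midsection)) midsection <- midsectionSlice(cal@dz)
  v <- voxels(normStack)
  if (midsection < 1L || midsection > dim(v)[3])
    stop("midsection slice index out of range")
  sl <- v[, , midsection]
  m <- autoLocalThreshold(sl, "median", r = params@rFoci, c = params@cFoci)
  if (params@use3dws && any(m)) {
    sl3 <- array(sl, c(dim(sl), 1L))
    seeds <- findMaxima3D(ImageStack(sl3, cal, bitDepth = 8),
                          params@maximaTolerance)
    lab <- fociWatershed3D(array(m, c(dim(m), 1L)), seeds, cal)[, , 1]
  } else {
    lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m))
  }
  K <- max(lab)
  rois <- nucleusROIs(nuclei)
  fp <- labelMap(nuclei)
  minPx <- max(2L, as.integer(floor(pi * (0.25 * cal@fociDiameter / 2)^2 /
                                      (cal@dx * cal@dy))))
  maxPx <- as.integer(ceiling(pi * cal@fociDiameter^2 / (cal@dx * cal@dy)))
  counts <- integer(nrow(rois))
  if (K > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = K)
    for (k in which(sizes >= minPx & sizes <= maxPx)) {
      cy <- mean(row(lab)[lab == k]); cx <- mean(col(lab)[lab == k])
      nl <- fp[pmin(pmax(round(cy), 1), nrow(fp)),
               pmin(pmax(round(cx), 1), ncol(fp))]
      if (nl > 0L) {
        i <- match(nl, rois$label)
        if (!is.na(i)) counts[i] <- counts[i] + 1L
      }
    }
  }
  data.frame(nucleusLabel = rois$label, fn2d = counts)
}

#' Full foci analysis of one stack
#'
#' Convenience composition: normalize, detect nuclei, build the foci mask,
#' count in 3D and optionally in the 2D midsection.
#'
#' @param stack raw \code{\linkS4class{ImageStack}}.
#' @param nucParams a \code{\linkS4class{NucleusParams}}.
#' @param params a \code{\linkS4class{FociParams}}.
#' @param mode \code{"3d"} or \code{"both"} (adds the 2D midsection count).
#' @param midsection optional 1-based midsection slice index.
#' @return list with elements \code{nuclei} (\code{NucleusSet}) and
#'   \code{foci} (\code{FociResult}; with \code{mode = "both"} the summary
#'   gains an \code{fn2d} column).
#' @export
analyzeStack <- function(stack,
                         nucParams = nucleusParams(calibration(stack)),
                         params = fociParams(calibration(stack)),
                         mode = c("3d", "both"), midsection = NULL) {
  mode <- match.arg(mode)
  norm <- normalizeSlicewise(stack)
  nuclei <- detectNuclei(stack, nucParams)
  mask <- fociMask(norm, params)
  res <- countFoci(mask, nuclei, norm, params)
  if (mode == "both") {
    f2 <- countFoci2D(norm, nuclei, params, midsection)
    res@nucleusSummary <- merge(res@nucleusSummary, f2, by = "nucleusLabel")
  }
  list(nuclei = nuclei, foci = res)
}
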