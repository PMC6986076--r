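#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib foci3d, .registration = TRUE
NULL

#' Voxel calibration and object-size priors
#'
#' Holds the physical voxel size of a confocal z-stack together with the two
#' object-scale priors the detection pipeline derives its window radii from:
#' the expected mean nucleus diameter and the expected effective focus
#' diameter (the full extent of a focus including its dim halo, not its
#' FWHM). All values are in micrometres.
#'
#' @slot dx,dy lateral voxel size (um per pixel).
#' @slot dz axial voxel size (um per slice).
#' @slot nucleusDiameter expected mean nucleus diameter (um).
#' @slot fociDiameter expected effective focus diameter (um).
#' @export
setClass("Calibration",
  representation(dx = "numeric", dy = "numeric", dz = "numeric",
                 nucleusDiameter = "numeric", fociDiameter = "numeric"))

setValidity("Calibration", function(object) {
  v <- c(dx = object@dx, dy = object@dy, dz = object@dz,
         nucleusDiameter = object@nucleusDiameter,
         fociDiameter = object@fociDiameter)
  if (any(lengths(list(object@dx, object@dy, object@dz,
                       object@nucleusDiameter, object@fociDiameter)) != 1L))
    return("all calibration fields must be single numbers")
  if (any(!is.finite(v)) || any(v <= 0))
    return("all calibration fields must be strictly positive")
  if (object@nucleusDiameter <= object@fociDiameter)
    return("nucleusDiameter must exceed fociDiameter")
  TRUE
})

#' Construct a Calibration
#'
#' Defaults match a typical confocal acquisition for repair-focus imaging:
#' 0.1 x 0.1 um lateral and 0.25 um axial voxels.
#'
#' @param dx,dy lateral voxel size (um/px).
#' @param dz axial voxel size (um/slice).
#' @param nucleusDiameter expected mean nucleus diameter (um).
#' @param fociDiameter expected effective focus diameter (um), i.e. the full
#'   visible extent of a focus; with the default 0.1 um pixels the focus
#'   thresholding radius becomes \code{2 * fociDiameter / dx = 30} px.
#' @return a \code{Calibration} object.
#' @examples
#' cal <- Calibration()
#' voxelVolume(cal)
#' @export
Calibration <- function(dx = 0.1, dy = 0.1, dz = 0.25,
                        nucleusDiameter = 16, fociDiameter = 1.5) {
  new("Calibration", dx = dx, dy = dy, dz = dz,
      nucleusDiameter = nucleusDiameter, fociDiameter = fociDiameter)
}

#' A calibrated 3D image stack
#'
#' The central data container: a 3D grid of non-negative intensities stored
#' as an array indexed \code{[y, x, z]} (1-based; slice 1 is the basal,
#' glass-side slice) plus its \code{\linkS4class{Calibration}}. Exported
#' physical coordinates are voxel centres: voxel index \code{i} (1-based)
#' maps to \code{(i - 0.5) * voxelsize}.
#'
#' @slot voxels 3D numeric array \code{[y, x, z]}.
#' @slot calibration a \code{Calibration}.
#' @slot bitDepth source bit depth (8 or 16).
#' @slot channelCount number of channels in the source file.
#' @export
setClass("ImageStack",
  representation(voxels = "array", calibration = "Calibration",
                 bitDepth = "numeric", channelCount = "integer"))

setValidity("ImageStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array [y, x, z]")
  if (any(d < 1L)) return("voxels must be non-empty")
  if (anyNA(object@voxels) || any(object@voxels < 0))
    return("voxel intensities must be non-negative and non-missing")
  if (!object@bitDepth %in% c(8, 16))
    return("bitDepth must be 8 or 16")
  if (object@channelCount < 1L) return("channelCount must be >= 1")
  TRUE
})

#' Construct an ImageStack
#'
#' @param voxels 3D numeric array \code{[y, x, z]}, or a matrix (treated as a
#'   single-slice stack).
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param bitDepth source bit depth (8 or 16).
#' @param channelCount number of channels in the source file.
#' @return an \code{ImageStack}.
#' @export
ImageStack <- function(voxels, calibration = Calibration(), bitDepth = 16,
                       channelCount = 1L) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "double"
  new("ImageStack", voxels = voxels, calibration = calibration,
      bitDepth = bitDepth, channelCount = as.integer(channelCount))
}

#' Nucleus-detection parameters
#'
#' Tunables of the stain-free nucleus recognition chain. Constructed with
#' \code{\link{nucleusParams}}, which derives the window radius and blur
#' sigma from the calibrated mean nucleus diameter.
#'
#' @slot rNuc local-threshold domain radius for the nucleus steps (px).
#' @slot sigmaBlur Gaussian sigma for the signal-separation blur (px).
#' @slot basalCutoff number of basal slices excluded from the z-projection.
#' @slot watershedTolerance minima-suppression tolerance of the 2D watershed
#'   (px of distance-map height).
#' @slot areaMin,areaMax retained particle area bounds (um^2).
#' @slot roundnessMin minimum circularity \code{4*pi*area/perimeter^2}.
#' @slot excludeEdges drop nuclei touching the image border.
#' @export
setClass("NucleusParams",
  representation(rNuc = "integer", sigmaBlur = "numeric",
                 basalCutoff = "integer", watershedTolerance = "numeric",
                 areaMin = "numeric", areaMax = "numeric",
                 roundnessMin = "numeric", excludeEdges = "logical"))

setValidity("NucleusParams", function(object) {
  if (object@rNuc < 1L) return("rNuc must be >= 1")
  if (object@sigmaBlur <= 0) return("sigmaBlur must be > 0")
  if (object@basalCutoff < 0L) return("basalCutoff must be >= 0")
  if (object@roundnessMin < 0 || object@roundnessMin > 1)
    return("roundnessMin must be in [0, 1]")
  if (object@areaMin >= object@areaMax) return("areaMin must be < areaMax")
  TRUE
})

#' Foci-detection parameters
#'
#' Constructed with \code{\link{fociParams}}; the threshold radius defaults
#' to twice the effective focus diameter in pixels.
#'
#' @slot rFoci median local-threshold domain radius (px).
#' @slot cFoci threshold offset (grey levels).
#' @slot preBlurSigma optional Gaussian pre-blur sigma (px; 0 = off).
#' @slot use3dws split touching foci with the seeded 3D watershed.
#' @slot maximaTolerance prominence threshold of the 3D seed finder (grey
#'   levels of the normalized 8-bit stack).
#' @slot minFocusVoxels minimum object size kept (voxels).
#' @slot maxFocusVoxels maximum object size kept (voxels); objects larger
#'   than any plausible focus (e.g. threshold artifacts spanning the
#'   nucleus) are discarded.
#' @export
setClass("FociParams",
  representation(rFoci = "integer", cFoci = "numeric",
                 preBlurSigma = "numeric", use3dws = "logical",
                 maximaTolerance = "numeric", minFocusVoxels = "integer",
                 maxFocusVoxels = "integer"))

setValidity("FociParams", function(object) {
  if (object@rFoci < 1L) return("rFoci must be >= 1")
  if (object@maximaTolerance < 0) return("maximaTolerance must be >= 0")
  if (object@minFocusVoxels < 1L) return("minFocusVoxels must be >= 1")
  if (object@maxFocusVoxels < object@minFocusVoxels)
    return("maxFocusVoxels must be >= minFocusVoxels")
  if (object@preBlurSigma < 0) return("preBlurSigma must be >= 0")
  TRUE
})

#' Detected nuclei of one stack
#'
#' A 2D label map of nucleus footprints (0 = background, labels 1..K
#' consecutive) plus one row of measurements per retained nucleus.
#'
#' @slot labels integer matrix of footprint labels.
#' @slot rois data.frame with columns \code{label}, \code{areaUm2},
#'   \code{xUm}, \code{yUm} (footprint centroid), \code{circularity},
#'   \code{touchesEdge}.
#' @slot calibration the stack calibration.
#' @export
setClass("NucleusSet",
  representation(labels = "matrix", rois = "data.frame",
                 calibration = "Calibration"))

#' Per-focus measurements and per-nucleus counts
#'
#' @slot foci data.frame, one row per retained focus: \code{focusId},
#'   \code{nucleusLabel}, \code{voxelCount}, \code{volumeUm3},
#'   \code{surfaceUm2}, \code{xUm}, \code{yUm}, \code{zUm},
#'   \code{meanIntensity}, \code{maxIntensity}.
#' @slot nucleusSummary data.frame, one row per nucleus: \code{nucleusLabel},
#'   \code{fn3d} and (when computed) \code{fn2d}.
#' @slot labels 3D integer label array of the retained foci (may be empty).
#' @export
setClass("FociResult",
  representation(foci = "data.frame", nucleusSummary = "data.frame",
                 labels = "array"))

#' Fitted induction-decay (Mariotti) model
#'
#' @slot params named numeric vector \code{A}, \code{tau1}, \code{tau2},
#'   \code{R}.
#' @slot rss residual sum of squares of the best start.
#' @slot converged whether any start converged.
#' @slot peakTime analytic time of the foci maximum,
#'   \code{tau1 * log(1 + tau2/tau1)} (min).
#' @slot nObs number of fitted time points.
#' @export
setClass("MariottiFit",
  representation(params = "numeric", rss = "numeric", converged = "logical",
                 peakTime = "numeric", nObs = "integer"))

#' Specification of a synthetic confocal scene
#'
#' Describes a ground-truthed scene: dim autofluorescent ellipsoidal nuclei
#' containing bright Gaussian foci over a flat background, with per-slice
#' multiplicative signal decay, an optional bright basal glass-surface
#' artifact layer and Gaussian read noise. Rendered by
#' \code{\link{renderScene}}.
#'
#' @slot dims integer vector \code{(ny, nx, nz)}.
#' @slot calibration a \code{Calibration}.
#' @slot nuclei data.frame: centre \code{cx,cy,cz} (um), semi-axes
#'   \code{ax,ay,az} (um), interior \code{intensity} (a.u.).
#' @slot foci data.frame: centre \code{x,y,z} (um), \code{sigma} (um),
#'   \code{peak} amplitude (a.u.), \code{nucleus} parent index (0 = none).
#' @slot background flat background intensity (a.u.).
#' @slot noiseSd Gaussian read-noise sd (a.u.).
#' @slot bleachRate per-slice multiplicative decay in (0, 1].
#' @slot basalArtifactSlices number of basal slices carrying the artifact.
#' @slot basalArtifactIntensity artifact peak intensity (a.u.).
#' @slot textureAmp smooth interior-texture amplitude as a fraction of the
#'   interior excess intensity (0 disables).
#' @slot seed RNG seed; rendering is deterministic per seed.
#' @export
setClass("SceneSpec",
  representation(dims = "integer", calibration = "Calibration",
                 nuclei = "data.frame", foci = "data.frame",
                 background = "numeric", noiseSd = "numeric",
                 bleachRate = "numeric", basalArtifactSlices = "integer",
                 basalArtifactIntensity = "numeric", textureAmp = "numeric",
                 seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers (ny, nx, nz)")
  if (object@bleachRate <= 0 || object@bleachRate > 1)
    return("bleachRate must be in (0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  nuc <- object@nuclei
  if (nrow(nuc) > 0 && any(nuc$intensity <= object@background))
    return("nucleus interior intensity must exceed the background")
  fc <- object@foci
  if (nrow(fc) > 0) {
    ext <- c(object@dims[2] * object@calibration@dx,
             object@dims[1] * object@calibration@dy,
             object@dims[3] * object@calibration@dz)
    if (any(fc$x < 0 | fc$x > ext[1] | fc$y < 0 | fc$y > ext[2] |
            fc$z < 0 | fc$z > ext[3]))
      return("all focus centres must lie inside the imaged volume")
    par <- fc$nucleus
    for (i in seq_len(nrow(fc))) {
      if (par[i] < 1) next
      if (par[i] > nrow(nuc)) return("focus parent nucleus index out of range")
      nn <- nuc[par[i], ]
      r2 <- ((fc$x[i] - nn$cx) / nn$ax)^2 + ((fc$y[i] - nn$cy) / nn$ay)^2 +
            ((fc$z[i] - nn$cz) / nn$az)^2
      if (r2 > 1) return("parented focus centre lies outside its nucleus")
      if (nrow(nuc) > 0 && any(fc$peak + 0 <= 0))
        return("focus peak must be positive")
    }
  }
  TRUE
})

#' Ground truth of a rendered scene
#'
#' @slot nuclei the scene's nucleus geometry plus a \code{fociCount} column.
#' @slot foci the scene's focus table.
#' @slot midsection 1-based index of the designated midsection slice.
#' @slot dims scene dimensions \code{(ny, nx, nz)}.
#' @slot calibration the scene calibration.
#' @export
setClass("GroundTruth",
  representation(nuclei = "data.frame", foci = "data.frame",
                 midsection = "integer", dims = "integer",
                 calibration = "Calibration"))
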