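#' Accessors
#'
#' @param object,x a foci3d object.
#' @name accessors
NULL

#' @describeIn accessors the calibration attached to an object.
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @describeIn accessors the raw voxel array \code{[y, x, z]}.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @describeIn accessors number of z slices.
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))

#' @describeIn accessors per-nucleus ROI table of a \code{NucleusSet}.
#' @export
setGeneric("nucleusROIs", function(object) standardGeneric("nucleusROIs"))

#' @describeIn accessors 2D/3D label map of a detection result.
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' @describeIn accessors per-focus measurement table of a \code{FociResult}.
#' @export
setGeneric("fociTable", function(object) standardGeneric("fociTable"))

#' @describeIn accessors per-nucleus foci-count summary of a
#'   \code{FociResult}.
#' @export
setGeneric("fociCounts", function(object) standardGeneric("fociCounts"))

#' @export
setMethod("calibration", "ImageStack", function(object) object@calibration)
#' @export
setMethod("calibration", "NucleusSet", function(object) object@calibration)
#' @export
setMethod("calibration", "SceneSpec", function(object) object@calibration)
#' @export
setMethod("calibration", "GroundTruth", function(object) object@calibration)

#' @export
setMethod("voxels", "ImageStack", function(object) object@voxels)
#' @export
setMethod("nSlices", "ImageStack", function(object) dim(object@voxels)[3])

#' @export
setMethod("nucleusROIs", "NucleusSet", function(object) object@rois)
#' @export
setMethod("labelMap", "NucleusSet", function(object) object@labels)
#' @export
setMethod("labelMap", "FociResult", function(object) object@labels)
#' @export
setMethod("fociTable", "FociResult", function(object) object@foci)
#' @export
setMethod("fociCounts", "FociResult", function(object) object@nucleusSummary)

#' Physical voxel volume
#'
#' @param cal a \code{\linkS4class{Calibration}}.
#' @return voxel volume in um^3 (\code{dx * dy * dz}).
#' @export
voxelVolume <- function(cal) cal@dx * cal@dy * cal@dz

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.3g x %.3g x %.3g um/voxel; nucleus ~%.3g um, focus ~%.3g um\n",
              object@dx, object@dy, object@dz,
              object@nucleusDiameter, object@fociDiameter))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d px, %d slices (%d-bit source, %d channel%s)\n",
              d[1], d[2], d[3], as.integer(object@bitDepth),
              object@channelCount, if (object@channelCount > 1) "s" else ""))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
  show(object@calibration)
})

setMethod("show", "NucleusSet", function(object) {
  cat(sprintf("NucleusSet: %d nucle%s retained\n", nrow(object@rois),
              if (nrow(object@rois) == 1) "us" else "i"))
  if (nrow(object@rois) > 0) print(utils::head(object@rois, 10))
})

setMethod("show", "FociResult", function(object) {
  cat(sprintf("FociResult: %d foc%s in %d nucle%s\n",
              nrow(object@foci), if (nrow(object@foci) == 1) "us" else "i",
              nrow(object@nucleusSummary),
              if (nrow(object@nucleusSummary) == 1) "us" else "i"))
  if (nrow(object@nucleusSummary) > 0) print(object@nucleusSummary)
})

setMethod("show", "MariottiFit", function(object) {
  p <- object@params
  cat("Induction-decay (Mariotti) model fit\n")
  cat(sprintf("  A = %.4g  tau1 = %.4g min  tau2 = %.4g min  R = %.4g foci\n",
              p["A"], p["tau1"], p["tau2"], p["R"]))
  cat(sprintf("  peak time t* = %.4g min;  RSS = %.4g;  converged: %s (n = %d)\n",
              object@peakTime, object@rss, object@converged, object@nObs))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d x %d voxels, %d nucle%s, %d foc%s (seed %d)\n",
              object@dims[1], object@dims[2], object@dims[3],
              nrow(object@nuclei), if (nrow(object@nuclei) == 1) "us" else "i",
              nrow(object@foci), if (nrow(object@foci) == 1) "us" else "i",
              object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d nucle%s, %d foc%s, midsection slice %d\n",
              nrow(object@nuclei), if (nrow(object@nuclei) == 1) "us" else "i",
              nrow(object@foci), if (nrow(object@foci) == 1) "us" else "i",
              object@midsection))
})
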