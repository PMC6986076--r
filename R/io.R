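#' Read a confocal z-stack from TIFF or PNG
#'
#' Reads a single- or multi-page grayscale TIFF, or a set of PNG slices, into
#' an \code{\linkS4class{ImageStack}}. Multi-channel data are supported
#' either as per-page samples (channels stored within each page) or as
#' separate pages, in which case the page layout must be stated explicitly.
#' Only one channel is processed per run.
#'
#' Calibration passed via \code{calibration} always wins over calibration
#' found alongside the file (a warning reports conflicts); files written by
#' \code{\link{writeStack}} carry their calibration in an open JSON
#' sidecar (\code{<file>.cal.json}), read back automatically.
#'
#' @param path a TIFF file, a directory of PNG slices, or a character vector
#'   of PNG files (sorted lexicographically).
#' @param channel 1-based channel index to extract.
#' @param calibration optional \code{\linkS4class{Calibration}} overriding
#'   file metadata.
#' @param layout page layout for multi-channel page-per-image TIFFs:
#'   \code{"auto"} (single channel, or channels within pages),
#'   \code{"interleaved"} (pages c1z1, c2z1, ...), or \code{"channel-major"}
#'   (all slices of channel 1, then channel 2, ...).
#' @param nChannels number of channels for page-interleaved layouts.
#' @return an \code{ImageStack} with intensities on the source scale.
#' @export
readStack <- function(path, channel = 1L, calibration = NULL,
                      layout = c("auto", "interleaved", "channel-major"),
                      nChannels = 1L) {
  layout <- match.arg(layout)
  channel <- as.integer(channel)
  isPng <- (length(path) > 1L) || dir.exists(path[1]) ||
    grepl("\\.png$", path[1], ignore.case = TRUE)
  if (isPng) {
    files <- if (length(path) == 1L && dir.exists(path)) {
      sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                      full.names = TRUE))
    } else sort(path)
    if (length(files) == 0L) stop("no PNG slices found under ", path)
    pages <- lapply(files, function(f) {
      x <- png::readPNG(f)
      if (length(dim(x)) == 3L) x <- x[, , channel]
      x
    })
    # readPNG rescales to [0,1]; recover integer grey values
    depth <- if (max(vapply(pages, max, 0)) > 0 &&
                 any(vapply(pages, function(p) any(abs(p * 255 - round(p * 255)) > 1e-9), FALSE)))
      16 else 8
    pages <- lapply(pages, function(p) round(p * (2^depth - 1)))
    fileCal <- NULL
  } else {
    if (!file.exists(path)) stop("cannot read ", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                     info = TRUE),
                      error = function(e) stop("unreadable TIFF '", path,
                                               "': ", conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    fileCal <- .readCalSidecar(path)
    if (length(dim(pages[[1]])) == 3L) {
      # channels stored within each page; multi-sample data come back as
      # [0,1] floats, so recover the integer grey values from the bit depth
      nch <- dim(pages[[1]])[3]
      if (channel > nch) stop("channel ", channel, " out of range (file has ",
                              nch, ")")
      bps <- attr(pages[[1]], "bits.per.sample")
      if (is.null(bps)) bps <- 8L
      pages <- lapply(pages, function(p) round(p[, , channel] * (2^bps - 1)))
      attr(pages, "nch") <- nch
    } else if (layout != "auto" || nChannels > 1L) {
      if (layout == "auto")
        stop("multi-channel page layout is ambiguous; pass layout=")
      nch <- as.integer(nChannels)
      if (channel > nch) stop("channel ", channel, " out of range")
      if (length(pages) %% nch != 0L)
        stop("page count is not a multiple of nChannels")
      idx <- if (layout == "interleaved") {
        seq(channel, length(pages), by = nch)
      } else {
        nzp <- length(pages) %/% nch
        seq((channel - 1L) * nzp + 1L, channel * nzp)
      }
      pages <- pages[idx]
      attr(pages, "nch") <- nch
    } else if (channel != 1L) {
      stop("channel ", channel, " out of range (single-channel file)")
    }
  }
  nch <- attr(pages, "nch")
  if (is.null(nch)) nch <- 1L
  depth <- if (max(vapply(pages, max, 0)) > 255) 16 else 8
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), FALSE)))
    stop("all slices must share the same (y, x) shape")
  vox <- array(0, c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]]
  cal <- .resolveCalibration(calibration, fileCal)
  ImageStack(vox, calibration = cal, bitDepth = depth,
             channelCount = as.integer(nch))
}

.calSidecarPath <- function(path) paste0(path, ".cal.json")

.readCalSidecar <- function(path) {
  sc <- .calSidecarPath(path)
  if (!file.exists(sc)) return(NULL)
  v <- tryCatch(jsonlite::read_json(sc, simplifyVector = TRUE),
                error = function(e) NULL)
  need <- c("dx", "dy", "dz", "nucleusDiameter", "fociDiameter")
  if (is.null(v) || !all(need %in% names(v))) return(NULL)
  Calibration(dx = v$dx, dy = v$dy, dz = v$dz,
              nucleusDiameter = v$nucleusDiameter,
              fociDiameter = v$fociDiameter)
}

.resolveCalibration <- function(userCal, fileCal) {
  if (!is.null(userCal)) {
    if (!is.null(fileCal) &&
        !isTRUE(all.equal(c(fileCal@dx, fileCal@dy, fileCal@dz),
                          c(userCal@dx, userCal@dy, userCal@dz))))
      warning("user calibration overrides conflicting file calibration")
    return(userCal)
  }
  if (!is.null(fileCal)) return(fileCal)
  Calibration()
}

#' Write a stack as a multi-page TIFF
#'
#' Values are stored at the requested bit depth; the calibration is written
#' to a JSON sidecar (\code{<path>.cal.json}) so that
#' \code{\link{readStack}} round-trips it.
#'
#' @param stack an \code{\linkS4class{ImageStack}} (values must fit the
#'   requested depth).
#' @param path output file.
#' @param bitDepth 8 or 16.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, bitDepth = stack@bitDepth) {
  v <- voxels(stack)
  mx <- 2^bitDepth - 1
  if (max(v) > mx) stop("intensities exceed the requested bit depth")
  cal <- calibration(stack)
  pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bitDepth,
                  compression = "none")
  jsonlite::write_json(list(dx = cal@dx, dy = cal@dy, dz = cal@dz,
                            nucleusDiameter = cal@nucleusDiameter,
                            fociDiameter = cal@fociDiameter),
                       .calSidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a binary mask as TIFF
#'
#' Object pixels are written as 255 by default; \code{imagejPolarity = TRUE}
#' inverts the encoding (object = 0, background = 255), matching the
#' black-objects convention of the ImageJ auto-local-threshold family.
#'
#' @param mask logical matrix or 3D logical array.
#' @param path output file.
#' @param imagejPolarity invert the object/background encoding.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path, imagejPolarity = FALSE) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  v <- array(as.numeric(mask), dim(mask))
  if (imagejPolarity) v <- 1 - v
  pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}
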