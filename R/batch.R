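#' Batch analysis of image stacks
#'
#' Processes every stack in \code{inputs} through the full pipeline and
#' writes, per stack, the binary nuclei map (TIFF), the per-nucleus ROI
#' table (CSV), and a tab-delimited foci table (one row per focus plus a
#' summary row per nucleus); a run-level summary TSV and the fully resolved
#' configuration (JSON) are written next to them. Failures are isolated per
#' stack: the run continues, logs the error and reports a non-zero status
#' if any stack failed.
#'
#' @param inputs directory, glob, or character vector of TIFF stacks.
#' @param outputDir output directory (created if missing).
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param nucParams,params detection parameter objects (defaults derived
#'   from \code{calibration}).
#' @param mode \code{"3d"} or \code{"both"} (adds midsection 2D counts).
#' @param midsection optional 1-based midsection slice index.
#' @param channel channel to analyze.
#' @param saveMasks also write the foci label stack per input.
#' @param imagejPolarity invert mask encoding on export.
#' @return invisibly, 0 if every stack succeeded, 1 otherwise.
#' @export
runBatch <- function(inputs, outputDir, calibration = Calibration(),
                     nucParams = nucleusParams(calibration),
                     params = fociParams(calibration),
                     mode = c("3d", "both"), midsection = NULL,
                     channel = 1L, saveMasks = FALSE,
                     imagejPolarity = FALSE) {
  mode <- match.arg(mode)
  files <- .resolveInputs(inputs)
  if (length(files) == 0L) stop("no input stacks found")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(inputs = files, mode = mode, midsection = midsection,
              channel = channel,
              calibration = .slots2list(calibration),
              nucleusParams = .slots2list(nucParams),
              fociParams = .slots2list(params))
  jsonlite::write_json(cfg, file.path(outputDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  summary <- list()
  failed <- character()
  for (f in files) {
    stem <- sub("\\.[^.]+$", "", basename(f))
    res <- tryCatch({
      stack <- readStack(f, channel = channel, calibration = calibration)
      out <- analyzeStack(stack, nucParams, params, mode = mode,
                          midsection = midsection)
      .writeStackResults(out, stem, outputDir, calibration, saveMasks,
                         imagejPolarity)
      s <- fociCounts(out$foci)
      if (nrow(s) > 0) s <- cbind(stack = stem, s)
      s
    }, error = function(e) {
      message("stack '", stem, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, f) else summary[[stem]] <- res
  }
  sm <- if (length(summary)) do.call(rbind, summary) else
    data.frame(stack = character(), nucleusLabel = integer(),
               fn3d = integer())
  utils::write.table(sm, file.path(outputDir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(failed) > 0)
    message(length(failed), " of ", length(files), " stacks failed")
  invisible(as.integer(length(failed) > 0))
}

.resolveInputs <- function(inputs) {
  out <- unlist(lapply(inputs, function(p) {
    if (dir.exists(p)) {
      list.files(p, pattern = "\\.tiff?$", ignore.case = TRUE,
                 full.names = TRUE)
    } else if (grepl("[*?]", p)) Sys.glob(p) else p
  }))
  sort(unique(out[file.exists(out)]))
}

.slots2list <- function(obj) {
  nm <- slotNames(class(obj))
  stats::setNames(lapply(nm, function(s) slot(obj, s)), nm)
}

.writeStackResults <- function(out, stem, outputDir, cal, saveMasks,
                               imagejPolarity) {
  nuc <- out$nuclei
  writeMask(labelMap(nuc) > 0L, file.path(outputDir,
                                          paste0(stem, "_nuclei.tif")),
            imagejPolarity = imagejPolarity)
  utils::write.csv(nucleusROIs(nuc),
                   file.path(outputDir, paste0(stem, "_nuclei.csv")),
                   row.names = FALSE)
  foci <- fociTable(out$foci)
  counts <- fociCounts(out$foci)
  rows <- merge(counts, foci, by = "nucleusLabel", all.x = TRUE)
  utils::write.table(cbind(stack = stem, rows),
                     file.path(outputDir, paste0(stem, "_foci.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (saveMasks) {
    lab <- labelMap(out$foci)
    writeMask(lab > 0L, file.path(outputDir, paste0(stem, "_foci.tif")),
              imagejPolarity = imagejPolarity)
  }
  invisible(NULL)
}

#' Fit the kinetics model to a time-course file
#'
#' Reads a 2-3 column TSV (time in minutes, mean foci count, optional
#' standard error), fits the induction-decay model and returns (and
#' optionally writes) a one-row report with the parameters, residual sum of
#' squares and the analytic peak time.
#'
#' @param path input TSV.
#' @param out optional output path; \code{.json} writes JSON, anything else
#'   TSV.
#' @return data.frame with \code{A}, \code{tau1}, \code{tau2}, \code{R},
#'   \code{rss}, \code{peakTime}, \code{converged}, \code{n}.
#' @export
runKinetics <- function(path, out = NULL) {
  df <- readKineticsTSV(path)
  fit <- fitMariotti(df$time, df$count, se = df$se)
  p <- fit@params
  rep <- data.frame(A = p["A"], tau1 = p["tau1"], tau2 = p["tau2"],
                    R = p["R"], rss = fit@rss, peakTime = fit@peakTime,
                    converged = fit@converged, n = fit@nObs,
                    row.names = NULL)
  if (!is.null(out)) {
    if (grepl("\\.json$", out)) {
      jsonlite::write_json(as.list(rep), out, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.table(rep, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  rep
}
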