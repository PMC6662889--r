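# Exporters: schedules and profiles as CSV, series as NIfTI, PSF plots as PNG.

#' Export a sampling schedule as CSV
#'
#' Columns: shot_index, acq_order, line_index, region, acq_time_ms.
#'
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param path output CSV path
#' @return invisibly, the exported data.frame
#' @export
exportScheduleCSV <- function(schedule, path) {
  e <- schedule@entries
  out <- data.frame(shot_index = schedule@shotIndex,
                    acq_order = e$acqOrder,
                    line_index = e$lineIndex,
                    region = e$region,
                    acq_time_ms = e$acqTimeMS)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Export a PSF profile as CSV
#'
#' Columns: position (FOV-normalized) and magnitude.
#'
#' @param profile a \linkS4class{PsfProfile}
#' @param path output CSV path
#' @return invisibly, the exported data.frame
#' @export
exportProfileCSV <- function(profile, path) {
  out <- data.frame(position = profile@positions,
                    magnitude = profile@magnitude)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a reconstructed series as NIfTI
#'
#' Frames are stored as single-slice volumes along the fourth dimension with
#' the repetition time recorded in the header time step.
#'
#' @param series a \linkS4class{VolumeSeries}
#' @param path output path (.nii or .nii.gz)
#' @return invisibly, the path written
#' @export
writeSeriesNIfTI <- function(series, path) {
  fr <- series@frames
  d <- dim(fr)
  arr <- array(fr, c(d[1], d[2], 1, d[3]))
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, series@trMS / 1000))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a reconstructed series as per-frame CSV
#'
#' One long-format CSV with columns frame, row, col, value — convenient for
#' small fixtures and diffing.
#'
#' @param series a \linkS4class{VolumeSeries}
#' @param path output CSV path
#' @return invisibly, the path written
#' @export
exportSeriesCSV <- function(series, path) {
  fr <- series@frames
  d <- dim(fr)
  out <- data.frame(frame = rep(seq_len(d[3]), each = d[1] * d[2]),
                    row = rep(rep(seq_len(d[1]), times = d[2]), d[3]),
                    col = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
                    value = as.vector(fr))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a statistical map (e.g. a t-map) as NIfTI
#'
#' @param map numeric matrix
#' @param path output path
#' @return invisibly, the path written
#' @export
writeMapNIfTI <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(array(map, c(dim(map), 1))), path)
  invisible(path)
}

#' Export the block paradigm as an FSL-style 3-column file
#'
#' One row per task block: onset (s), duration (s), weight 1.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param path output path
#' @return invisibly, the exported data.frame
#' @export
exportParadigmFSL <- function(spec, path) {
  onsets <- spec@fixationS + (seq_len(spec@cycles) - 1) * 2 * spec@blockS
  out <- data.frame(onset = onsets, duration = spec@blockS, weight = 1)
  utils::write.table(out, path, row.names = FALSE, col.names = FALSE)
  invisible(out)
}

#' Read a phantom specification from a structured text config
#'
#' YAML fields mirror the arguments of \code{\link{phantomSpec}}; \code{rois}
#' is a list of name/center/radius/amplitude entries.
#'
#' @param path YAML file path
#' @return a \linkS4class{PhantomSpec}
#' @export
readPhantomSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  rois <- lapply(cfg$rois, function(r)
    list(name = r$name, center = as.numeric(r$center),
         radius = r$radius, amplitude = r$amplitude))
  phantomSpec(shape = as.integer(cfg$shape),
              background = cfg$background %||% 0,
              tissue = cfg$tissue %||% 1,
              rois = if (length(rois)) rois else NULL,
              fixationS = cfg$fixationS %||% 20,
              blockS = cfg$blockS %||% 32,
              cycles = cfg$cycles %||% 7L,
              trMS = cfg$trMS %||% 2200,
              noiseSD = cfg$noiseSD %||% 0,
              seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a PSF profile (full range and central zoom)
#'
#' Two-panel base-graphics plot of the magnitude PSF: the whole FOV and the
#' central region around the main lobe.
#'
#' @param profile a \linkS4class{PsfProfile}
#' @param zoomHalfWidth half-width of the zoom panel, FOV-normalized
#' @param main title prefix
#' @return invisibly NULL
#' @export
plotPsf <- function(profile, zoomHalfWidth = 0.05, main = "PSF") {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  x <- profile@positions
  y <- profile@magnitude
  graphics::plot(x, y, type = "l", xlab = "position (FOV)",
                 ylab = "magnitude", main = paste(main, "(full)"))
  sel <- abs(x) <= zoomHalfWidth
  graphics::plot(x[sel], y[sel], type = "l", xlab = "position (FOV)",
                 ylab = "magnitude", main = paste(main, "(central)"))
  invisible(NULL)
}
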