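#' Construct sequence parameters for an EPI or EPIK readout
#'
#' @param scheme "EPI" or "EPIK"
#' @param matrixPE number of phase-encode lines
#' @param matrixRO number of readout samples (defaults to \code{matrixPE};
#'   the readout axis is treated as instantaneously sampled)
#' @param fovMM field of view in mm
#' @param teMS echo time in ms
#' @param trMS repetition time in ms
#' @param echoSpacingMS actual per-acquired-line echo spacing in ms
#' @param keyholeFraction fraction of k-space fully sampled every shot
#' @param nInterleaves peripheral interleave count
#' @param t2starMS tissue T2* in ms
#' @return a \linkS4class{SequenceParams}
#' @examples
#' p <- seqPreset("epik96")
#' samplingWindow(p)
#' @export
sequenceParams <- function(scheme = c("EPI", "EPIK"),
                           matrixPE,
                           matrixRO = matrixPE,
                           fovMM = 200,
                           teMS = 30,
                           trMS = 2200,
                           echoSpacingMS,
                           keyholeFraction = if (scheme == "EPI") 1 else 0.25,
                           nInterleaves = if (scheme == "EPI") 1L else 3L,
                           t2starMS = 66) {
  scheme <- match.arg(scheme)
  new("SequenceParams",
      scheme = scheme,
      matrixPE = as.integer(matrixPE),
      matrixRO = as.integer(matrixRO),
      fovMM = fovMM, teMS = teMS, trMS = trMS,
      echoSpacingMS = echoSpacingMS,
      keyholeFraction = keyholeFraction,
      nInterleaves = as.integer(nInterleaves),
      t2starMS = t2starMS)
}

#' Named parameter presets
#'
#' Presets are shipped as a structured text config
#' (\code{inst/extdata/presets.yaml}). \code{"epi64"}: single-shot EPI, 64
#' phase-encode lines, 0.510 ms echo spacing. \code{"epik96"}:
#' three-interleave EPIK, 96 lines, one-fourth keyhole, 0.890 ms actual echo
#' spacing. Both: 200 mm FOV, TR/TE 2200/30 ms, T2* 66 ms.
#'
#' @param name preset name
#' @param file optional path to an alternative preset config
#' @return a \linkS4class{SequenceParams}
#' @export
seqPreset <- function(name, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "presets.yaml", package = "epiksim",
                        mustWork = TRUE)
  presets <- yaml::read_yaml(file)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  sequenceParams(scheme = p$scheme, matrixPE = p$matrixPE,
                 fovMM = p$fovMM, teMS = p$teMS, trMS = p$trMS,
                 echoSpacingMS = p$echoSpacingMS,
                 keyholeFraction = p$keyholeFraction,
                 nInterleaves = p$nInterleaves, t2starMS = p$t2starMS)
}

#' @describeIn sequenceParams number of keyhole lines
#' @param params a \linkS4class{SequenceParams}
#' @export
keyholeLineCount <- function(params) {
  as.integer(round(params@matrixPE * params@keyholeFraction))
}

#' @describeIn sequenceParams 0-based line indices of the keyhole band,
#'   symmetric about the DC line with DC inside
#' @export
keyholeLines <- function(params) {
  nk <- keyholeLineCount(params)
  lo <- params@matrixPE %/% 2L - nk %/% 2L
  seq.int(lo, lo + nk - 1L)
}

#' @describeIn sequenceParams number of lines acquired per shot
#' @export
linesPerShot <- function(params) {
  nk <- keyholeLineCount(params)
  as.integer(nk + (params@matrixPE - nk) %/% params@nInterleaves)
}

#' @describeIn sequenceParams scheme accessor
#' @export
scheme <- function(params) params@scheme

#' @describeIn sequenceParams phase-encode matrix size accessor
#' @export
matrixPE <- function(params) params@matrixPE

setMethod("show", "SequenceParams", function(object) {
  cat(sprintf("%s readout: %d x %d matrix, FOV %g mm\n",
              object@scheme, object@matrixPE, object@matrixRO, object@fovMM))
  cat(sprintf("  TR/TE %g/%g ms, echo spacing %g ms, T2* %g ms\n",
              object@trMS, object@teMS, object@echoSpacingMS, object@t2starMS))
  cat(sprintf("  keyhole %d/%d lines, %d interleave(s), %d lines/shot\n",
              keyholeLineCount(object), object@matrixPE,
              object@nInterleaves, linesPerShot(object)))
  invisible(object)
})

setMethod("show", "SamplingSchedule", function(object) {
  e <- object@entries
  cat(sprintf("SamplingSchedule: shot %d, %d lines (%d keyhole, %d periphery)\n",
              object@shotIndex, nrow(e), sum(e$region == "keyhole"),
              sum(e$region == "periphery")))
  cat(sprintf("  acquisition %g .. %g ms after excitation\n",
              min(e$acqTimeMS), max(e$acqTimeMS)))
  invisible(object)
})

setMethod("show", "EffectiveTimeMap", function(object) {
  cat(sprintf("EffectiveTimeMap (%s): %d lines, %g .. %g ms, span %g ms\n",
              object@model, length(object@timesMS),
              min(object@timesMS), max(object@timesMS), object@spanMS))
  invisible(object)
})

setMethod("show", "PsfProfile", function(object) {
  cat(sprintf("PsfProfile: %d lines x %d oversampling, FOV %g mm\n",
              object@matrixPE, object@oversampleFactor, object@fovMM))
  invisible(object)
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VolumeSeries: %d frame(s) of %d x %d, TR %g ms, first scan %d\n",
              d[3], d[1], d[2], object@trMS, object@firstScanIndex))
  invisible(object)
})

setMethod("scheduleTable", "SamplingSchedule", function(x) x@entries)
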