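#' Full width at half maximum of a point-spread profile
#'
#' @param profile a \linkS4class{PsfProfile}
#' @param ... passed to methods
#' @export
setGeneric("fwhm", function(profile, ...) standardGeneric("fwhm"))

#' Side peaks (view-sharing ghosts) of a point-spread profile
#'
#' @param profile a \linkS4class{PsfProfile}
#' @param ... passed to methods
#' @export
setGeneric("sidePeaks", function(profile, ...) standardGeneric("sidePeaks"))

#' Temporal signal-to-noise ratio of a reconstructed series
#'
#' @param series a \linkS4class{VolumeSeries}
#' @param ... passed to methods
#' @export
setGeneric("tsnr", function(series, ...) standardGeneric("tsnr"))

#' Schedule entries as a data.frame
#'
#' @param x a \linkS4class{SamplingSchedule}
#' @export
setGeneric("scheduleTable", function(x) standardGeneric("scheduleTable"))

#' Number of frames in a series
#'
#' @param x a \linkS4class{VolumeSeries}
#' @export
setGeneric("frameCount", function(x) standardGeneric("frameCount"))

#' Extract the frame array of a series
#'
#' @param x a \linkS4class{VolumeSeries}
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Per-line k-space weights of a decay trajectory
#'
#' @param x a \linkS4class{DecayTrajectory}
#' @export
setGeneric("lineWeights", function(x) standardGeneric("lineWeights"))

#' Attenuation-free scaling factor Q of a susceptibility model
#'
#' @param model a \linkS4class{SusceptibilityModel}
#' @export
setGeneric("qFactor", function(model) standardGeneric("qFactor"))

#' Effective echo time under a local susceptibility gradient
#'
#' @param model a \linkS4class{SusceptibilityModel}
#' @param teMS nominal echo time, ms
#' @export
setGeneric("effectiveTE", function(model, teMS) standardGeneric("effectiveTE"))
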