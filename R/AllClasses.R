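#' @import methods
NULL

#' SequenceParams: full parameterization of one readout scheme
#'
#' Holds the acquisition parameters of a single-shot EPI or EPIK readout:
#' matrix size, field of view, echo/repetition times, the actual per-line echo
#' spacing, the keyhole fraction (the portion of k-space fully sampled every
#' shot), the number of peripheral interleaves, and the tissue T2* used in
#' decay simulations.
#'
#' Invariants enforced by the validity method: \code{matrixPE *
#' keyholeFraction} is an integer (the keyhole line count); the peripheral
#' line count is divisible by \code{nInterleaves}; all times are strictly
#' positive; \code{keyholeFraction} lies in (0, 1]. A scheme of \code{"EPI"}
#' is the degenerate keyhole case (fraction 1, one interleave).
#'
#' @slot scheme either "EPI" or "EPIK"
#' @slot matrixPE integer, number of phase-encode lines
#' @slot matrixRO integer, number of readout samples
#' @slot fovMM field of view in mm
#' @slot teMS echo time in ms (acquisition time of the central k-space line)
#' @slot trMS repetition time in ms
#' @slot echoSpacingMS actual per-acquired-line echo spacing in ms
#' @slot keyholeFraction fraction of k-space fully sampled every shot
#' @slot nInterleaves number of peripheral interleaves cycled across shots
#' @slot t2starMS tissue T2* in ms used for decay weighting
#' @export
setClass("SequenceParams",
  representation(
    scheme          = "character",
    matrixPE        = "integer",
    matrixRO        = "integer",
    fovMM           = "numeric",
    teMS            = "numeric",
    trMS            = "numeric",
    echoSpacingMS   = "numeric",
    keyholeFraction = "numeric",
    nInterleaves    = "integer",
    t2starMS        = "numeric"
  )
)

setValidity("SequenceParams", function(object) {
  msg <- character()
  if (!object@scheme %in% c("EPI", "EPIK"))
    msg <- c(msg, "scheme must be 'EPI' or 'EPIK'")
  if (object@matrixPE < 2L)
    msg <- c(msg, "matrixPE must be >= 2")
  if (object@matrixRO < 1L)
    msg <- c(msg, "matrixRO must be >= 1")
  for (s in c("fovMM", "teMS", "trMS", "echoSpacingMS", "t2starMS")) {
    if (!(slot(object, s) > 0))
      msg <- c(msg, paste(s, "must be strictly positive"))
  }
  kf <- object@keyholeFraction
  if (!(kf > 0 && kf <= 1))
    msg <- c(msg, "keyholeFraction must lie in (0, 1]")
  nk <- object@matrixPE * kf
  if (abs(nk - round(nk)) > 1e-9)
    msg <- c(msg, "matrixPE * keyholeFraction must be an integer")
  nPeriph <- object@matrixPE - round(nk)
  if (object@nInterleaves < 1L)
    msg <- c(msg, "nInterleaves must be >= 1")
  else if (nPeriph %% object@nInterleaves != 0)
    msg <- c(msg, "peripheral line count must be divisible by nInterleaves")
  if (object@scheme == "EPI" &&
      (object@nInterleaves != 1L || abs(kf - 1) > 1e-12))
    msg <- c(msg, "EPI requires keyholeFraction = 1 and nInterleaves = 1")
  if (length(msg)) msg else TRUE
})

#' SamplingSchedule: ordered phase-encode acquisition of one shot
#'
#' The per-shot ordered list of phase-encode line indices with per-line
#' acquisition times (echo-time shifting applied) and a region tag (keyhole or
#' periphery) per entry. Line indices are 0-based; line 0 is the most negative
#' k_y.
#'
#' @slot shotIndex 0-based scan index this schedule belongs to
#' @slot entries data.frame with columns acqOrder, lineIndex, region, acqTimeMS
#' @slot params the generating \linkS4class{SequenceParams}
#' @export
setClass("SamplingSchedule",
  representation(
    shotIndex = "integer",
    entries   = "data.frame",
    params    = "SequenceParams"
  )
)

setValidity("SamplingSchedule", function(object) {
  e <- object@entries
  need <- c("acqOrder", "lineIndex", "region", "acqTimeMS")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (object@shotIndex < 0L) return("shotIndex must be >= 0")
  if (is.unsorted(e$acqTimeMS, strictly = TRUE))
    return("acqTimeMS must be strictly increasing along acquisition order")
  if (any(e$lineIndex < 0L) || any(e$lineIndex >= object@params@matrixPE))
    return("lineIndex out of range")
  if (anyDuplicated(e$lineIndex)) return("duplicated lineIndex within a shot")
  TRUE
})

#' EffectiveTimeMap: acquisition time per reconstructed k-space line
#'
#' One acquisition time (ms from excitation) per reconstructed phase-encode
#' line, under either the uniform-effective model (constant effective spacing)
#' or the physical piecewise model (keyhole lines at the actual echo spacing,
#' peripheral lines at actual spacing / nInterleaves). The central line is
#' always assigned the nominal echo time.
#'
#' @slot model "uniform_effective" or "physical_piecewise"
#' @slot timesMS acquisition time per line, length matrixPE
#' @slot spanMS total readout span: sum of per-line spacings
#' @slot params the generating \linkS4class{SequenceParams}
#' @export
setClass("EffectiveTimeMap",
  representation(
    model   = "character",
    timesMS = "numeric",
    spanMS  = "numeric",
    params  = "SequenceParams"
  )
)

setValidity("EffectiveTimeMap", function(object) {
  p <- object@params
  if (length(object@timesMS) != p@matrixPE)
    return("timesMS must have one entry per phase-encode line")
  if (is.unsorted(object@timesMS))
    return("timesMS must be monotonically non-decreasing in line index")
  ctr <- p@matrixPE %/% 2L + 1L
  if (abs(object@timesMS[ctr] - p@teMS) > 1e-9)
    return("central line must be acquired at teMS")
  TRUE
})

#' DecayTrajectory: per-line k-space weights under T2* decay
#'
#' Non-negative amplitude per reconstructed k-space line: the source scan's
#' object amplitude times exp(-t/T2*) at the line's acquisition time. In the
#' dynamic case the scan amplitudes impose a period-nInterleaves modulation
#' confined to the periphery.
#'
#' @slot weights one weight per reconstructed line
#' @slot timesMS acquisition time per line (ms)
#' @slot scanAmplitudes per-contributing-scan object amplitude (oldest first)
#' @slot params the generating \linkS4class{SequenceParams}
#' @export
setClass("DecayTrajectory",
  representation(
    weights        = "numeric",
    timesMS        = "numeric",
    scanAmplitudes = "numeric",
    params         = "SequenceParams"
  )
)

setValidity("DecayTrajectory", function(object) {
  if (length(object@weights) != object@params@matrixPE)
    return("weights must have one entry per phase-encode line")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (length(object@weights) != length(object@timesMS))
    return("weights and timesMS length mismatch")
  TRUE
})

#' PsfProfile: oversampled 1-D point-spread magnitude
#'
#' Magnitude of the zero-padded discrete Fourier transform of a k-space weight
#' profile on an axis of matrixPE * oversampleFactor points, peak-normalized
#' to 1, with positions in FOV-normalized units spanning [-0.5, 0.5). Every
#' reconstruction pixel centre is a grid point of the profile, so pixel-grid
#' metrics are exact subsets.
#'
#' @slot positions FOV-normalized image-axis coordinates
#' @slot magnitude non-negative profile, unit peak
#' @slot oversampleFactor integer >= 16
#' @slot matrixPE number of phase-encode lines behind the profile
#' @slot fovMM field of view in mm (for mm-unit conversions)
#' @export
setClass("PsfProfile",
  representation(
    positions        = "numeric",
    magnitude        = "numeric",
    oversampleFactor = "integer",
    matrixPE         = "integer",
    fovMM            = "numeric"
  )
)

setValidity("PsfProfile", function(object) {
  if (length(object@positions) != length(object@magnitude))
    return("positions/magnitude length mismatch")
  if (object@oversampleFactor < 16L)
    return("oversampleFactor must be >= 16")
  if (abs(max(object@magnitude) - 1) > 1e-9)
    return("magnitude must be normalized to unit peak")
  if (any(object@magnitude < 0)) return("magnitude must be non-negative")
  TRUE
})

#' ShotFrame: per-excitation k-space data
#'
#' The complex k-space rows acquired in one excitation, stored in acquisition
#' order together with the generating schedule.
#'
#' @slot scanIndex 0-based scan index
#' @slot kRows complex matrix, one row per scheduled line (acquisition order)
#' @slot schedule the generating \linkS4class{SamplingSchedule}
#' @export
setClass("ShotFrame",
  representation(
    scanIndex = "integer",
    kRows     = "matrix",
    schedule  = "SamplingSchedule"
  )
)

setValidity("ShotFrame", function(object) {
  if (nrow(object@kRows) != nrow(object@schedule@entries))
    return("kRows must have one row per scheduled line")
  if (!is.complex(object@kRows)) return("kRows must be complex")
  if (object@scanIndex != object@schedule@shotIndex)
    return("scanIndex must match the schedule's shotIndex")
  TRUE
})

#' VolumeSeries: reconstructed magnitude image time series
#'
#' Ordered magnitude images, one per reconstructed scan, with the repetition
#' time and the acquisition index of the first reconstructed scan.
#'
#' @slot frames numeric array (phase-encode, readout, frame)
#' @slot trMS repetition time in ms (frame spacing)
#' @slot firstScanIndex 0-based acquisition index of the first frame
#' @export
setClass("VolumeSeries",
  representation(
    frames         = "array",
    trMS           = "numeric",
    firstScanIndex = "integer"
  )
)

setValidity("VolumeSeries", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be a 3-D array (py, ro, frame)")
  if (!(object@trMS > 0)) return("trMS must be positive")
  if (object@firstScanIndex < 0L) return("firstScanIndex must be >= 0")
  TRUE
})

#' PhantomSpec: synthetic object, paradigm and noise configuration
#'
#' Describes the synthetic 2-D object (layered ellipses), the ROI discs that
#' carry BOLD modulation, the block paradigm (initial fixation followed by
#' alternating task/rest blocks), complex noise level, susceptibility-gradient
#' map and the random seed.
#'
#' @slot shape integer length-2 grid shape (phase-encode, readout)
#' @slot background background intensity
#' @slot tissue main-object tissue intensity
#' @slot rois list of ROI descriptors: name, center (px), radius (px),
#'   amplitude (fractional BOLD amplitude)
#' @slot fixationS initial fixation duration, seconds
#' @slot blockS task and rest block duration, seconds
#' @slot cycles number of task/rest cycles
#' @slot trMS repetition time, ms
#' @slot noiseSD standard deviation of complex k-space noise per line
#' @slot seed integer random seed
#' @slot gspMap local susceptibility gradient per pixel (mT/m), or 0 x 0
#'   matrix for none
#' @export
setClass("PhantomSpec",
  representation(
    shape      = "integer",
    background = "numeric",
    tissue     = "numeric",
    rois       = "list",
    fixationS  = "numeric",
    blockS     = "numeric",
    cycles     = "integer",
    trMS       = "numeric",
    noiseSD    = "numeric",
    seed       = "integer",
    gspMap     = "matrix"
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 2L || any(object@shape < 4L))
    return("shape must be two integers >= 4")
  if (object@fixationS < 0 || object@blockS <= 0 || object@cycles < 1L)
    return("paradigm durations must be positive")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  for (r in object@rois) {
    if (!all(c("name", "center", "radius", "amplitude") %in% names(r)))
      return("each ROI needs name, center, radius, amplitude")
    if (r$amplitude < 0) return("ROI amplitudes must be >= 0")
  }
  # ROI masks must be disjoint
  if (length(object@rois) > 1L) {
    cnt <- matrix(0L, object@shape[1], object@shape[2])
    for (r in object@rois) cnt <- cnt + discMask(object@shape, r$center, r$radius)
    if (any(cnt > 1L)) return("ROI masks must be disjoint")
  }
  TRUE
})

#' SusceptibilityModel: local-gradient effective echo time
#'
#' Parameters of the effective-TE shift caused by a local susceptibility
#' gradient G_SP during an EPI-type readout with echo spacing Delta-t:
#' Q = 1 - gamma * Delta-t / (2*pi) * FOV * G_SP and TE' = TE / Q. A
#' non-positive Q marks the signal-void regime.
#'
#' @slot gammaRadTS gyromagnetic ratio, rad s^-1 T^-1
#' @slot deltaTMS echo spacing, ms
#' @slot fovMM field of view, mm
#' @slot gspMTM local susceptibility gradient, mT/m
#' @export
setClass("SusceptibilityModel",
  representation(
    gammaRadTS = "numeric",
    deltaTMS   = "numeric",
    fovMM      = "numeric",
    gspMTM     = "numeric"
  )
)

setValidity("SusceptibilityModel", function(object) {
  if (!(object@gammaRadTS > 0)) return("gammaRadTS must be positive")
  if (!(object@deltaTMS > 0)) return("deltaTMS must be positive")
  if (!(object@fovMM > 0)) return("fovMM must be positive")
  TRUE
})

#' GlmResult: per-pixel and per-ROI GLM activation fit
#'
#' Ordinary-least-squares fit of an HRF-convolved block design (plus temporal
#' derivative, constant and linear drift) to a reconstructed series.
#'
#' @slot beta array (py, ro, regressor) of coefficient maps
#' @slot tMap matrix of task-regressor t statistics
#' @slot design design matrix (one column per regressor)
#' @slot roiStats data.frame of ROI-level beta, t, percent signal change
#' @slot roiResiduals named list of ROI-mean residual series
#' @export
setClass("GlmResult",
  representation(
    beta         = "array",
    tMap         = "matrix",
    design       = "matrix",
    roiStats     = "data.frame",
    roiResiduals = "list"
  )
)
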