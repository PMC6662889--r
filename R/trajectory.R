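#' Single-shot EPI sampling schedule
#'
#' Linear bottom-up ordering: line j (0-based) is acquired at
#' \code{teMS + (j - matrixPE/2) * echoSpacingMS}, so the central line falls
#' exactly on the echo time. All lines are tagged as keyhole (the degenerate
#' keyhole-fraction-1 case).
#'
#' @param params a \linkS4class{SequenceParams} with scheme "EPI"
#' @param shotIndex 0-based scan index recorded on the schedule
#' @return a \linkS4class{SamplingSchedule}
#' @export
epiSchedule <- function(params, shotIndex = 0L) {
  if (params@scheme != "EPI")
    stop("epiSchedule requires scheme 'EPI'")
  n <- params@matrixPE
  j <- seq.int(0L, n - 1L)
  entries <- data.frame(
    acqOrder = j,
    lineIndex = j,
    region = rep("keyhole", n),
    acqTimeMS = params@teMS + (j - n / 2) * params@echoSpacingMS,
    stringsAsFactors = FALSE)
  new("SamplingSchedule", shotIndex = as.integer(shotIndex),
      entries = entries, params = params)
}

#' EPIK sampling schedule for one shot
#'
#' Every shot fully samples the central keyhole band and one interleave of the
#' periphery: peripheral lines whose index is congruent to
#' \code{shotIndex mod nInterleaves}. Acquisition order is bottom-periphery
#' interleave, keyhole block, top-periphery interleave, at the actual echo
#' spacing, so acquisition time is monotone in k_y. Echo-time shifting is
#' applied as a per-shot offset of
#' \code{offset * echoSpacingMS / nInterleaves} on the peripheral entries,
#' so that the combined multi-shot peripheral time map increases smoothly
#' with a uniform effective spacing of \code{echoSpacingMS / nInterleaves};
#' the keyhole is re-acquired at its nominal timing every shot, keeping the
#' reconstruction-relevant acquisition time of every k-space line
#' independent of which window scan sourced it.
#'
#' The shot is anchored so that the central k-space line is acquired exactly
#' at the echo time.
#'
#' @param params a \linkS4class{SequenceParams} (scheme "EPIK", or "EPI" as
#'   the degenerate single-interleave case)
#' @param shotIndex 0-based scan index; the interleave offset is
#'   \code{shotIndex mod nInterleaves}
#' @return a \linkS4class{SamplingSchedule}
#' @export
epikSchedule <- function(params, shotIndex = 0L) {
  shotIndex <- as.integer(shotIndex)
  if (shotIndex < 0L) stop("shotIndex must be >= 0")
  n <- params@matrixPE
  ni <- params@nInterleaves
  kh <- keyholeLines(params)
  offset <- shotIndex %% ni
  periph <- setdiff(seq.int(0L, n - 1L), kh)
  mine <- periph[periph %% ni == offset]
  lines <- c(mine[mine < kh[1]], kh, mine[mine > kh[length(kh)]])
  region <- ifelse(lines %in% kh, "keyhole", "periphery")
  nAcq <- length(lines)
  # anchor: the central keyhole line sits at TE
  ctrPos <- sum(mine < kh[1]) + match(n %/% 2L, kh) - 1L
  tStart <- params@teMS - ctrPos * params@echoSpacingMS
  ets <- ifelse(region == "periphery",
                offset * params@echoSpacingMS / ni, 0)
  entries <- data.frame(
    acqOrder = seq.int(0L, nAcq - 1L),
    lineIndex = lines,
    region = region,
    acqTimeMS = tStart + seq.int(0L, nAcq - 1L) * params@echoSpacingMS + ets,
    stringsAsFactors = FALSE)
  new("SamplingSchedule", shotIndex = shotIndex,
      entries = entries, params = params)
}

#' Schedule for a shot under either scheme
#'
#' Dispatches to \code{\link{epiSchedule}} or \code{\link{epikSchedule}}
#' according to the scheme of \code{params}.
#'
#' @inheritParams epikSchedule
#' @return a \linkS4class{SamplingSchedule}
#' @export
shotSchedule <- function(params, shotIndex = 0L) {
  if (params@scheme == "EPI") epiSchedule(params, shotIndex)
  else epikSchedule(params, shotIndex)
}

#' Acquisition time per reconstructed k-space line
#'
#' Under the \code{uniform_effective} model every line is assigned the
#' effective spacing \code{echoSpacingMS * linesPerShot / matrixPE} (0.445 ms
#' for the 96-line EPIK preset); under \code{physical_piecewise} keyhole lines
#' carry the actual spacing and peripheral lines carry
#' \code{echoSpacingMS / nInterleaves}, consistent with echo-time-shifted
#' sharing. Both models anchor the central line at the echo time and have a
#' total span (sum of per-line spacings) equal to the per-shot readout
#' duration \code{linesPerShot * echoSpacingMS}.
#'
#' @param params a \linkS4class{SequenceParams}
#' @param model timing model
#' @return an \linkS4class{EffectiveTimeMap}
#' @export
effectiveLineTimes <- function(params,
                               model = c("uniform_effective",
                                         "physical_piecewise")) {
  model <- match.arg(model)
  n <- params@matrixPE
  j <- seq.int(0L, n - 1L)
  if (model == "uniform_effective") {
    eff <- effectiveEchoSpacing(params)
    times <- params@teMS + (j - n / 2) * eff
    span <- n * eff
  } else {
    kh <- keyholeLines(params)
    sp <- ifelse(j %in% kh, params@echoSpacingMS,
                 params@echoSpacingMS / params@nInterleaves)
    times <- cumsum(c(0, sp[-n]))
    times <- times - times[n %/% 2L + 1L] + params@teMS
    span <- sum(sp)
  }
  new("EffectiveTimeMap", model = model, timesMS = times,
      spanMS = span, params = params)
}

#' @describeIn effectiveLineTimes effective per-line echo spacing in ms
#'   (actual spacing scaled by the per-shot line fraction)
#' @export
effectiveEchoSpacing <- function(params) {
  params@echoSpacingMS * linesPerShot(params) / params@matrixPE
}

#' Sampling window of a readout scheme
#'
#' Returns \code{teMS +/- (matrixPE/2) * effective spacing}; the window is
#' symmetric about the echo time and its width is
#' \code{matrixPE * effective spacing}.
#'
#' @param params a \linkS4class{SequenceParams}
#' @return named numeric: \code{tMinMS}, \code{tMaxMS}, \code{widthMS}
#' @export
samplingWindow <- function(params) {
  eff <- effectiveEchoSpacing(params)
  half <- params@matrixPE / 2 * eff
  c(tMinMS = params@teMS - half, tMaxMS = params@teMS + half,
    widthMS = params@matrixPE * eff)
}

#' Peripheral k-space update rate
#'
#' The periphery is fully refreshed once every \code{nInterleaves} shots, so
#' its update rate is \code{1 / (TR * nInterleaves)}: 0.15 Hz (one update per
#' 6.6 s) for the three-interleave 2200 ms preset.
#'
#' @param params a \linkS4class{SequenceParams}
#' @return update frequency in Hz
#' @export
peripheryUpdateRate <- function(params) {
  1 / (params@trMS / 1000 * params@nInterleaves)
}

#' Sliding-window source map for one reconstructed scan
#'
#' For each reconstructed phase-encode line, the scan index it is filled from:
#' keyhole lines always come from the current scan, peripheral lines from the
#' most recent scan among the previous \code{nInterleaves} whose interleave
#' offset covers them. Data older than \code{nInterleaves} scans is never
#' referenced (the oldest interleave is discarded as the window slides).
#'
#' @param scanIndex 0-based scan index, at least \code{nInterleaves - 1}
#' @param params a \linkS4class{SequenceParams}
#' @return integer vector, one source scan index per line (names are 0-based
#'   line indices)
#' @export
slidingWindowSources <- function(scanIndex, params) {
  scanIndex <- as.integer(scanIndex)
  ni <- params@nInterleaves
  if (scanIndex < ni - 1L)
    stop("scan ", scanIndex, " is not yet reconstructable: ",
         "a full sliding window needs ", ni, " scans")
  n <- params@matrixPE
  lines <- seq.int(0L, n - 1L)
  src <- rep(scanIndex, n)
  periph <- !(lines %in% keyholeLines(params))
  # most recent scan j <= scanIndex with j mod ni == line mod ni
  src[periph] <- scanIndex - ((scanIndex - lines[periph]) %% ni)
  names(src) <- lines
  src
}
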