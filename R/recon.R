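# Forward k-space synthesis and direct / sliding-window reconstruction.
#
# k-space layout: axes (phase-encode, readout), DC at 0-based index
# matrix/2 on both axes (row j holds phase-encode line j).

fftShift2 <- function(m) {
  d <- dim(m)
  m[c((d[1] %/% 2 + 1):d[1], 1:(d[1] %/% 2)),
    c((d[2] %/% 2 + 1):d[2], 1:(d[2] %/% 2))]
}

ifftShift2 <- function(m) {
  d <- dim(m)
  m[c((d[1] - d[1] %/% 2 + 1):d[1], 1:(d[1] - d[1] %/% 2)),
    c((d[2] - d[2] %/% 2 + 1):d[2], 1:(d[2] - d[2] %/% 2))]
}

#' Full 2-D k-space of an image (DC centred)
#'
#' @param img real or complex image matrix
#' @return complex matrix with DC at 0-based index (matrix/2, matrix/2)
#' @export
kspaceFromImage <- function(img) {
  fftShift2(stats::fft(ifftShift2(as.matrix(img))))
}

#' Image from a full DC-centred k-space grid
#'
#' Inverse of \code{\link{kspaceFromImage}} up to floating error.
#'
#' @param k complex k-space matrix
#' @return complex image matrix
#' @export
imageFromKspace <- function(k) {
  fftShift2(stats::fft(ifftShift2(k), inverse = TRUE)) / length(k)
}

#' Synthesize the k-space lines of one shot from a time-varying phantom
#'
#' Each scheduled line is the corresponding row of the 2-D Fourier transform
#' of the object as it exists at that line's acquisition time, scaled by
#' \code{exp(-t/T2*)}, plus independent circularly-symmetric complex Gaussian
#' noise. Acquisition times are global: the shot's excitation happens at
#' \code{scanIndex * TR}.
#'
#' @param phantomStateFn function of global time (ms) returning the object
#'   image matrix
#' @param schedule a \linkS4class{SamplingSchedule}
#' @param noiseSD standard deviation of the complex noise per sample (real
#'   and imaginary parts each have sd \code{noiseSD/sqrt(2)})
#' @param seed optional integer; when given, the shot is reproducible
#' @param t2starMS decay constant; defaults to the schedule's params;
#'   \code{Inf} disables decay
#' @param perLine if \code{FALSE}, evaluate the phantom once at the shot's
#'   echo time instead of per line (cheaper; exact for slow dynamics)
#' @return a \linkS4class{ShotFrame}
#' @export
synthesizeShot <- function(phantomStateFn, schedule, noiseSD = 0, seed = NULL,
                           t2starMS = NULL, perLine = TRUE) {
  p <- schedule@params
  if (is.null(t2starMS)) t2starMS <- p@t2starMS
  if (!is.null(seed)) set.seed(seed)
  e <- schedule@entries
  t0 <- schedule@shotIndex * p@trMS
  rows <- matrix(complex(1), nrow(e), p@matrixRO)
  if (!perLine) {
    img <- phantomStateFn(t0 + p@teMS)
    if (!all(dim(img) == c(p@matrixPE, p@matrixRO)))
      stop("phantom shape does not match the schedule's matrix")
    k <- kspaceFromImage(img)
  }
  for (i in seq_len(nrow(e))) {
    if (perLine) {
      img <- phantomStateFn(t0 + e$acqTimeMS[i])
      if (!all(dim(img) == c(p@matrixPE, p@matrixRO)))
        stop("phantom shape does not match the schedule's matrix")
      k <- kspaceFromImage(img)
    }
    decay <- if (is.finite(t2starMS)) exp(-e$acqTimeMS[i] / t2starMS) else 1
    rows[i, ] <- k[e$lineIndex[i] + 1L, ] * decay
  }
  if (noiseSD > 0) {
    nn <- length(rows)
    rows <- rows + complex(real = stats::rnorm(nn, 0, noiseSD / sqrt(2)),
                           imaginary = stats::rnorm(nn, 0, noiseSD / sqrt(2)))
  }
  new("ShotFrame", scanIndex = schedule@shotIndex, kRows = rows,
      schedule = schedule)
}

setMethod("show", "ShotFrame", function(object) {
  cat(sprintf("ShotFrame: scan %d, %d k-space line(s) x %d samples\n",
              object@scanIndex, nrow(object@kRows), ncol(object@kRows)))
  invisible(object)
})

#' Assemble a complete k-space grid by sliding-window sharing
#'
#' Fills every phase-encode line from its source shot according to
#' \code{\link{slidingWindowSources}}: the keyhole strictly from the current
#' scan, peripheral lines from the most recent covering interleave.
#'
#' @param shots list of \linkS4class{ShotFrame}s covering the window (indexed
#'   by \code{scanIndex + 1})
#' @param scanIndex 0-based index of the scan to reconstruct
#' @param params a \linkS4class{SequenceParams}
#' @return complex k-space matrix
#' @export
assembleKspace <- function(shots, scanIndex, params) {
  src <- slidingWindowSources(scanIndex, params)
  k <- matrix(NA_complex_, params@matrixPE, params@matrixRO)
  for (line in seq.int(0L, params@matrixPE - 1L)) {
    s <- src[[as.character(line)]]
    shot <- if (s + 1L <= length(shots)) shots[[s + 1L]] else NULL
    if (is.null(shot) || shot@scanIndex != s)
      stop("missing source shot ", s, " for line ", line)
    row <- match(line, shot@schedule@entries$lineIndex)
    if (is.na(row)) stop("source shot ", s, " does not contain line ", line)
    k[line + 1L, ] <- shot@kRows[row, ]
  }
  k
}

#' Magnitude image from an assembled k-space grid
#'
#' Magnitude of the inverse 2-D discrete Fourier transform; the DC convention
#' matches \code{\link{synthesizeShot}}, so a noiseless static round trip
#' reproduces the object up to the decay apodization.
#'
#' @param k complex k-space matrix (no missing lines)
#' @return magnitude image matrix
#' @export
reconImage <- function(k) {
  if (anyNA(k)) stop("k-space grid contains unassembled (missing) lines")
  Mod(imageFromKspace(k))
}

#' Reconstruct an image time series from a stream of shots
#'
#' One frame per scan from the first reconstructable index onward:
#' \code{max(dropFirst, nInterleaves - 1)}. The first
#' \code{nInterleaves - 1} scans lack a full sliding window and are never
#' reconstructed; \code{dropFirst} mirrors dummy-scan discarding.
#'
#' @param shots list of \linkS4class{ShotFrame}s, scan 0 first
#' @param params a \linkS4class{SequenceParams}
#' @param dropFirst number of initial (dummy) scans to drop
#' @return a \linkS4class{VolumeSeries}
#' @export
reconSeries <- function(shots, params, dropFirst = 2L) {
  ni <- params@nInterleaves
  if (length(shots) < ni) stop("need at least nInterleaves shots")
  first <- max(as.integer(dropFirst), ni - 1L)
  idx <- seq.int(first, length(shots) - 1L)
  fr <- array(0, c(params@matrixPE, params@matrixRO, length(idx)))
  for (i in seq_along(idx)) {
    fr[, , i] <- reconImage(assembleKspace(shots, idx[i], params))
  }
  new("VolumeSeries", frames = fr, trMS = params@trMS,
      firstScanIndex = as.integer(first))
}

setMethod("frames", "VolumeSeries", function(x) x@frames)
setMethod("frameCount", "VolumeSeries", function(x) dim(x@frames)[3])

#' Simulate and reconstruct a full phantom experiment
#'
#' Builds the time-varying phantom from a \linkS4class{PhantomSpec} (baseline
#' object, per-ROI BOLD modulation, optional susceptibility attenuation),
#' synthesizes \code{nScans} shots under the scheme of \code{params}, and
#' reconstructs the series. Noise is drawn once per acquired line, so
#' peripheral noise shared by the sliding window is genuinely shared across
#' the frames that reuse it.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param params a \linkS4class{SequenceParams}; its matrix must match the
#'   spec's shape
#' @param nScans number of shots to acquire
#' @param dropFirst initial scans to drop from the reconstructed series
#' @param seed overrides the spec's seed when given
#' @param perLine per-line phantom evaluation (see
#'   \code{\link{synthesizeShot}})
#' @return list with \code{series} (a \linkS4class{VolumeSeries}),
#'   \code{phantom} (baseline + masks) and \code{shots}
#' @export
simulateSeries <- function(spec, params, nScans, dropFirst = 2L,
                           seed = NULL, perLine = FALSE) {
  if (!all(spec@shape == c(params@matrixPE, params@matrixRO)))
    stop("phantom shape does not match the sequence matrix")
  assertParadigmFits(spec, nScans)
  ph <- makePhantom(spec)
  baseline <- ph$baseline
  if (length(spec@gspMap))
    baseline <- applySusceptibility(baseline, spec@gspMap, params)
  resp <- paradigmResponse(spec)
  amps <- vapply(spec@rois, `[[`, numeric(1), "amplitude")
  phantomFn <- function(tMS) {
    img <- baseline
    f <- resp(tMS / 1000)
    for (i in seq_along(spec@rois)) {
      m <- ph$masks[[spec@rois[[i]]$name]]
      img[m] <- img[m] * (1 + amps[i] * f)
    }
    img
  }
  set.seed(if (is.null(seed)) spec@seed else as.integer(seed))
  shots <- vector("list", nScans)
  for (s in seq_len(nScans) - 1L) {
    shots[[s + 1L]] <- synthesizeShot(phantomFn, shotSchedule(params, s),
                                      noiseSD = spec@noiseSD,
                                      perLine = perLine)
  }
  list(series = reconSeries(shots, params, dropFirst),
       phantom = ph, shots = shots)
}
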