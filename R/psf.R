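#' T2*-decay-weighted k-space line weights
#'
#' Computes the per-line k-space weight \code{w_j = amplitude(source scan of
#' line j) * exp(-t_j / T2*)} from an acquisition time map. In the stationary
#' case all scan amplitudes are 1 and the weights follow the pure decay
#' envelope. In the dynamic case \code{scanAmplitudes} holds one object
#' amplitude per contributing scan of the sliding window, oldest first;
#' peripheral interleaves then carry a period-\code{nInterleaves}
#' multiplicative modulation while the keyhole is uniformly scaled by the
#' amplitude of the scan it is taken from.
#'
#' The reconstructed frame is referenced to the first scan of the window, so
#' by default the keyhole carries \code{scanAmplitudes[1]} (the baseline
#' amplitude) and the shared periphery sweeps through the ramp; the
#' \code{keyholeScan} argument overrides this.
#'
#' @param timemap an \linkS4class{EffectiveTimeMap} or
#'   \linkS4class{SamplingSchedule} (its per-line acquisition times are used)
#' @param t2starMS T2* in ms; \code{Inf} disables decay
#' @param scanAmplitudes numeric vector of length 1 (stationary) or
#'   \code{nInterleaves} (one amplitude per contributing scan, oldest first)
#' @param keyholeScan 1-based index into \code{scanAmplitudes} for the scan
#'   the keyhole is taken from
#' @return a \linkS4class{DecayTrajectory}
#' @export
decayTrajectory <- function(timemap, t2starMS = NULL, scanAmplitudes = 1,
                            keyholeScan = 1L) {
  if (is(timemap, "SamplingSchedule")) {
    p <- timemap@params
    e <- timemap@entries
    times <- numeric(p@matrixPE)
    times[] <- NA_real_
    times[e$lineIndex + 1L] <- e$acqTimeMS
    if (anyNA(times))
      stop("schedule does not cover all lines; use an EffectiveTimeMap ",
           "for multi-shot line weights")
  } else if (is(timemap, "EffectiveTimeMap")) {
    p <- timemap@params
    times <- timemap@timesMS
  } else stop("timemap must be a SamplingSchedule or EffectiveTimeMap")
  if (is.null(t2starMS)) t2starMS <- p@t2starMS
  if (!(t2starMS > 0)) stop("t2starMS must be positive")
  ni <- p@nInterleaves
  if (!length(scanAmplitudes) %in% c(1L, ni))
    stop("scanAmplitudes must have length 1 or nInterleaves (", ni, ")")
  n <- p@matrixPE
  lines <- seq.int(0L, n - 1L)
  if (length(scanAmplitudes) == 1L) {
    amp <- rep(scanAmplitudes, n)
  } else {
    # peripheral line l is sourced from the window scan with matching
    # interleave offset; scan s (0-based, oldest first) samples lines
    # congruent to s mod nInterleaves
    amp <- scanAmplitudes[(lines %% ni) + 1L]
    amp[lines %in% keyholeLines(p)] <- scanAmplitudes[keyholeScan]
  }
  w <- amp * exp(-times / t2starMS)
  new("DecayTrajectory", weights = w, timesMS = times,
      scanAmplitudes = as.numeric(scanAmplitudes), params = p)
}

setMethod("lineWeights", "DecayTrajectory", function(x) x@weights)

setMethod("show", "DecayTrajectory", function(object) {
  cat(sprintf("DecayTrajectory: %d lines, weights %.4g .. %.4g\n",
              length(object@weights), min(object@weights),
              max(object@weights)))
  invisible(object)
})

#' Point spread function of a k-space weight profile
#'
#' Magnitude of the zero-padded discrete Fourier transform of the per-line
#' weights, evaluated on \code{matrixPE * oversampleFactor} points spanning
#' one FOV, peak-normalized to 1. Line j occupies the Nyquist grid position
#' \code{j - matrixPE/2} (DC at the central line), so a symmetric real weight
#' profile yields a symmetric PSF centred at position 0.
#'
#' @param trajectory a \linkS4class{DecayTrajectory}, or a bare numeric weight
#'   vector (then \code{fovMM} supplies the FOV)
#' @param oversampleFactor integer >= 16
#' @param fovMM field of view in mm, only used when \code{trajectory} is a
#'   bare numeric vector
#' @return a \linkS4class{PsfProfile}
#' @export
computePsf <- function(trajectory, oversampleFactor = 64L, fovMM = 200) {
  if (is(trajectory, "DecayTrajectory")) {
    w <- trajectory@weights
    fovMM <- trajectory@params@fovMM
  } else {
    w <- as.numeric(trajectory)
  }
  n <- length(w)
  if (n < 2L) stop("need at least 2 k-space lines")
  oversampleFactor <- as.integer(oversampleFactor)
  if (oversampleFactor < 16L) stop("oversampleFactor must be >= 16")
  if (all(w == 0)) stop("all-zero weight profile")
  m <- n * oversampleFactor
  buf <- complex(m)
  idx <- ((seq_len(n) - 1L) - n %/% 2L) %% m  # line j at frequency j - n/2
  buf[idx + 1L] <- w
  prof <- Mod(stats::fft(buf))
  prof <- c(prof[(m %/% 2L + 1L):m], prof[1:(m %/% 2L)])  # x in [-0.5, 0.5)
  new("PsfProfile",
      positions = (seq_len(m) - 1 - m / 2) / m,
      magnitude = prof / max(prof),
      oversampleFactor = oversampleFactor,
      matrixPE = as.integer(n),
      fovMM = fovMM)
}

# indices of the profile that fall on reconstruction pixel centres
pixelGridIndex <- function(profile) {
  seq.int(1L, length(profile@positions), by = profile@oversampleFactor)
}

halfMaxWidth <- function(x, y) {
  y <- y / max(y)
  i0 <- which.max(y)
  half <- 0.5
  ir <- i0
  while (ir <= length(y) && y[ir] >= half) ir <- ir + 1L
  if (ir > length(y)) stop("profile never falls below half maximum ",
                           "(insufficient support on the right)")
  xr <- x[ir - 1L] + (half - y[ir - 1L]) * (x[ir] - x[ir - 1L]) /
    (y[ir] - y[ir - 1L])
  il <- i0
  while (il >= 1L && y[il] >= half) il <- il - 1L
  if (il < 1L) stop("profile never falls below half maximum ",
                    "(insufficient support on the left)")
  xl <- x[il + 1L] + (half - y[il + 1L]) * (x[il] - x[il + 1L]) /
    (y[il] - y[il + 1L])
  xr - xl
}

#' @describeIn fwhm width between the two half-maximum crossings bracketing
#'   the peak, located by linear interpolation. With \code{grid = "pixel"}
#'   (the default) the profile is evaluated at reconstruction pixel centres
#'   only, i.e. the width of the point response as it appears on the image
#'   grid; \code{grid = "fine"} uses the full oversampled profile. The
#'   \code{convention} selects the magnitude or the squared-magnitude
#'   (intensity) profile.
#' @param convention "magnitude" or "intensity"
#' @param grid "pixel" or "fine"
#' @return named numeric \code{c(norm, mm)}: FOV-normalized width and its
#'   exact mm conversion \code{norm * fovMM}
#' @export
setMethod("fwhm", "PsfProfile",
  function(profile, convention = c("magnitude", "intensity"),
           grid = c("pixel", "fine")) {
    convention <- match.arg(convention)
    grid <- match.arg(grid)
    y <- profile@magnitude
    if (convention == "intensity") y <- y^2
    x <- profile@positions
    if (grid == "pixel") {
      keep <- pixelGridIndex(profile)
      x <- x[keep]
      y <- y[keep]
    }
    wNorm <- halfMaxWidth(x, y)
    c(norm = wNorm, mm = wNorm * profile@fovMM)
  })

#' @describeIn sidePeaks local maxima of the magnitude profile outside the
#'   main-lobe exclusion zone, sorted by magnitude descending. For a
#'   period-\code{nInterleaves} peripheral modulation the dominant peaks sit
#'   at FOV-normalized positions +-1/nInterleaves.
#' @param mainlobeExclusionNorm half-width of the excluded central zone,
#'   FOV-normalized
#' @param grid "pixel" or "fine"
#' @return data.frame with columns \code{position}, \code{magnitude}
#' @export
setMethod("sidePeaks", "PsfProfile",
  function(profile, mainlobeExclusionNorm = 0.1, grid = c("pixel", "fine")) {
    grid <- match.arg(grid)
    x <- profile@positions
    y <- profile@magnitude
    if (grid == "pixel") {
      keep <- pixelGridIndex(profile)
      x <- x[keep]
      y <- y[keep]
    }
    n <- length(y)
    isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                       y[2:(n - 1)] >= y[3:n], FALSE)
    sel <- isMax & abs(x) > mainlobeExclusionNorm
    out <- data.frame(position = x[sel], magnitude = y[sel])
    out[order(out$magnitude, decreasing = TRUE), , drop = FALSE]
  })

#' Relative FWHM change between dynamic and stationary acquisition
#'
#' Recomputes the PSF FWHM with and without per-scan amplitude modulation and
#' returns \code{100 * (FWHM_dynamic - FWHM_stationary) / FWHM_stationary}
#' under identical convention, grid and oversampling.
#'
#' @param params a \linkS4class{SequenceParams}
#' @param scanAmplitudes per-scan amplitudes, oldest first (e.g.
#'   \code{c(1, 1.025, 1.05)} for a 5 percent ramp over three scans)
#' @param timingModel passed to \code{\link{effectiveLineTimes}}
#' @param convention,grid passed to \code{\link{fwhm}}
#' @param oversampleFactor passed to \code{\link{computePsf}}
#' @param keyholeScan passed to \code{\link{decayTrajectory}}
#' @return percent FWHM change
#' @export
dynamicFwhmChange <- function(params, scanAmplitudes,
                              timingModel = "physical_piecewise",
                              convention = "magnitude", grid = "pixel",
                              oversampleFactor = 64L, keyholeScan = 1L) {
  tm <- effectiveLineTimes(params, timingModel)
  fs <- fwhm(computePsf(decayTrajectory(tm), oversampleFactor),
             convention, grid)[["norm"]]
  fd <- fwhm(computePsf(decayTrajectory(tm, scanAmplitudes = scanAmplitudes,
                                        keyholeScan = keyholeScan),
                        oversampleFactor),
             convention, grid)[["norm"]]
  100 * (fd - fs) / fs
}
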