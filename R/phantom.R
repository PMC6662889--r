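# Synthetic object, BOLD paradigm and susceptibility models.

# logical disc mask on a grid; center in (row, col) pixels, 1-based
discMask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

ellipseMask <- function(shape, center, semi) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
}

#' Construct a synthetic phantom specification
#'
#' The phantom is a structured 2-D object (a large tissue ellipse with
#' internal intensity layers) carrying disc-shaped ROIs whose intensity is
#' modulated by a block-design BOLD paradigm: an initial fixation period
#' followed by alternating task/rest blocks, convolved with a canonical
#' double-gamma haemodynamic response function.
#'
#' Defaults mirror a typical 3 T block-design protocol: a 20 s fixation, 7
#' cycles of 32 s task / 32 s rest, TR 2200 ms, and a 5 percent BOLD
#' amplitude (a typical task-induced signal increase relative to baseline at
#' 3 T).
#'
#' @param shape grid shape (phase-encode, readout)
#' @param background background intensity
#' @param tissue tissue intensity of the main ellipse
#' @param rois list of ROI descriptors (name, center, radius, amplitude); the
#'   default places a "motor" and a "visual" disc inside the object
#' @param fixationS initial fixation duration, s
#' @param blockS task/rest block duration, s
#' @param cycles number of task/rest cycles
#' @param trMS repetition time, ms
#' @param noiseSD complex k-space noise standard deviation per line sample
#' @param seed integer seed for noise generation
#' @param gspMap per-pixel susceptibility gradient (mT/m); defaults to none
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(shape = c(96L, 96L),
                        background = 0,
                        tissue = 1,
                        rois = NULL,
                        fixationS = 20,
                        blockS = 32,
                        cycles = 7L,
                        trMS = 2200,
                        noiseSD = 0,
                        seed = 1L,
                        gspMap = NULL) {
  shape <- as.integer(shape)
  if (is.null(rois)) {
    rois <- list(
      list(name = "motor", center = round(shape * c(0.36, 0.40)),
           radius = max(2, round(min(shape) / 12)), amplitude = 0.05),
      list(name = "visual", center = round(shape * c(0.66, 0.62)),
           radius = max(2, round(min(shape) / 12)), amplitude = 0.05))
  }
  if (is.null(gspMap)) gspMap <- matrix(numeric(0), 0, 0)
  new("PhantomSpec", shape = shape, background = background,
      tissue = tissue, rois = rois, fixationS = fixationS, blockS = blockS,
      cycles = as.integer(cycles), trMS = trMS, noiseSD = noiseSD,
      seed = as.integer(seed), gspMap = gspMap)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d grid, %d ROI(s), noise sd %g, seed %d\n",
              object@shape[1], object@shape[2], length(object@rois),
              object@noiseSD, object@seed))
  cat(sprintf("  paradigm: %gs fixation + %d x (%gs task / %gs rest), TR %g ms\n",
              object@fixationS, object@cycles, object@blockS, object@blockS,
              object@trMS))
  invisible(object)
})

#' Render the baseline phantom image and its ROI masks
#'
#' Deterministic given the spec: a large tissue ellipse, an off-centre darker
#' inner ellipse and a brighter rim layer, plus the ROI discs at tissue
#' intensity (the BOLD modulation is purely temporal, so the baseline ROI
#' intensity equals the surrounding tissue unless an ROI lies outside the
#' object).
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return list with \code{baseline} (matrix) and \code{masks} (named list of
#'   logical matrices, one per ROI)
#' @export
makePhantom <- function(spec) {
  sh <- spec@shape
  img <- matrix(spec@background, sh[1], sh[2])
  ctr <- (sh + 1) / 2
  body <- ellipseMask(sh, ctr, sh * 0.42)
  img[body] <- spec@tissue
  rim <- body & !ellipseMask(sh, ctr, sh * 0.38)
  img[rim] <- spec@tissue * 1.15
  inner <- ellipseMask(sh, ctr + sh * c(0.08, -0.06), sh * c(0.14, 0.10))
  img[inner] <- spec@tissue * 0.7
  masks <- list()
  for (r in spec@rois) {
    m <- discMask(sh, r$center, r$radius)
    img[m] <- spec@tissue  # ROI sits at plain tissue intensity
    masks[[r$name]] <- m
  }
  list(baseline = img, masks = masks)
}

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking at 6 s minus a 16 s
#' undershoot gamma scaled by 1/6, evaluated at \code{tSec} (seconds after
#' stimulus onset; zero for negative times).
#'
#' @param tSec time in seconds
#' @param peak1,peak2 shape parameters of response and undershoot gammas
#' @param ratio undershoot ratio
#' @return HRF amplitude (arbitrary units)
#' @export
canonicalHRF <- function(tSec, peak1 = 6, peak2 = 16, ratio = 6) {
  h <- stats::dgamma(tSec, shape = peak1, rate = 1) -
    stats::dgamma(tSec, shape = peak2, rate = 1) / ratio
  h[tSec < 0] <- 0
  h
}

# HRF-convolved paradigm response on a fine grid, plateau-normalized so a
# sustained block reaches ~1. Returns a function of time in seconds.
paradigmResponse <- function(spec, dtS = 0.1) {
  totalS <- spec@fixationS + 2 * spec@blockS * spec@cycles
  tt <- seq(0, totalS + 32, by = dtS)
  box <- numeric(length(tt))
  for (k in seq_len(spec@cycles)) {
    on <- spec@fixationS + (k - 1) * 2 * spec@blockS
    box[tt >= on & tt < on + spec@blockS] <- 1
  }
  h <- canonicalHRF(seq(0, 32, by = dtS))
  resp <- stats::convolve(box, rev(h), type = "open")[seq_along(tt)] * dtS
  resp <- resp / (sum(h) * dtS)  # steady-state plateau of a long block -> 1
  function(tS) {
    out <- stats::approx(tt, resp, xout = tS, rule = 2)$y
    out[tS < 0] <- NA_real_
    out
  }
}

#' Per-ROI BOLD modulation factor at a given time
#'
#' Boxcar paradigm (fixation, then alternating task/rest blocks) convolved
#' with the canonical HRF and scaled so that the sustained-block plateau
#' approximates \code{1 + amplitude}; the factor is 1 outside ROIs and during
#' the initial fixation.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param tMS time from the start of the experiment, ms
#' @return named numeric vector of multiplicative factors, one per ROI
#' @export
boldTimecourse <- function(spec, tMS) {
  if (any(tMS < 0)) stop("negative time")
  resp <- paradigmResponse(spec)(tMS / 1000)
  out <- vapply(spec@rois, function(r) 1 + r$amplitude * resp, numeric(length(tMS)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(tMS))
  colnames(out) <- vapply(spec@rois, `[[`, "", "name")
  if (length(tMS) == 1L) out[1, ] else out
}

#' Check that the paradigm fits within a scan count
#'
#' Asserts that the full paradigm (fixation plus all task/rest cycles) fits
#' into \code{nScans} repetitions of the TR.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param nScans number of acquired scans
#' @return invisibly, the paradigm duration in seconds
#' @export
assertParadigmFits <- function(spec, nScans) {
  durS <- spec@fixationS + 2 * spec@blockS * spec@cycles
  availS <- nScans * spec@trMS / 1000
  if (durS > availS)
    stop(sprintf("paradigm lasts %.1f s but %d scans cover only %.1f s",
                 durS, nScans, availS))
  invisible(durS)
}

#' Construct a susceptibility effective-TE model
#'
#' @param gspMTM local susceptibility gradient, mT/m (may be a matrix)
#' @param deltaTMS echo spacing, ms (the effective spacing of the scheme)
#' @param fovMM field of view, mm
#' @param gammaRadTS gyromagnetic ratio, rad s^-1 T^-1 (default: proton)
#' @return a \linkS4class{SusceptibilityModel}
#' @export
susceptibilityModel <- function(gspMTM, deltaTMS, fovMM = 200,
                                gammaRadTS = 2.675e8) {
  new("SusceptibilityModel", gammaRadTS = gammaRadTS, deltaTMS = deltaTMS,
      fovMM = fovMM, gspMTM = as.numeric(gspMTM))
}

#' @describeIn susceptibilityModel the attenuation-free scaling factor
#'   \code{Q = 1 - gamma * Delta-t / (2*pi) * FOV * G_SP} (dimensionless; all
#'   quantities converted to SI internally)
#' @param model a \linkS4class{SusceptibilityModel}
#' @export
setMethod("qFactor", "SusceptibilityModel", function(model) {
  1 - model@gammaRadTS * (model@deltaTMS * 1e-3) / (2 * pi) *
    (model@fovMM * 1e-3) * (model@gspMTM * 1e-3)
})

#' @describeIn susceptibilityModel the effective echo time \code{TE' = TE/Q};
#'   pixels with \code{Q <= 0} are flagged as the signal-void regime and
#'   returned as \code{NA}
#' @param teMS nominal echo time, ms
#' @export
setMethod("effectiveTE", "SusceptibilityModel", function(model, teMS) {
  q <- qFactor(model)
  te <- teMS / q
  te[q <= 0] <- NA_real_  # void regime: echo pushed out of the window
  te
})

setMethod("show", "SusceptibilityModel", function(object) {
  q <- qFactor(object)
  cat(sprintf("SusceptibilityModel: dt %g ms, FOV %g mm, G_SP %s mT/m\n",
              object@deltaTMS, object@fovMM,
              paste(format(range(object@gspMTM)), collapse = " .. ")))
  cat(sprintf("  Q %s\n", paste(format(range(q)), collapse = " .. ")))
  invisible(object)
})

#' Apply susceptibility-induced signal attenuation to an image
#'
#' Scales each pixel by \code{exp(-TE'/T2*) / exp(-TE/T2*)} where TE' follows
#' from the pixel's local gradient and the scheme's effective echo spacing;
#' void-regime pixels (Q <= 0) are set to 0. With a zero gradient map the
#' image is returned unchanged.
#'
#' @param image baseline image matrix
#' @param gspMap per-pixel susceptibility gradient, mT/m (same shape)
#' @param params a \linkS4class{SequenceParams}; its effective echo spacing
#'   and TE/T2* feed the model
#' @return attenuated image matrix
#' @export
applySusceptibility <- function(image, gspMap, params) {
  if (!all(dim(image) == dim(gspMap)))
    stop("gspMap shape must match the image")
  m <- susceptibilityModel(gspMap, effectiveEchoSpacing(params),
                           params@fovMM)
  tePrime <- effectiveTE(m, params@teMS)
  fac <- exp(-(tePrime - params@teMS) / params@t2starMS)
  fac[is.na(tePrime)] <- 0
  image * matrix(fac, nrow(image), ncol(image))
}
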