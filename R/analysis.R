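# Functional metrics: tSNR, GLM activation, residual autocorrelation,
# scheme comparison.

#' @describeIn tsnr pixelwise temporal mean over temporal standard deviation;
#'   zero-variance pixels are reported as \code{Inf} and excluded from the
#'   masked summary.
#' @param mask optional logical matrix restricting the summary
#' @return list with \code{map} (matrix) and \code{summary} (mean of finite
#'   values within the mask)
#' @export
setMethod("tsnr", "VolumeSeries", function(series, mask = NULL) {
  fr <- series@frames
  if (dim(fr)[3] < 3L) stop("need at least 3 frames")
  mu <- apply(fr, c(1, 2), mean)
  sd <- apply(fr, c(1, 2), stats::sd)
  map <- mu / sd
  map[sd == 0] <- Inf
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map), ncol(map))
  vals <- map[mask]
  list(map = map, summary = mean(vals[is.finite(vals)]))
})

# design matrix: HRF-convolved boxcar (plateau ~ 1), its temporal
# derivative, constant, linear drift
glmDesign <- function(spec, series) {
  n <- frameCount(series)
  tS <- (series@firstScanIndex + seq_len(n) - 1) * series@trMS / 1000
  resp <- paradigmResponse(spec)
  task <- resp(tS)
  dt <- 0.1
  deriv <- (resp(tS + dt) - resp(tS - dt)) / (2 * dt)
  drift <- seq_len(n) - (n + 1) / 2
  X <- cbind(task = task, deriv = deriv,
             const = 1, drift = drift / max(abs(drift)))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  X
}

#' GLM activation analysis of a reconstructed series
#'
#' Pixelwise ordinary least squares against an HRF-convolved block regressor,
#' its temporal derivative, a constant and a linear drift. The task regressor
#' is plateau-normalized, so the task beta divided by the constant beta is
#' the fractional signal change; ROI-level statistics are computed on
#' ROI-mean time series.
#'
#' @param series a \linkS4class{VolumeSeries}
#' @param spec the \linkS4class{PhantomSpec} that defines the paradigm
#' @param masks named list of logical ROI masks (e.g. from
#'   \code{\link{makePhantom}})
#' @return a \linkS4class{GlmResult}
#' @export
glmActivation <- function(series, spec, masks = list()) {
  X <- glmDesign(spec, series)
  fr <- series@frames
  d <- dim(fr)
  Y <- t(matrix(fr, d[1] * d[2], d[3]))  # frames x pixels
  fit <- stats::lm.fit(X, Y)
  beta <- array(t(fit$coefficients), c(d[1], d[2], ncol(X)))
  res <- fit$residuals
  dfRes <- d[3] - ncol(X)
  sigma2 <- colSums(res^2) / dfRes
  xtxInv <- chol2inv(chol(crossprod(X)))
  seTask <- sqrt(sigma2 * xtxInv[1, 1])
  tMap <- matrix(t(fit$coefficients)[, 1] / seTask, d[1], d[2])
  tMap[seTask == 0] <- NA_real_
  roiStats <- data.frame(roi = character(), beta = numeric(), t = numeric(),
                         pValue = numeric(), percentChange = numeric(),
                         stringsAsFactors = FALSE)
  roiResiduals <- list()
  for (nm in names(masks)) {
    y <- apply(fr, 3, function(f) mean(f[masks[[nm]]]))
    f1 <- stats::lm.fit(X, y)
    s2 <- sum(f1$residuals^2) / dfRes
    se <- sqrt(s2 * xtxInv[1, 1])
    tval <- f1$coefficients[1] / se
    roiStats <- rbind(roiStats, data.frame(
      roi = nm, beta = unname(f1$coefficients[1]), t = unname(tval),
      pValue = 2 * stats::pt(-abs(tval), dfRes),
      percentChange = 100 * unname(f1$coefficients[1] /
                                     f1$coefficients[3]),
      stringsAsFactors = FALSE))
    roiResiduals[[nm]] <- unname(f1$residuals)
  }
  new("GlmResult", beta = beta, tMap = tMap, design = X,
      roiStats = roiStats, roiResiduals = roiResiduals)
}

setMethod("show", "GlmResult", function(object) {
  cat(sprintf("GlmResult: %d frames x %d regressors, %d ROI(s)\n",
              nrow(object@design), ncol(object@design),
              nrow(object@roiStats)))
  if (nrow(object@roiStats)) print(object@roiStats, row.names = FALSE)
  invisible(object)
})

#' Lag-k autocorrelation of ROI-mean GLM residuals
#'
#' Standard sample autocorrelation of the ROI-mean residual series for lags
#' 1..\code{maxLag}. Sliding-window sharing of peripheral k-space noise is
#' expected to raise the low-lag coefficients slightly relative to a
#' direct-reconstruction series.
#'
#' @param glm a \linkS4class{GlmResult}
#' @param roi ROI name
#' @param maxLag maximum lag
#' @return named numeric vector of lag-1..maxLag coefficients
#' @export
residualAutocorrelation <- function(glm, roi, maxLag = 5L) {
  r <- glm@roiResiduals[[roi]]
  if (is.null(r)) stop("no residuals for ROI '", roi, "'")
  if (length(r) <= maxLag + 2L) stop("residual series too short")
  if (stats::sd(r) == 0) stop("degenerate (constant) residuals")
  ac <- stats::acf(r, lag.max = maxLag, plot = FALSE)$acf[-1]
  stats::setNames(ac, paste0("lag", seq_len(maxLag)))
}

#' Side-by-side comparison of two schemes' metrics
#'
#' Tabulates matched metrics from two named lists (as produced by a
#' simulation run: tSNR summary, recovered amplitude, t statistic, lag-1
#' autocorrelation, ...) without recomputing anything.
#'
#' @param epiMetrics,epikMetrics named lists of scalar metrics
#' @param labels column labels
#' @return data.frame with one row per metric and a delta column
#' @export
compareSchemes <- function(epiMetrics, epikMetrics,
                           labels = c("EPI", "EPIK")) {
  keys <- union(names(epiMetrics), names(epikMetrics))
  pick <- function(l, k) if (is.null(l[[k]])) NA_real_ else as.numeric(l[[k]])
  a <- vapply(keys, pick, numeric(1), l = epiMetrics)
  b <- vapply(keys, pick, numeric(1), l = epikMetrics)
  out <- data.frame(metric = keys, a = a, b = b, delta = b - a,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- labels
  out
}

#' Scalar functional metrics of a simulated run
#'
#' Convenience wrapper computing the metrics the scheme comparison reports:
#' masked tSNR summary, ROI percent signal change and t statistic for the
#' first ROI, and lag-1 residual autocorrelation.
#'
#' @param sim result of \code{\link{simulateSeries}}
#' @param spec the generating \linkS4class{PhantomSpec}
#' @param roi ROI to report; defaults to the first
#' @return named list of scalar metrics
#' @export
seriesMetrics <- function(sim, spec, roi = NULL) {
  masks <- sim$phantom$masks
  if (is.null(roi)) roi <- names(masks)[1]
  objMask <- sim$phantom$baseline > 0
  ts <- tsnr(sim$series, objMask)
  g <- glmActivation(sim$series, spec, masks)
  row <- g@roiStats[g@roiStats$roi == roi, ]
  ac <- residualAutocorrelation(g, roi)
  list(tsnr = ts$summary,
       percentChange = row$percentChange,
       tStat = row$t,
       lag1Autocorrelation = unname(ac["lag1"]))
}
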