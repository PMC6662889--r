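test_that("decay trajectories follow the exponential envelope", {
  p <- seqPreset("epi64")
  tm <- effectiveLineTimes(p, "uniform_effective")
  tr <- decayTrajectory(tm)
  w <- lineWeights(tr)
  # closed form: last/first = exp(-(t_last - t_first)/T2*)
  expect_equal(w[64] / w[1], exp(-((46.32 - 0.510) - 13.68) / 66))
  expect_true(all(diff(w) < 0))  # monotone decay across lines

  trInf <- decayTrajectory(tm, t2starMS = Inf)
  expect_equal(lineWeights(trInf), rep(1, 64))

  pk <- seqPreset("epik96")
  tmk <- effectiveLineTimes(pk, "physical_piecewise")
  amps <- c(1, 1.025, 1.05)
  trd <- decayTrajectory(tmk, scanAmplitudes = amps)
  wd <- lineWeights(trd)
  ws <- lineWeights(decayTrajectory(tmk))
  ratio <- wd / ws
  kh <- keyholeLines(pk) + 1
  expect_equal(unique(ratio[kh]), amps[1])  # keyhole from the baseline scan
  periph <- setdiff(1:96, kh)
  # periphery carries the period-3 multiplicative pattern
  expect_equal(unname(ratio[periph]), amps[((periph - 1) %% 3) + 1])

  expect_error(decayTrajectory(tmk, scanAmplitudes = c(1, 1.05)),
               "scanAmplitudes")
})

test_that("computePsf matches a direct-summation Fourier oracle", {
  set.seed(7)
  w <- stats::runif(16, 0.5, 1.5)
  prof <- computePsf(w, oversampleFactor = 32L, fovMM = 100)
  expect_equal(prof@magnitude, naivePsf(w, prof@positions) /
                 max(naivePsf(w, prof@positions)), tolerance = 1e-12)

  # single nonzero line: flat magnitude (no localization)
  flat <- computePsf(c(0, 0, 1, 0, 0, 0, 0, 0), 16L)
  expect_equal(flat@magnitude, rep(1, length(flat@magnitude)))

  # symmetric real weights give a symmetric profile
  ws <- exp(-abs(seq(-7.5, 7.5)) / 10)
  ps <- computePsf(ws, 32L)
  m <- ps@magnitude
  expect_equal(m[-1], rev(m[-1]), tolerance = 1e-10)

  expect_error(computePsf(rep(0, 8)), "zero")
  expect_error(computePsf(w, oversampleFactor = 8L), "oversample")
})

test_that("fine-grid FWHM agrees with the Dirichlet-kernel closed form", {
  for (n in c(64L, 96L)) {
    prof <- computePsf(rep(1, n), oversampleFactor = 64L)
    step <- 1 / (n * 64L)
    oracleMag <- bruteFwhm(dirichletKernel(n))
    oracleInt <- bruteFwhm(function(x) dirichletKernel(n)(x)^2)
    expect_equal(fwhm(prof, "magnitude", "fine")[["norm"]], oracleMag,
                 tolerance = step / oracleMag)
    expect_equal(fwhm(prof, "intensity", "fine")[["norm"]], oracleInt,
                 tolerance = step / oracleInt)
    # and the classical constants
    expect_equal(oracleMag, 1.2067 / n, tolerance = 1e-3)
    expect_equal(oracleInt, 0.886 / n, tolerance = 1e-3)
  }
})

test_that("FWHM conversions and failure modes behave", {
  prof <- computePsf(rep(1, 32), 64L, fovMM = 200)
  f <- fwhm(prof, "magnitude", "fine")
  expect_equal(f[["mm"]], f[["norm"]] * 200)  # exact conversion
  # pixel-grid width of the uniform profile is exactly one pixel
  expect_equal(fwhm(prof, "magnitude", "pixel")[["norm"]], 1 / 32)

  # near-delta weight profile never crosses half maximum
  expect_error(fwhm(computePsf(c(1, 1e-8, 0, 0), 64L)), "half maximum")
})

test_that("periodic peripheral modulation creates ghosts at +-1/interleave", {
  n <- 48L
  base <- rep(1, n)
  ghostMag <- function(eps) {
    # on the pixel grid the uniform background samples to zero away from
    # the main lobe, so the modulation ghost is isolated exactly at +-1/3
    w <- base * (1 + eps * ((seq_len(n) - 1) %% 3 - 1))
    pk <- sidePeaks(computePsf(w, 64L), mainlobeExclusionNorm = 0.1,
                    grid = "pixel")
    pk[abs(abs(pk$position) - 1 / 3) < 0.01, ]
  }
  g1 <- ghostMag(0.02)
  expect_equal(nrow(g1), 2L)  # symmetric pair
  expect_equal(sort(g1$position), c(-1, 1) / 3, tolerance = 1e-3)
  g2 <- ghostMag(0.04)
  # ghost magnitude is linear in modulation depth
  expect_equal(g2$magnitude[1] / g1$magnitude[1], 2, tolerance = 0.02)

  # no modulation: nothing coherent at exactly +-1/3 above numerical floor
  profFlat <- computePsf(base, 64L)
  at13 <- which(abs(abs(profFlat@positions) - 1 / 3) < 1e-12)
  expect_length(at13, 2L)
  expect_true(all(profFlat@magnitude[at13] < 1e-10))
})

test_that("dynamic FWHM change is zero without modulation and stable in sign", {
  p <- seqPreset("epik96")
  expect_equal(dynamicFwhmChange(p, c(1, 1, 1)), 0)
  up <- dynamicFwhmChange(p, c(1, 1.025, 1.05))
  down <- dynamicFwhmChange(p, c(1, 0.975, 0.95))
  # a ramp of opposite sign produces a change of comparable small magnitude
  expect_lt(abs(abs(down) - abs(up)), 0.25)
  expect_lt(abs(up), 1)
})

test_that("decay only broadens and shorter spacing never widens the PSF", {
  n <- 48L
  uniformF <- fwhm(computePsf(rep(1, n), 64L), "magnitude", "fine")[["norm"]]
  prev <- NULL
  for (t2 in c(20, 40, 80, 1e6)) {
    p <- sequenceParams("EPI", matrixPE = n, echoSpacingMS = 0.6,
                        teMS = 25, t2starMS = t2)
    f <- fwhm(computePsf(decayTrajectory(effectiveLineTimes(p))),
              "magnitude", "fine")[["norm"]]
    expect_gte(f, uniformF - 1e-12)        # decay only broadens
    if (!is.null(prev)) expect_lte(f, prev + 1e-12)  # longer T2* narrows
    prev <- f
  }
  # monotonicity in spacing at fixed line count
  fOf <- function(dt) {
    p <- sequenceParams("EPI", matrixPE = n, echoSpacingMS = dt,
                        teMS = 25, t2starMS = 50)
    fwhm(computePsf(decayTrajectory(effectiveLineTimes(p))),
         "magnitude", "fine")[["norm"]]
  }
  sweep <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), fOf, numeric(1))
  expect_true(all(diff(sweep) >= -1e-12))
})

test_that("degenerate EPIK reproduces the EPI PSF bit for bit", {
  epi <- tinyEpi()
  degenerate <- sequenceParams("EPIK", matrixPE = epi@matrixPE,
                               echoSpacingMS = epi@echoSpacingMS,
                               teMS = epi@teMS, trMS = epi@trMS,
                               keyholeFraction = 1, nInterleaves = 1L,
                               t2starMS = epi@t2starMS)
  pe <- computePsf(decayTrajectory(effectiveLineTimes(epi,
                                                      "physical_piecewise")))
  pk <- computePsf(decayTrajectory(effectiveLineTimes(degenerate,
                                                      "physical_piecewise")))
  expect_identical(pe@magnitude, pk@magnitude)
})
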