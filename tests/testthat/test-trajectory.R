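test_that("EPI schedule follows the linear centre-anchored timing", {
  p <- seqPreset("epi64")
  s <- epiSchedule(p)
  e <- scheduleTable(s)
  expect_equal(nrow(e), 64L)
  expect_equal(e$acqTimeMS[e$lineIndex == 0], 13.68)
  expect_equal(e$acqTimeMS[e$lineIndex == 32], 30)
  expect_equal(e$acqTimeMS[e$lineIndex == 63], 46.32 - 0.510)
  expect_true(all(e$region == "keyhole"))

  p8 <- sequenceParams("EPI", matrixPE = 8L, echoSpacingMS = 1, teMS = 10)
  expect_equal(epiSchedule(p8)@entries$acqTimeMS, 6:13)

  expect_error(epiSchedule(seqPreset("epik96")), "EPI")
})

test_that("EPIK shots interleave the periphery and jointly cover k-space", {
  p <- seqPreset("epik96")
  sh <- lapply(0:3, function(i) epikSchedule(p, i))
  for (i in 0:3) {
    e <- scheduleTable(sh[[i + 1]])
    expect_equal(nrow(e), 48L)  # half the 96 lines per shot
    expect_equal(sum(e$region == "keyhole"), 24L)
    periph <- e$lineIndex[e$region == "periphery"]
    expect_true(all(periph %% 3 == i %% 3))  # offsets 0,1,2 then 0 again
    expect_true(48L %in% e$lineIndex[e$region == "keyhole"])  # DC in keyhole
  }
  expect_equal(scheduleTable(sh[[1]])$lineIndex,
               scheduleTable(sh[[4]])$lineIndex)
  covered <- sort(unlist(lapply(sh[1:3], function(s)
    scheduleTable(s)$lineIndex[scheduleTable(s)$region == "periphery"])))
  covered <- sort(c(covered, scheduleTable(sh[[1]])$lineIndex[
    scheduleTable(sh[[1]])$region == "keyhole"]))
  expect_equal(unique(covered), 0:95)  # every peripheral line exactly once

  expect_error(epikSchedule(p, -1), "shotIndex")
})

test_that("effective time maps anchor TE and conserve readout duration", {
  p <- seqPreset("epik96")
  uni <- effectiveLineTimes(p, "uniform_effective")
  expect_equal(effectiveEchoSpacing(p), 0.445)
  expect_equal(min(uni@timesMS), 8.64)
  expect_equal(uni@timesMS[49], 30)  # central line at TE
  expect_equal(uni@spanMS, 42.72)

  pw <- effectiveLineTimes(p, "physical_piecewise")
  expect_equal(pw@spanMS, 48 * 0.890)      # same span as the uniform model
  expect_equal(pw@spanMS, uni@spanMS)
  expect_equal(pw@timesMS[49], 30)
  expect_false(is.unsorted(pw@timesMS))

  # the piecewise map equals the combined echo-time-shifted shot times
  combined <- numeric(96)
  for (i in 0:2) {
    e <- scheduleTable(epikSchedule(p, i))
    sel <- if (i == 0) rep(TRUE, nrow(e)) else e$region == "periphery"
    combined[e$lineIndex[sel] + 1] <- e$acqTimeMS[sel]
  }
  expect_equal(combined, pw@timesMS)

  # EPI: both models and the schedule agree
  pe <- seqPreset("epi64")
  expect_equal(effectiveLineTimes(pe, "uniform_effective")@timesMS,
               scheduleTable(epiSchedule(pe))$acqTimeMS)
  expect_equal(effectiveLineTimes(pe, "physical_piecewise")@timesMS,
               scheduleTable(epiSchedule(pe))$acqTimeMS)

  expect_error(effectiveLineTimes(p, "no_such_model"))
})

test_that("sampling windows and periphery update rates match the protocol", {
  epi <- seqPreset("epi64")
  epik <- seqPreset("epik96")
  wE <- samplingWindow(epi)
  wK <- samplingWindow(epik)
  expect_equal(unname(wE[c("tMinMS", "tMaxMS")]), c(13.68, 46.32))
  expect_equal(unname(wK[c("tMinMS", "tMaxMS")]), c(8.64, 51.36))
  expect_equal(unname(wK["widthMS"] - wE["widthMS"]), 10.08)
  # symmetric about TE
  expect_equal(unname((wK["tMinMS"] + wK["tMaxMS"]) / 2), epik@teMS)

  expect_equal(peripheryUpdateRate(epik), 1 / 6.6)
  expect_equal(peripheryUpdateRate(epi), 1000 / epi@trMS)
  p3 <- tinyEpik(trMS = 1000)
  expect_equal(peripheryUpdateRate(p3), 1 / 3)
})

test_that("sliding-window sources are total, unique and causal", {
  p <- seqPreset("epik96")
  src2 <- slidingWindowSources(2, p)
  kh <- keyholeLines(p)
  expect_true(all(src2[as.character(kh)] == 2))
  periph <- setdiff(0:95, kh)
  expect_setequal(unique(src2[as.character(periph)]), 0:2)
  # each peripheral source covers its own interleave
  expect_true(all(periph %% 3 == src2[as.character(periph)] %% 3))

  src3 <- slidingWindowSources(3, p)
  expect_setequal(unique(src3[as.character(periph)]), 1:3)  # scan 0 dropped
  expect_equal(length(src3), 96L)
  expect_true(all(src3 >= 1 & src3 <= 3))

  expect_error(slidingWindowSources(1, p), "reconstructable")
})

test_that("EPI is the degenerate single-interleave keyhole case", {
  p <- tinyEpi()
  degenerate <- sequenceParams("EPIK", matrixPE = p@matrixPE,
                               echoSpacingMS = p@echoSpacingMS,
                               teMS = p@teMS, trMS = p@trMS,
                               keyholeFraction = 1, nInterleaves = 1L,
                               t2starMS = p@t2starMS)
  expect_equal(scheduleTable(epikSchedule(degenerate, 0)),
               scheduleTable(epiSchedule(p, 0)))
})

test_that("random valid parameterizations keep coverage and conservation", {
  set.seed(42)
  for (rep in 1:100) {
    p <- randomValidParams()
    ni <- p@nInterleaves
    covered <- unlist(lapply(seq_len(ni) - 1L, function(i) {
      e <- scheduleTable(epikSchedule(p, i))
      if (i == 0) e$lineIndex else e$lineIndex[e$region == "periphery"]
    }))
    expect_equal(sort(covered), 0:(p@matrixPE - 1))  # Nyquist coverage

    src <- slidingWindowSources(ni + 2L, p)
    expect_equal(length(src), p@matrixPE)            # total
    expect_true(all(src > 2L & src <= ni + 2L))      # window-aged sources

    # readout-duration conservation: eff spacing x matrix = lines/shot x dt
    expect_equal(effectiveEchoSpacing(p) * p@matrixPE,
                 linesPerShot(p) * p@echoSpacingMS)
  }
})

test_that("invalid parameter combinations are rejected", {
  expect_error(sequenceParams("EPIK", matrixPE = 96L, echoSpacingMS = 0.89,
                              keyholeFraction = 0.3), "integer")
  expect_error(sequenceParams("EPIK", matrixPE = 96L, echoSpacingMS = 0.89,
                              keyholeFraction = 0.25, nInterleaves = 5L),
               "divisible")
  expect_error(sequenceParams("EPI", matrixPE = 64L, echoSpacingMS = -1),
               "positive")
})
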