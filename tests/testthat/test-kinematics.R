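emptyRunProgram <- function(cfg, duration = 10) {
  ## a run with no waves: zero-rate behavior on a flat trace, waves removed
  tr <- generateTemperature(temperatureWaveform(amplitude = 0), duration, 8)
  prog <- sampleBehavior(simulationConfig(turnRateWarming = 0,
                                          turnRateCooling = 0), tr, seed = 1)
  prog@waves <- prog@waves[0, ]
  prog
}

test_that("an empty program leaves the body static", {
  cfg <- simulationConfig(noiseSd = 0)
  body <- larvaBodyModel()
  truth <- synthesizeKinematics(emptyRunProgram(cfg), body, cfg, geometry = "full")
  expect_true(all(truth@frames$theta_deg == 0))
  expect_equal(max(abs(diff(truth@frames$tail_x_mm))), 0)
  expect_equal(max(abs(truth@spine[, , 1] - truth@spine[, , nFrames(truth)])), 0)
})

test_that("net displacement equals the summed per-wave displacement", {
  cfg <- simulationConfig(turnRateWarming = 0, turnRateCooling = 0,
                          displacementSd = 0)
  body <- larvaBodyModel()
  tr <- generateTemperature(temperatureWaveform(amplitude = 0), 30, 8)
  prog <- sampleBehavior(cfg, tr, seed = 2)
  truth <- synthesizeKinematics(prog, body, cfg, geometry = "theta")
  fr <- truth@frames
  ## a wave's translation completes when its pulse passes segment A4
  tDone <- prog@waves$onset_s + 8 / larvagram:::pulseSpeed(cfg)
  expected <- sum(prog@waves$disp_bl[tDone <= max(fr$time_s)]) * bodyLength(body)
  moved <- fr$tail_x_mm[nrow(fr)] - fr$tail_x_mm[1]
  expect_equal(moved, expected, tolerance = cfg@pixelScale / expected)
  ## with displacementSd = 0, four completed waves advance 4 x 0.13 BL
  t4 <- prog@waves$onset_s[4] + cfg@waveTraversal
  f4 <- which.min(abs(fr$time_s - t4))
  expect_equal(fr$tail_x_mm[f4] - fr$tail_x_mm[1], 4 * 0.13 * 2,
               tolerance = 0.02)
})

test_that("fluorophore is conserved per segment over time", {
  rv <- runVideoFixture()
  tot <- apply(rv$truth@quadIntensity * rv$truth@quadArea, c(1, 3), sum)
  rel <- abs(sweep(tot, 1, tot[, 1], "/") - 1)
  expect_lt(max(rel), 0.01)
})

test_that("a sweep bends the pivot segments with peak asymmetry at A1", {
  cfg <- simulationConfig(noiseSd = 0)
  body <- larvaBodyModel()
  prog <- makeSweepProgram(60, config = cfg, body = body, gap = 5, lead = 4,
                           seed = 3)
  truth <- synthesizeKinematics(prog, body, cfg, geometry = "theta")
  ## ground-truth peak bend angle reaches the 60 degree target
  expect_equal(max(abs(truth@frames$theta_deg)), 60, tolerance = 0.5)
  ## first attainment of the peak (the bend starts moving tail-ward
  ## while the bend angle still plateaus)
  th <- abs(truth@frames$theta_deg)
  pk <- which(th >= max(th) - 0.2)[1]
  a <- log(truth@segLenRight[, pk] / truth@segLenLeft[, pk])
  expect_equal(names(which.max(abs(a))), "A1")
  hot <- names(a)[abs(a) >= 0.05]
  expect_true(all(hot %in% c("T3", "A1", "A2", "A3")))
  ## leftward sweep: left side shorter, asymmetry positive
  expect_true(all(a[hot] > 0))
})

test_that("sweep amplitude calibration is accurate across sizes", {
  cfg <- simulationConfig()
  body <- larvaBodyModel()
  for (target in c(50, 90, 130)) {
    prog <- makeSweepProgram(target, config = cfg, body = body, gap = 5,
                             lead = 4, seed = 1)
    truth <- synthesizeKinematics(prog, body, cfg, geometry = "theta")
    expect_equal(max(abs(truth@frames$theta_deg)), target, tolerance = 1)
  }
})

test_that("kinematic synthesis is deterministic and validates the program", {
  cfg <- simulationConfig()
  body <- larvaBodyModel()
  tr <- generateTemperature(temperatureWaveform(amplitude = 0), 12, 8)
  prog <- sampleBehavior(simulationConfig(turnRateWarming = 0, turnRateCooling = 0),
                         tr, seed = 1)
  t1 <- synthesizeKinematics(prog, body, cfg, geometry = "theta")
  t2 <- synthesizeKinematics(prog, body, cfg, geometry = "theta")
  expect_identical(t1@frames, t2@frames)
  bad <- prog
  bad@events$t_end[1] <- bad@duration + 10
  expect_error(synthesizeKinematics(bad, body, cfg),
               class = "larvagram_invalid_argument")
})
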