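test_that("wave detection requires a travelling contraction ridge", {
  flat <- buildKymograph(matrix(0, 11, 50, dimnames = list(larvagram:::SEGMENT_NAMES, NULL)),
                         "fractional_intensity", frameRate = 8)
  expect_equal(nrow(detectWaves(flat)$waves), 0)

  ## a constructed anti-diagonal ridge from A8 to T1
  m <- matrix(0, 11, 60, dimnames = list(larvagram:::SEGMENT_NAMES, NULL))
  for (i in 11:1) m[i, 5 + 2 * (11 - i)] <- 0.15
  ky <- buildKymograph(m, "fractional_intensity", frameRate = 8)
  det <- detectWaves(ky)
  expect_equal(nrow(det$waves), 1)
  expect_equal(det$waves$init_segment, "A8")
  expect_equal(det$waves$term_segment, "T1")
  expect_equal(det$waves$n_segments, 11)
  ## ridge slope: 2 frames per segment at 8 Hz -> 4 segments/s
  expect_equal(det$waves$speed_seg_s, 4, tolerance = 1e-9)

  ## the same ridge as a fractional length decrease
  kyL <- buildKymograph(-m, "fractional_length", frameRate = 8)
  expect_equal(nrow(detectWaves(kyL)$waves), 1)
})

test_that("detected wave count and speed match the generator on a run video", {
  rv <- runVideoFixture()
  completed <- sum(rv$prog@waves$onset_s + rv$cfg@waveTraversal <= 25)
  expect_equal(nrow(rv$ev$waves), completed)
  expect_true(all(rv$ev$waves$init_segment %in% c("A7", "A8")))
  genSpeed <- larvagram:::pulseSpeed(rv$cfg)
  expect_lt(max(abs(rv$ev$waves$speed_seg_s / genSpeed - 1)), 0.1)
})

test_that("wave displacement projects the tail track onto the body axis", {
  tr <- data.frame(head_x = rep(10, 20), head_y = 0, tail_x = rep(0, 20), tail_y = 0)
  w <- data.frame(onset_frame = 2, offset_frame = 15)
  expect_equal(waveDisplacement(tr, w, 10), 0)
  tr2 <- tr
  tr2$tail_x <- seq(0, 1.9, 0.1); tr2$head_x <- tr2$tail_x + 10
  expect_equal(waveDisplacement(tr2, w, 10), 1.3 / 10)
  expect_error(waveDisplacement(tr, data.frame(onset_frame = 2, offset_frame = 50), 10),
               class = "larvagram_gap")
})

test_that("per-wave displacement scales linearly with the generator setting", {
  body <- larvaBodyModel()
  tr <- generateTemperature(temperatureWaveform(amplitude = 0), 30, 8)
  disp <- vapply(c(0.13, 0.26), function(d) {
    cfg <- simulationConfig(turnRateWarming = 0, turnRateCooling = 0,
                            displacementPerWave = d, displacementSd = 0)
    prog <- sampleBehavior(cfg, tr, seed = 2)
    truth <- synthesizeKinematics(prog, body, cfg, geometry = "theta")
    fr <- truth@frames
    track <- data.frame(head_x = fr$head_x_mm, head_y = fr$head_y_mm,
                        tail_x = fr$tail_x_mm, tail_y = fr$tail_y_mm)
    v <- larvagram:::pulseSpeed(cfg)
    w <- prog@waves[3, ]
    p0 <- larvagram:::pulseStart(11, cfg)
    wv <- data.frame(onset_frame = round((w$onset_s + (p0 - 10.5) / v) * 8) + 1,
                     offset_frame = round((w$onset_s + (p0 - 0.5) / v) * 8) + 1)
    waveDisplacement(track, wv, bodyLength(body))
  }, numeric(1))
  expect_equal(disp[2] / disp[1], 2, tolerance = 1e-6)
  expect_equal(disp[1], 0.13, tolerance = 1e-6)
})

test_that("the asymmetric region is delimited by the threshold rule", {
  m <- matrix(0, 11, 10, dimnames = list(larvagram:::SEGMENT_NAMES, NULL))
  ky0 <- buildKymograph(m, "asymmetry", frameRate = 8)
  sweep1 <- data.frame(peak_frame = 5)
  expect_error(measureAsymmetricRegion(ky0, sweep1), class = "larvagram_no_region")

  m["A2", 5] <- 0.2
  ky <- buildKymograph(m, "asymmetry", frameRate = 8)
  reg <- measureAsymmetricRegion(ky, sweep1)
  expect_equal(reg$anterior, "A2")
  expect_equal(reg$posterior, "A2")
  expect_equal(reg$peak, "A2")
})

test_that("wave initiation is classified against the asymmetric region", {
  region <- list(anterior_idx = 3, posterior_idx = 6)  # T3..A3
  expect_equal(classifyWaveInitiation(data.frame(init_segment = "A8"), region), "tail")
  expect_equal(classifyWaveInitiation(data.frame(init_segment = "A3"), region), "within_bend")
  expect_equal(classifyWaveInitiation(data.frame(init_segment = "A5"), region), "ambiguous")
})

test_that("maneuver assembly merges sweeps unless the body straightened between", {
  fr <- 8
  mkTheta <- function(gapStraight) {
    c(rep(0, 16), seq(0, 60, 10), rep(60, 3), seq(60, 10, -10),
      rep(if (gapStraight) 5 else 25, 20),
      seq(10, 70, 10), rep(70, 3), seq(70, 0, -10), rep(0, 16))
  }
  waves <- data.frame(wave_id = 1, onset_frame = 40, offset_frame = 50,
                      init_segment = "A8", term_segment = "T1",
                      n_segments = 11, speed_seg_s = 6)
  thA <- mkTheta(TRUE)
  swA <- detectHeadSweeps(thA, visionConfig())
  manA <- assembleManeuvers(swA, waves, thA, frameRate = fr)
  expect_equal(nrow(manA), 2)
  expect_equal(manA$n_sweeps, c(1, 1))

  thB <- mkTheta(FALSE)
  swB <- detectHeadSweeps(thB, visionConfig())
  manB <- assembleManeuvers(swB, waves, thB, frameRate = fr)
  expect_equal(nrow(manB), 1)
  expect_equal(manB$n_sweeps, 2)
  expect_equal(manB$accepted_peak_deg, 70)
  expect_equal(manB$first_sweep_peak_deg, 60)
  expect_equal(manB$intervening_waves, 1)

  over <- swB; over$onset_frame[2] <- over$offset_frame[1] - 2
  expect_error(assembleManeuvers(over, waves, thB, frameRate = fr),
               class = "larvagram_malformed_events")
})

test_that("straightening progression and initiation sites match the generator", {
  sv <- sweepVideoFixture()
  man <- sv$ev$maneuvers
  expect_equal(nrow(man), 2)
  expect_equal(man$size_class, c("small", "large"))
  expect_equal(man$init_class, c("tail", "within_bend"))
  expect_equal(man$region_peak, c("A1", "A1"))
  expect_equal(man$region_anterior, c("T3", "T3"))
  expect_equal(man$region_posterior, c("A3", "A3"))
  expect_true(all(man$waves_to_straighten <= 4 | man$size_class == "large"))
  adv <- straighteningAdvance(sv$ev$kymoAsym, man, sv$ev$waves)
  expect_equal(mean(adv$segments_per_wave), 2, tolerance = 0.5)
})

test_that("waves to straighten do not decrease with sweep amplitude", {
  cfg <- simulationConfig()
  body <- larvaBodyModel()
  wts <- vapply(c(50, 90, 130), function(a) {
    prog <- makeSweepProgram(a, config = cfg, body = body, gap = 6, lead = 5,
                             seed = 9)
    truth <- synthesizeKinematics(prog, body, cfg, geometry = "theta")
    th <- truth@frames$theta_deg
    segLen <- truth@segLenLeft + truth@segLenRight
    ky <- buildKymograph(fractionalChange(segLen, chooseReferenceFrame(segLen)),
                         "fractional_length", frameRate = 8)
    man <- assembleManeuvers(detectHeadSweeps(th, visionConfig()),
                             detectWaves(ky)$waves, th, frameRate = 8)
    man$waves_to_straighten[1]
  }, numeric(1))
  expect_true(all(diff(wts) >= 0))
})
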