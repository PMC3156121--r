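test_that("zero turn rates give a single uninterrupted run", {
  cfg <- simulationConfig(turnRateWarming = 0, turnRateCooling = 0)
  tr <- generateTemperature(temperatureWaveform(), 60, 8)
  prog <- sampleBehavior(cfg, tr, seed = 1)
  expect_equal(nrow(prog@events), 1)
  expect_equal(prog@events$type, "run")
  expect_equal(nrow(prog@sweeps), 0)
  expect_true(all(prog@waves$init_segment == 11))
})

test_that("behavior sampling is deterministic under a fixed seed", {
  cfg <- simulationConfig()
  tr <- generateTemperature(temperatureWaveform(offset = 20, period = 360), 600, 8)
  p1 <- sampleBehavior(cfg, tr, seed = 7)
  p2 <- sampleBehavior(cfg, tr, seed = 7)
  expect_identical(p1@events, p2@events)
  expect_identical(p1@sweeps, p2@sweeps)
  expect_identical(p1@waves, p2@waves)
  p3 <- sampleBehavior(cfg, tr, seed = 8)
  expect_false(identical(p1@events, p3@events))
})

test_that("program structure satisfies its invariants", {
  cfg <- simulationConfig()
  tr <- generateTemperature(temperatureWaveform(offset = 20, period = 360), 900, 8)
  prog <- sampleBehavior(cfg, tr, seed = 3)
  ev <- prog@events[order(prog@events$t_start), ]
  expect_true(all(ev$t_end[-nrow(ev)] <= ev$t_start[-1] + 1e-9))
  sw <- prog@sweeps
  last <- !duplicated(sw$event_id, fromLast = TRUE)
  expect_true(all(sw$accepted[last]))
  expect_true(all(sw$target_deg > 0))
  ## first sweep of each maneuver starts after the last wave of the
  ## preceding run has completed
  turns <- ev[ev$type == "turn", ]
  for (k in seq_len(nrow(turns))) {
    prevWaves <- prog@waves[!prog@waves$ramp &
                              prog@waves$onset_s < turns$t_start[k], ]
    if (nrow(prevWaves)) {
      lastEnd <- max(prevWaves$onset_s) + cfg@waveTraversal
      expect_gte(turns$t_start[k], lastEnd - 1e-9)
    }
  }
})

test_that("empirical turn rates recover the configured phase rates", {
  cfg <- simulationConfig("canton_s")  # warming 3.2, cooling 3.8 min^-1
  tr <- generateTemperature(temperatureWaveform(offset = 20, amplitude = 1,
                                                period = 360), 3600, 8)
  ph <- classifyPhases(tr)
  prog <- sampleBehavior(cfg, tr, seed = 5)
  turns <- prog@events[prog@events$type == "turn", ]
  tf <- turnFrequency(data.frame(onset_s = turns$t_start), ph)
  cool <- tf[tf$phase == "cooling", ]
  warm <- tf[tf$phase == "warming", ]
  expect_lt(abs(cool$rate_min - 3.8), 3 * cool$se_min)
  expect_lt(abs(warm$rate_min - 3.2), 3 * warm$se_min)
})

test_that("truncated-normal location solver hits the requested mean", {
  mu <- larvagram:::truncnormMeanParam(53, 10, 45, 130)
  set.seed(1)
  draws <- larvagram:::rtruncnorm(2e5, mu, 10, 45, 130)
  expect_equal(mean(draws), 53, tolerance = 0.1)
  expect_true(all(draws >= 45 & draws <= 130))
})

test_that("sweep rejection responds to thermal phase direction", {
  cfg <- simulationConfig()
  tr <- generateTemperature(temperatureWaveform(offset = 20, amplitude = 1,
                                                period = 360), 3600, 8)
  prog <- sampleBehavior(cfg, tr, seed = 11)
  sw <- prog@sweeps
  ev <- prog@events
  nsw <- table(sw$event_id)
  phase <- ev$phase[match(as.integer(names(nsw)), ev$event_id)]
  mCool <- mean(nsw[phase == "cooling"])
  mWarm <- mean(nsw[phase == "warming"])
  expect_gt(mCool, mWarm)  # cooling raises rejection, so more sweeps
})
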