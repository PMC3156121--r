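test_that("closed-form OLS equals hand-computed and lm results", {
  ## exact fit
  x <- 0:4; y <- -2 * x
  r <- regressIntensityVsLength(x, y)
  expect_equal(r$slope, -2)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope_se, 0)

  ## 4-point set with hand-computed normal equations
  x <- c(0, 1, 2, 3); y <- c(0, 1, 1, 2)
  r <- regressIntensityVsLength(x, y)
  expect_equal(r$slope, 0.6)
  expect_equal(r$intercept, 0.1)
  expect_equal(r$r_squared, 0.9)

  ## oracle equivalence with lm on random inputs
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(30); y <- 1.5 * x + rnorm(30, 0, 0.5)
    r <- regressIntensityVsLength(x, y)
    fit <- summary(lm(y ~ x))
    expect_equal(r$slope, unname(fit$coefficients[2, 1]))
    expect_equal(r$slope_se, unname(fit$coefficients[2, 2]))
    expect_equal(r$intercept, unname(fit$coefficients[1, 1]))
    expect_equal(r$r_squared, fit$r.squared)
  }
  expect_error(regressIntensityVsLength(rep(1, 5), 1:5),
               class = "larvagram_degenerate_regression")
  expect_error(regressIntensityVsLength(1:2, 1:2),
               class = "larvagram_invalid_argument")
})

test_that("intensity and length changes are negatively coupled on synthetic data", {
  rv <- runVideoFixture()
  ref <- rv$ev$referenceFrame
  segInt <- apply(rv$meas$quad, c(1, 3), mean)
  segLen <- rv$meas$lenLeft + rv$meas$lenRight
  fi <- fractionalChange(segInt, ref)
  fl <- fractionalChange(segLen, ref)
  for (seg in c("A1", "A3", "A5")) {
    r <- regressIntensityVsLength(fl[seg, ], fi[seg, ])
    expect_lt(r$slope, 0)
    expect_gt(r$r_squared, 0.8)
  }
})

test_that("turn frequency is events per phase-minute with Poisson errors", {
  ph <- data.frame(time_s = seq(0, 240 - 0.125, 0.125),
                   phase = rep(c("warming", "cooling"), each = 960))
  man0 <- data.frame(onset_s = numeric(0))
  tf0 <- turnFrequency(man0, ph)
  expect_true(all(tf0$rate_min == 0))

  man <- data.frame(onset_s = c(10, 30, 50, 70, 90, 110))  # 6 in 2 warming min
  tf <- turnFrequency(man, ph)
  w <- tf[tf$phase == "warming", ]
  expect_equal(w$rate_min, 3)
  expect_equal(w$se_min, sqrt(6) / 2)
})

test_that("first sweep size averages per phase with standard errors", {
  ph <- data.frame(time_s = 0:100, phase = rep("cooling", 101))
  one <- data.frame(onset_s = 10, first_sweep_peak_deg = 53)
  f1 <- firstSweepSize(one, ph)
  expect_equal(f1$mean_deg, 53)
  expect_true(is.na(f1$se_deg))

  two <- data.frame(onset_s = c(10, 20), first_sweep_peak_deg = c(40, 60))
  f2 <- firstSweepSize(two, ph)
  expect_equal(f2$mean_deg, 50)
  expect_equal(f2$se_deg, 10)
})

test_that("binned initiation probability uses the binomial formula exactly", {
  man <- data.frame(accepted_peak_deg = c(rep(50, 10), rep(110, 10)),
                    init_class = c(rep("tail", 10),
                                   rep(c("within_bend", "tail"), c(3, 7))))
  bp <- initiationProbabilityByAngle(man, binWidth = 60)
  expect_equal(bp$p, c(0, 0.3))
  expect_equal(bp$se, c(0, sqrt(0.3 * 0.7 / 10)))
  ## ambiguous maneuvers are excluded from n and counted separately
  man$init_class[1] <- "ambiguous"
  bp2 <- initiationProbabilityByAngle(man, binWidth = 60)
  expect_equal(bp2$n[1], 9)
  expect_equal(bp2$ambiguous[1], 1)
})

test_that("straightening-wave summaries bin by sweep size", {
  man <- data.frame(accepted_peak_deg = c(50, 55, 120),
                    waves_to_straighten = c(3, 3, 5))
  sb <- straighteningWavesByAngle(man, binWidth = 60)
  expect_equal(sb$mean_waves, c(3, 5))
  expect_equal(sb$sd_waves, c(0, 0))
})

test_that("forward speed averages run frames only", {
  tr <- data.frame(time_s = seq(0, 10, 0.125), x_mm = 0, y_mm = 0)
  expect_equal(forwardSpeed(tr)$speed_mm_s, 0)
  tr$x_mm <- 0.32 * tr$time_s
  fs <- forwardSpeed(tr)
  expect_equal(fs$speed_mm_s, 0.32, tolerance = 1e-9)
  ## frames inside maneuvers are excluded
  tr2 <- tr
  sel <- tr2$time_s >= 4 & tr2$time_s <= 6
  tr2$x_mm[sel] <- tr2$x_mm[min(which(sel))]
  tr2$x_mm[tr2$time_s > 6] <- tr2$x_mm[tr2$time_s > 6] - 0.32 * 2
  fs2 <- forwardSpeed(tr2, data.frame(onset_s = 4, offset_s = 6))
  expect_equal(fs2$speed_mm_s, 0.32, tolerance = 1e-9)
})

test_that("thermotaxis speed fits the mean population drift", {
  times <- seq(0, 600, 1)
  pos <- sapply(1:5, function(i) 0.075 * times)
  ts <- thermotaxisSpeed(pos, times)
  expect_equal(ts$speed_mm_s, 0.075, tolerance = 1e-9)
  expect_true(is.na(ts$stabilized_at_s))

  static <- matrix(2, length(times), 5)
  ts0 <- thermotaxisSpeed(static, times)
  expect_equal(ts0$speed_mm_s, 0)
  expect_equal(ts0$stabilized_at_s, 0)

  ## truncation at stabilization recovers the pre-plateau drift
  pop <- simulateThermotaxisPopulation(nAnimals = 12, duration = 1200,
                                       drift = 0.075, stabilizeAt = 600,
                                       noiseSd = 0.2, seed = 2)
  tsS <- thermotaxisSpeed(pop$positions, pop$times)
  expect_false(is.na(tsS$stabilized_at_s))
  expect_lt(abs(tsS$speed_mm_s - 0.075), max(3 * tsS$se, 0.008))
  expect_error(thermotaxisSpeed(pos[, 1, drop = FALSE], times),
               class = "larvagram_invalid_argument")
})

test_that("phase comparison tests behave under null, symmetry and power", {
  a <- rep(5, 10); b <- rep(5, 12)
  expect_equal(phaseComparisonTest(a, b)$p_value, 1)

  set.seed(9)
  x <- rnorm(50, 53, 10); y <- rnorm(50, 60, 10)
  p1 <- phaseComparisonTest(x, y)$p_value
  p2 <- phaseComparisonTest(y, x)$p_value
  expect_equal(p1, p2)

  ## power: n = 200 per group separates 53 from 60 at P < 0.005
  hits <- vapply(1:10, function(i) {
    set.seed(100 + i)
    phaseComparisonTest(rnorm(200, 53, 10), rnorm(200, 60, 10))$p_value < 0.005
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ## the permutation route agrees with Welch on a clear separation
  set.seed(3)
  pp <- phaseComparisonTest(rnorm(40, 0, 1), rnorm(40, 2, 1),
                            method = "permutation", nPerm = 400, seed = 1)
  expect_lt(pp$p_value, 0.01)
})
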