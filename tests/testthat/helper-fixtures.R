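# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## a rendered two-maneuver video (60 deg small, 110 deg large) at default
## noise, fully measured
sweepVideoFixture <- function() {
  fixture("sweepVideo", function() {
    cfg <- simulationConfig()
    body <- larvaBodyModel()
    prog <- makeSweepProgram(c(60, 110), config = cfg, body = body,
                             gap = 6, lead = 5, seed = 4)
    truth <- synthesizeKinematics(prog, body, cfg, geometry = "full")
    truth <- addPixelOrigins(truth, cfg)
    meas <- analyzeSynthetic(truth, cfg, visionConfig())
    ev <- analyzeEvents(meas, cfg)
    list(cfg = cfg, body = body, prog = prog, truth = truth,
         meas = meas, ev = ev)
  })
}

## a short noiseless forward run with quadrant intensities measured
runVideoFixture <- function() {
  fixture("runVideo", function() {
    cfg <- simulationConfig(turnRateWarming = 0, turnRateCooling = 0,
                            noiseSd = 0)
    body <- larvaBodyModel()
    ds <- simulateLarvaDataset(cfg, duration = 25, seed = 13)
    meas <- analyzeSynthetic(ds@truth, cfg, visionConfig(),
                             images = ds@images, intensity = TRUE)
    ev <- analyzeEvents(meas, cfg)
    list(cfg = cfg, body = body, ds = ds, truth = ds@truth,
         prog = ds@truth@program, meas = meas, ev = ev)
  })
}

## draw a filled disk image
diskFrame <- function(H, W, cx, cy, r, value = 1000) {
  m <- matrix(0, H, W)
  for (rr in seq_len(H)) {
    d2 <- (seq_len(W) - cx)^2 + (rr - cy)^2
    m[rr, d2 <= r^2] <- value
  }
  m
}

## filled ellipse mask
ellipseMask <- function(H, W, cx, cy, a, b) {
  m <- matrix(FALSE, H, W)
  for (rr in seq_len(H)) {
    v <- ((seq_len(W) - cx) / a)^2 + ((rr - cy) / b)^2
    m[rr, v <= 1] <- TRUE
  }
  m
}

## truth head/tail positions of a frame in vision (x, y-up) pixels
truthTips <- function(truth, f) {
  ann <- truthAnnotation(truth, f, "yup")
  list(head = c(ann$x[ann$point_id == 0], ann$y[ann$point_id == 0]),
       tail = c(ann$x[ann$point_id == 11], ann$y[ann$point_id == 11]))
}

## truth head/tail for all frames as matrices (x, y-up)
truthTipSeries <- function(truth) {
  fr <- truth@frames
  s <- truth@config@pixelScale
  H <- fr$px_h[1]
  list(
    head = cbind((fr$head_x_mm - fr$origin_x_mm) / s + 0.5,
                 H + 0.5 - (fr$origin_y_mm - fr$head_y_mm) / s),
    tail = cbind((fr$tail_x_mm - fr$origin_x_mm) / s + 0.5,
                 H + 0.5 - (fr$origin_y_mm - fr$tail_y_mm) / s))
}
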