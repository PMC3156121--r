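# Event-level track simulators: centroid trajectories without rendering.
#
# These emulate the navigation assays in which many animals are followed
# at low magnification: runs at a configured crawling speed with
# reorientation maneuvers interspersed (temporal-gradient assay), and
# populations drifting up a spatial gradient.

#' Simulate a centroid track from a behavior program
#'
#' During runs the centroid advances along the current heading at the run
#' speed (with mild multiplicative speed noise); during maneuvers it
#' pauses with positional jitter, and the heading is offset by the
#' accepted sweep angle at maneuver end.
#'
#' @param program a [BehaviorProgram-class]
#' @param speed run crawling speed (mm/s)
#' @param frameRate samples per second
#' @param speedCV coefficient of variation of the instantaneous run speed
#' @param pauseJitterSd positional jitter while paused (mm per step)
#' @param seed seed
#' @return list `track` (data.frame `time_s`, `x_mm`, `y_mm`) and
#'   `maneuvers` (data.frame `onset_s`, `offset_s`)
#' @export
simulateRunTracks <- function(program, speed = 0.32, frameRate = 8,
                              speedCV = 0.05, pauseJitterSd = 0.002,
                              seed = 1) {
  set.seed(as.integer(seed))
  nf <- floor(program@duration * frameRate)
  times <- (0:(nf - 1)) / frameRate
  ev <- program@events
  turns <- ev[ev$type == "turn", , drop = FALSE]
  x <- y <- numeric(nf)
  psi <- 0
  evIdx <- 1L
  for (f in 2:nf) {
    t <- times[f]
    while (evIdx < nrow(ev) && t >= ev$t_start[evIdx + 1]) {
      evIdx <- evIdx + 1L
      if (ev$type[evIdx] == "run" && evIdx > 1)
        psi <- psi + ev$dpsi_rad[evIdx - 1]
    }
    dt <- times[f] - times[f - 1]
    if (ev$type[evIdx] == "run") {
      v <- speed * (1 + speedCV * rnorm(1))
      x[f] <- x[f - 1] + v * dt * cos(psi)
      y[f] <- y[f - 1] + v * dt * sin(psi)
    } else {
      x[f] <- x[f - 1] + rnorm(1, 0, pauseJitterSd)
      y[f] <- y[f - 1] + rnorm(1, 0, pauseJitterSd)
    }
  }
  list(track = data.frame(time_s = times, x_mm = x, y_mm = y),
       maneuvers = data.frame(onset_s = turns$t_start, offset_s = turns$t_end))
}

#' Simulate a thermotaxing population on a spatial gradient
#'
#' Each animal's gradient-axis position drifts at the configured speed
#' with Ornstein-Uhlenbeck positional noise; after `stabilizeAt` seconds
#' the drift stops (the population has reached its preferred temperature).
#'
#' @param nAnimals number of tracks
#' @param duration track duration (s)
#' @param drift up-gradient drift speed (mm/s)
#' @param dt sampling interval (s)
#' @param noiseSd stationary sd of the positional noise (mm)
#' @param tau noise correlation time (s)
#' @param stabilizeAt time at which drift ceases (s; Inf to never)
#' @param seed seed
#' @return list `positions` (time x animals matrix, mm), `times` (s)
#' @export
simulateThermotaxisPopulation <- function(nAnimals = 20, duration = 900,
                                          drift = 0.075, dt = 1,
                                          noiseSd = 0.5, tau = 30,
                                          stabilizeAt = Inf, seed = 1) {
  if (nAnimals < 2) stopc("larvagram_invalid_argument", "need >= 2 animals")
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = dt)
  n <- length(times)
  a <- exp(-dt / tau)
  innovSd <- noiseSd * sqrt(1 - a^2)
  pos <- matrix(0, n, nAnimals)
  for (j in seq_len(nAnimals)) {
    ou <- numeric(n)
    ou[1] <- rnorm(1, 0, noiseSd)
    for (i in 2:n) ou[i] <- a * ou[i - 1] + rnorm(1, 0, innovSd)
    driftPath <- drift * pmin(times, stabilizeAt)
    pos[, j] <- driftPath + ou
  }
  list(positions = pos, times = times)
}
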