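# Behavior-level simulation: run/turn event programs.
#
# A program is a strictly ordered sequence of runs and reorientation
# maneuvers. Maneuvers contain one or more head sweeps (all but the last
# "rejected"), separated by single intervening peristalsis waves, and are
# completed by straightening waves that carry the bend towards the tail.

## fixed kinematic timing constants (s); these shape individual maneuvers
## and are deliberately not user-facing configuration
.timing <- list(
  rampT = 0.7,          # head-sweep rise time
  holdT = 0.25,         # plateau at peak bend
  runWaveLead = 0.3,    # first wave after a run starts
  interveningGap = 0.15, # rejected-peak -> intervening wave onset
  interSweepGap = 0.1,  # intervening wave end -> next sweep onset
  strStartGap = 0.2,    # accepted peak end -> first straightening wave
  strWavePeriod = 1.1,  # straightening wave spacing
  rejectDecayDur = 0.8, # unwinding of a rejected sweep's bend
  endDecayDur = 0.4,    # residual tail-bend decay at maneuver end
  endSettle = 0.1       # quiet tail of a maneuver
)

## pulse geometry helpers: pulse center travels from (init - 0.5 + h) down
## to -1 at constant speed; full body span is 13 units for h = 1.5
pulseSpeed <- function(config) {
  (11 + 0.5 + config@pulseHalfWidth + 1) / config@waveTraversal
}

pulseStart <- function(initSegment, config) {
  initSegment - 0.5 + config@pulseHalfWidth
}

pulseDuration <- function(initSegment, config) {
  (pulseStart(initSegment, config) + 1) / pulseSpeed(config)
}

#' Plan the internal timeline of one reorientation maneuver
#'
#' Lays out sweep onsets, intervening waves between rejected sweeps, and the
#' straightening-wave schedule (each wave carrying
#' `segmentsPerWaveAroundBend` segments around the bend), all relative to
#' maneuver onset.
#'
#' @param targetsDeg peak bend angle (deg) of each sweep; last is accepted
#' @param directions +1 (left) / -1 (right) per sweep
#' @param amplitudesRad calibrated actuation amplitudes (rad) per sweep
#' @param config a [SimulationConfig-class]
#' @return list with `duration`, `sweeps`, `waves`, `mode`, `dpsi_rad`,
#'   `lock_psi_s`, `decay_start_s`
#' @keywords internal
planManeuver <- function(targetsDeg, directions, amplitudesRad, config) {
  tm <- .timing
  m <- length(targetsDeg)
  spw <- config@segmentsPerWaveAroundBend
  antEdge <- segmentIndex(config@pivotAnterior) - 1
  postEdge <- segmentIndex(config@pivotPosterior)
  mode <- if (targetsDeg[m] >= 90) "bend" else "tail"
  Tv <- config@waveTraversal

  sweeps <- data.frame(sweep = seq_len(m), onset_s = NA_real_, peak_s = NA_real_,
                       direction = directions, target_deg = targetsDeg,
                       amplitude_rad = amplitudesRad,
                       accepted = seq_len(m) == m,
                       decay_start_s = NA_real_, s_at_peak = NA_real_)
  waves <- list()
  t <- 0
  S <- 0  # global bend-shift state (segments)
  for (j in seq_len(m)) {
    sweeps$onset_s[j] <- t
    peak <- t + tm$rampT + tm$holdT / 2
    sweeps$peak_s[j] <- peak
    sweeps$s_at_peak[j] <- S
    t <- t + tm$rampT + tm$holdT
    if (j < m) {
      ## rejected sweep: one intervening (full) wave; the next sweep's
      ## rise overlaps the tail of the wave (its pass through the pivot
      ## region is complete by 75% of the traversal)
      w0 <- t + tm$interveningGap
      waves[[length(waves) + 1]] <- data.frame(
        onset_s = w0, init_segment = 11, full = TRUE,
        ramp = TRUE, ramp_lo = antEdge, ramp_hi = postEdge + 1,
        spw_amount = spw)
      S <- S + spw
      t <- w0 + 0.75 * Tv
      sweeps$decay_start_s[j] <- t
    }
  }
  ## straightening waves after the accepted sweep; the small residual bend
  ## left near the rigid tail region afterwards unwinds in the end decay
  nStr <- ceiling((11 - postEdge) / spw)
  strOnset <- t + tm$strStartGap
  for (k in seq_len(nStr)) {
    eff <- (k - 1) * spw
    init <- if (mode == "tail") 11 else min(11, postEdge + eff)
    w0 <- strOnset + (k - 1) * tm$strWavePeriod
    waves[[length(waves) + 1]] <- data.frame(
      onset_s = w0, init_segment = init, full = (init == 11 && mode == "tail"),
      ramp = TRUE, ramp_lo = antEdge + eff,
      ramp_hi = min(11, postEdge + eff) + 1, spw_amount = spw)
  }
  lastWave <- waves[[length(waves)]]
  decayStart <- lastWave$onset_s + 0.6 * pulseDuration(lastWave$init_segment, config)
  duration <- decayStart + tm$endDecayDur + tm$endSettle
  sweeps$decay_start_s[m] <- decayStart
  list(duration = duration, sweeps = sweeps, waves = do.call(rbind, waves),
       mode = mode, dpsi_rad = directions[m] * amplitudesRad[m],
       lock_psi_s = sweeps$peak_s[m], decay_start_s = decayStart)
}

## numeric dT/dt of a sampled trace: boxcar-smoothed central differences
traceRate <- function(temperature, smoothSec = 1) {
  t <- temperature$time_s
  dt <- median(diff(t))
  v <- boxcarSmooth(temperature$temp_C, max(1, round(smoothSec / dt)))
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

#' Sample a run-and-turn behavior program
#'
#' Reorientation onsets are drawn as an inhomogeneous Poisson process whose
#' rate is `turnRateWarming` while the temperature derivative is positive
#' and `turnRateCooling` while it is negative (the mean of the two in the
#' neutral band). Head-sweep sizes are drawn per phase from a truncated
#' normal whose realized mean equals the configured value; each non-final
#' sweep is rejected with a logistic probability in dT/dt (cooling raises
#' the rejection probability). Onsets falling inside an ongoing maneuver
#' are deferred to its end, and every maneuver starts only after the last
#' initiated peristalsis wave has completed.
#'
#' @param config a [SimulationConfig-class]
#' @param temperature data.frame `time_s`, `temp_C` covering the simulation
#' @param seed integer seed; identical seeds give identical programs
#' @param body a [LarvaBodyModel-class] (used to calibrate sweep actuation)
#' @return a [BehaviorProgram-class]
#' @export
sampleBehavior <- function(config, temperature, seed = config@rngSeed,
                           body = larvaBodyModel()) {
  if (!all(c("time_s", "temp_C") %in% names(temperature)))
    stopc("larvagram_invalid_argument", "temperature must have time_s and temp_C")
  duration <- max(temperature$time_s)
  set.seed(as.integer(seed))
  dT <- traceRate(temperature)
  dTat <- function(tt) approx(temperature$time_s, dT, xout = tt, rule = 2)$y

  rateAt <- function(tt) {
    d <- dTat(tt)
    r <- ifelse(d > 0.001, config@turnRateWarming,
                ifelse(d < -0.001, config@turnRateCooling,
                       (config@turnRateWarming + config@turnRateCooling) / 2))
    r / 60
  }
  rmax <- max(config@turnRateWarming, config@turnRateCooling) / 60

  ## per-phase truncated-normal location parameters: solved so the mean of
  ## the realized (truncated) sweep-size distribution equals the config value
  muW <- truncnormMeanParam(config@sweepMeanWarming, config@sweepSd,
                            config@sweepMin, config@sweepMax)
  muC <- truncnormMeanParam(config@sweepMeanCooling, config@sweepSd,
                            config@sweepMin, config@sweepMax)
  thetaToAmp <- calibrateSweepAmplitude(body, config)

  events <- list(); sweeps <- list(); waves <- list()
  evId <- 0L
  runStart <- 0
  tc <- 0
  finishRun <- function(runStart, runEnd, evId) {
    ## only waves that complete before the run ends are initiated (the
    ## larva finishes its current wave before starting a head sweep)
    k <- 0; w <- list()
    repeat {
      o <- runStart + .timing$runWaveLead + k / config@waveRate
      if (o > runEnd - config@waveTraversal + 1e-9) break
      w[[k + 1]] <- data.frame(onset_s = o, init_segment = 11, full = TRUE,
                               ramp = FALSE, ramp_lo = NA_real_,
                               ramp_hi = NA_real_, spw_amount = 0,
                               event_id = evId)
      k <- k + 1
    }
    w
  }

  if (rmax > 0) {
    repeat {
      tc <- tc + rexp(1, rmax)
      if (tc >= duration) break
      if (runif(1) > rateAt(tc) / rmax) next
      ## candidates that arrive during a maneuver are deferred (not
      ## dropped), preserving the realized event rate; a short gap after
      ## the previous maneuver keeps consecutive maneuvers separable
      td <- max(tc, runStart + 1.6)
      ## defer to completion of the last initiated wave of the current run
      K <- floor((td - runStart - .timing$runWaveLead) * config@waveRate)
      onset <- if (K >= 0) {
        max(td, runStart + .timing$runWaveLead + K / config@waveRate +
              config@waveTraversal) + 0.1
      } else td + 0.1

      d0 <- dTat(onset)
      phase <- if (d0 > 0.001) "warming" else if (d0 < -0.001) "cooling" else "neutral"
      mu <- switch(phase, warming = muW, cooling = muC, (muW + muC) / 2)
      ## logistic rejection in dT/dt around the configured neutral
      ## baseline; cooling raises, warming lowers the rejection probability
      pReject <- if (config@rejectionBaseline <= 0) 0 else
        stats::plogis(stats::qlogis(config@rejectionBaseline) -
                        d0 / config@rejectionScale)
      targets <- c(); dirs <- c()
      repeat {
        targets <- c(targets, rtruncnorm(1, mu, config@sweepSd,
                                         config@sweepMin, config@sweepMax))
        dirs <- c(dirs, sample(c(-1, 1), 1))
        if (length(targets) >= 4 || runif(1) > pReject) break
      }
      amps <- vapply(targets, thetaToAmp, numeric(1))
      plan <- planManeuver(targets, dirs, amps, config)
      if (onset + plan$duration > duration) next

      ## close the run that precedes this maneuver
      evId <- evId + 1L
      events[[evId]] <- data.frame(event_id = evId, type = "run",
                                   t_start = runStart, t_end = onset,
                                   t_decision = NA_real_,
                                   mode = NA_character_, phase = NA_character_,
                                   lock_psi_s = NA_real_, decay_start_s = NA_real_,
                                   dpsi_rad = 0)
      waves <- c(waves, finishRun(runStart, onset, evId))

      evId <- evId + 1L
      events[[evId]] <- data.frame(event_id = evId, type = "turn",
                                   t_start = onset, t_end = onset + plan$duration,
                                   t_decision = tc,
                                   mode = plan$mode, phase = phase,
                                   lock_psi_s = onset + plan$lock_psi_s,
                                   decay_start_s = onset + plan$decay_start_s,
                                   dpsi_rad = plan$dpsi_rad)
      sw <- plan$sweeps
      sw$onset_s <- sw$onset_s + onset
      sw$peak_s <- sw$peak_s + onset
      sw$decay_start_s <- sw$decay_start_s + onset
      sw$event_id <- evId
      sweeps[[length(sweeps) + 1]] <- sw
      mw <- plan$waves
      mw$onset_s <- mw$onset_s + onset
      mw$event_id <- evId
      waves[[length(waves) + 1]] <- mw

      runStart <- onset + plan$duration
    }
  }
  ## trailing run
  evId <- evId + 1L
  events[[evId]] <- data.frame(event_id = evId, type = "run",
                               t_start = runStart, t_end = duration,
                               t_decision = NA_real_,
                               mode = NA_character_, phase = NA_character_,
                               lock_psi_s = NA_real_, decay_start_s = NA_real_,
                               dpsi_rad = 0)
  waves <- c(waves, finishRun(runStart, duration, evId))

  events <- do.call(rbind, events)
  sweeps <- if (length(sweeps)) do.call(rbind, sweeps) else
    data.frame(event_id = integer(0), sweep = integer(0), onset_s = numeric(0),
               peak_s = numeric(0), direction = numeric(0),
               target_deg = numeric(0), amplitude_rad = numeric(0),
               accepted = logical(0), decay_start_s = numeric(0),
               s_at_peak = numeric(0))
  waves <- if (length(waves)) do.call(rbind, waves) else
    data.frame(onset_s = numeric(0), init_segment = numeric(0),
               full = logical(0), ramp = logical(0), ramp_lo = numeric(0),
               ramp_hi = numeric(0), spw_amount = numeric(0),
               event_id = integer(0))
  waves <- waves[order(waves$onset_s), , drop = FALSE]
  waves$wave_id <- seq_len(nrow(waves))
  ## per-wave forward displacement (body lengths); partial waves carry none
  waves$disp_bl <- ifelse(waves$full,
                          pmax(0.02, rnorm(nrow(waves), config@displacementPerWave,
                                           config@displacementSd)), 0)
  rownames(waves) <- NULL; rownames(events) <- NULL
  if (nrow(sweeps)) rownames(sweeps) <- NULL
  new("BehaviorProgram", events = events, sweeps = sweeps, waves = waves,
      duration = duration, seed = as.integer(seed))
}

#' Build a program of prescribed reorientation maneuvers
#'
#' Deterministic scaffolding for controlled experiments: maneuvers with the
#' given sweep sizes are separated by runs of length `gap`.
#'
#' @param targetsDeg one accepted sweep size (deg) per maneuver
#' @param directions +1/-1 per maneuver (default alternating)
#' @param config a [SimulationConfig-class]
#' @param body a [LarvaBodyModel-class]
#' @param gap run duration between maneuvers (s)
#' @param lead initial run duration (s)
#' @param seed seed for per-wave displacement draws
#' @return a [BehaviorProgram-class]
#' @export
makeSweepProgram <- function(targetsDeg, directions = NULL,
                             config = simulationConfig(),
                             body = larvaBodyModel(), gap = 8, lead = 8,
                             seed = config@rngSeed) {
  set.seed(as.integer(seed))
  if (is.null(directions)) directions <- rep(c(1, -1), length.out = length(targetsDeg))
  thetaToAmp <- calibrateSweepAmplitude(body, config)
  events <- list(); sweeps <- list(); waves <- list()
  evId <- 0L; runStart <- 0
  addRunWaves <- function(runStart, runEnd, evId) {
    k <- 0; w <- list()
    repeat {
      o <- runStart + .timing$runWaveLead + k / config@waveRate
      if (o > runEnd - config@waveTraversal + 1e-9) break
      w[[k + 1]] <- data.frame(onset_s = o, init_segment = 11, full = TRUE,
                               ramp = FALSE, ramp_lo = NA_real_,
                               ramp_hi = NA_real_, spw_amount = 0,
                               event_id = evId)
      k <- k + 1
    }
    w
  }
  for (i in seq_along(targetsDeg)) {
    ## runs end at a wave-completion boundary so sweeps follow completed waves
    K <- floor((gap - .timing$runWaveLead) * config@waveRate)
    onset <- if (K >= 0)
      runStart + .timing$runWaveLead + K / config@waveRate + config@waveTraversal + 0.1
    else runStart + gap
    if (i == 1) onset <- max(onset, runStart + lead)
    amp <- thetaToAmp(targetsDeg[i])
    plan <- planManeuver(targetsDeg[i], directions[i], amp, config)
    evId <- evId + 1L
    events[[evId]] <- data.frame(event_id = evId, type = "run",
                                 t_start = runStart, t_end = onset,
                                 t_decision = NA_real_,
                                 mode = NA_character_, phase = NA_character_,
                                 lock_psi_s = NA_real_, decay_start_s = NA_real_,
                                 dpsi_rad = 0)
    waves <- c(waves, addRunWaves(runStart, onset, evId))
    evId <- evId + 1L
    events[[evId]] <- data.frame(event_id = evId, type = "turn",
                                 t_start = onset, t_end = onset + plan$duration,
                                 t_decision = onset,
                                 mode = plan$mode, phase = "neutral",
                                 lock_psi_s = onset + plan$lock_psi_s,
                                 decay_start_s = onset + plan$decay_start_s,
                                 dpsi_rad = plan$dpsi_rad)
    sw <- plan$sweeps
    sw$onset_s <- sw$onset_s + onset; sw$peak_s <- sw$peak_s + onset
    sw$decay_start_s <- sw$decay_start_s + onset
    sw$event_id <- evId
    sweeps[[length(sweeps) + 1]] <- sw
    mw <- plan$waves
    mw$onset_s <- mw$onset_s + onset; mw$event_id <- evId
    waves[[length(waves) + 1]] <- mw
    runStart <- onset + plan$duration
  }
  duration <- runStart + gap
  evId <- evId + 1L
  events[[evId]] <- data.frame(event_id = evId, type = "run",
                               t_start = runStart, t_end = duration,
                               t_decision = NA_real_,
                               mode = NA_character_, phase = NA_character_,
                               lock_psi_s = NA_real_, decay_start_s = NA_real_,
                               dpsi_rad = 0)
  waves <- c(waves, addRunWaves(runStart, duration, evId))
  events <- do.call(rbind, events)
  sweeps <- do.call(rbind, sweeps)
  waves <- do.call(rbind, waves)
  waves <- waves[order(waves$onset_s), , drop = FALSE]
  waves$wave_id <- seq_len(nrow(waves))
  waves$disp_bl <- ifelse(waves$full,
                          pmax(0.02, rnorm(nrow(waves), config@displacementPerWave,
                                           config@displacementSd)), 0)
  rownames(waves) <- NULL; rownames(events) <- NULL; rownames(sweeps) <- NULL
  new("BehaviorProgram", events = events, sweeps = sweeps, waves = waves,
      duration = duration, seed = as.integer(seed))
}
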