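# S4 classes for the simulation and analysis containers.

#' Sinusoidal temperature waveform
#'
#' Describes the temporal temperature stimulus
#' \eqn{T(t) = \mathrm{offset} + \mathrm{amplitude}\,\sin(2\pi t/\mathrm{period} + \mathrm{phase})}
#' applied to a crawling larva. The two stimulus regimes used throughout are
#' a 1 degC amplitude / 2 min period sine at 15 degC offset (imaging rig)
#' and a ~1 degC amplitude / 6 min period sine at ~20 degC offset
#' (navigation assays).
#'
#' @slot offset baseline temperature (degC)
#' @slot amplitude half peak-to-peak amplitude (degC), non-negative
#' @slot period oscillation period (s), positive
#' @slot phase phase at t = 0 (radians)
#' @export
setClass("TemperatureWaveform",
  representation(offset = "numeric", amplitude = "numeric",
                 period = "numeric", phase = "numeric"),
  validity = function(object) {
    if (object@amplitude < 0) return("amplitude must be >= 0")
    if (object@period <= 0) return("period must be > 0")
    TRUE
  }
)

#' @param offset,amplitude,period,phase see slots
#' @return a `TemperatureWaveform`
#' @rdname TemperatureWaveform-class
#' @export
temperatureWaveform <- function(offset = 15, amplitude = 1, period = 120,
                                phase = 0) {
  new("TemperatureWaveform", offset = offset, amplitude = amplitude,
      period = period, phase = phase)
}

#' Larva body model
#'
#' Geometry of the 11-segment body (three thoracic T1-T3, eight abdominal
#' A1-A8). Segment rest lengths are equal shares of the body length; the
#' width profile tapers towards both tips and towards the anterior, as in
#' second-instar larvae.
#'
#' @slot segmentNames ordered labels, head to tail
#' @slot restLengths per-segment rest length (mm)
#' @slot restWidths per-segment full width at the segment center (mm)
#' @export
setClass("LarvaBodyModel",
  representation(segmentNames = "character", restLengths = "numeric",
                 restWidths = "numeric"),
  validity = function(object) {
    if (length(object@segmentNames) != 11) return("exactly 11 segments required")
    if (length(object@restLengths) != 11 || any(object@restLengths <= 0))
      return("11 positive rest lengths required")
    if (length(object@restWidths) != 11 || any(object@restWidths <= 0))
      return("11 positive rest widths required")
    TRUE
  }
)

#' Half-width of the body envelope at body coordinate x
#'
#' Body coordinate runs 0 (head tip) to 11 (tail tip); segment i spans
#' [i-1, i]. Both tips are pointed (width -> 0) and the anterior body is
#' narrower than the mid-abdomen.
#' @noRd
bodyHalfWidth <- function(x, maxWidth = 0.35, segLen = 2 / 11) {
  taper <- 0.45 + 0.55 * pmin(1, x / 6)
  wb <- 0.5 * maxWidth * taper
  ## rounded tip caps: parabolic profiles with apex radii ~20%/30% of the
  ## body width so both tips are blunt enough to render and to stand out
  ## as curvature maxima
  sh <- pmax(x, 0) * segLen
  st <- pmax(11 - x, 0) * segLen
  rh <- 0.20 * maxWidth
  rt <- 0.30 * maxWidth
  pmin(wb, sqrt(2 * rh * sh), sqrt(2 * rt * st))
}

#' @param bodyLength total body length (mm)
#' @param maxWidth maximum full body width (mm)
#' @return a `LarvaBodyModel`
#' @rdname LarvaBodyModel-class
#' @export
larvaBodyModel <- function(bodyLength = 2, maxWidth = 0.35) {
  centers <- seq_len(11) - 0.5
  new("LarvaBodyModel",
      segmentNames = SEGMENT_NAMES,
      restLengths = rep(bodyLength / 11, 11),
      restWidths = 2 * bodyHalfWidth(centers, maxWidth))
}

#' Total body length of a body model
#' @param body a `LarvaBodyModel`
#' @return length in mm
#' @export
bodyLength <- function(body) sum(body@restLengths)

#' Simulation configuration
#'
#' All tunable parameters of the synthetic larva generator. Defaults follow
#' the transgenic (Mhc-GFP) navigation statistics; use
#' [simulationConfig()] with `strain = "canton_s"` for the wild-type rates.
#'
#' @slot frameRate acquisition rate (Hz)
#' @slot pixelScale mm per pixel
#' @slot noiseSd additive Gaussian camera noise, as a fraction of the
#'   calibration (rest-state) intensity; 0 disables noise
#' @slot calibration rest-state segment mean intensity (16-bit counts)
#' @slot waveRate peristalsis waves per second during runs
#' @slot waveTraversal time (s) for one contraction pulse to travel the
#'   full body
#' @slot displacementPerWave forward displacement per completed wave
#'   (body lengths)
#' @slot displacementSd per-wave displacement variability (body lengths)
#' @slot contractionAmplitude fractional shortening of a segment at the
#'   pulse peak
#' @slot pulseHalfWidth pulse half width (segments)
#' @slot pivotAnterior,pivotCenter,pivotPosterior segment labels delimiting
#'   the asymmetric-contraction pivot and its peak
#' @slot segmentsPerWaveAroundBend segments carried around the bend per
#'   straightening wave
#' @slot straightenedThreshold bend angle (deg) below which the generator
#'   considers the body straight
#' @slot turnRateWarming,turnRateCooling reorientation rates (min^-1) by
#'   thermal phase
#' @slot sweepMeanWarming,sweepMeanCooling mean first-head-sweep size (deg)
#'   by phase (mean of the realized, truncated distribution)
#' @slot sweepSd head-sweep size spread (deg)
#' @slot sweepMin,sweepMax truncation bounds for sweep sizes (deg)
#' @slot rejectionBaseline head-sweep rejection probability at dT/dt = 0
#'   (0 disables rejection entirely, giving single-sweep maneuvers)
#' @slot rejectionScale scale (degC/s) of the logistic rejection model in
#'   dT/dt; cooling raises, warming lowers the rejection probability
#' @slot driftSpeed up-gradient population drift (mm/s) for spatial-gradient
#'   track simulations
#' @slot rngSeed integer seed recorded with the dataset
#' @export
setClass("SimulationConfig",
  representation(
    frameRate = "numeric", pixelScale = "numeric", noiseSd = "numeric",
    calibration = "numeric", waveRate = "numeric", waveTraversal = "numeric",
    displacementPerWave = "numeric", displacementSd = "numeric",
    contractionAmplitude = "numeric", pulseHalfWidth = "numeric",
    pivotAnterior = "character", pivotCenter = "character",
    pivotPosterior = "character", segmentsPerWaveAroundBend = "numeric",
    straightenedThreshold = "numeric",
    turnRateWarming = "numeric", turnRateCooling = "numeric",
    sweepMeanWarming = "numeric", sweepMeanCooling = "numeric",
    sweepSd = "numeric", sweepMin = "numeric", sweepMax = "numeric",
    rejectionBaseline = "numeric", rejectionScale = "numeric",
    driftSpeed = "numeric", rngSeed = "integer"
  ),
  validity = function(object) {
    if (object@frameRate <= 0) return("frameRate must be > 0")
    if (object@displacementPerWave <= 0 || object@displacementPerWave >= 1)
      return("displacementPerWave must be in (0, 1)")
    labs <- c(object@pivotAnterior, object@pivotCenter, object@pivotPosterior)
    if (!all(labs %in% SEGMENT_NAMES)) return("pivot labels must be segment names")
    i <- match(labs, SEGMENT_NAMES)
    if (!(i[1] <= i[2] && i[2] <= i[3])) return("pivot labels out of order")
    if (object@contractionAmplitude <= 0 || object@contractionAmplitude >= 1)
      return("contractionAmplitude must be in (0, 1)")
    TRUE
  }
)

#' @param strain `"mhc_gfp"` (transgenic defaults) or `"canton_s"`
#'   (wild-type navigation rates)
#' @param ... named overrides for any slot
#' @return a `SimulationConfig`
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(strain = c("mhc_gfp", "canton_s"), ...) {
  strain <- match.arg(strain)
  defaults <- list(
    frameRate = 8, pixelScale = 0.01, noiseSd = 0.02, calibration = 12000,
    waveRate = 0.65, waveTraversal = 2.0,
    displacementPerWave = 0.13, displacementSd = 0.013,
    contractionAmplitude = 0.15, pulseHalfWidth = 1.5,
    pivotAnterior = "T3", pivotCenter = "A1", pivotPosterior = "A3",
    segmentsPerWaveAroundBend = 2, straightenedThreshold = 20,
    turnRateWarming = 2.6, turnRateCooling = 3.8,
    sweepMeanWarming = 53, sweepMeanCooling = 60,
    sweepSd = 10, sweepMin = 45, sweepMax = 130,
    rejectionBaseline = 0.3, rejectionScale = 0.025,
    driftSpeed = 0.055, rngSeed = 1L
  )
  if (strain == "canton_s") {
    defaults$turnRateWarming <- 3.2
    defaults$sweepMeanCooling <- 57
    defaults$driftSpeed <- 0.075
  }
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stopc("larvagram_invalid_argument",
                         paste("unknown config fields:", paste(bad, collapse = ", ")))
  defaults[names(overrides)] <- overrides
  defaults$rngSeed <- as.integer(defaults$rngSeed)
  do.call(new, c(list("SimulationConfig"), defaults))
}

#' Vision (image-analysis) configuration
#'
#' @slot thresholdMethod `"otsu"` or `"fixed"`
#' @slot fixedThreshold intensity threshold when `thresholdMethod = "fixed"`
#' @slot morphRadius disk radius (px) for the erosion/dilation smoothing of
#'   the binary image
#' @slot boundarySmoothFrac Gaussian smoothing width for the outline, as a
#'   fraction of boundary length
#' @slot curvatureWindowFrac sliding-window width for boundary curvature, as
#'   a fraction of total boundary length
#' @slot centerlinePoints number of centerline points
#' @slot sweepThreshold bend angle (deg) flagging head-sweep onset
#' @slot sweepRelease bend angle (deg) releasing a flagged sweep
#' @slot minSweepFrames shortest accepted sweep event (frames); debounces
#'   single-frame tracking glitches
#' @slot minComponentArea smallest acceptable component area (px^2)
#' @export
setClass("VisionConfig",
  representation(
    thresholdMethod = "character", fixedThreshold = "numeric",
    morphRadius = "numeric", boundarySmoothFrac = "numeric",
    curvatureWindowFrac = "numeric", centerlinePoints = "numeric",
    sweepThreshold = "numeric", sweepRelease = "numeric",
    minSweepFrames = "numeric", minComponentArea = "numeric"
  ),
  validity = function(object) {
    if (!object@thresholdMethod %in% c("otsu", "fixed"))
      return("thresholdMethod must be 'otsu' or 'fixed'")
    if (!(object@boundarySmoothFrac >= 0 &&
          object@boundarySmoothFrac < object@curvatureWindowFrac &&
          object@curvatureWindowFrac < 0.5))
      return("need 0 <= boundarySmoothFrac < curvatureWindowFrac < 0.5")
    if (object@sweepRelease >= object@sweepThreshold)
      return("sweepRelease must be below sweepThreshold")
    TRUE
  }
)

#' @param ... named overrides for any slot
#' @return a `VisionConfig`
#' @rdname VisionConfig-class
#' @export
visionConfig <- function(...) {
  defaults <- list(
    thresholdMethod = "otsu", fixedThreshold = 0.1, morphRadius = 2,
    boundarySmoothFrac = 0.005, curvatureWindowFrac = 0.20,
    centerlinePoints = 51, sweepThreshold = 40, sweepRelease = 20,
    minSweepFrames = 3, minComponentArea = 50
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stopc("larvagram_invalid_argument",
                         paste("unknown config fields:", paste(bad, collapse = ", ")))
  defaults[names(overrides)] <- overrides
  do.call(new, c(list("VisionConfig"), defaults))
}

#' Behavior program: runs, reorientation maneuvers, and wave schedule
#'
#' @slot events data.frame with one row per run or turn (`event_id`,
#'   `type`, `t_start`, `t_end`, and for turns the straightening `mode` and
#'   phase at onset)
#' @slot sweeps data.frame of head sweeps (`event_id`, `sweep`, `onset_s`,
#'   `peak_s`, `direction`, `target_deg`, `amplitude_rad`, `accepted`)
#' @slot waves data.frame of scheduled peristalsis waves (`wave_id`,
#'   `onset_s`, `init_segment`, `full`, `disp_bl`, `event_id`,
#'   `shift_before`, `ramp_lo`, `ramp_hi`)
#' @slot duration total simulated time (s)
#' @slot seed integer seed used to sample the program
#' @export
setClass("BehaviorProgram",
  representation(events = "data.frame", sweeps = "data.frame",
                 waves = "data.frame", duration = "numeric", seed = "integer"),
  validity = function(object) {
    ev <- object@events
    if (nrow(ev) > 1) {
      o <- order(ev$t_start)
      if (any(ev$t_end[o][-nrow(ev)] > ev$t_start[o][-1] + 1e-9))
        return("events overlap in time")
    }
    sw <- object@sweeps
    if (nrow(sw)) {
      if (any(sw$target_deg <= 0)) return("sweep amplitudes must be > 0")
      last <- !duplicated(sw$event_id, fromLast = TRUE)
      if (!all(sw$accepted[last])) return("last sweep of each maneuver must be accepted")
    }
    TRUE
  }
)

#' Ground truth for a synthetic video
#'
#' Per-frame true geometry and per-segment metrics produced by
#' [synthesizeKinematics()]. Arrays are indexed `[sample, xy, frame]` for
#' polylines and `[segment, frame]` for segment metrics. Coordinates are mm
#' in a fixed y-up world frame; `frames` carries the per-frame pixel origin
#' used by the renderer.
#'
#' @slot frames per-frame scalar table (time, true bend angle, wave id,
#'   event label, head/tail/centroid positions, pixel origin)
#' @slot spine,left,right dense body polylines `[sample, 2, frame]`
#' @slot segLenLeft,segLenRight per-segment side arc lengths (mm)
#' @slot segArea per-segment area (mm^2)
#' @slot quadArea,quadIntensity `[segment, quadrant, frame]` quadrant areas
#'   (mm^2) and rendered mean intensities (counts); quadrant order AL, AR,
#'   PL, PR
#' @slot body,config,program the inputs that generated the truth
#' @export
setClass("GroundTruth",
  representation(frames = "data.frame", spine = "array", left = "array",
                 right = "array", segLenLeft = "matrix", segLenRight = "matrix",
                 segArea = "matrix", quadArea = "array", quadIntensity = "array",
                 body = "LarvaBodyModel", config = "SimulationConfig",
                 program = "BehaviorProgram"))

#' Synthetic larva dataset
#'
#' Bundles rendered frames, ground truth, temperature trace and generating
#' configuration.
#'
#' @slot truth a [GroundTruth-class]
#' @slot images integer array `[row, col, frame]` of 16-bit counts (may have
#'   zero frames when rendering was skipped)
#' @slot temperature data.frame `time_s`, `temp_C`
#' @export
setClass("LarvaDataset",
  representation(truth = "GroundTruth", images = "array",
                 temperature = "data.frame"))

#' Body outline of one frame
#'
#' Closed boundary polygon (counterclockwise in the internal y-up frame)
#' with optional head/tail vertex indices.
#'
#' @slot vertices n x 2 matrix of (x, y-up) pixel coordinates
#' @slot headIndex,tailIndex vertex indices (NA until located)
#' @slot frameId frame number
#' @export
setClass("BodyOutline",
  representation(vertices = "matrix", headIndex = "numeric",
                 tailIndex = "numeric", frameId = "numeric"),
  validity = function(object) {
    if (nrow(object@vertices) < 3) return("outline needs >= 3 vertices")
    if (!is.na(object@headIndex) && !is.na(object@tailIndex) &&
        object@headIndex == object@tailIndex)
      return("head and tail indices must differ")
    TRUE
  }
)

#' Body centerline of one frame
#'
#' Ordered head-to-tail midline points.
#' @slot points n x 2 matrix (x, y-up), head first
#' @export
setClass("Centerline", representation(points = "matrix"),
  validity = function(object) {
    if (nrow(object@points) < 4) return("centerline needs >= 4 points")
    TRUE
  }
)

#' Kymograph of a contraction metric
#'
#' A (body row) x (frame) matrix of one metric with its reference frame.
#'
#' @slot data numeric matrix; rownames are segment labels or signed
#'   boundary coordinates
#' @slot metric one of `"fractional_length"`, `"fractional_intensity"`,
#'   `"asymmetry"`, `"length"`, `"intensity"`
#' @slot referenceFrame frame id of the reference image (NA for asymmetry)
#' @slot frameRate frames per second
#' @export
setClass("Kymograph",
  representation(data = "matrix", metric = "character",
                 referenceFrame = "numeric", frameRate = "numeric"),
  validity = function(object) {
    if (is.null(rownames(object@data))) return("kymograph rows must be named")
    TRUE
  }
)

#' @describeIn Kymograph-class matrix accessor
#' @param kymo a `Kymograph`
#' @export
kymoData <- function(kymo) kymo@data

#' @describeIn Kymograph-class metric tag accessor
#' @export
kymoMetric <- function(kymo) kymo@metric

#' @describeIn GroundTruth-class number of frames
#' @param truth a `GroundTruth`
#' @export
nFrames <- function(truth) nrow(truth@frames)

setMethod("show", "TemperatureWaveform", function(object) {
  cat(sprintf("TemperatureWaveform: %.3g degC offset, %.3g degC amplitude, %.4g s period\n",
              object@offset, object@amplitude, object@period))
})

setMethod("show", "LarvaBodyModel", function(object) {
  cat(sprintf("LarvaBodyModel: 11 segments (%s...%s), length %.3g mm, max width %.3g mm\n",
              object@segmentNames[1], object@segmentNames[11],
              sum(object@restLengths), max(object@restWidths)))
})

setMethod("show", "BehaviorProgram", function(object) {
  nturn <- sum(object@events$type == "turn")
  cat(sprintf("BehaviorProgram: %.4g s, %d maneuvers, %d sweeps, %d waves (seed %d)\n",
              object@duration, nturn, nrow(object@sweeps), nrow(object@waves),
              object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frames at %g Hz, body %.3g mm\n",
              nrow(object@frames), object@config@frameRate,
              sum(object@body@restLengths)))
})

setMethod("show", "LarvaDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf("LarvaDataset: %d frames, %s px, %d temperature samples\n",
              nrow(object@truth@frames),
              if (length(d) == 3 && d[3] > 0) paste0(d[1], "x", d[2]) else "unrendered",
              nrow(object@temperature)))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph [%s]: %d rows x %d frames (reference frame %s)\n",
              object@metric, nrow(object@data), ncol(object@data),
              format(object@referenceFrame)))
})

setMethod("show", "BodyOutline", function(object) {
  cat(sprintf("BodyOutline: %d vertices, head %s, tail %s (frame %s)\n",
              nrow(object@vertices), format(object@headIndex),
              format(object@tailIndex), format(object@frameId)))
})
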