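# Event detection: peristalsis waves, asymmetric-contraction regions,
# wave-initiation classification, and reorientation-maneuver assembly.

#' Default event-detection parameters
#'
#' @param ampThreshold minimum fractional-change amplitude of a segment
#'   contraction peak
#' @param lagRange allowed inter-segment peak lag (frames) for chaining
#' @param minChain minimum number of segments in a wave
#' @param allowSkip tolerated missed segments within a chain
#' @param asymThreshold asymmetry-index magnitude delimiting the region of
#'   asymmetric contraction
#' @param straightThreshold bend angle (deg) below which the body counts as
#'   straight
#' @param sustainSec time (s) the straight condition must hold
#' @return list of parameters
#' @export
eventConfig <- function(ampThreshold = 0.05, lagRange = c(1, 16),
                        minChain = 4, allowSkip = 1, asymThreshold = 0.05,
                        straightThreshold = 20, sustainSec = 1) {
  list(ampThreshold = ampThreshold, lagRange = lagRange, minChain = minChain,
       allowSkip = allowSkip, asymThreshold = asymThreshold,
       straightThreshold = straightThreshold, sustainSec = sustainSec)
}

#' Detect peristalsis waves in a contraction kymograph
#'
#' Finds per-segment local maxima of the contraction measure (fractional
#' intensity increases, or fractional length decreases) above the
#' amplitude threshold, and chains peaks into waves when they progress
#' head-ward with inter-segment lags inside `lagRange`.
#'
#' @param kymo a [Kymograph-class] with one row per segment (T1..A8) and
#'   metric `"fractional_intensity"` or `"fractional_length"`
#' @param config list from [eventConfig()]
#' @return list with `waves` (data.frame: wave_id, onset_frame,
#'   offset_frame, init_segment, term_segment, n_segments, speed_seg_s)
#'   and `peaks` (data.frame: wave_id, segment, frame); both empty when
#'   nothing is detected
#' @export
detectWaves <- function(kymo, config = eventConfig()) {
  if (!kymo@metric %in% c("fractional_intensity", "fractional_length"))
    stopc("larvagram_invalid_argument",
          "wave detection needs a fractional contraction kymograph")
  M <- kymo@data
  if (!all(SEGMENT_NAMES %in% rownames(M)))
    stopc("larvagram_invalid_argument", "kymograph must have one row per segment")
  M <- M[SEGMENT_NAMES, , drop = FALSE]
  if (kymo@metric == "fractional_length") M <- -M
  M[is.na(M)] <- -Inf
  peaks <- list()
  for (i in seq_len(11)) {
    pk <- localMaxima(M[i, ])
    pk <- pk[M[i, pk] >= config$ampThreshold]
    if (length(pk)) peaks[[length(peaks) + 1]] <-
      data.frame(segment = i, frame = pk, value = M[i, pk])
  }
  emptyW <- list(
    waves = data.frame(wave_id = integer(0), onset_frame = integer(0),
                       offset_frame = integer(0), init_segment = character(0),
                       term_segment = character(0), n_segments = integer(0),
                       speed_seg_s = numeric(0)),
    peaks = data.frame(wave_id = integer(0), segment = character(0),
                       frame = integer(0)))
  if (!length(peaks)) return(emptyW)
  peaks <- do.call(rbind, peaks)

  chains <- list()  # each: segs (descending), frames (ascending)
  for (s in 11:1) {
    pf <- sort(peaks$frame[peaks$segment == s])
    for (f in pf) {
      best <- 0; bestFrame <- -Inf
      for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        gap <- ch$lastSeg - s
        if (gap < 1 || gap > 1 + config$allowSkip) next
        lag <- f - ch$lastFrame
        if (lag < config$lagRange[1] * gap || lag > config$lagRange[2] * gap) next
        if (ch$extendedAt == s) next
        if (ch$lastFrame > bestFrame) { best <- ci; bestFrame <- ch$lastFrame }
      }
      if (best > 0) {
        chains[[best]]$segs <- c(chains[[best]]$segs, s)
        chains[[best]]$frames <- c(chains[[best]]$frames, f)
        chains[[best]]$lastSeg <- s
        chains[[best]]$lastFrame <- f
        chains[[best]]$extendedAt <- s
      } else {
        chains[[length(chains) + 1]] <- list(segs = s, frames = f,
                                             lastSeg = s, lastFrame = f,
                                             extendedAt = s)
      }
    }
  }
  chains <- Filter(function(ch) length(ch$segs) >= config$minChain, chains)
  if (!length(chains)) return(emptyW)
  ord <- order(vapply(chains, function(ch) ch$frames[1], numeric(1)))
  chains <- chains[ord]
  waves <- do.call(rbind, lapply(seq_along(chains), function(k) {
    ch <- chains[[k]]
    data.frame(wave_id = k, onset_frame = ch$frames[1],
               offset_frame = ch$frames[length(ch$frames)],
               init_segment = SEGMENT_NAMES[ch$segs[1]],
               term_segment = SEGMENT_NAMES[ch$segs[length(ch$segs)]],
               n_segments = length(ch$segs),
               speed_seg_s = (ch$segs[1] - ch$segs[length(ch$segs)]) /
                 ((ch$frames[length(ch$frames)] - ch$frames[1]) / kymo@frameRate))
  }))
  pk <- do.call(rbind, lapply(seq_along(chains), function(k) {
    ch <- chains[[k]]
    data.frame(wave_id = k, segment = SEGMENT_NAMES[ch$segs], frame = ch$frames)
  }))
  list(waves = waves, peaks = pk)
}

#' Forward displacement of one wave
#'
#' Tail-point displacement between the wave's first and last contraction
#' peaks, projected on the mean body axis over that interval, in body
#' lengths.
#'
#' @param track data.frame with per-frame `head_x`, `head_y`, `tail_x`,
#'   `tail_y` in a fixed (stage-corrected) frame
#' @param wave one row of the `waves` table from [detectWaves()]
#' @param bodyLength body length in the same units as the track
#' @return displacement in body lengths (signed; forward positive)
#' @export
waveDisplacement <- function(track, wave, bodyLength) {
  f0 <- wave$onset_frame; f1 <- wave$offset_frame
  if (f0 < 1 || f1 > nrow(track) ||
      anyNA(track[c(f0, f1), c("tail_x", "tail_y")]))
    stopc("larvagram_gap", "track does not cover the wave interval")
  sel <- f0:f1
  ax <- mean(track$head_x[sel] - track$tail_x[sel], na.rm = TRUE)
  ay <- mean(track$head_y[sel] - track$tail_y[sel], na.rm = TRUE)
  nrm <- sqrt(ax^2 + ay^2)
  if (nrm == 0) stopc("larvagram_degenerate", "zero-length body axis")
  dx <- track$tail_x[f1] - track$tail_x[f0]
  dy <- track$tail_y[f1] - track$tail_y[f0]
  (dx * ax + dy * ay) / nrm / bodyLength
}

#' Measure the region of asymmetric contraction of a head sweep
#'
#' At the frame of peak bend angle, the maximal contiguous run of segments
#' whose asymmetry index magnitude reaches `asymThreshold`, containing the
#' peak segment.
#'
#' @param asymKymo a [Kymograph-class] with metric `"asymmetry"`, one row
#'   per segment
#' @param sweep one row of the sweep table from [detectHeadSweeps()]
#' @param config list from [eventConfig()]
#' @return list `anterior`, `posterior`, `peak` (segment labels),
#'   `anterior_idx`, `posterior_idx`, `peak_idx`, `frame`
#' @export
measureAsymmetricRegion <- function(asymKymo, sweep, config = eventConfig()) {
  if (asymKymo@metric != "asymmetry")
    stopc("larvagram_invalid_argument", "need an asymmetry kymograph")
  f <- sweep$peak_frame
  if (f < 1 || f > ncol(asymKymo@data))
    stopc("larvagram_invalid_argument", "sweep peak outside kymograph")
  a <- asymKymo@data[SEGMENT_NAMES, f]
  hot <- abs(a) >= config$asymThreshold
  if (!any(hot)) stopc("larvagram_no_region", "no segment above the asymmetry threshold")
  pk <- which.max(abs(a))
  lo <- pk; while (lo > 1 && hot[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < 11 && hot[hi + 1]) hi <- hi + 1
  list(anterior = SEGMENT_NAMES[lo], posterior = SEGMENT_NAMES[hi],
       peak = SEGMENT_NAMES[pk], anterior_idx = lo, posterior_idx = hi,
       peak_idx = pk, frame = f)
}

#' Classify where a post-sweep wave was initiated
#'
#' @param wave one row of the waves table
#' @param region result of [measureAsymmetricRegion()]
#' @return `"within_bend"`, `"tail"` or `"ambiguous"`
#' @export
classifyWaveInitiation <- function(wave, region) {
  i <- segmentIndex(wave$init_segment)
  if (i >= region$anterior_idx && i <= region$posterior_idx) "within_bend"
  else if (i >= 10) "tail"
  else "ambiguous"
}

#' Assemble head sweeps and waves into reorientation maneuvers
#'
#' Consecutive sweeps merge into one maneuver when the body never
#' satisfies the straightened criterion (|theta| below
#' `straightThreshold`, sustained for `sustainSec`) between them; the last
#' sweep of each maneuver is the accepted one. Waves are counted from the
#' accepted sweep's peak until the straightened criterion first holds.
#'
#' @param sweeps data.frame from [detectHeadSweeps()]
#' @param waves waves table from [detectWaves()]
#' @param theta per-frame bend-angle series (deg)
#' @param frameRate frames per second
#' @param config list from [eventConfig()]
#' @param asymKymo optional asymmetry [Kymograph-class] for region
#'   measurement and initiation-site classification
#' @param phases optional data.frame `time_s`, `phase` (from
#'   [classifyPhases()]) to label each maneuver's thermal phase at onset
#' @return data.frame, one row per maneuver
#' @export
assembleManeuvers <- function(sweeps, waves, theta, frameRate = 8,
                              config = eventConfig(), asymKymo = NULL,
                              phases = NULL) {
  if (!nrow(sweeps))
    return(data.frame(maneuver_id = integer(0)))
  o <- order(sweeps$onset_frame)
  sweeps <- sweeps[o, , drop = FALSE]
  if (any(diff(sweeps$onset_frame) <= 0) ||
      any(sweeps$offset_frame[-nrow(sweeps)] > sweeps$onset_frame[-1]))
    stopc("larvagram_malformed_events", "overlapping head sweeps")

  sustainN <- max(1L, round(config$sustainSec * frameRate))
  straight <- !is.na(theta) & abs(theta) < config$straightThreshold
  r <- rle(straight)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  okRun <- r$values & r$lengths >= sustainN
  sustainedStart <- starts[okRun]
  sustainedFrames <- unlist(mapply(function(a, b) a:b, starts[okRun], ends[okRun],
                                   SIMPLIFY = FALSE))
  if (is.null(sustainedFrames)) sustainedFrames <- integer(0)

  n <- nrow(sweeps)
  grp <- integer(n); grp[1] <- 1
  if (n > 1) for (i in 2:n) {
    between <- (sweeps$offset_frame[i - 1] + 1):(sweeps$onset_frame[i] - 1)
    straightBetween <- length(between) > 0 && any(between %in% sustainedFrames)
    grp[i] <- if (straightBetween) grp[i - 1] + 1 else grp[i - 1]
  }

  out <- lapply(unique(grp), function(g) {
    sw <- sweeps[grp == g, , drop = FALSE]
    acc <- sw[nrow(sw), ]
    interWaves <- if (nrow(sw) > 1) {
      sum(vapply(seq_len(nrow(sw) - 1), function(j) {
        sum(waves$onset_frame > sw$peak_frame[j] &
              waves$onset_frame < sw$onset_frame[j + 1])
      }, numeric(1)))
    } else 0
    after <- which(sustainedStart > acc$peak_frame)
    straightFrame <- if (length(after)) sustainedStart[min(after)] else NA_integer_
    wAfter <- waves$onset_frame >= acc$peak_frame
    wts <- if (is.na(straightFrame)) NA_integer_ else
      sum(wAfter & waves$onset_frame < straightFrame)
    firstWaveIdx <- which(wAfter)[1]
    region <- NULL
    initClass <- NA_character_
    if (!is.null(asymKymo)) {
      region <- tryCatch(measureAsymmetricRegion(asymKymo, acc, config),
                         larvagram_no_region = function(e) NULL)
      if (!is.null(region) && !is.na(firstWaveIdx))
        initClass <- classifyWaveInitiation(waves[firstWaveIdx, ], region)
    }
    ph <- NA_character_
    if (!is.null(phases)) {
      tOn <- (sw$onset_frame[1] - 1) / frameRate
      ph <- phases$phase[which.min(abs(phases$time_s - tOn))]
    }
    data.frame(
      maneuver_id = g, onset_frame = sw$onset_frame[1],
      offset_frame = if (is.na(straightFrame)) acc$offset_frame else straightFrame,
      onset_s = (sw$onset_frame[1] - 1) / frameRate,
      n_sweeps = nrow(sw),
      first_sweep_peak_deg = sw$peak_deg[1],
      first_sweep_direction = sw$direction[1],
      accepted_peak_deg = acc$peak_deg,
      accepted_direction = acc$direction,
      accepted_peak_frame = acc$peak_frame,
      size_class = acc$size_class,
      intervening_waves = interWaves,
      first_wave_id = if (is.na(firstWaveIdx)) NA_integer_ else waves$wave_id[firstWaveIdx],
      init_segment = if (is.na(firstWaveIdx)) NA_character_ else waves$init_segment[firstWaveIdx],
      init_class = initClass,
      region_anterior = if (is.null(region)) NA_character_ else region$anterior,
      region_posterior = if (is.null(region)) NA_character_ else region$posterior,
      region_peak = if (is.null(region)) NA_character_ else region$peak,
      waves_to_straighten = wts,
      phase = ph
    )
  })
  res <- do.call(rbind, out)
  res$maneuver_id <- seq_len(nrow(res))
  res
}

#' Segments carried around the bend per straightening wave
#'
#' Tracks the posterior extent of the region of asymmetric contraction at
#' the onset of each post-sweep wave of a maneuver and reports the mean
#' advance (segments per wave), excluding steps where the extent has
#' saturated at the tail.
#'
#' @param asymKymo asymmetry [Kymograph-class]
#' @param maneuvers maneuvers table from [assembleManeuvers()]
#' @param waves waves table from [detectWaves()]
#' @param config list from [eventConfig()]
#' @return data.frame `maneuver_id`, `n_steps`, `segments_per_wave`
#' @export
straighteningAdvance <- function(asymKymo, maneuvers, waves,
                                 config = eventConfig()) {
  A <- asymKymo@data[SEGMENT_NAMES, , drop = FALSE]
  out <- lapply(seq_len(nrow(maneuvers)), function(m) {
    man <- maneuvers[m, ]
    wv <- waves[waves$onset_frame >= man$accepted_peak_frame &
                  waves$onset_frame <= man$offset_frame + 20, , drop = FALSE]
    post <- vapply(wv$onset_frame, function(f) {
      a <- A[, f]
      hot <- !is.na(a) & abs(a) >= config$asymThreshold
      if (!any(hot)) return(NA_real_)
      pk <- which.max(abs(a))
      hi <- pk
      while (hi < 11 && hot[hi + 1]) hi <- hi + 1
      as.numeric(hi)
    }, numeric(1))
    d <- diff(post)
    keep <- !is.na(d) & post[-1] < 11  # drop saturated or undefined steps
    data.frame(maneuver_id = man$maneuver_id, n_steps = sum(keep),
               segments_per_wave = if (any(keep)) mean(d[keep]) else NA_real_)
  })
  do.call(rbind, out)
}
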