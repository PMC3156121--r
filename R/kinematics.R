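# Kinematic synthesis: from a behavior program to ground-truth geometry.
#
# The body is a chain of 11 segments along a spine. Peristalsis is a
# raised-cosine contraction pulse travelling tail to head at constant
# speed; forward translation is applied while the pulse passes the rear
# segments so that per-wave displacement is well defined. A head sweep adds
# a signed curvature-density profile over the pivot segments (raised cosine
# peaked at the pivot center); straightening waves translate that profile
# towards the tail, and curvature mass that passes the tail tip is absorbed
# into the base heading (the body re-aligns with the head's new direction).

## asymmetric raised-cosine bend profile, unit mass, support [-hl, hr]
bendDensity <- function(u, hl, hr) {
  z <- (hl + hr) / 2
  out <- numeric(length(u))
  i <- u >= -hl & u < 0
  out[i] <- cos(pi * u[i] / (2 * hl))^2 / z
  i <- u >= 0 & u <= hr
  out[i] <- cos(pi * u[i] / (2 * hr))^2 / z
  out
}

## cumulative integral of bendDensity from -Inf to u
bendCum <- function(u, hl, hr) {
  z <- (hl + hr) / 2
  out <- numeric(length(u))
  i <- u >= -hl & u < 0
  out[i] <- ((u[i] + hl) / 2 + (hl / (2 * pi)) * sin(pi * u[i] / hl)) / z
  i <- u >= 0 & u <= hr
  out[i] <- (hl / 2 + u[i] / 2 + (hr / (2 * pi)) * sin(pi * u[i] / hr)) / z
  out[u > hr] <- 1
  out
}

pivotGeometry <- function(config) {
  list(center = segmentIndex(config@pivotCenter) - 0.5,
       hl = (segmentIndex(config@pivotCenter) - 0.5) -
         (segmentIndex(config@pivotAnterior) - 1),
       hr = segmentIndex(config@pivotPosterior) -
         (segmentIndex(config@pivotCenter) - 0.5))
}

#' Operational bend angle of a head-to-tail midline
#'
#' The angle (degrees, leftward positive in a y-up frame) between the
#' tail-to-midpoint vector and the three-quarter-point-to-head vector,
#' with fractional positions measured from the tail.
#' @noRd
operationalThetaFromMid <- function(mid) {
  rev <- mid[rev(seq_len(nrow(mid))), , drop = FALSE]  # tail first
  tailP <- rev[1, ]
  headP <- rev[nrow(rev), ]
  midP <- polylinePointAt(rev, 0.5)
  q3P <- polylinePointAt(rev, 0.75)
  v1 <- midP - tailP
  v2 <- headP - q3P
  signedAngleDeg(v1, v2)
}

## operational theta from the two side boundaries: resample both sides to
## equal-arc points, midline = pairwise midpoints
operationalTheta <- function(left, right, K = 51) {
  L <- resamplePolyline(left, K)
  R <- resamplePolyline(right, K)
  operationalThetaFromMid((L + R) / 2)
}

#' Compute one body pose
#'
#' @param lengths current per-segment lengths (mm)
#' @param compAmp,compEff signed bend amplitudes (rad) and profile shifts
#'   (segments) of the active bend components
#' @param psi base heading (rad): tail heading, or head heading when
#'   `lockHead`
#' @param anchorTail tail-tip position (mm)
#' @param maxW maximum full body width (mm)
#' @param pivot list from `pivotGeometry()`
#' @param nsub spine samples per segment
#' @return list with x, spine, left, right, psiTail, psiHead
#' @keywords internal
larvaPose <- function(lengths, compAmp, compEff, psi, anchorTail, maxW,
                      pivot, nsub = 8, lockHead = FALSE) {
  x <- seq(0, 11, by = 1 / nsub)
  n <- length(x)
  ## the terminal tail region (x > 10.4, the rounded tail cap) is rigid:
  ## bend mass carried past it straightens into the base heading rather
  ## than curling the tail tip
  xExit <- 10.4
  thetaCum <- function(xq) {
    xq <- pmin(xq, xExit)
    tot <- numeric(length(xq))
    for (j in seq_along(compAmp)) {
      cj <- pivot$center + compEff[j]
      tot <- tot + compAmp[j] *
        (bendCum(xExit - cj, pivot$hl, pivot$hr) - bendCum(xq - cj, pivot$hl, pivot$hr))
    }
    tot
  }
  totalTurn <- if (length(compAmp)) thetaCum(0) else 0
  psiTail <- if (lockHead) psi - totalTurn else psi
  xm <- (x[-1] + x[-n]) / 2
  psim <- psiTail + (if (length(compAmp)) thetaCum(xm) else 0)
  ds <- rep(lengths / nsub, each = nsub)
  stepx <- cos(psim) * ds
  stepy <- sin(psim) * ds
  ## positions integrate from the tail anchor towards the head
  px <- anchorTail[1] + rev(cumsum(rev(stepx)))
  py <- anchorTail[2] + rev(cumsum(rev(stepy)))
  spine <- cbind(c(px, anchorTail[1]), c(py, anchorTail[2]))
  psis <- psiTail + (if (length(compAmp)) thetaCum(x) else 0)
  w <- bodyHalfWidth(x, maxW)
  nx <- -sin(psis) * w
  ny <- cos(psis) * w
  list(x = x, spine = spine,
       left = cbind(spine[, 1] + nx, spine[, 2] + ny),
       right = cbind(spine[, 1] - nx, spine[, 2] - ny),
       psiTail = psiTail, psiHead = psiTail + totalTurn)
}

#' Calibrate sweep actuation amplitude against the operational bend angle
#'
#' Returns a function mapping a target peak bend angle (deg) to the bend
#' amplitude (rad) that produces it under the operational midline
#' definition, for the given body and pivot profile.
#'
#' @param body a [LarvaBodyModel-class]
#' @param config a [SimulationConfig-class]
#' @return function(thetaDeg) -> amplitude (rad)
#' @export
calibrateSweepAmplitude <- function(body, config) {
  pivot <- pivotGeometry(config)
  maxW <- max(body@restWidths)
  grid <- seq(0, 2.9, length.out = 30)
  th <- vapply(grid, function(a) {
    if (a == 0) return(0)
    pose <- larvaPose(body@restLengths, a, 0, 0, c(0, 0), maxW, pivot)
    operationalTheta(pose$left, pose$right)
  }, numeric(1))
  if (any(diff(th) <= 0))
    th <- cummax(th + seq_along(th) * 1e-9)
  function(thetaDeg) approx(th, grid, xout = abs(thetaDeg), rule = 2)$y
}

## quadrant polygons of one segment from dense side polylines
## order: AL, AR, PL, PR (anterior/posterior x left/right)
segmentQuadrants <- function(left, right, i, nsub = 8) {
  a <- (i - 1) * nsub + 1
  b <- i * nsub + 1
  m <- a + nsub / 2
  L <- left[a:b, , drop = FALSE]
  R <- right[a:b, , drop = FALSE]
  M <- (L + R) / 2
  h <- nsub / 2 + 1
  k <- nsub + 1
  list(
    AL = rbind(L[1:h, ], M[h:1, ]),
    AR = rbind(R[1:h, ], M[h:1, ]),
    PL = rbind(L[h:k, ], M[k:h, ]),
    PR = rbind(R[h:k, ], M[k:h, ])
  )
}

#' Synthesize ground-truth kinematics for a behavior program
#'
#' Plays the program through the body model frame by frame, producing true
#' spine/boundary geometry, per-segment side lengths, quadrant areas and
#' conserved-fluorophore intensities, and the true operational bend angle.
#'
#' @param program a [BehaviorProgram-class]
#' @param body a [LarvaBodyModel-class]
#' @param config a [SimulationConfig-class]
#' @param geometry `"full"` keeps dense polylines and quadrant metrics (as
#'   needed for rendering); `"theta"` keeps only per-frame scalars and
#'   segment lengths (fast path for long event-level simulations)
#' @return a [GroundTruth-class]
#' @export
synthesizeKinematics <- function(program, body, config, geometry = c("full", "theta")) {
  geometry <- match.arg(geometry)
  ev <- program@events
  if (nrow(ev) == 0 || any(ev$t_end > program@duration + 1e-6) || any(ev$t_start < 0))
    stopc("larvagram_invalid_argument", "program events outside simulated duration")
  fr <- config@frameRate
  nf <- max(2L, floor(program@duration * fr))
  times <- (0:(nf - 1)) / fr
  nsub <- 8L
  pivot <- pivotGeometry(config)
  maxW <- max(body@restWidths)
  L0 <- bodyLength(body)
  cA <- config@contractionAmplitude
  h <- config@pulseHalfWidth
  v <- pulseSpeed(config)
  xc <- seq_len(11) - 0.5

  ## base heading before each event: cumulative turn of all prior maneuvers
  psiBase <- cumsum(c(0, ev$dpsi_rad))[seq_len(nrow(ev))]

  wv <- program@waves
  wv$p0 <- pulseStart(wv$init_segment, config)
  wv$dur <- pulseDuration(wv$init_segment, config)
  sw <- program@sweeps
  tm <- .timing

  rest <- body@restLengths
  restPose <- larvaPose(rest, numeric(0), numeric(0), 0, c(0, 0), maxW, pivot, nsub)
  restQuadArea <- t(vapply(seq_len(11), function(i) {
    q <- segmentQuadrants(restPose$left, restPose$right, i, nsub)
    vapply(q, function(p) abs(shoelaceArea(p)), numeric(1))
  }, numeric(4)))

  keepGeom <- geometry == "full"
  np <- 11 * nsub + 1
  spineA <- if (keepGeom) array(NA_real_, c(np, 2, nf)) else array(0, c(1, 2, 1))
  leftA <- spineA; rightA <- spineA
  segLenLeft <- matrix(NA_real_, 11, nf, dimnames = list(SEGMENT_NAMES, NULL))
  segLenRight <- segLenLeft
  segArea <- segLenLeft
  quadArea <- if (keepGeom) array(NA_real_, c(11, 4, nf),
                                  dimnames = list(SEGMENT_NAMES, c("AL", "AR", "PL", "PR"), NULL))
              else array(0, c(1, 1, 1))
  quadInt <- quadArea

  frames <- data.frame(
    frame = seq_len(nf), time_s = times, theta_deg = NA_real_,
    wave_id = NA_integer_, event_id = NA_integer_, event_label = NA_character_,
    head_x_mm = NA_real_, head_y_mm = NA_real_,
    tail_x_mm = NA_real_, tail_y_mm = NA_real_,
    centroid_x_mm = NA_real_, centroid_y_mm = NA_real_,
    psi_tail_rad = NA_real_, origin_x_mm = NA_real_, origin_y_mm = NA_real_
  )

  tailPos <- c(0, 0)
  Fprev <- numeric(nrow(wv))
  wlo <- 1L
  evIdx <- 1L
  for (f in seq_len(nf)) {
    t <- times[f]
    while (evIdx < nrow(ev) && t >= ev$t_start[evIdx + 1]) evIdx <- evIdx + 1L
    isTurn <- ev$type[evIdx] == "turn"

    while (wlo <= nrow(wv) && wv$onset_s[wlo] + wv$dur[wlo] < t - 0.5) {
      Fprev[wlo] <- 1  # settled long ago; ensure no residual increments
      wlo <- wlo + 1L
    }
    wIdx <- if (wlo > nrow(wv)) integer(0) else
      wlo - 1L + which(wv$onset_s[wlo:nrow(wv)] <= t)
    g <- numeric(11)
    waveHere <- NA_integer_
    dD <- c(0, 0)
    if (length(wIdx)) {
      p <- wv$p0[wIdx] - v * (t - wv$onset_s[wIdx])
      active <- p > -1 - h & p < wv$p0[wIdx] + 1e-9
      for (k in seq_along(wIdx)) {
        if (!active[k]) next
        w <- wIdx[k]
        d <- xc - p[k]
        gi <- ifelse(abs(d) < h & xc <= wv$init_segment[w] - 0.4,
                     cos(pi * d / (2 * h))^2, 0)
        g <- g + gi
        if (is.na(waveHere) && p[k] > -1 && p[k] < wv$p0[w])
          waveHere <- wv$wave_id[w]
      }
      ## pulsed forward translation while the pulse passes the rear segments
      Fnow <- Fprev
      for (k in seq_along(wIdx)) {
        w <- wIdx[k]
        if (!wv$full[w]) next
        ## ramp sits mid-way between the rearmost- and frontmost-segment
        ## peaks, so the displacement accrued between a wave's first and
        ## last contraction peaks equals exactly its per-wave displacement
        ## when the wave period matches that window
        Fnow[w] <- smoothstep((6 - p[k]) / 2)
      }
      dmag <- sum(wv$disp_bl[wIdx] * (Fnow[wIdx] - Fprev[wIdx])) * L0
      Fprev[wIdx] <- Fnow[wIdx]
      dD <- c(dmag, dmag)  # direction applied below once psiTail is known
    }
    g <- pmin(g, 1)
    lengths <- rest * (1 - cA * g)

    compAmp <- numeric(0); compEff <- numeric(0)
    lock <- FALSE
    psi <- psiBase[evIdx]
    label <- "run"
    if (isTurn) {
      eswk <- which(sw$event_id == ev$event_id[evIdx] & sw$onset_s <= t)
      if (length(eswk)) {
        ## global shift S(t) within this maneuver
        mwk <- which(wv$event_id == ev$event_id[evIdx] & wv$ramp & wv$onset_s <= t)
        S <- 0
        if (length(mwk)) {
          pm <- wv$p0[mwk] - v * (t - wv$onset_s[mwk])
          S <- sum(wv$spw_amount[mwk] *
                     smoothstep((wv$ramp_hi[mwk] - pm) /
                                  pmax(wv$ramp_hi[mwk] - wv$ramp_lo[mwk], 1e-6)))
        }
        for (j in eswk) {
          A <- sw$amplitude_rad[j] * smoothstep((t - sw$onset_s[j]) / tm$rampT)
          dec <- sw$decay_start_s[j]
          if (!is.na(dec) && t > dec) {
            dur <- if (sw$accepted[j]) tm$endDecayDur else tm$rejectDecayDur
            A <- A * (1 - smoothstep((t - dec) / dur))
          }
          if (A > 1e-6) {
            compAmp <- c(compAmp, sw$direction[j] * A)
            compEff <- c(compEff, S - sw$s_at_peak[j])
          }
        }
      }
      if (t >= ev$lock_psi_s[evIdx]) {
        lock <- TRUE
        psi <- psiBase[evIdx] + ev$dpsi_rad[evIdx]
        label <- "straighten"
      } else label <- "sweep"
    }

    pose <- larvaPose(lengths, compAmp, compEff, psi, tailPos, maxW, pivot,
                      nsub, lockHead = lock)
    if (dD[1] != 0) {
      u <- c(cos(pose$psiTail), sin(pose$psiTail))
      tailPos <- tailPos + dD[1] * u
      pose$spine <- sweep2(pose$spine, dD[1] * u)
      pose$left <- sweep2(pose$left, dD[1] * u)
      pose$right <- sweep2(pose$right, dD[1] * u)
    }

    dl <- sqrt(rowSums(diff(pose$left)^2))
    dr <- sqrt(rowSums(diff(pose$right)^2))
    idx <- rep(seq_len(11), each = nsub)
    segLenLeft[, f] <- tapply(dl, idx, sum)
    segLenRight[, f] <- tapply(dr, idx, sum)

    if (keepGeom) {
      spineA[, , f] <- pose$spine
      leftA[, , f] <- pose$left
      rightA[, , f] <- pose$right
      for (i in seq_len(11)) {
        q <- segmentQuadrants(pose$left, pose$right, i, nsub)
        ar <- vapply(q, function(p) abs(shoelaceArea(p)), numeric(1))
        quadArea[i, , f] <- ar
        quadInt[i, , f] <- config@calibration * restQuadArea[i, ] / ar
      }
      segArea[, f] <- rowSums(quadArea[, , f])
    }

    frames$theta_deg[f] <- operationalTheta(pose$left, pose$right)
    frames$wave_id[f] <- waveHere
    frames$event_id[f] <- ev$event_id[evIdx]
    frames$event_label[f] <- label
    frames$head_x_mm[f] <- pose$spine[1, 1]; frames$head_y_mm[f] <- pose$spine[1, 2]
    frames$tail_x_mm[f] <- pose$spine[np, 1]; frames$tail_y_mm[f] <- pose$spine[np, 2]
    cen <- colMeans(rbind(pose$left, pose$right))
    frames$centroid_x_mm[f] <- cen[1]; frames$centroid_y_mm[f] <- cen[2]
    frames$psi_tail_rad[f] <- pose$psiTail
  }

  if (!keepGeom) {
    segArea <- matrix(NA_real_, 11, nf, dimnames = list(SEGMENT_NAMES, NULL))
  }
  new("GroundTruth", frames = frames, spine = spineA, left = leftA,
      right = rightA, segLenLeft = segLenLeft, segLenRight = segLenRight,
      segArea = segArea, quadArea = quadArea, quadIntensity = quadInt,
      body = body, config = config, program = program)
}

## add a row vector to every row of a two-column matrix
sweep2 <- function(m, v) cbind(m[, 1] + v[1], m[, 2] + v[2])
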