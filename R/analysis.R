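# High-level analysis drivers: run the full measurement pipeline over a
# synthetic dataset (streamed frame by frame) and assemble event tables.

#' Measure a synthetic video frame by frame
#'
#' Streams rendered frames through the vision chain (threshold, outline,
#' head/tail with chained priors, centerline, bend angle) and the segment
#' measurements (ground-truth annotation resolved onto the extracted
#' outline, side arc lengths, optionally quadrant intensities). Frames are
#' rendered on the fly, so arbitrarily long videos use constant memory.
#'
#' @param truth a [GroundTruth-class] with full geometry (origins are
#'   assigned if missing)
#' @param config the generating [SimulationConfig-class]
#' @param vision a [VisionConfig-class]
#' @param images optional pre-rendered array `[row, col, frame]`; when
#'   NULL frames are rendered (with the configured noise) on the fly
#' @param intensity also measure quadrant intensities (slower)
#' @param frames frame subset (default all)
#' @return list: `track` (per-frame px and absolute-mm positions and bend
#'   angle), `lenLeft`, `lenRight` (11 x frames, mm), `quad` (11 x 4 x
#'   frames intensities or NULL)
#' @export
analyzeSynthetic <- function(truth, config, vision = visionConfig(),
                             images = NULL, intensity = FALSE,
                             frames = NULL) {
  if (is.na(truth@frames$origin_x_mm[1]))
    truth <- addPixelOrigins(truth, config)
  nf <- nrow(truth@frames)
  if (is.null(frames)) frames <- seq_len(nf)
  s <- config@pixelScale
  H <- truth@frames$px_h[1]
  ann1 <- truthAnnotation(truth, frames[1], "yup")
  prior <- list(head = c(ann1$x[ann1$point_id == 0], ann1$y[ann1$point_id == 0]),
                tail = c(ann1$x[ann1$point_id == 11], ann1$y[ann1$point_id == 11]))
  n <- length(frames)
  track <- data.frame(frame = frames, time_s = truth@frames$time_s[frames],
                      head_x = NA_real_, head_y = NA_real_,
                      tail_x = NA_real_, tail_y = NA_real_,
                      theta_deg = NA_real_, ok = FALSE,
                      head_x_mm = NA_real_, head_y_mm = NA_real_,
                      tail_x_mm = NA_real_, tail_y_mm = NA_real_,
                      x_mm = NA_real_, y_mm = NA_real_)
  lenLeft <- matrix(NA_real_, 11, n, dimnames = list(SEGMENT_NAMES, NULL))
  lenRight <- lenLeft
  quad <- if (intensity) array(NA_real_, c(11, 4, n),
                               dimnames = list(SEGMENT_NAMES,
                                               c("AL", "AR", "PL", "PR"), NULL))
          else NULL
  for (k in seq_len(n)) {
    f <- frames[k]
    img <- if (is.null(images)) renderFrameNoisy(truth, f, config)
           else images[, , f]
    res <- tryCatch({
      mask <- segmentBody(img, vision)
      ol <- extractOutline(mask, vision, frameId = f)
      curv <- outlineCurvature(ol, vision@curvatureWindowFrac)
      ol <- locateHeadTail(ol, curv, prior)
      cl <- computeCenterline(ol, vision)
      annT <- truthAnnotation(truth, f, "yup")
      names(annT) <- c("frame", "point_id", "x", "y")
      ann <- resolveAnnotation(annT, ol)
      bl <- boundaryLengths(ann)
      qv <- if (intensity) quadrantIntensities(ann, img)$quad else NULL
      list(ol = ol, theta = bendAngle(cl), bl = bl, qv = qv)
    }, larvagram_error = function(e) e)
    if (inherits(res, "error")) next
    ol <- res$ol
    hx <- ol@vertices[ol@headIndex, 1]; hy <- ol@vertices[ol@headIndex, 2]
    tx <- ol@vertices[ol@tailIndex, 1]; ty <- ol@vertices[ol@tailIndex, 2]
    track$head_x[k] <- hx; track$head_y[k] <- hy
    track$tail_x[k] <- tx; track$tail_y[k] <- ty
    track$theta_deg[k] <- res$theta
    track$ok[k] <- TRUE
    ox <- truth@frames$origin_x_mm[f]; oy <- truth@frames$origin_y_mm[f]
    hw <- pxToWorld(hx, hy, ox, oy, s, H)
    tw <- pxToWorld(tx, ty, ox, oy, s, H)
    track$head_x_mm[k] <- hw[1]; track$head_y_mm[k] <- hw[2]
    track$tail_x_mm[k] <- tw[1]; track$tail_y_mm[k] <- tw[2]
    cen <- colMeans(ol@vertices)
    cw <- pxToWorld(cen[1], cen[2], ox, oy, s, H)
    track$x_mm[k] <- cw[1]; track$y_mm[k] <- cw[2]
    track$theta_deg[k] <- res$theta
    lenLeft[, k] <- res$bl[, "left"] * s
    lenRight[, k] <- res$bl[, "right"] * s
    if (intensity) quad[, , k] <- res$qv
    prior <- list(head = c(hx, hy), tail = c(tx, ty))
  }
  list(track = track, lenLeft = lenLeft, lenRight = lenRight, quad = quad)
}

#' Build kymographs and event tables from per-frame measurements
#'
#' Two-pass reference choice: a provisional first-frame reference gives a
#' first wave detection, the reference is re-chosen as the inter-wave
#' frame with minimal total fractional length deviation, and the
#' fractional kymographs are rebuilt once.
#'
#' @param meas result of [analyzeSynthetic()]
#' @param config the generating [SimulationConfig-class] (frame rate)
#' @param vision a [VisionConfig-class]
#' @param events list from [eventConfig()]
#' @return list: `kymoLength`, `kymoAsym` (and `kymoIntensity` when
#'   intensities were measured), `referenceFrame`, `waves`, `peaks`,
#'   `sweeps`, `maneuvers`
#' @export
analyzeEvents <- function(meas, config, vision = visionConfig(),
                          events = eventConfig()) {
  fr <- config@frameRate
  segLen <- meas$lenLeft + meas$lenRight
  ky0 <- buildKymograph(fractionalChange(segLen, 1), "fractional_length",
                        referenceFrame = 1, frameRate = fr)
  det0 <- detectWaves(ky0, events)
  ref <- chooseReferenceFrame(segLen, det0$waves)
  kyLen <- buildKymograph(fractionalChange(segLen, ref), "fractional_length",
                          referenceFrame = ref, frameRate = fr)
  det <- detectWaves(kyLen, events)
  kyInt <- NULL
  if (!is.null(meas$quad)) {
    segInt <- apply(meas$quad, c(1, 3), mean)
    kyInt <- buildKymograph(fractionalChange(segInt, ref),
                            "fractional_intensity", referenceFrame = ref,
                            frameRate = fr)
  }
  kyAsym <- buildKymograph(asymmetryIndex(meas$lenLeft, meas$lenRight),
                           "asymmetry", frameRate = fr)
  sweeps <- detectHeadSweeps(meas$track$theta_deg, vision)
  maneuvers <- assembleManeuvers(sweeps, det$waves, meas$track$theta_deg,
                                 frameRate = fr, config = events,
                                 asymKymo = kyAsym)
  list(kymoLength = kyLen, kymoIntensity = kyInt, kymoAsym = kyAsym,
       referenceFrame = ref, waves = det$waves, peaks = det$peaks,
       sweeps = sweeps, maneuvers = maneuvers)
}

#' Per-wave displacements for a set of detected waves
#'
#' @param meas result of [analyzeSynthetic()] (absolute-mm track)
#' @param waves waves table from [detectWaves()]
#' @param bodyLength body length (mm)
#' @param fullOnly restrict to tail-initiated waves spanning most of the
#'   body (the forward-crawling waves)
#' @return numeric vector of displacements (body lengths)
#' @export
waveDisplacements <- function(meas, waves, bodyLength, fullOnly = TRUE) {
  if (fullOnly)
    waves <- waves[waves$init_segment %in% c("A7", "A8") & waves$n_segments >= 9, ,
                   drop = FALSE]
  tr <- data.frame(head_x = meas$track$head_x_mm, head_y = meas$track$head_y_mm,
                   tail_x = meas$track$tail_x_mm, tail_y = meas$track$tail_y_mm)
  vapply(seq_len(nrow(waves)), function(k)
    tryCatch(waveDisplacement(tr, waves[k, ], bodyLength),
             larvagram_error = function(e) NA_real_),
    numeric(1))
}
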