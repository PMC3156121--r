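# Machine-vision extraction: outline, head/tail, centerline, bend angle.
#
# Pixel geometry is handled internally in a y-up frame (x = column,
# y = H + 1 - row) so that signed angles follow the usual mathematical
# convention and "leftward positive" matches the animal's left.

#' Threshold and morphologically smooth one frame
#'
#' Binarizes the frame (Otsu by default) and applies one erosion and one
#' dilation with a disk, removing speckle noise.
#'
#' @param frame numeric matrix `[row, col]` of intensities
#' @param config a [VisionConfig-class]
#' @return logical matrix body mask
#' @export
segmentBody <- function(frame, config = visionConfig()) {
  if (length(frame) == 0)
    stopc("larvagram_invalid_argument", "empty frame")
  thr <- if (config@thresholdMethod == "otsu") {
    if (max(frame) <= min(frame))
      stopc("larvagram_no_larva", "frame has no contrast; no larva found")
    mx <- max(frame)
    EBImage::otsu(EBImage::Image(t(frame) / mx), range = c(0, 1)) * mx
  } else config@fixedThreshold
  mask <- frame > thr
  if (!any(mask)) stopc("larvagram_no_larva", "no foreground after thresholding")
  if (config@morphRadius > 0) {
    brush <- EBImage::makeBrush(2 * config@morphRadius + 1, "disc")
    m <- EBImage::Image(t(mask) * 1)
    m <- EBImage::dilate(EBImage::erode(m, brush), brush)
    mask <- t(EBImage::imageData(m)) > 0.5
  }
  if (!any(mask)) stopc("larvagram_no_larva", "no foreground after morphology")
  mask
}

#' Extract the smoothed boundary of the largest component
#'
#' Traces the boundary of the largest connected component and smooths the
#' vertex coordinates with a circular Gaussian whose sd is
#' `boundarySmoothFrac` of the vertex count.
#'
#' @param mask logical or 0/1 matrix `[row, col]`
#' @param config a [VisionConfig-class]
#' @param frameId frame number carried on the result
#' @return a [BodyOutline-class] (head/tail unset), vertices in (x, y-up)
#' @export
extractOutline <- function(mask, config = visionConfig(), frameId = NA_real_) {
  if (!any(mask)) stopc("larvagram_no_larva", "empty mask")
  H <- nrow(mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  sizes <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  big <- as.integer(names(sizes)[which.max(sizes)])
  if (max(sizes) < config@minComponentArea)
    stopc("larvagram_too_small", sprintf("largest component is %d px^2", max(sizes)))
  oc <- EBImage::ocontour(lab)[[big]]
  verts <- cbind(oc[, 1] + 1, H - oc[, 2])  # (col, y-up)
  if (shoelaceArea(verts) < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
  ## boundary tracing follows the centers of edge pixels, which sit about
  ## half a pixel inside the true object boundary; offset outward to
  ## compensate for this digitization bias
  n <- nrow(verts)
  tang <- verts[c(2:n, 1), ] - verts[c(n, 1:(n - 1)), ]
  tlen <- sqrt(rowSums(tang^2))
  tlen[tlen == 0] <- 1
  verts <- verts + 0.5 * cbind(tang[, 2], -tang[, 1]) / tlen
  sd <- config@boundarySmoothFrac * nrow(verts)
  if (sd > 0) {
    verts <- cbind(circularGaussianSmooth(verts[, 1], sd),
                   circularGaussianSmooth(verts[, 2], sd))
  }
  new("BodyOutline", vertices = verts, headIndex = NA_real_,
      tailIndex = NA_real_, frameId = frameId)
}

#' Signed boundary curvature from a sliding tangent window
#'
#' At each vertex, the turning angle between the chord arriving from
#' `windowFrac/2` of the perimeter behind and the chord leaving towards
#' `windowFrac/2` ahead, divided by the half-window arc length. Convex
#' protrusions of a counterclockwise boundary are positive; a circle of
#' radius r gives 1/r everywhere.
#'
#' @param outline a [BodyOutline-class]
#' @param windowFrac window size as a fraction of total boundary length
#' @return numeric curvature per vertex (1/px)
#' @export
outlineCurvature <- function(outline, windowFrac = 0.20) {
  p <- outline@vertices
  n <- nrow(p)
  if (n < 20) stopc("larvagram_invalid_argument", "need >= 20 vertices")
  d <- sqrt(rowSums((p[c(2:n, 1), ] - p)^2))
  s <- c(0, cumsum(d))[seq_len(n)]
  per <- sum(d)
  W <- windowFrac * per
  if (W > per / 2) stopc("larvagram_invalid_argument", "window exceeds half the perimeter")
  sExt <- c(s - per, s, s + per)
  xExt <- rep(p[, 1], 3); yExt <- rep(p[, 2], 3)
  xb <- approx(sExt, xExt, xout = s - W / 2)$y
  yb <- approx(sExt, yExt, xout = s - W / 2)$y
  xf <- approx(sExt, xExt, xout = s + W / 2)$y
  yf <- approx(sExt, yExt, xout = s + W / 2)$y
  c1x <- p[, 1] - xb; c1y <- p[, 2] - yb
  c2x <- xf - p[, 1]; c2y <- yf - p[, 2]
  ang <- atan2(c1x * c2y - c1y * c2x, c1x * c2x + c1y * c2y)
  ang / (W / 2)
}

#' Locate head and tail from curvature maxima
#'
#' The two highest curvature local maxima separated by at least a quarter
#' of the perimeter are the tip candidates; they are assigned to head and
#' tail by proximity to their positions in the previous frame (or a
#' user-supplied prior for the first frame).
#'
#' @param outline a [BodyOutline-class]
#' @param curvature per-vertex curvature from [outlineCurvature()]
#' @param prior list with elements `head`, `tail`: (x, y-up) positions
#' @return the outline with `headIndex`/`tailIndex` set
#' @export
locateHeadTail <- function(outline, curvature, prior) {
  if (is.null(prior) || is.null(prior$head) || is.null(prior$tail))
    stopc("larvagram_invalid_argument",
          "a head/tail prior is required (ground truth or user input for the first frame)")
  p <- outline@vertices
  n <- nrow(p)
  d <- sqrt(rowSums((p[c(2:n, 1), ] - p)^2))
  s <- c(0, cumsum(d))[seq_len(n)]
  per <- sum(d)
  cand <- localMaximaCircular(curvature)
  cand <- cand[order(curvature[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 2) break
    circDist <- function(a, b) {
      dd <- abs(s[a] - s[b]); min(dd, per - dd)
    }
    if (all(vapply(keep, function(k) circDist(i, k) >= 0.25 * per, logical(1))))
      keep <- c(keep, i)
  }
  if (length(keep) < 2)
    stopc("larvagram_degenerate_shape", "fewer than two separated curvature maxima")
  ## two-scale refinement: the broad window is robust for candidate
  ## selection but its maximum drifts when a body bend sits next to a tip;
  ## re-localize each tip with a small window in a local neighbourhood
  fine <- outlineCurvature(outline, 0.06)
  keep <- vapply(keep, function(k) {
    lo <- s[k] - 0.07 * per; hi <- s[k] + 0.07 * per
    sAdj <- s + per * ((s - s[k]) < -per / 2) - per * ((s - s[k]) > per / 2)
    nb <- which(sAdj >= lo & sAdj <= hi)
    nb[which.max(fine[nb])]
  }, integer(1))
  c1 <- p[keep[1], ]; c2 <- p[keep[2], ]
  d11 <- sum((c1 - prior$head)^2) + sum((c2 - prior$tail)^2)
  d12 <- sum((c2 - prior$head)^2) + sum((c1 - prior$tail)^2)
  if (d11 <= d12) {
    outline@headIndex <- keep[1]; outline@tailIndex <- keep[2]
  } else {
    outline@headIndex <- keep[2]; outline@tailIndex <- keep[1]
  }
  outline
}

#' Compute the body centerline
#'
#' Splits the outline at head and tail into left and right arcs, resamples
#' each to `centerlinePoints` equal-arc-length points, and takes pairwise
#' midpoints, ordered head to tail.
#'
#' @param outline a [BodyOutline-class] with head/tail set
#' @param config a [VisionConfig-class]
#' @return a [Centerline-class]
#' @export
computeCenterline <- function(outline, config = visionConfig()) {
  h <- outline@headIndex; t <- outline@tailIndex
  if (is.na(h) || is.na(t))
    stopc("larvagram_invalid_argument", "head/tail not located")
  p <- outline@vertices
  n <- nrow(p)
  seqF <- if (h <= t) h:t else c(h:n, 1:t)
  seqB <- if (t <= h) t:h else c(t:n, 1:h)
  arcA <- p[seqF, , drop = FALSE]                    # head -> tail one way
  arcB <- p[rev(seqB), , drop = FALSE]               # head -> tail other way
  lenA <- polylineLength(arcA); lenB <- polylineLength(arcB)
  if (max(lenA, lenB) > 3 * min(lenA, lenB))
    stopc("larvagram_self_occlusion", "side arcs grossly unequal; posture not resolvable")
  K <- config@centerlinePoints
  A <- resamplePolyline(arcA, K)
  B <- resamplePolyline(arcB, K)
  new("Centerline", points = (A + B) / 2)
}

#' Signed body bend angle
#'
#' The operational bend angle: the signed angle from the tail-to-midpoint
#' vector to the three-quarter-point-to-head vector, with fractional
#' positions measured from the tail along the centerline. Leftward bends
#' are positive (y-up frame).
#'
#' @param centerline a [Centerline-class]
#' @return angle in degrees, in (-180, 180]
#' @export
bendAngle <- function(centerline) {
  operationalThetaFromMid(centerline@points)
}

#' Detect head sweeps from a bend-angle series
#'
#' A sweep starts when |theta| reaches `sweepThreshold` and ends when
#' |theta| falls below `sweepRelease` (hysteresis) or the sign flips.
#' Events are classified large/small by the 90-degree rule.
#'
#' @param theta numeric bend-angle series (deg); NAs close any open event
#' @param config a [VisionConfig-class]
#' @return data.frame `onset_frame`, `offset_frame`, `peak_frame`,
#'   `direction` ("left"/"right"), `peak_deg`, `size_class`
#' @export
detectHeadSweeps <- function(theta, config = visionConfig()) {
  if (length(theta) < 2)
    stopc("larvagram_invalid_argument", "need at least two frames")
  ## bridge isolated tracking dropouts (runs of up to 2 NA frames) with
  ## the last valid angle so they do not split ongoing sweeps
  r <- rle(is.na(theta))
  ends <- cumsum(r$lengths)
  for (k in which(r$values & r$lengths <= 2)) {
    i0 <- ends[k] - r$lengths[k] + 1
    if (i0 > 1) theta[i0:ends[k]] <- theta[i0 - 1]
  }
  thr <- config@sweepThreshold; rel <- config@sweepRelease
  out <- list()
  inEv <- FALSE; sgn <- 0; onset <- NA; peak <- 0; peakf <- NA
  closeEv <- function(offset) {
    out[[length(out) + 1]] <<- data.frame(
      onset_frame = onset, offset_frame = offset, peak_frame = peakf,
      direction = if (sgn > 0) "left" else "right",
      peak_deg = peak, size_class = if (peak > 90) "large" else "small")
    inEv <<- FALSE
  }
  for (i in seq_along(theta)) {
    a <- theta[i]
    if (is.na(a)) { if (inEv) closeEv(i - 1); next }
    if (!inEv) {
      if (abs(a) >= thr) {
        inEv <- TRUE; sgn <- sign(a); onset <- i; peak <- abs(a); peakf <- i
      }
    } else {
      if (sign(a) != sgn && a != 0) {
        closeEv(i - 1)
        if (abs(a) >= thr) {
          inEv <- TRUE; sgn <- sign(a); onset <- i; peak <- abs(a); peakf <- i
        }
      } else if (abs(a) < rel) {
        closeEv(i - 1)
      } else if (abs(a) > peak) {
        peak <- abs(a); peakf <- i
      }
    }
  }
  if (inEv) closeEv(length(theta))
  empty <- data.frame(onset_frame = integer(0), offset_frame = integer(0),
                      peak_frame = integer(0), direction = character(0),
                      peak_deg = numeric(0), size_class = character(0))
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[res$offset_frame - res$onset_frame + 1 >= config@minSweepFrames, ,
             drop = FALSE]
  if (!nrow(res)) return(empty)
  ## bends plateau at their peak while the asymmetric region starts moving
  ## tail-ward; report the first attainment of the peak (within 2 deg) so
  ## downstream region measurements see the unshifted pivot
  for (i in seq_len(nrow(res))) {
    sel <- res$onset_frame[i]:res$offset_frame[i]
    hit <- sel[!is.na(theta[sel]) & abs(theta[sel]) >= res$peak_deg[i] - 2]
    if (length(hit)) res$peak_frame[i] <- hit[1]
  }
  rownames(res) <- NULL
  res
}

#' Track a stack of frames
#'
#' Runs the full per-frame vision chain (threshold, outline, curvature
#' head/tail with frame-to-frame priors, centerline, bend angle).
#'
#' @param getFrame function(f) returning the frame matrix, or a 3-D array
#'   `[row, col, frame]`
#' @param nf number of frames
#' @param config a [VisionConfig-class]
#' @param prior first-frame head/tail prior: list(head=, tail=) in (x,
#'   y-up) pixels
#' @param keepOutlines keep per-frame outlines (needed for segment metrics)
#' @return list with `track` (data.frame: frame, head_x, head_y, tail_x,
#'   tail_y, theta_deg, ok) and `outlines`
#' @export
trackFrames <- function(getFrame, nf = NULL, config = visionConfig(),
                        prior = NULL, keepOutlines = TRUE) {
  if (is.array(getFrame)) {
    arr <- getFrame
    nf <- dim(arr)[3]
    getFrame <- function(f) arr[, , f]
  }
  if (is.null(nf)) stopc("larvagram_invalid_argument", "nf required with a frame function")
  track <- data.frame(frame = seq_len(nf), head_x = NA_real_, head_y = NA_real_,
                      tail_x = NA_real_, tail_y = NA_real_,
                      theta_deg = NA_real_, ok = FALSE)
  outlines <- if (keepOutlines) vector("list", nf) else NULL
  for (f in seq_len(nf)) {
    res <- tryCatch({
      mask <- segmentBody(getFrame(f), config)
      ol <- extractOutline(mask, config, frameId = f)
      curv <- outlineCurvature(ol, config@curvatureWindowFrac)
      ol <- locateHeadTail(ol, curv, prior)
      cl <- computeCenterline(ol, config)
      list(ol = ol, theta = bendAngle(cl))
    }, larvagram_error = function(e) e)
    if (inherits(res, "error")) next
    ol <- res$ol
    track$head_x[f] <- ol@vertices[ol@headIndex, 1]
    track$head_y[f] <- ol@vertices[ol@headIndex, 2]
    track$tail_x[f] <- ol@vertices[ol@tailIndex, 1]
    track$tail_y[f] <- ol@vertices[ol@tailIndex, 2]
    track$theta_deg[f] <- res$theta
    track$ok[f] <- TRUE
    prior <- list(head = c(track$head_x[f], track$head_y[f]),
                  tail = c(track$tail_x[f], track$tail_y[f]))
    if (keepOutlines) outlines[[f]] <- ol
  }
  list(track = track, outlines = outlines)
}
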