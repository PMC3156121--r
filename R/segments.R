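# Per-segment contraction metrics from the outline and the 20-point
# segment-boundary annotation.

#' Segment-boundary annotation resolved onto an outline
#'
#' @slot outline the [BodyOutline-class] the points were snapped to
#' @slot ids point ids (0 head, +1..+10 left, -1..-10 right, 11 tail)
#' @slot vertexIndex snapped outline vertex index per point
#' @slot leftPath,rightPath outline vertex index sequences, head to tail,
#'   along the left and right sides
#' @export
setClass("SegmentAnnotation",
  representation(outline = "BodyOutline", ids = "numeric",
                 vertexIndex = "numeric", leftPath = "numeric",
                 rightPath = "numeric", points = "data.frame"))

#' Resolve a 20-point segment annotation onto an extracted outline
#'
#' Snaps each annotated point (head tip, ten boundaries per side, tail
#' tip) to the nearest outline vertex and validates ordering along each
#' side.
#'
#' @param points data.frame `point_id`, `x`, `y` in the outline's (x, y-up)
#'   pixel frame (e.g. from [truthAnnotation()])
#' @param outline a [BodyOutline-class] (head/tail need not be set)
#' @param maxSnap largest tolerated snap distance (px)
#' @return a [SegmentAnnotation-class]
#' @export
resolveAnnotation <- function(points, outline, maxSnap = 5) {
  req <- c(0, 1:10, -(1:10), 11)
  if (!setequal(points$point_id, req) || nrow(points) != 22 ||
      anyDuplicated(points$point_id))
    stopc("larvagram_malformed_annotation",
          "annotation must contain point ids 0, +/-1..10, 11 exactly once")
  v <- outline@vertices
  n <- nrow(v)
  vidx <- integer(22)
  dists <- numeric(22)
  for (k in seq_len(22)) {
    d2 <- (v[, 1] - points$x[k])^2 + (v[, 2] - points$y[k])^2
    vidx[k] <- which.min(d2)
    dists[k] <- sqrt(d2[vidx[k]])
  }
  if (max(dists) > maxSnap)
    stopc("larvagram_misregistration",
          sprintf("annotation point %g is %.1f px from the outline",
                  points$point_id[which.max(dists)], max(dists)))
  ids <- points$point_id
  vh <- vidx[ids == 0]
  vt <- vidx[ids == 11]
  ## the two arcs from head to tail
  arcF <- if (vh <= vt) vh:vt else c(vh:n, 1:vt)
  arcB <- rev(if (vt <= vh) vt:vh else c(vt:n, 1:vh))
  posIn <- function(arc, vi) match(vi, arc)
  lIds <- 1:10; rIds <- -(1:10)
  lV <- vidx[match(lIds, ids)]
  rV <- vidx[match(rIds, ids)]
  onF <- function(vs) !any(is.na(posIn(arcF, vs)))
  leftPath <- if (onF(lV)) arcF else if (onF(rev(lV)) || !any(is.na(posIn(arcB, lV)))) arcB else NULL
  if (is.null(leftPath))
    stopc("larvagram_malformed_annotation", "left-side points span both outline arcs")
  rightPath <- if (identical(leftPath, arcF)) arcB else arcF
  if (any(is.na(posIn(rightPath, rV))))
    stopc("larvagram_malformed_annotation", "right-side points span both outline arcs")
  if (is.unsorted(posIn(leftPath, lV), strictly = TRUE) ||
      is.unsorted(posIn(rightPath, rV), strictly = TRUE))
    stopc("larvagram_malformed_annotation",
          "boundary points are not ordered head to tail along the outline")
  new("SegmentAnnotation", outline = outline, ids = ids, vertexIndex = vidx,
      leftPath = leftPath, rightPath = rightPath,
      points = points[, c("point_id", "x", "y")])
}

sidePathArc <- function(annotation, side = c("left", "right")) {
  side <- match.arg(side)
  path <- if (side == "left") annotation@leftPath else annotation@rightPath
  pts <- annotation@outline@vertices[path, , drop = FALSE]
  list(path = path, pts = pts, s = polylineCumArc(pts))
}

## continuous arc position of a point near path position j: project onto
## the adjacent edges and take the closer foot
refineArcPos <- function(pt, pts, s, j) {
  best <- s[j]; bestD <- sum((pts[j, ] - pt)^2)
  for (e in c(j - 1, j)) {
    if (e < 1 || e >= nrow(pts)) next
    a <- pts[e, ]; b <- pts[e + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    tt <- clamp(sum((pt - a) * ab) / len2, 0, 1)
    foot <- a + tt * ab
    d2 <- sum((foot - pt)^2)
    if (d2 < bestD) { bestD <- d2; best <- s[e] + tt * sqrt(len2) }
  }
  best
}

#' Per-segment side boundary lengths
#'
#' Arc length of the outline between consecutive annotation points on each
#' side (positions refined to sub-vertex accuracy by projection); the
#' quantity entering the asymmetry index ln(L_right/L_left).
#'
#' @param annotation a [SegmentAnnotation-class]
#' @return matrix 11 x 2 (`left`, `right`), rownames T1..A8
#' @export
boundaryLengths <- function(annotation) {
  res <- matrix(NA_real_, 11, 2, dimnames = list(SEGMENT_NAMES, c("left", "right")))
  for (side in c("left", "right")) {
    sp <- sidePathArc(annotation, side)
    ids <- if (side == "left") c(0, 1:10, 11) else c(0, -(1:10), 11)
    ord <- match(ids, annotation@ids)
    vi <- annotation@vertexIndex[ord]
    pos <- match(vi, sp$path)
    sv <- vapply(seq_along(pos), function(k) {
      pt <- c(annotation@points$x[ord[k]], annotation@points$y[ord[k]])
      refineArcPos(pt, sp$pts, sp$s, pos[k])
    }, numeric(1))
    res[, side] <- diff(sv)
  }
  if (any(!is.finite(res)) || any(res <= 0))
    stopc("larvagram_invalid_argument", "non-positive or undefined side length")
  res
}

insetPolygon <- function(poly, d) {
  c0 <- colMeans(poly)
  r <- sqrt((poly[, 1] - c0[1])^2 + (poly[, 2] - c0[2])^2)
  f <- pmax(0.2, (r - d) / pmax(r, 1e-9))
  cbind(c0[1] + (poly[, 1] - c0[1]) * f, c0[2] + (poly[, 2] - c0[2]) * f)
}

#' Per-segment quadrant mean intensities
#'
#' Splits each segment into anterior/posterior x left/right quadrants using
#' the chord between the side-arc midpoints and the local midline, and
#' averages the pixel values inside each quadrant polygon (inset by one
#' pixel to avoid boundary mixing).
#'
#' @param annotation a [SegmentAnnotation-class]
#' @param frame numeric matrix `[row, col]` matching the outline's frame
#' @return list `quad` (11 x 4 matrix, AL/AR/PL/PR), `segment` (length-11
#'   mean), `npx` (pixel counts)
#' @export
quadrantIntensities <- function(annotation, frame) {
  H <- nrow(frame)
  quad <- matrix(NA_real_, 11, 4, dimnames = list(SEGMENT_NAMES, c("AL", "AR", "PL", "PR")))
  npx <- quad
  floorVal <- 0.01 * max(frame)
  spL <- sidePathArc(annotation, "left")
  spR <- sidePathArc(annotation, "right")
  bIdL <- c(0, 1:10, 11); bIdR <- c(0, -(1:10), 11)
  posL <- match(annotation@vertexIndex[match(bIdL, annotation@ids)], spL$path)
  posR <- match(annotation@vertexIndex[match(bIdR, annotation@ids)], spR$path)
  for (i in seq_len(11)) {
    L <- resamplePolyline(spL$pts[posL[i]:posL[i + 1], , drop = FALSE], 9)
    R <- resamplePolyline(spR$pts[posR[i]:posR[i + 1], , drop = FALSE], 9)
    M <- (L + R) / 2
    polys <- list(AL = rbind(L[1:5, ], M[5:1, ]), AR = rbind(R[1:5, ], M[5:1, ]),
                  PL = rbind(L[5:9, ], M[9:5, ]), PR = rbind(R[5:9, ], M[9:5, ]))
    for (k in seq_along(polys)) {
      p <- insetPolygon(polys[[k]], 1)
      pr <- cbind(p[, 1], H + 1 - p[, 2])  # (col, row) for pixel lookup
      pm <- polygonPixelMean(frame, pr)
      if (pm$n == 0 || !is.finite(pm$mean) || pm$mean <= floorVal)
        stopc("larvagram_degenerate_segment",
              sprintf("segment %s quadrant %s is empty or background-only",
                      SEGMENT_NAMES[i], names(polys)[k]))
      quad[i, k] <- pm$mean
      npx[i, k] <- pm$n
    }
  }
  list(quad = quad, segment = rowSums(quad * npx) / rowSums(npx), npx = npx)
}

#' Fractional change of a metric against a reference frame
#'
#' @param series numeric vector or matrix (rows = body coordinate,
#'   columns = frames)
#' @param referenceFrame column index of the reference
#' @return same shape as `series`: (x - x_ref) / x_ref
#' @export
fractionalChange <- function(series, referenceFrame) {
  m <- if (is.matrix(series)) series else matrix(series, nrow = 1)
  if (referenceFrame < 1 || referenceFrame > ncol(m))
    stopc("larvagram_invalid_reference", "reference frame out of range")
  ref <- m[, referenceFrame]
  if (any(ref == 0) || any(!is.finite(ref)))
    stopc("larvagram_invalid_reference", "zero or undefined reference value")
  out <- sweep(m, 1, ref, "/") - 1
  if (is.matrix(series)) out else as.numeric(out)
}

#' Left/right asymmetry index
#'
#' `a = ln(L_right / L_left)` per segment; positive for leftward bends
#' (the left side is the inner, shorter side).
#'
#' @param lenLeft,lenRight positive side lengths (vectors or matrices of
#'   matching shape)
#' @return same shape: the asymmetry index
#' @export
asymmetryIndex <- function(lenLeft, lenRight) {
  if (any(lenLeft <= 0, na.rm = TRUE) || any(lenRight <= 0, na.rm = TRUE))
    stopc("larvagram_invalid_argument", "side lengths must be positive")
  log(lenRight / lenLeft)
}

#' Assemble a kymograph
#'
#' @param series matrix (rows = body coordinate, columns = frames) or list
#'   of equal-length per-frame vectors
#' @param metric metric tag (see [Kymograph-class])
#' @param referenceFrame reference frame id (NA where not applicable)
#' @param frameRate frames per second
#' @param rowNames optional row names when `series` has none
#' @return a [Kymograph-class]
#' @export
buildKymograph <- function(series, metric, referenceFrame = NA_real_,
                           frameRate = 8, rowNames = NULL) {
  if (is.list(series)) {
    lens <- lengths(series)
    if (length(unique(lens)) != 1)
      stopc("larvagram_malformed_series", "ragged per-frame series")
    series <- do.call(cbind, series)
  }
  if (!is.matrix(series))
    stopc("larvagram_malformed_series", "series must be a matrix or list of vectors")
  if (!is.null(rowNames)) rownames(series) <- rowNames
  if (is.null(rownames(series))) rownames(series) <- SEGMENT_NAMES[seq_len(nrow(series))]
  new("Kymograph", data = series, metric = metric,
      referenceFrame = as.numeric(referenceFrame), frameRate = frameRate)
}

#' Choose a reference frame between peristalsis waves
#'
#' Among frames outside every detected wave interval, picks the one whose
#' segment lengths deviate least (total fractional deviation) from the
#' per-segment medians.
#'
#' @param lengthMatrix 11 x frames matrix of segment lengths (either side
#'   or their sum)
#' @param waves data.frame with `onset_frame`, `offset_frame` (may be
#'   empty)
#' @return frame id
#' @export
chooseReferenceFrame <- function(lengthMatrix, waves = NULL) {
  nf <- ncol(lengthMatrix)
  inWave <- rep(FALSE, nf)
  if (!is.null(waves) && nrow(waves)) {
    for (k in seq_len(nrow(waves))) {
      lo <- max(1, waves$onset_frame[k] - 2)
      hi <- min(nf, waves$offset_frame[k] + 2)
      inWave[lo:hi] <- TRUE
    }
  }
  cand <- which(!inWave & colSums(is.na(lengthMatrix)) == 0)
  if (!length(cand)) cand <- which(colSums(is.na(lengthMatrix)) == 0)
  if (!length(cand))
    stopc("larvagram_invalid_reference", "no complete frame available as reference")
  med <- apply(lengthMatrix, 1, median, na.rm = TRUE)
  score <- colSums(abs(sweep(lengthMatrix[, cand, drop = FALSE], 1, med, "/") - 1))
  cand[which.min(score)]
}
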