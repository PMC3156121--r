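# Rendering ground-truth geometry into 16-bit fluorescence frames.
#
# Each segment quadrant is drawn as a filled polygon whose mean intensity
# is calibration * rest_area / current_area, enforcing fluorophore
# conservation (contraction concentrates signal and brightens). The frame
# is recentered on the body centroid every frame, emulating the motorized
# tracking stage; the per-frame pixel origin is recorded so absolute
# positions can be recovered.

#' Assign the pixel grid (field of view and per-frame origins)
#'
#' Chooses a fixed field of view large enough for the body in every frame
#' plus a margin, and centers it on the per-frame body centroid.
#'
#' @param truth a [GroundTruth-class] with full geometry
#' @param config a [SimulationConfig-class]
#' @param marginPx margin around the body (px)
#' @return the truth with `origin_x_mm`, `origin_y_mm`, `px_w`, `px_h`
#'   filled in
#' @export
addPixelOrigins <- function(truth, config, marginPx = 14) {
  if (dim(truth@left)[1] < 10)
    stopc("larvagram_invalid_argument", "truth lacks full geometry; rerun with geometry='full'")
  s <- config@pixelScale
  nf <- nrow(truth@frames)
  exw <- exh <- numeric(nf)
  for (f in seq_len(nf)) {
    xs <- c(truth@left[, 1, f], truth@right[, 1, f])
    ys <- c(truth@left[, 2, f], truth@right[, 2, f])
    exw[f] <- max(xs) - min(xs)
    exh[f] <- max(ys) - min(ys)
  }
  W <- 2L * ceiling((max(exw) / s + 2 * marginPx) / 2)
  H <- 2L * ceiling((max(exh) / s + 2 * marginPx) / 2)
  fr <- truth@frames
  fr$origin_x_mm <- fr$centroid_x_mm - (W / 2) * s
  fr$origin_y_mm <- fr$centroid_y_mm + (H / 2) * s
  fr$px_w <- W
  fr$px_h <- H
  truth@frames <- fr
  truth
}

## world (mm, y-up) -> pixel (col, row) given a frame's origin
worldToPx <- function(xy, ox, oy, scale) {
  cbind((xy[, 1] - ox) / scale + 0.5, (oy - xy[, 2]) / scale + 0.5)
}

## pixel (col, yup) -> world mm
pxToWorld <- function(colv, yupv, ox, oy, scale, H) {
  cbind(ox + (colv - 0.5) * scale, oy - (H + 0.5 - yupv) * scale)
}

fillPolygon <- function(img, poly, value) {
  nr <- nrow(img); nc <- ncol(img)
  cmin <- max(1L, floor(min(poly[, 1]))); cmax <- min(nc, ceiling(max(poly[, 1])))
  rmin <- max(1L, floor(min(poly[, 2]))); rmax <- min(nr, ceiling(max(poly[, 2])))
  if (cmin > cmax || rmin > rmax) return(img)
  cols <- rep(cmin:cmax, times = rmax - rmin + 1)
  rows <- rep(rmin:rmax, each = cmax - cmin + 1)
  keep <- pointsInPolygon(cols, rows, poly)
  if (any(keep)) img[cbind(rows[keep], cols[keep])] <- value
  img
}

#' Render one frame (noise-free)
#'
#' @param truth a [GroundTruth-class] with pixel origins assigned
#' @param f frame number
#' @param config a [SimulationConfig-class]
#' @return numeric matrix `[row, col]` of intensities (counts)
#' @export
renderFrame <- function(truth, f, config) {
  fr <- truth@frames
  if (is.na(fr$origin_x_mm[f]))
    stopc("larvagram_invalid_argument", "pixel origins not assigned; call addPixelOrigins()")
  H <- fr$px_h[f]; W <- fr$px_w[f]
  ox <- fr$origin_x_mm[f]; oy <- fr$origin_y_mm[f]
  s <- config@pixelScale
  img <- matrix(0, H, W)
  for (i in seq_len(11)) {
    q <- segmentQuadrants(truth@left[, , f], truth@right[, , f], i)
    for (k in seq_along(q)) {
      poly <- worldToPx(q[[k]], ox, oy, s)
      if (min(poly[, 1]) < 1 || max(poly[, 1]) > W ||
          min(poly[, 2]) < 1 || max(poly[, 2]) > H)
        stopc("larvagram_out_of_frame", "body exceeds the field of view")
      img <- fillPolygon(img, poly, truth@quadIntensity[i, k, f])
    }
  }
  img
}

#' Render all frames of a ground truth
#'
#' Adds the configured additive Gaussian camera noise and quantizes to
#' 16-bit counts.
#'
#' @param truth a [GroundTruth-class] (origins assigned automatically)
#' @param config a [SimulationConfig-class]
#' @param seed seed for the noise stream
#' @return list with `images` (integer array `[row, col, frame]`) and
#'   `truth` (with pixel origins)
#' @export
renderFrames <- function(truth, config, seed = config@rngSeed) {
  if (is.na(truth@frames$origin_x_mm[1]))
    truth <- addPixelOrigins(truth, config)
  nf <- nrow(truth@frames)
  H <- truth@frames$px_h[1]; W <- truth@frames$px_w[1]
  set.seed(as.integer(seed) + 7L)
  sdN <- config@noiseSd * config@calibration
  images <- array(0L, c(H, W, nf))
  for (f in seq_len(nf)) {
    img <- renderFrame(truth, f, config)
    if (sdN > 0) img <- img + matrix(rnorm(H * W, 0, sdN), H, W)
    images[, , f] <- as.integer(round(clamp(img, 0, 65535)))
  }
  list(images = images, truth = truth)
}

#' Ground-truth segment-boundary annotation for one frame
#'
#' The 22 points where the head tip (id 0), the ten inter-segment
#' boundaries (+1..+10 left, -1..-10 right) and the tail tip (id 11)
#' meet the body boundary.
#'
#' @param truth a [GroundTruth-class] with pixel origins
#' @param f frame number
#' @param coords `"yup"` (vision-internal: col, H+1-row), `"px"` (col,
#'   row) or `"world"` (mm)
#' @return data.frame `frame`, `point_id`, `x`, `y`
#' @export
truthAnnotation <- function(truth, f, coords = c("yup", "px", "world")) {
  coords <- match.arg(coords)
  nsub <- 8L
  idxB <- (1:10) * nsub + 1
  np <- 11 * nsub + 1
  pts <- rbind(
    truth@spine[1, , f],                    # head tip, id 0
    truth@left[idxB, , f],                  # +1..+10
    truth@right[idxB, , f],                 # -1..-10
    truth@spine[np, , f]                    # tail tip, id 11
  )
  ids <- c(0, 1:10, -(1:10), 11)
  if (coords == "world")
    return(data.frame(frame = f, point_id = ids, x = pts[, 1], y = pts[, 2]))
  fr <- truth@frames
  px <- worldToPx(pts, fr$origin_x_mm[f], fr$origin_y_mm[f],
                  truth@config@pixelScale)
  if (coords == "px")
    data.frame(frame = f, point_id = ids, x = px[, 1], y = px[, 2])
  else
    data.frame(frame = f, point_id = ids, x = px[, 1],
               y = fr$px_h[f] + 1 - px[, 2])
}
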