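# Internal geometry and numerics helpers shared across modules.

#' @importFrom stats approx filter rnorm runif qnorm pnorm dnorm sd lm t.test
#'   median uniroot complete.cases
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed larvagram error
#'
#' All operational failures raise conditions of class
#' `c(<class>, "larvagram_error", "error")` so callers can trap specific
#' failure modes (e.g. `larvagram_no_larva`).
#' @noRd
stopc <- function(class, msg) {
  stop(structure(
    class = c(class, "larvagram_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

smoothstep <- function(x) {
  x <- clamp(x, 0, 1)
  x * x * (3 - 2 * x)
}

## rotate unit vectors by +90 degrees (counterclockwise in a y-up frame);
## for a tail-to-head tangent this points to the animal's left
leftNormal <- function(u) cbind(-u[, 2], u[, 1])

polylineCumArc <- function(p) {
  d <- sqrt(rowSums(diff(p)^2))
  c(0, cumsum(d))
}

polylineLength <- function(p) sum(sqrt(rowSums(diff(p)^2)))

#' Resample an open polyline to n points at equal arc-length spacing
#' @noRd
resamplePolyline <- function(p, n) {
  s <- polylineCumArc(p)
  if (s[length(s)] <= 0) return(matrix(rep(p[1, ], n), ncol = 2, byrow = TRUE))
  si <- seq(0, s[length(s)], length.out = n)
  cbind(approx(s, p[, 1], xout = si, ties = "ordered")$y,
        approx(s, p[, 2], xout = si, ties = "ordered")$y)
}

#' Interpolate a point at arc-length fraction f (0 = first vertex)
#' @noRd
polylinePointAt <- function(p, f) {
  s <- polylineCumArc(p)
  tot <- s[length(s)]
  c(approx(s, p[, 1], xout = f * tot, ties = "ordered")$y,
    approx(s, p[, 2], xout = f * tot, ties = "ordered")$y)
}

## signed polygon area; positive for counterclockwise orientation (y-up)
shoelaceArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygonCentroid <- function(p) colMeans(p)

#' Even-odd point-in-polygon test, vectorized over query points
#' @noRd
pointsInPolygon <- function(px, py, poly) {
  n <- length(px)
  inside <- rep(FALSE, n)
  m <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- m
  for (i in seq_len(m)) {
    yi <- ys[i]; yj <- ys[j]
    if (yi != yj) {
      xi <- xs[i]; xj <- xs[j]
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Mean of a frame's pixels whose centers fall inside a polygon (px coords)
#' @return list(mean, n)
#' @noRd
polygonPixelMean <- function(frame, poly) {
  nr <- nrow(frame); nc <- ncol(frame)
  cmin <- max(1L, floor(min(poly[, 1]))); cmax <- min(nc, ceiling(max(poly[, 1])))
  rmin <- max(1L, floor(min(poly[, 2]))); rmax <- min(nr, ceiling(max(poly[, 2])))
  if (cmin > cmax || rmin > rmax) return(list(mean = NA_real_, n = 0L))
  cols <- cmin:cmax; rows <- rmin:rmax
  grid <- expand.grid(col = cols, row = rows)
  keep <- pointsInPolygon(grid$col, grid$row, poly)
  if (!any(keep)) return(list(mean = NA_real_, n = 0L))
  vals <- frame[cbind(grid$row[keep], grid$col[keep])]
  list(mean = mean(vals), n = sum(keep))
}

#' Circular (wrap-around) Gaussian smoothing of a numeric vector
#' @noRd
circularGaussianSmooth <- function(v, sd) {
  if (sd <= 0) return(v)
  half <- max(1L, ceiling(3 * sd))
  k <- dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  as.numeric(stats::filter(v, k, method = "convolution", sides = 2,
                           circular = TRUE))
}

## boxcar moving average (non-circular, edges use shrinking windows)
boxcarSmooth <- function(v, width) {
  if (width <= 1) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  half <- floor(width / 2)
  lo <- pmax(0, seq_len(n) - 1 - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

## local maxima of a circular series: strictly above both neighbours
localMaximaCircular <- function(v) {
  prev <- c(v[length(v)], v[-length(v)])
  nxt <- c(v[-1], v[1])
  which(v > prev & v >= nxt)
}

## local maxima of an open series (interior points only)
localMaxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- 2:(n - 1)
  idx[v[idx] > v[idx - 1] & v[idx] >= v[idx + 1]]
}

#' Signed angle (degrees) from vector v1 to vector v2, positive
#' counterclockwise in a y-up frame
#' @noRd
signedAngleDeg <- function(v1, v2) {
  cr <- v1[1] * v2[2] - v1[2] * v2[1]
  dt <- v1[1] * v2[1] + v1[2] * v2[2]
  if (cr == 0 && dt == 0) stopc("larvagram_degenerate", "zero-length vector in angle computation")
  atan2(cr, dt) * 180 / pi
}

#' Draws from a normal distribution truncated to [lower, upper]
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## mean of a normal truncated to [lower, upper]
truncnormMean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / Z
}

#' Solve for the mu parameter so that the [lower, upper]-truncated normal
#' has the requested mean
#' @noRd
truncnormMeanParam <- function(targetMean, sd, lower, upper) {
  f <- function(mu) truncnormMean(mu, sd, lower, upper) - targetMean
  uniroot(f, lower = targetMean - 4 * sd, upper = targetMean + 4 * sd,
          extendInt = "yes")$root
}

## segment labels in head-to-tail order; used everywhere
SEGMENT_NAMES <- c("T1", "T2", "T3", "A1", "A2", "A3", "A4", "A5", "A6", "A7", "A8")

segmentIndex <- function(label) {
  i <- match(label, SEGMENT_NAMES)
  if (any(is.na(i))) stopc("larvagram_invalid_argument",
                           paste("unknown segment label:", paste(label[is.na(i)], collapse = ", ")))
  i
}
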