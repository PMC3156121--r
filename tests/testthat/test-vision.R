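test_that("thresholding and morphology isolate the body and reject speckle", {
  expect_error(segmentBody(matrix(0, 50, 50)), class = "larvagram_no_larva")

  frame <- diskFrame(80, 80, 40, 40, 20, value = 1000) + 10
  mask <- segmentBody(frame, visionConfig())
  body <- frame > 500
  expect_gt(sum(mask & body) / sum(body), 0.99)   # opening may trim edge px
  expect_equal(sum(mask & !body), 0)

  ## single-pixel salt specks are removed by the erosion/dilation pass
  salted <- frame
  set.seed(1)
  idx <- cbind(sample(1:80, 30), sample(1:80, 30))
  keep <- (idx[, 1] - 40)^2 + (idx[, 2] - 40)^2 > 26^2
  salted[idx[keep, , drop = FALSE]] <- 1200
  maskS <- segmentBody(salted, visionConfig())
  expect_false(any(maskS[idx[keep, , drop = FALSE]]))
  expect_gt(sum(maskS & body) / sum(body), 0.98)
})

test_that("outline extraction recovers analytic shapes", {
  frame <- diskFrame(120, 120, 60, 60, 40)
  ol <- extractOutline(segmentBody(frame, visionConfig()), visionConfig())
  per <- sum(sqrt(rowSums((ol@vertices[c(2:nrow(ol@vertices), 1), ] -
                             ol@vertices)^2)))
  expect_equal(per, 2 * pi * 40, tolerance = 0.02 * 2 * pi * 40)

  ## two components: the larger is selected
  two <- frame
  two[5:12, 5:12] <- 1000
  ol2 <- extractOutline(two > 500, visionConfig())
  cen <- colMeans(ol2@vertices)
  expect_equal(cen, c(60.5, 60.5), tolerance = 2)

  ## tiny component -> too-small signal
  tiny <- matrix(FALSE, 40, 40); tiny[20:21, 20:22] <- TRUE
  expect_error(extractOutline(tiny, visionConfig()), class = "larvagram_too_small")

  ## zero smoothing leaves vertices unchanged
  v0 <- extractOutline(frame > 500, visionConfig(boundarySmoothFrac = 0))
  v1 <- extractOutline(frame > 500, visionConfig(boundarySmoothFrac = 1e-9))
  expect_identical(v0@vertices, v1@vertices)
})

test_that("windowed curvature matches analytic values", {
  frame <- diskFrame(120, 120, 60, 60, 40)
  ol <- extractOutline(segmentBody(frame, visionConfig()), visionConfig())
  k <- outlineCurvature(ol, 0.2)
  expect_equal(mean(k), 1 / 40, tolerance = 0.02)
  expect_lt(stats::sd(k) / mean(k), 0.1)

  ## ellipse: the two global maxima sit at the major-axis endpoints
  olE <- extractOutline(ellipseMask(140, 200, 100, 70, 80, 35), visionConfig())
  kE <- outlineCurvature(olE, 0.2)
  top <- order(kE, decreasing = TRUE)[1:2]
  xs <- sort(olE@vertices[top, 1])
  expect_lt(abs(xs[1] - 20), 4)
  expect_lt(abs(xs[2] - 180), 4)

  ## square with a small window: maxima at the corners, ~0 on edges
  sq <- matrix(FALSE, 80, 80); sq[20:60, 20:60] <- TRUE
  olS <- extractOutline(sq, visionConfig(boundarySmoothFrac = 0.002))
  kS <- outlineCurvature(olS, 0.05)
  corners <- rbind(c(20, 80 - 20 + 1), c(20, 80 - 60 + 1),
                   c(60, 80 - 20 + 1), c(60, 80 - 60 + 1))
  for (i in 1:4) {
    d <- sqrt((olS@vertices[, 1] - corners[i, 1])^2 +
                (olS@vertices[, 2] - corners[i, 2])^2)
    expect_gt(max(kS[d < 5]), 0.1)
  }
  edgeMid <- which(abs(olS@vertices[, 1] - 40) < 3 &
                     olS@vertices[, 2] > 55)
  expect_lt(max(abs(kS[edgeMid])), 0.02)

  expect_error(outlineCurvature(olS, 0.6), class = "larvagram_invalid_argument")
})

test_that("head/tail assignment follows the prior, not the geometry", {
  olE <- extractOutline(ellipseMask(140, 200, 100, 70, 80, 35), visionConfig())
  kE <- outlineCurvature(olE, 0.2)
  a <- locateHeadTail(olE, kE, list(head = c(185, 70), tail = c(15, 70)))
  expect_gt(olE@vertices[a@headIndex, 1], 150)
  expect_lt(olE@vertices[a@tailIndex, 1], 50)
  ## swapped prior swaps the labels
  b <- locateHeadTail(olE, kE, list(head = c(15, 70), tail = c(185, 70)))
  expect_equal(b@headIndex, a@tailIndex)
  expect_equal(b@tailIndex, a@headIndex)
  expect_error(locateHeadTail(olE, kE, NULL), class = "larvagram_invalid_argument")
})

test_that("the centerline of symmetric shapes lies on the symmetry axis", {
  ## axis-aligned rectangle, head/tail at the short-side midpoints
  rect <- matrix(FALSE, 60, 160); rect[20:40, 20:140] <- TRUE
  ol <- extractOutline(rect, visionConfig())
  v <- ol@vertices
  ol@headIndex <- which.min((v[, 1] - 141)^2 + (v[, 2] - 30.5)^2)
  ol@tailIndex <- which.min((v[, 1] - 19)^2 + (v[, 2] - 30.5)^2)
  cl <- computeCenterline(ol, visionConfig())
  expect_lt(max(abs(cl@points[, 2] - 30.5)), 1.5)
  ## near zero; limited by the +-0.5 px placement of the end vertices
  expect_lt(abs(bendAngle(cl)), 4)

  ## bent tube (quarter annulus): centerline approximates the mid-radius arc
  H <- 70; W <- 70
  m <- matrix(FALSE, H, W)
  for (rr in seq_len(H)) {
    x <- seq_len(W) - 5; y <- (H - rr + 1) - 5
    rad2 <- x^2 + y^2
    m[rr, rad2 >= 20^2 & rad2 <= 40^2 & x >= 0 & y >= 0] <- TRUE
  }
  olA <- extractOutline(m, visionConfig())
  vx <- olA@vertices[, 1] - 5; vy <- olA@vertices[, 2] - 5
  hIdx <- which.min((vx - 30)^2 + vy^2)
  tIdx <- which.min(vx^2 + (vy - 30)^2)
  olA@headIndex <- hIdx; olA@tailIndex <- tIdx
  clA <- computeCenterline(olA, visionConfig())
  rad <- sqrt((clA@points[, 1] - 5)^2 + (clA@points[, 2] - 5)^2)
  expect_lt(max(abs(rad[10:40] - 30)), 2)
})

test_that("grossly unequal side arcs raise a self-occlusion signal", {
  rect <- matrix(FALSE, 60, 160); rect[20:40, 20:140] <- TRUE
  ol <- extractOutline(rect, visionConfig())
  ol@headIndex <- 1
  ol@tailIndex <- 5  # splits the boundary into absurdly unequal arcs
  expect_error(computeCenterline(ol, visionConfig()),
               class = "larvagram_self_occlusion")
})

test_that("bend angle follows the tail/midpoint and 3/4-point/head chords", {
  ## polyline through tail (0,0), midpoint (1,0), 3/4-point (1.5,0),
  ## head (1.5,0.5): arc fractions from the tail are 1/2, 3/4, 1
  seg <- function(a, b, n) cbind(seq(a[1], b[1], length.out = n),
                                 seq(a[2], b[2], length.out = n))
  path <- rbind(seg(c(1.5, 0.5), c(1.5, 0), 26)[-26, ],
                seg(c(1.5, 0), c(1, 0), 26)[-26, ],
                seg(c(1, 0), c(0, 0), 51))
  cl <- new("Centerline", points = path)
  expect_equal(bendAngle(cl), 90, tolerance = 1e-6)

  ## mirror reflection negates the angle
  mir <- path; mir[, 2] <- -mir[, 2]
  expect_equal(bendAngle(new("Centerline", points = mir)), -90, tolerance = 1e-6)

  ## rigid motions leave it unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- sweep(path %*% t(R), 2, c(3, -2), "+")
  expect_equal(bendAngle(new("Centerline", points = rot)), 90, tolerance = 1e-6)
})

test_that("head-sweep flagging uses threshold, hysteresis and sign", {
  vis <- visionConfig()
  expect_equal(nrow(detectHeadSweeps(rep(0, 100), vis)), 0)

  ramp <- c(rep(0, 10), seq(0, 60, 5), rep(60, 4), seq(60, 0, -5), rep(0, 10))
  ev <- detectHeadSweeps(ramp, vis)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "left")
  expect_equal(ev$peak_deg, 60)
  expect_equal(ev$size_class, "small")
  ## onset at the first frame at or above 40 degrees
  expect_equal(ramp[ev$onset_frame], 40)

  ## +70 then -110 with a brief 10-degree return: two events
  tr <- c(rep(0, 5), seq(0, 70, 10), rep(70, 4), seq(70, 10, -15), rep(10, 2),
          seq(10, -110, -20), rep(-110, 4), seq(-110, 0, 15), rep(0, 5))
  ev2 <- detectHeadSweeps(tr, vis)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$direction, c("left", "right"))
  expect_equal(ev2$size_class, c("small", "large"))

  ## brief dropout inside a sweep does not split it
  gap <- ramp; gap[25:26] <- NA
  expect_equal(nrow(detectHeadSweeps(gap, vis)), 1)
})
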