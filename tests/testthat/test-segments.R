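noiselessFrameSetup <- function() {
  rv <- runVideoFixture()
  f <- 10
  img <- rv$ds@images[, , f]
  ol <- extractOutline(segmentBody(img, visionConfig()), visionConfig(), f)
  annT <- truthAnnotation(rv$truth, f, "yup")
  names(annT) <- c("frame", "point_id", "x", "y")
  list(rv = rv, f = f, img = img, ol = ol, annT = annT)
}

test_that("ground-truth annotation resolves onto the extracted outline", {
  s <- noiselessFrameSetup()
  ann <- resolveAnnotation(s$annT, s$ol)
  ## snap displacement below one pixel for every point on a noiseless render
  v <- s$ol@vertices
  d <- vapply(seq_len(22), function(k)
    min(sqrt((v[, 1] - s$annT$x[k])^2 + (v[, 2] - s$annT$y[k])^2)), numeric(1))
  expect_lt(max(d), 1.25)
  expect_lt(max(d[!s$annT$point_id %in% c(0, 11)]), 1)

  ## shuffled ids -> malformed; large offset -> misregistration
  bad <- s$annT; bad$point_id[2:3] <- bad$point_id[3:2] + 100
  expect_error(resolveAnnotation(bad, s$ol), class = "larvagram_malformed_annotation")
  off <- s$annT; off$x <- off$x + 10
  expect_error(resolveAnnotation(off, s$ol), class = "larvagram_misregistration")
})

test_that("side arc lengths recover ground truth on noiseless frames", {
  s <- noiselessFrameSetup()
  ann <- resolveAnnotation(s$annT, s$ol)
  bl <- boundaryLengths(ann)
  scale <- s$rv$cfg@pixelScale
  relL <- bl[, "left"] * scale / s$rv$truth@segLenLeft[, s$f] - 1
  relR <- bl[, "right"] * scale / s$rv$truth@segLenRight[, s$f] - 1
  ## interior segments within 2%; tip segments are harder (their side
  ## lengths hinge on the exact tip position) and get a looser bound
  interior <- 2:10
  expect_lt(max(abs(relL[interior])), 0.02)
  expect_lt(max(abs(relR[interior])), 0.02)
  expect_lt(max(abs(c(relL[c(1, 11)], relR[c(1, 11)]))), 0.10)
  ## a straight-bodied larva is left/right symmetric
  expect_lt(max(abs(log(bl[interior, "right"] / bl[interior, "left"]))), 0.02)
})

test_that("quadrant intensities recover the rendered values", {
  s <- noiselessFrameSetup()
  ann <- resolveAnnotation(s$annT, s$ol)
  qi <- quadrantIntensities(ann, s$img)
  rel <- qi$quad / s$rv$truth@quadIntensity[, , s$f] - 1
  expect_lt(max(abs(rel)), 0.02)
  ## a background-only polygon is flagged as degenerate: the body is
  ## absent under the annotation, only a bright corner elsewhere
  dark <- matrix(0, nrow(s$img), ncol(s$img))
  dark[1:5, 1:5] <- 10000
  expect_error(quadrantIntensities(ann, dark),
               class = "larvagram_degenerate_segment")
})

test_that("fractional change is exact arithmetic with a guarded reference", {
  m <- matrix(c(1, 1, 1.1, 2), 2, 2)
  fc <- fractionalChange(m, 1)
  expect_equal(fc[, 1], c(0, 0))
  expect_equal(fc[1, 2], 0.1)
  expect_equal(fc[2, 2], 1)
  expect_equal(fractionalChange(c(1, 1.1), 1), c(0, 0.1))
  expect_error(fractionalChange(matrix(c(0, 1), 1), 1),
               class = "larvagram_invalid_reference")
})

test_that("the asymmetry index is the signed log length ratio", {
  expect_equal(asymmetryIndex(1, 1), 0)
  expect_equal(asymmetryIndex(1, 1.2), log(1.2))
  expect_equal(asymmetryIndex(1.2, 1), -log(1.2))
  a <- asymmetryIndex(c(1, 2), c(1.5, 1))
  expect_equal(asymmetryIndex(c(1.5, 1), c(1, 2)), -a)
  expect_error(asymmetryIndex(0, 1), class = "larvagram_invalid_argument")
})

test_that("kymograph assembly validates shape and keeps order", {
  m <- matrix(rnorm(33), 11, 3, dimnames = list(larvagram:::SEGMENT_NAMES, NULL))
  ky <- buildKymograph(m, "asymmetry", frameRate = 8)
  expect_equal(dim(kymoData(ky)), c(11, 3))
  expect_equal(kymoMetric(ky), "asymmetry")
  ragged <- list(1:11, 1:10)
  expect_error(buildKymograph(ragged, "asymmetry"),
               class = "larvagram_malformed_series")
})

test_that("the reference frame is chosen between waves", {
  rv <- runVideoFixture()
  segLen <- rv$meas$lenLeft + rv$meas$lenRight
  ref <- rv$ev$referenceFrame
  waves <- rv$ev$waves
  inWave <- any(waves$onset_frame - 2 <= ref & ref <= waves$offset_frame + 2)
  expect_false(inWave)
  ## at the reference, fractional change is identically zero
  expect_true(all(kymoData(rv$ev$kymoLength)[, ref] == 0))
})
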