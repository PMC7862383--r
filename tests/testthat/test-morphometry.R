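test_that("circularity matches analytic oracles exactly", {
  r <- 250
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  a <- 7
  expect_equal(circularity(a^2, 4 * a), pi / 4, tolerance = 1e-12)
  # 3-4-5 right triangle: area 6, perimeter 12
  expect_equal(circularity(6, 12), pi / 6, tolerance = 1e-12)
  expect_error(circularity(0, 1), "> 0")
  expect_error(circularity(1, -1), "> 0")
  # scale invariance on polygons: scaling lengths by k scales area by k^2
  for (k in c(0.1, 3, 42)) {
    expect_equal(circularity(6 * k^2, 12 * k), pi / 6, tolerance = 1e-12)
    expect_equal(circularity(k^2, 4 * k), pi / 4, tolerance = 1e-12)
  }
})

test_that("Crofton perimeter converges on digital disks", {
  for (dpx in c(100, 200)) {
    m <- digitalDisk(dpx, 1)
    p <- croftonPerimeter(m, 1)
    expect_lt(abs(p - pi * dpx) / (pi * dpx), 0.02)
    circ <- circularity(sum(m), p)
    expect_gt(circ, 0.98)
    expect_lt(circ, 1.02)
  }
})

test_that("segmentation finds each post and hole exactly once", {
  d <- makeCheckerboardDesign(rows = 3L, cols = 4L)
  r <- renderFeatureLayer(d, imagingConfig(blurSigma = 0, noiseSd = 0,
                                           background = 0, seed = 1L))
  postLab <- segmentFeatures(channelImage(r, "post"), 5, "post",
                             threshold = "half-max")
  holeLab <- segmentFeatures(channelImage(r, "lattice"), 5, "hole",
                             threshold = "half-max")
  expect_identical(max(postLab), 12L)
  expect_identical(max(holeLab), 12L)
  # deterministic row-major label order: label 1 is the topmost-first blob
  first1 <- which(t(postLab) == 1L)[1]
  firstAll <- vapply(1:12, function(k) which(t(postLab) == k)[1], numeric(1))
  expect_identical(order(firstAll), 1:12)
})

test_that("a blank image yields zero features with a warning", {
  expect_warning(lab <- segmentFeatures(matrix(0, 50, 50), 5, "post"),
                 "blank")
  expect_identical(max(lab), 0L)
  expect_identical(nrow(measureFeatures(lab)), 0L)
})

test_that("measured disks recover diameter and circularity without bias", {
  # rendered disks across the meso-scale range, noise-free at 5 um/px
  for (diam in c(100, 300, 500, 1000)) {
    ps <- 5
    n <- as.integer(ceiling((diam + 200) / ps))
    d <- PrintDesign(list(layerSpec(0L, 100, list(
      ink = list(diskShape(rep(n * ps / 2, 2), diam))))),
      materialTable("ink"), rep(n * ps, 2),
      projector = ProjectorConfig(pixelPitch = ps, resolution = c(n, n)))
    cov <- mmsla:::coverageMatrix(d@layers[[1]]$regions$ink, n, n, ps, 4L)
    lab <- segmentFeatures(cov, ps, "post", threshold = 0.5,
                           minArea = 100)
    m <- measureFeatures(lab)
    expect_identical(nrow(m), 1L)
    expect_lt(abs(m$equivalentDiameter - diam), ps / 2)
    if (diam >= 500) {
      expect_gt(m$circularity, 0.98)
      expect_lt(m$circularity, 1.02)
    }
    # centroid lands on the true center to sub-pixel accuracy
    expect_lt(abs(m$x - n * ps / 2), ps / 2)
    expect_lt(abs(m$y - n * ps / 2), ps / 2)
  }
})

test_that("single-pixel feature measures one pixel of area", {
  lab <- matrix(0L, 10, 10)
  lab[4, 7] <- 1L
  attr(lab, "pixelSize") <- 5
  attr(lab, "featureClass") <- "post"
  m <- measureFeatures(lab)
  expect_equal(m$area, 25)
  expect_equal(m$x, 6.5 * 5)
  expect_equal(m$y, 3.5 * 5)
  expect_equal(m$equivalentDiameter, 2 * sqrt(25 / pi), tolerance = 1e-9)
})

test_that("nearest-neighbor distances equal the brute-force oracle", {
  expect_equal(nearestNeighborDistances(rbind(c(0, 0), c(3, 4))), c(5, 5))
  d <- makeCheckerboardDesign(rows = 4L, cols = 4L)
  expect_equal(nearestNeighborDistances(postCenters(d)), rep(1000, 16))
  withr::local_seed(7)
  for (n in c(50, 500)) {
    pts <- matrix(stats::runif(2 * n, 0, 10000), ncol = 2)
    expect_equal(nearestNeighborDistances(pts), bruteForceNND(pts))
  }
})

test_that("post/hole pairing is mutual, gated and symmetric", {
  withr::local_seed(1)
  pts <- matrix(stats::runif(40, 0, 5000), ncol = 2)
  # identical sets: perfect bijection at zero error
  p0 <- pairPostsHoles(pts, pts, maxPairDistance = 100)
  expect_identical(nrow(p0$pairs), 20L)
  expect_equal(p0$pairs$error, rep(0, 20))

  # uniform (30, 40) shift: every error exactly 50
  p1 <- pairPostsHoles(pts, sweep(pts, 2, c(-30, -40)),
                       maxPairDistance = 500)
  expect_identical(nrow(p1$pairs), 20L)
  expect_equal(p1$pairs$error, rep(50, 20))

  # an extra far-away hole stays unpaired
  holes <- rbind(pts, c(99999, 99999))
  p2 <- pairPostsHoles(pts, holes, maxPairDistance = 100)
  expect_identical(nrow(p2$pairs), 20L)
  expect_identical(p2$unpairedHoles, 21L)

  # swapping roles transposes the pairing but preserves the error multiset
  d <- makeCheckerboardDesign(rows = 3L, cols = 3L)
  ctr <- postCenters(d)
  jit <- ctr + matrix(stats::rnorm(length(ctr), 0, 20), ncol = 2)
  a <- pairPostsHoles(ctr, jit)
  b <- pairPostsHoles(jit, ctr)
  expect_equal(sort(a$pairs$error), sort(b$pairs$error))
  expect_identical(a$pairs$postLabel[order(a$pairs$holeLabel)],
                   b$pairs$holeLabel[order(b$pairs$postLabel)])
})

test_that("summary reports the strict below-threshold fraction", {
  meas <- data.frame(label = 1:3, class = "post",
                     area = pi * 250^2, perimeter = 2 * pi * 250,
                     equivalentDiameter = 500, circularity = 1,
                     x = c(0, 1000, 2000), y = 0)
  pairs <- data.frame(postLabel = 1:3, holeLabel = 1:3,
                      error = c(10, 20, 60))
  rep <- summarizeMorphometry(meas, pairs, threshold = 50)
  expect_equal(fractionBelowThreshold(rep), 2 / 3)
  # an error exactly at the threshold does not count (strict inequality)
  repEdge <- summarizeMorphometry(meas, transform(pairs, error = c(10, 50, 60)),
                                  threshold = 50)
  expect_equal(fractionBelowThreshold(repEdge), 1 / 3)
  repZero <- summarizeMorphometry(meas, transform(pairs, error = 0),
                                  threshold = 50)
  expect_equal(fractionBelowThreshold(repZero), 1)
  expect_error(summarizeMorphometry(meas[0, ], pairs), "no measurements")
})

test_that("per-batch alignment fractions are reported alongside pooled", {
  meas <- data.frame(label = 1:2, class = "post", area = 1, perimeter = 1,
                     equivalentDiameter = 500, circularity = 1,
                     x = c(0, 1000), y = 0)
  pairs <- data.frame(postLabel = 1:6, holeLabel = 1:6,
                      error = c(10, 10, 60, 10, 10, 10),
                      batch = rep(c("b1", "b2"), each = 3))
  rep <- summarizeMorphometry(meas, pairs, threshold = 50)
  expect_equal(fractionBelowThreshold(rep), 5 / 6)
  expect_equal(rep@perBatchFraction,
               c(b1 = 2 / 3, b2 = 1))
})

test_that("jittered renders recover the placement-error distribution", {
  # end-to-end parameter recovery across jitter levels, holes fixed
  d <- makeCheckerboardDesign(rows = 5L, cols = 5L)
  for (sigma in c(5, 15, 30)) {
    r <- renderFeatureLayer(d, imagingConfig(blurSigma = 0, noiseSd = 0,
                                             background = 0, seed = 21L),
                            fidelityModel(placementJitterSd = sigma))
    a <- analyzeCheckerboard(r, segmentation = "half-max")
    err <- alignmentErrors(a$report)
    n <- length(err)
    expect_identical(n, 25L)
    se <- sigma * sqrt(2 - pi / 2) / sqrt(n)
    expect_lt(abs(mean(err) - sigma * sqrt(pi / 2)), 3 * se)
    # measured errors track ground truth to within one imaging pixel
    gt <- groundTruth(r)
    p <- gt[gt$class == "post", ]
    h <- gt[gt$class == "hole", ]
    trueErr <- sqrt((p$x - h$x[match(p$pairId, h$pairId)])^2 +
                    (p$y - h$y[match(p$pairId, h$pairId)])^2)
    meas <- a$measurements
    posts <- meas[meas$class == "post", ]
    ord <- apply(outer(posts$x, p$x, function(a, b) abs(a - b)) +
                 outer(posts$y, p$y, function(a, b) abs(a - b)),
                 1, which.min)
    pairedErr <- a$report@alignment$error[
      match(posts$label, a$report@alignment$postLabel)]
    expect_lt(mean(abs(pairedErr - trueErr[ord])), r@pixelSize)
  }
})
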