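test_that("label maps peak at 1 with the mean-then-normalise construction", {
  # one centre: exactly 1 at the centre, isotropic sigma = 1 decay
  L1 <- buildLabel(matrix(c(10, 12), 1), c(24, 24))
  expect_equal(L1[10, 12], 1)
  expect_equal(L1[11, 12], exp(-0.5), tolerance = 1e-12)
  expect_equal(L1[10, 13], exp(-0.5), tolerance = 1e-12)
  expect_equal(L1[11, 13], exp(-1), tolerance = 1e-12)

  # two far-apart centres: mean halves the peaks, normalisation restores 1
  cen <- matrix(c(5, 5, 20, 20), 2, byrow = TRUE)
  raw <- (exp(-((row(matrix(0, 24, 24)) - 5)^2 +
                (col(matrix(0, 24, 24)) - 5)^2) / 2) +
          exp(-((row(matrix(0, 24, 24)) - 20)^2 +
                (col(matrix(0, 24, 24)) - 20)^2) / 2)) / 2
  expect_equal(max(raw), 0.5, tolerance = 1e-6)
  L2 <- buildLabel(cen, c(24, 24))
  expect_equal(L2[5, 5], 1, tolerance = 1e-6)
  expect_equal(L2[20, 20], 1, tolerance = 1e-6)

  # zero centres: all-zero map, normalisation skipped
  expect_equal(buildLabel(matrix(numeric(), 0, 2), c(8, 8)), matrix(0, 8, 8))
  expect_error(buildLabel(matrix(c(30, 2), 1), c(24, 24)), "outside")

  # well-separated centres dominate every non-centre pixel
  L3 <- buildLabel(matrix(c(6, 6, 18, 18), 2, byrow = TRUE), c(24, 24))
  centreVals <- L3[cbind(c(6, 18), c(6, 18))]
  L3[cbind(c(6, 18), c(6, 18))] <- -Inf
  expect_true(min(centreVals) >= max(L3))
})

test_that("local maxima match the exhaustive 8-neighbour scan oracle", {
  g <- buildLabel(matrix(c(7, 9), 1), c(16, 16))
  m <- localMaxima(g)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$row, m$col), c(7, 9))
  expect_equal(nrow(localMaxima(matrix(3, 6, 6))), 0L)  # constant map

  # interior plateau surrounded by smaller values -> centroid candidate
  p <- matrix(0, 9, 9)
  p[4:5, 4:6] <- 2
  mp <- localMaxima(p)
  expect_equal(nrow(mp), 1L)
  expect_equal(c(mp$row, mp$col), c(round(4.5), 5))

  withr::with_seed(99, {
    for (i in 1:200) {
      # mix of continuous maps and quantised ones (to exercise plateaus)
      map <- matrix(runif(144), 12, 12)
      if (i %% 2 == 0) map <- round(map * 8) / 8
      a <- localMaxima(map)
      b <- oracleMaxima(map)
      expect_equal(a[order(a$row, a$col), c("row", "col", "value")],
                   b[order(b$row, b$col), c("row", "col", "value")],
                   ignore_attr = TRUE)
    }
  })
})

test_that("detection matching honours the 2-voxel Euclidean tolerance", {
  ann <- matrix(c(10, 10), 1)
  candAt <- function(r, c, v = 0.9) data.frame(row = r, col = c, value = v)
  expect_equal(matchDetections(candAt(10, 12), ann, 0.5)$tp, 1L)   # d = 2.0
  m <- matchDetections(candAt(11, 12), ann, 0.5)                   # d = sqrt(5)
  expect_equal(m$tp, 0L)
  expect_equal(m$fp, 1L)
  # below-threshold candidates are dropped entirely
  expect_equal(matchDetections(candAt(10, 10, v = 0.3), ann, 0.5)$fp, 0L)
  # each annotation is matched at most once
  two <- rbind(candAt(10, 10, 0.9), candAt(10, 11, 0.8))
  m2 <- matchDetections(two, ann, 0.5)
  expect_equal(m2$tp, 1L)
  expect_equal(m2$fp, 1L)
})

test_that("greedy matching equals optimal assignment for separated targets", {
  withr::with_seed(13, {
    for (i in 1:50) {
      na <- sample(1:4, 1)
      # annotations separated by > 2 * tolerance on a coarse grid
      ann <- unique(matrix(5 * sample(1:8, 2 * na, replace = TRUE), ncol = 2))
      nc <- sample(0:nrow(ann), 1)
      cand <- data.frame(row = numeric(0), col = numeric(0), value = numeric(0))
      if (nc > 0) {
        pick <- sample(nrow(ann), nc)
        cand <- data.frame(row = ann[pick, 1] + runif(nc, -1.4, 1.4),
                           col = ann[pick, 2] + runif(nc, -1.4, 1.4),
                           value = runif(nc, 0.5, 1))
      }
      got <- matchDetections(cand, ann, threshold = 0.5, tolerance = 2)
      expect_equal(got$tp, oracleAssignment(cand, ann, 2))
      expect_equal(got$tp + got$fp, nrow(cand))
    }
  })
})

test_that("threshold sweep on perfect and degenerate maps gives the expected counts", {
  shape <- c(32, 32)
  cen <- matrix(c(8, 8, 8, 24, 24, 8, 24, 24, 16, 16), ncol = 2, byrow = TRUE)
  lab <- buildLabel(cen, shape, sigma = c(1, 1))
  imgs <- array(0, c(shape, 3))
  cfg <- detectionConfig(epochs = 1L)
  # likelihood maps equal to the labels: all markers at every threshold
  met <- sweepEvaluate(NULL, imgs, annotations = cen, config = cfg,
                       maps = rep(list(lab), 3))
  expect_true(all(met@perFrame$tp == nrow(cen)))
  expect_true(all(met@perFrame$fp == 0))
  expect_equal(met@summary$tp_median, nrow(cen))
  expect_true(all(met@perFrame$tp <= met@perFrame$n_annotated))

  # all-zero maps: nothing detected, nothing false
  met0 <- sweepEvaluate(NULL, imgs, annotations = cen, config = cfg,
                        maps = rep(list(matrix(0, 32, 32)), 3))
  expect_true(all(met0@perFrame$tp == 0))
  expect_true(all(met0@perFrame$fp == 0))

  # one spurious strong peak: fp = 1 below its value, 0 above
  spur <- lab
  spur[2, 30] <- 0.62
  met1 <- sweepEvaluate(NULL, imgs[, , 1, drop = FALSE], annotations = cen,
                        config = cfg, maps = list(spur))
  pf <- met1@perFrame
  expect_true(all(pf$fp[pf$threshold <= 0.6] == 1))
  expect_true(all(pf$fp[pf$threshold > 0.65] == 0))
})

test_that("tp and fp are non-increasing in the threshold", {
  withr::with_seed(55, {
    cen <- matrix(c(6, 6, 6, 18, 18, 12), ncol = 2, byrow = TRUE)
    map <- buildLabel(cen, c(24, 24)) * 0.9 +
      matrix(runif(576, 0, 0.15), 24, 24)
    map <- pmin(map, 1)
    cfg <- detectionConfig(epochs = 1L)
    met <- sweepEvaluate(NULL, array(0, c(24, 24, 1)), annotations = cen,
                         config = cfg, maps = list(map))
    pf <- met@perFrame[order(met@perFrame$threshold), ]
    expect_true(all(diff(pf$tp) <= 0))
    expect_true(all(diff(pf$fp) <= 0))
    expect_true(all(pf$tp >= 0 & pf$tp <= pf$n_annotated))
  })
})
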