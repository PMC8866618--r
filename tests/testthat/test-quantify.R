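test_that("frame discard drops exactly the leading frames", {
  s <- cachedSeries("disc", simulateSeries(smallPhantom(), NULL, smallAcq(),
                                           30, seed = 8))
  expect_equal(nFrames(discardInitialFrames(s, 5L)), 25L)
  expect_identical(discardInitialFrames(s, 0L), s)
  s6 <- MarkerSeries(frames(s)[, , 1:6], acq = acqParams(s))
  s1 <- discardInitialFrames(s6, 5L)
  expect_equal(nFrames(s1), 1L)
  expect_equal(frames(s1)[, , 1], frames(s)[, , 6])
  expect_error(discardInitialFrames(s6, 6L), "empty")
})

test_that("frame pairing minimises the blood-mean gap with low-index ties", {
  mkFrame <- function(v) matrix(v, 4, 4)
  roi <- c(1L, 1L, 2L, 2L)
  refs <- MarkerSeries(simplify2array(lapply(c(10, 20, 30), mkFrame)),
                       acq = AcquisitionParams(matrixSize = c(4L, 4L)),
                       rois = ROISet(roi, c(3L, 3L, 2L, 2L), c(1L, 3L, 2L, 2L)))
  mk1 <- MarkerSeries(simplify2array(list(mkFrame(19))), acq = acqParams(refs),
                      rois = roiSet(refs))
  p <- pairFrames(mk1, refs, roi)
  expect_equal(p$reference, 2L)
  expect_equal(p$gap, 1)
  # exactly between 10 and 20: documented tie-break to the lower index
  mk2 <- MarkerSeries(simplify2array(list(mkFrame(15))), acq = acqParams(refs),
                      rois = roiSet(refs))
  expect_equal(pairFrames(mk2, refs, roi)$reference, 1L)
  # a series paired with itself has zero gaps
  pSelf <- pairFrames(refs, refs, roi)
  expect_equal(pSelf$gap, rep(0, 3))
})

test_that("subtraction is signed reference minus marker and anti-symmetric", {
  a <- matrix(runif(12, 0, 100), 3, 4)
  b <- matrix(runif(12, 0, 100), 3, 4)
  expect_equal(subtractPair(a, a), matrix(0, 3, 4))
  expect_equal(subtractPair(matrix(100, 2, 2), matrix(30, 2, 2)),
               matrix(70, 2, 2))
  expect_equal(subtractPair(a, b), -subtractPair(b, a))
  expect_error(subtractPair(a, matrix(0, 4, 3)), "shape")
})

test_that("agar threshold is mean + 3 sample SD and scales linearly", {
  img <- matrix(0, 3, 3)
  img[1, ] <- c(1, 2, 3)
  expect_equal(agarThreshold(img, c(1L, 1L, 1L, 3L)), 2 + 3 * 1)
  flat <- matrix(10, 4, 4)
  expect_equal(agarThreshold(flat, c(1L, 1L, 2L, 2L)), 10)
  expect_error(agarThreshold(img, c(1L, 1L, 1L, 1L)), "at least 2")
  img2 <- matrix(rnorm(100), 10, 10)
  roi <- c(2L, 2L, 5L, 5L)
  expect_equal(agarThreshold(img2 * 3.5, roi), 3.5 * agarThreshold(img2, roi))
})

test_that("segmentation is a strict > threshold rule matching brute force", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(segmentArtifacts(img, 5), matrix(FALSE, 2, 2))
  # a pixel exactly at the threshold is excluded
  expect_false(segmentArtifacts(img, 3)[1, 2])
  expect_true(segmentArtifacts(img, 3)[2, 2])
  withr::with_seed(42, {
    for (i in 1:25) {
      sub <- matrix(rnorm(100, sd = 5), 10, 10)
      roi <- c(2L, 3L, 4L, 5L)
      px <- sub[2:5, 3:7]
      thr <- mean(px) + 3 * sd(px)                 # two-line oracle
      expect_equal(segmentArtifacts(sub, agarThreshold(sub, roi)), sub > thr)
    }
  })
})

test_that("mean artifact width matches the per-line counting oracle", {
  # uniform bar: wire along cols, 3 pixels thick, 1.7 mm row spacing
  bar <- matrix(TRUE, 3, 4)
  expect_equal(meanArtifactWidth(bar, "cols", pixelSpacing = c(1.7, 1.74)),
               3 * 1.7)
  expect_equal(meanArtifactWidth(matrix(FALSE, 5, 5), "rows"), 0)
  withr::with_seed(7, {
    for (i in 1:200) {
      m <- matrix(runif(15 * 12) < 0.25, 15, 12)
      sp <- c(runif(1, 0.5, 3), runif(1, 0.5, 3))
      ax <- sample(c("rows", "cols"), 1)
      ce <- sample(c(TRUE, FALSE), 1)
      expect_equal(meanArtifactWidth(m, ax, sp, countEmpty = ce),
                   oracleWidth(m, ax, sp, countEmpty = ce))
    }
  })
})

test_that("width is invariant to translating the mask along the wire axis", {
  withr::with_seed(21, {
    m <- matrix(FALSE, 20, 10)
    m[5:9, 3:7] <- matrix(runif(25) < 0.5, 5, 5)
    shifted <- m[c(11:20, 1:10), ]          # circular shift along rows
    expect_equal(meanArtifactWidth(m, "rows"), meanArtifactWidth(shifted, "rows"))
  })
})

test_that("CNR follows the mean-difference over noise-SD definition", {
  noise <- rnorm(50, sd = 5)
  sdn <- sd(noise)
  expect_equal(computeCNR(rep(100, 10), rep(50, 8), noise),
               50 / sdn)
  expect_equal(computeCNR(1:5, 1:5, noise), 0)
  # absolute mode is symmetric under swapping the ROIs
  expect_equal(computeCNR(rep(10, 4), rep(30, 4), noise, absolute = TRUE),
               computeCNR(rep(30, 4), rep(10, 4), noise, absolute = TRUE))
  # scale consistency: scaling the whole frame leaves CNR unchanged
  expect_equal(computeCNR(3 * rep(100, 10), 3 * rep(50, 8), 3 * noise),
               computeCNR(rep(100, 10), rep(50, 8), noise))
  expect_error(computeCNR(1:3, 1:3, rep(1, 10)), "zero standard deviation")
})

test_that("contamination exclusion supports explicit lists and the 4-SD rule", {
  m <- rep(60, 25)
  none <- excludeContaminatedFrames(m, rule = integer(0))
  expect_false(any(none$excluded))
  listed <- excludeContaminatedFrames(m, rule = c(3, 7))
  expect_equal(which(listed$excluded), c(3L, 7L))
  withr::with_seed(30, {
    m2 <- rnorm(25, 60, 0.05)
    m2[12] <- 90                           # bright stripe through the agar ROI
    auto <- excludeContaminatedFrames(m2, rule = "auto")
    expect_equal(which(auto$excluded), 12L)
    expect_match(auto$reason[12], "deviates")
  })
})

test_that("the assembled pipeline recovers a constructed bar artifact exactly", {
  # noise-free synthetic: flat background 100, a 3-col x 20-row bar void
  H <- 40L; W <- 40L; n <- 8L
  ref <- array(100, c(H, W, n))
  mk <- ref
  mk[11:30, 19:21, ] <- 40
  rois <- ROISet(blood = c(2L, 2L, 4L, 2L), agar = c(2L, 30L, 6L, 6L),
                 noise = c(30L, 2L, 8L, 8L))
  acq <- AcquisitionParams(matrixSize = c(H, W), pixelSpacing = c(1, 2))
  # add tiny deterministic noise so the noise-ROI SD is positive
  set.seed(1)
  nz <- array(rnorm(H * W * n, sd = 1e-3), c(H, W, n))
  mkS <- MarkerSeries(mk + nz, acq = acq, rois = rois)
  refS <- MarkerSeries(ref + nz, acq = acq, rois = rois)
  q <- quantifyDataset(mkS, refS, discard = 2L, exclusionRule = NULL)
  expect_equal(nrow(q@perFrame), 6L)
  expect_equal(q@summary$width_median, 3 * 2)      # 3 cols x 2 mm
  expect_equal(q@summary$width_q1, 6)
  expect_true(all(abs(q@perFrame$threshold) < 0.01))
  # re-running gives the identical summary (determinism)
  q2 <- quantifyDataset(mkS, refS, discard = 2L, exclusionRule = NULL)
  expect_identical(q@perFrame, q2@perFrame)
})

test_that("a wire-free series quantified against itself yields zero width", {
  ph <- smallPhantom(); acq <- smallAcq()
  a <- simulateSeries(ph, NULL, acq, 12, seed = 41, rois = smallRois())
  b <- simulateSeries(ph, NULL, acq, 12, seed = 42, rois = smallRois())
  q <- quantifyDataset(a, b, discard = 2L, exclusionRule = NULL)
  expect_lt(q@summary$width_median, 2.5)  # stray suprathreshold noise only
})
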