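test_that("dipole field obeys the magic-angle null, 1/r^3 law and linearity", {
  magic <- acos(1 / sqrt(3))
  expect_equal(dipoleFieldOffset(c(1, 5, 20), magic, 3), rep(0, 3))
  f1 <- dipoleFieldOffset(2, 0.4, 1.5)
  expect_equal(dipoleFieldOffset(4, 0.4, 1.5), f1 / 8)
  expect_equal(dipoleFieldOffset(2, 0.4, 3), 2 * f1)
  expect_error(dipoleFieldOffset(0, 0, 1), "singular")
})

test_that("GRE magnitude: pure phase, destructive sum, and TE -> 0 limits", {
  s <- 8L
  acq <- AcquisitionParams(te = 2.48, tr = 4.6, matrixSize = c(2L, 2L))
  # uniform field: |e^{i phi}| = 1 for every pixel
  fm <- matrix(37, 2 * s, 2 * s)
  expect_equal(greMagnitude(fm, acq, base = 50, s = s),
               matrix(50, 2, 2))
  # sub-voxel phases uniformly spanning [0, 2pi): destructive
  span <- (0:(s^2 - 1)) / s^2 / (acq@te * 1e-3)
  fm2 <- matrix(0, 2 * s, 2 * s)
  for (pr in 0:1) for (pc in 0:1)
    fm2[pr * s + 1:s, pc * s + 1:s] <- matrix(span, s, s)
  expect_lt(max(greMagnitude(fm2, acq, base = 50, s = s)), 1e-8)
  # TE -> 0 restores the base
  acq0 <- AcquisitionParams(te = 1e-9, tr = 4.6, matrixSize = c(2L, 2L))
  fm3 <- matrix(rnorm((2 * s)^2, sd = 100), 2 * s, 2 * s)
  expect_equal(greMagnitude(fm3, acq0, base = 50, s = s), matrix(50, 2, 2),
               tolerance = 1e-6)
})

test_that("bSSFP banding profile has pass-bands at 0 and 1/TR and a null at 1/(2 TR)", {
  s <- 4L
  acq <- AcquisitionParams(sequence = "bSSFP", te = 1.47, tr = 2.9,
                           flipAngle = 39, matrixSize = c(1L, 1L))
  tr_s <- acq@tr * 1e-3
  m0 <- bssfpMagnitude(matrix(0, s, s), acq, base = 1, s = s)
  null <- bssfpMagnitude(matrix(1 / (2 * tr_s), s, s), acq, base = 1, s = s)
  m1 <- bssfpMagnitude(matrix(1 / tr_s, s, s), acq, base = 1, s = s)
  expect_equal(as.numeric(m0), 1)
  expect_equal(as.numeric(null), 0)
  expect_equal(abs(as.numeric(m1)), 1)
})

test_that("pulsatile modulation is unity without pulsatility and averages to 1", {
  acq <- acquisitionPreset("a")   # 3.3 frames/s
  still <- PhantomSpec(pulsatility = 0)
  expect_equal(pulsatileModulation(1:20, acq, still), rep(1, 20))
  ph <- PhantomSpec(pulsatility = 0.15)
  # period = frameRate / (pulseRate/60) frames; numeric integration over
  # one period on a fine grid has mean 1
  tFine <- seq(0, 1, length.out = 10001)[-10001]
  mFine <- 1 + ph@pulsatility * cos(2 * pi * tFine)
  expect_equal(mean(mFine), 1, tolerance = 1e-10)
  # discrete frames at 3.3 f/s and 60 bpm repeat every 3.3 frames:
  # frames 1 and 34 are 33 frames = 10 pulse periods apart
  expect_equal(pulsatileModulation(1, acq, ph), pulsatileModulation(34, acq, ph))
  expect_true(all(pulsatileModulation(1:50, acq, ph) > 0))
})

test_that("series simulation is deterministic and respects the no-wire null", {
  ph <- smallPhantom(); acq <- smallAcq()
  a <- simulateSeries(ph, NULL, acq, 4, seed = 5, rois = smallRois())
  b <- simulateSeries(ph, NULL, acq, 4, seed = 5, rois = smallRois())
  expect_identical(frames(a), frames(b))
  expect_equal(nrow(markerCentresPx(a)), 0L)

  # wire absent + zero noise: reference and marker renders are identical
  ph0 <- smallPhantom(noiseSigma = 0)
  r1 <- simulateSeries(ph0, NULL, acq, 2, seed = 1)
  r2 <- simulateSeries(ph0, NULL, acq, 2, seed = 99)
  expect_identical(frames(r1), frames(r2))

  # same-phase frames differ by noise only when the wire is absent
  phN <- smallPhantom()
  s1 <- simulateSeries(phN, NULL, acq, 40, seed = 3, satAmp = 0)
  # frames 1 and 34 share the pulsatile phase at 3.3 f/s
  d <- frames(s1)[, , 1] - frames(s1)[, , 34]
  expect_lt(abs(mean(d)), 0.05)
  expect_lt(sd(d), 4 * phN@noiseSigma)
})

test_that("noise-free magnitudes respect the energy bound", {
  ph <- smallPhantom(noiseSigma = 0, pulsatility = 0.15)
  for (p in c("a", "e")) {
    acq <- acquisitionPreset(p)
    acq@matrixSize <- c(48L, 48L)
    wire <- smallWire()
    s <- simulateSeries(ph, wire, acq, 3, seed = 2, satAmp = 0,
                        bloodBoost = 2.5)
    bound <- max(ph@bloodBase * 2.5, ph@agarBase) * (1 + ph@pulsatility)
    expect_true(all(frames(s) >= 0))
    expect_lte(max(frames(s)), bound + 1e-9)
  }
})

test_that("a wire outside the field of view raises a geometry error", {
  ph <- smallPhantom()
  wire <- GuidewireSpec(intermarkerGaps = c(50, 50), tipPosition = c(20, 40))
  expect_error(simulateSeries(ph, wire, smallAcq(), 2, seed = 1),
               "outside the field of view")
})

test_that("saturation ramp brightens exactly the first frames", {
  ph <- smallPhantom(noiseSigma = 0)
  acq <- smallAcq()
  withRamp <- simulateSeries(ph, NULL, acq, 8, seed = 1, satAmp = 0.3,
                             satFrames = 5L)
  noRamp <- simulateSeries(ph, NULL, acq, 8, seed = 1, satAmp = 0)
  ratio <- vapply(1:8, function(i)
    median(frames(withRamp)[, , i] / pmax(frames(noRamp)[, , i], 1e-12),
           na.rm = TRUE), numeric(1))
  expect_equal(ratio[1], 1.3, tolerance = 1e-6)
  expect_true(all(diff(ratio[1:5]) < 0))
  expect_equal(ratio[6:8], rep(1, 3), tolerance = 1e-9)
})

test_that("artifact attenuation darkens the marker neighbourhood only", {
  ph <- smallPhantom(); acq <- smallAcq()
  wire <- smallWire()
  A <- artifactAttenuation(ph, wire, acq)
  expect_true(all(A >= 0 & A <= 1 + 1e-12))
  cen <- markerCentresPx(simulateSeries(ph, wire, acq, 1, seed = 1))
  expect_lt(max(A[cen]), 0.1)          # marker cores are voids
  expect_gt(min(A[, 1:5]), 0.99)       # far-away columns untouched
  # no wire: attenuation-free GRE render
  expect_equal(artifactAttenuation(ph, NULL, acq), matrix(1, 48, 48))
})
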