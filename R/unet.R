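# Training wrapper around the compiled encoder-decoder heatmap regressor.

# per-frame standardisation (zero mean, unit SD); all-positive inputs slow
# the escape from the predict-zero basin on sparse heatmap targets
.normalizeFrames <- function(x) {
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  for (i in seq_len(dim(x)[3])) {
    f <- x[, , i]
    x[, , i] <- (f - mean(f)) / max(stats::sd(f), 1e-8)
  }
  x
}

.initWeights <- function(depth, base) {
  shapes <- .unetLayerShapes(depth, base)
  lapply(shapes, function(s) {
    fanIn <- s[["cin"]] * s[["k"]]^2
    list(W = matrix(stats::rnorm(s[["cout"]] * fanIn, sd = sqrt(2 / fanIn)),
                    nrow = fanIn),
         b = numeric(s[["cout"]]))
  })
}

# random affine augmentation of an (image, label) pair; RNG from caller
.augmentPair <- function(img, lab, ranges) {
  th <- stats::runif(1, -ranges$rotate, ranges$rotate) * pi / 180
  tr <- stats::runif(1, -ranges$translate, ranges$translate)
  tc <- stats::runif(1, -ranges$translate, ranges$translate)
  sc <- stats::runif(1, ranges$scale[1], ranges$scale[2])
  crop <- stats::runif(1, ranges$crop, 1)
  s <- sc / crop                       # crop-and-resize = extra zoom
  m11 <- cos(th) / s; m12 <- sin(th) / s
  m21 <- -sin(th) / s; m22 <- cos(th) / s
  w <- function(m, fill) .warpAffine(m, m11, m12, m21, m22, tr, tc, fill)
  lab2 <- w(lab, 0)
  mx <- max(lab2)
  if (mx > 0) lab2 <- lab2 / mx        # keep the label peak at 1
  list(img = w(img, 0), lab = pmin(pmax(lab2, 0), 1))
}

#' Images and likelihood-map labels from a simulated series
#'
#' Standardises every frame (zero mean, unit SD) and builds the Gaussian
#' label map from the series' ground-truth marker centres.
#'
#' @param series a [MarkerSeries-class] with a wire
#' @param config a [DetectionConfig-class] (label `sigma`)
#' @return list(images, labels): two `rows x cols x n` arrays
#' @export
detectionDataset <- function(series, config = detectionConfig()) {
  imgs <- .normalizeFrames(frames(series))
  d <- dim(imgs)
  lab <- buildLabel(markerCentresPx(series), d[1:2], config@sigma)
  list(images = imgs, labels = array(lab, dim = d))
}

#' Train the heatmap marker detector
#'
#' Trains the encoder-decoder (U-Net) regressor on (image, likelihood map)
#' pairs with a mean-squared-error loss and the Adam optimiser (study
#' protocol: 400 epochs, learning rate 1e-4; see [deskDetectionConfig()]
#' for the scaled-down preset).  Each epoch is one pass over the shuffled
#' training images; with `patchSize > 0` (the default) every image
#' contributes `patchesPerImage` random tiles per pass — the classic U-Net
#' tile regime, which takes more optimiser steps per epoch and resolves
#' fine structure (closely spaced markers) much more reliably than
#' whole-frame batches.  Optional random rotation/translation/scale/crop
#' augmentation precedes tiling.  Validation MSE is logged per epoch on
#' whole frames and the returned model carries the weights of the epoch
#' with the best validation loss.  All randomness derives from
#' `config@seed`, so two runs are identical.
#'
#' @param trainImages,trainLabels `rows x cols x n` arrays (images are
#'   standardised per frame internally)
#' @param valImages,valLabels validation arrays
#' @param config a [DetectionConfig-class]
#' @param verbose print the per-epoch losses
#' @return a [DetectorModel-class]
#' @export
trainDetector <- function(trainImages, trainLabels, valImages, valLabels,
                          config = detectionConfig(), verbose = FALSE) {
  if (!length(trainImages) || dim(trainImages)[3] < 1)
    stop("empty training set")
  d <- dim(trainImages)
  if (any(d[1:2] %% 2^(config@depth - 1L) != 0))
    stop("image dimensions must be divisible by 2^(depth-1)")
  X <- .normalizeFrames(trainImages)
  Xv <- .normalizeFrames(valImages)
  n <- d[3]
  log <- data.frame(epoch = integer(), train_mse = numeric(),
                    val_mse = numeric())
  best <- NULL; bestVal <- Inf; bestEpoch <- 0L
  P <- config@patchSize
  if (P > 0 && (P %% 2^(config@depth - 1L) != 0 || P > min(d[1:2])))
    stop("patchSize must fit the image and be divisible by 2^(depth-1)")
  withr::with_seed(config@seed, {
    ptr <- .unetCreate(.initWeights(config@depth, config@baseChannels),
                       config@depth, config@baseChannels)
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      Xa <- X; Ya <- trainLabels
      if (config@augment) {
        for (i in seq_len(n)) {
          a <- .augmentPair(X[, , i], trainLabels[, , i], config@augmentRanges)
          Xa[, , i] <- a$img; Ya[, , i] <- a$lab
        }
      }
      if (P > 0) {
        K <- config@patchesPerImage
        Xp <- array(0, c(P, P, n * K)); Yp <- Xp
        idx <- 0L
        for (i in ord) for (k in seq_len(K)) {
          r0 <- sample.int(d[1] - P + 1L, 1L)
          c0 <- sample.int(d[2] - P + 1L, 1L)
          idx <- idx + 1L
          Xp[, , idx] <- Xa[r0:(r0 + P - 1L), c0:(c0 + P - 1L), i]
          Yp[, , idx] <- Ya[r0:(r0 + P - 1L), c0:(c0 + P - 1L), i]
        }
        tl <- .unetTrainEpoch(ptr, Xp, Yp, seq_len(n * K),
                              config@learningRate)
      } else {
        tl <- .unetTrainEpoch(ptr, Xa, Ya, ord, config@learningRate)
      }
      vl <- .unetLoss(ptr, Xv, valLabels)
      log <- rbind(log, data.frame(epoch = ep, train_mse = tl, val_mse = vl))
      if (vl < bestVal) {
        bestVal <- vl; bestEpoch <- ep
        best <- .unetGetWeights(ptr)
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep, tl, vl))
    }
  })
  new("DetectorModel", weights = best, depth = config@depth,
      baseChannels = config@baseChannels, config = config, log = log,
      bestEpoch = bestEpoch)
}

#' Predict a marker-location likelihood map
#'
#' Applies the same per-frame standardisation used in training, runs the
#' network, and clips the output to `[0, 1]`.
#'
#' @param model a [DetectorModel-class]
#' @param image numeric matrix with the training image shape
#' @return likelihood map in `[0, 1]`, same shape as the input
#' @export
predictLikelihood <- function(model, image) {
  stopifnot(is(model, "DetectorModel"), is.matrix(image))
  if (any(dim(image) %% 2^(model@depth - 1L) != 0))
    stop("image dimensions incompatible with the model depth")
  img <- .normalizeFrames(array(image, dim = c(dim(image), 1)))[, , 1]
  ptr <- .unetCreate(model@weights, model@depth, model@baseChannels)
  out <- .unetPredict(ptr, img)
  pmin(pmax(out, 0), 1)
}
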