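# Artifact quantification: frame discard, blood-intensity pairing,
# subtraction, agar mean+3SD thresholding, segmentation, mean artifact
# width, CNRs, frame exclusion, and the dataset summary.

.roiPixels <- function(frame, roi) {
  frame[roi[1]:(roi[1] + roi[3] - 1L), roi[2]:(roi[2] + roi[4] - 1L)]
}

#' Discard the initial frames of a series
#'
#' The first frames of each acquisition are dropped to mitigate saturation
#' effects (default: 5, leaving 25 of the study's 30 frames for analysis).
#'
#' @param series a [MarkerSeries-class] with more than `k` frames
#' @param k number of leading frames to drop
#' @return the series minus its first `k` frames, order preserved
#' @export
discardInitialFrames <- function(series, k = 5L) {
  n <- nFrames(series)
  if (k >= n) stop("discarding ", k, " frames would empty a ", n, "-frame series")
  if (k == 0L) return(series)
  initialize(series, frames = series@frames[, , -(seq_len(k)), drop = FALSE])
}

#' Pair marker frames with reference frames by blood signal intensity
#'
#' The pulsatile flow makes the blood signal fluctuate frame to frame, so
#' each marker frame is paired with the reference frame whose mean blood-ROI
#' intensity is closest (reference frames may be reused; ties go to the
#' lowest reference index).
#'
#' @param markerSeries,referenceSeries [MarkerSeries-class] objects
#' @param bloodRoi `c(row0, col0, nrows, ncols)`; default: the marker
#'   series' blood ROI
#' @return data.frame(marker, reference, gap) with `gap` the absolute
#'   blood-mean difference of the pair
#' @export
pairFrames <- function(markerSeries, referenceSeries,
                       bloodRoi = roiSet(markerSeries)@blood) {
  mMeans <- vapply(seq_len(nFrames(markerSeries)), function(i)
    mean(.roiPixels(markerSeries@frames[, , i], bloodRoi)), numeric(1))
  rMeans <- vapply(seq_len(nFrames(referenceSeries)), function(i)
    mean(.roiPixels(referenceSeries@frames[, , i], bloodRoi)), numeric(1))
  ref <- vapply(mMeans, function(m) which.min(abs(rMeans - m)), integer(1))
  data.frame(marker = seq_along(mMeans), reference = ref,
             gap = abs(mMeans - rMeans[ref]))
}

#' Subtract a marker frame from its paired reference frame
#'
#' Pixelwise `reference - marker`: the marker's signal void appears as a
#' positive excursion in the subtraction image.
#'
#' @param referenceFrame,markerFrame numeric matrices of equal shape
#' @return signed subtraction image
#' @export
subtractPair <- function(referenceFrame, markerFrame) {
  if (!identical(dim(referenceFrame), dim(markerFrame)))
    stop("reference and marker frames must have the same shape")
  referenceFrame - markerFrame
}

#' Standardised subtraction-image threshold from agar statistics
#'
#' `mean + 3 * SD` of the agar-ROI pixels of the subtraction image, with the
#' sample SD (n-1 denominator).
#'
#' @param subtractionImage signed subtraction image
#' @param agarRoi `c(row0, col0, nrows, ncols)`
#' @return the threshold (signal units)
#' @export
agarThreshold <- function(subtractionImage, agarRoi) {
  px <- .roiPixels(subtractionImage, agarRoi)
  if (length(px) < 2) stop("agar ROI must contain at least 2 pixels (SD undefined)")
  mean(px) + 3 * stats::sd(px)
}

#' Segment marker artifacts by thresholding the subtraction image
#'
#' Pixels with intensity strictly higher than the threshold are assigned to
#' the artifact mask.
#'
#' @param subtractionImage signed subtraction image
#' @param threshold finite scalar
#' @return logical mask of the same shape
#' @export
segmentArtifacts <- function(subtractionImage, threshold) {
  stopifnot(is.finite(threshold))
  subtractionImage > threshold
}

#' Mean artifact width perpendicular to the guidewire
#'
#' For each index along the wire axis where the mask contains at least one
#' pixel, the width is the pixel count along the perpendicular axis times
#' the perpendicular pixel spacing; the mean over those indices is returned
#' (0 for an empty mask).  Lines without mask pixels can optionally be
#' counted as zero-width instead of skipped.
#'
#' @param mask logical matrix
#' @param wireAxis "rows" (wire along rows; width counted across columns)
#'   or "cols"
#' @param pixelSpacing `c(row mm, col mm)`
#' @param countEmpty if TRUE, average over all wire-axis indices including
#'   empty ones (default FALSE: occupied indices only)
#' @return mean width in mm
#' @export
meanArtifactWidth <- function(mask, wireAxis = c("rows", "cols"),
                              pixelSpacing = c(1.74, 1.7),
                              countEmpty = FALSE) {
  wireAxis <- match.arg(wireAxis)
  counts <- if (wireAxis == "rows") rowSums(mask) else colSums(mask)
  spacing <- if (wireAxis == "rows") pixelSpacing[2] else pixelSpacing[1]
  if (!countEmpty) counts <- counts[counts > 0]
  if (!length(counts) || all(counts == 0)) return(0)
  mean(counts) * spacing
}

#' Contrast-to-noise ratio between two pixel sets
#'
#' `CNR = (mean(a) - mean(b)) / SD(noise ROI)` with the sample SD.  The
#' study's blood-artifact CNR uses the blood ROI of the original marker
#' image as `a` and the segmented artifact pixels of that image as `b`;
#' the agar-artifact CNR uses the agar ROI as `a`.  `absolute = TRUE`
#' applies `|.|` to the mean difference.
#'
#' @param roiA,roiB numeric vectors of pixel values (non-empty)
#' @param noisePixels numeric vector from the noise ROI; its SD must be > 0
#' @param absolute take the absolute mean difference (default FALSE: signed)
#' @return dimensionless CNR
#' @export
computeCNR <- function(roiA, roiB, noisePixels, absolute = FALSE) {
  stopifnot(length(roiA) > 0, length(roiB) > 0, length(noisePixels) > 1)
  sdn <- stats::sd(noisePixels)
  if (sdn <= 0) stop("noise ROI has zero standard deviation")
  d <- mean(roiA) - mean(roiB)
  if (absolute) abs(d) / sdn else d / sdn
}

#' Flag frames contaminated by artifacts unrelated to the markers
#'
#' Either an explicit frame-index list, or the automatic rule: a frame whose
#' agar-ROI mean deviates more than 4 SD from the dataset's median agar-ROI
#' mean (SD over frames) is excluded.
#'
#' @param agarMeans per-frame agar-ROI means (original marker frames)
#' @param rule "auto" or an integer vector of frame indices
#' @param nSD deviation cut for the automatic rule
#' @return data.frame(excluded, reason) with one row per frame
#' @export
excludeContaminatedFrames <- function(agarMeans, rule = "auto", nSD = 4) {
  n <- length(agarMeans)
  out <- data.frame(excluded = rep(FALSE, n), reason = rep("", n),
                    stringsAsFactors = FALSE)
  if (is.numeric(rule)) {
    idx <- intersect(as.integer(rule), seq_len(n))
    out$excluded[idx] <- TRUE
    out$reason[idx] <- "listed"
    return(out)
  }
  if (!identical(rule, "auto")) stop("rule must be 'auto' or an index vector")
  if (n < 3) return(out)
  s <- stats::sd(agarMeans)
  if (s == 0) return(out)
  dev <- abs(agarMeans - stats::median(agarMeans))
  bad <- dev > nSD * s
  out$excluded[bad] <- TRUE
  out$reason[bad] <- sprintf("agar mean deviates %.1f SD from dataset median",
                             dev[bad] / s)
  out
}

#' Quantify marker artifacts over a paired dataset
#'
#' Runs the full per-dataset analysis: discard the first `k` frames of both
#' series, pair marker frames to reference frames by blood intensity,
#' subtract, derive the agar mean+3SD threshold per pair, segment, measure
#' the mean artifact width and the blood-/agar-artifact CNRs on the original
#' marker frame, apply the contamination exclusion, and summarise medians
#' and IQRs over the retained frames.
#'
#' @param markerSeries,referenceSeries [MarkerSeries-class] objects sharing
#'   the acquisition geometry
#' @param rois an [ROISet-class]; default: the marker series' own
#' @param discard leading frames to drop from each series
#' @param wireAxis wire direction for the width measurement
#' @param exclusionRule "auto", an index vector, or NULL to skip
#' @param absoluteCNR passed to [computeCNR()]
#' @param keepMasks retain the per-frame masks in the result
#' @return an [ArtifactQuant-class]
#' @export
quantifyDataset <- function(markerSeries, referenceSeries,
                            rois = roiSet(markerSeries), discard = 5L,
                            wireAxis = "rows", exclusionRule = "auto",
                            absoluteCNR = FALSE, keepMasks = FALSE) {
  if (!all(dim(markerSeries@frames)[1:2] == dim(referenceSeries@frames)[1:2]))
    stop("marker and reference series must share the acquisition geometry")
  mk <- discardInitialFrames(markerSeries, discard)
  rf <- discardInitialFrames(referenceSeries, discard)
  pairs <- pairFrames(mk, rf, bloodRoi = rois@blood)
  spacing <- acqParams(mk)@pixelSpacing
  n <- nrow(pairs)
  res <- data.frame(frame = pairs$marker, reference = pairs$reference,
                    blood_gap = pairs$gap, threshold = NA_real_,
                    width_mm = NA_real_, cnr_blood = NA_real_,
                    cnr_agar = NA_real_)
  masks <- vector("list", n)
  agarMeans <- numeric(n)
  for (i in seq_len(n)) {
    mframe <- mk@frames[, , pairs$marker[i]]
    rframe <- rf@frames[, , pairs$reference[i]]
    sub <- subtractPair(rframe, mframe)
    thr <- agarThreshold(sub, rois@agar)
    mask <- segmentArtifacts(sub, thr)
    res$threshold[i] <- thr
    res$width_mm[i] <- meanArtifactWidth(mask, wireAxis, spacing)
    noisePx <- .roiPixels(mframe, rois@noise)
    artPx <- mframe[mask]
    if (length(artPx)) {
      res$cnr_blood[i] <- computeCNR(.roiPixels(mframe, rois@blood), artPx,
                                     noisePx, absolute = absoluteCNR)
      res$cnr_agar[i] <- computeCNR(.roiPixels(mframe, rois@agar), artPx,
                                    noisePx, absolute = absoluteCNR)
    }
    agarMeans[i] <- mean(.roiPixels(mframe, rois@agar))
    if (keepMasks) masks[[i]] <- mask
  }
  excl <- if (is.null(exclusionRule))
    data.frame(excluded = rep(FALSE, n), reason = rep("", n))
  else excludeContaminatedFrames(agarMeans, exclusionRule)
  res$excluded <- excl$excluded
  res$reason <- excl$reason
  keep <- res[!res$excluded, , drop = FALSE]
  summ <- list(n_analysed = nrow(keep), n_excluded = sum(res$excluded))
  for (v in c("width_mm", "cnr_blood", "cnr_agar")) {
    q <- .safeIQR(keep[[v]])
    nm <- sub("_mm$", "", v)
    summ[[paste0(nm, "_median")]] <- q[["median"]]
    summ[[paste0(nm, "_q1")]] <- q[["q1"]]
    summ[[paste0(nm, "_q3")]] <- q[["q3"]]
  }
  new("ArtifactQuant", perFrame = res, summary = summ,
      masks = if (keepMasks) masks else list())
}
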