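# Accessors and show methods for the core containers.

#' Number of frames in a series
#' @param x a [MarkerSeries-class]
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame data of a series
#' @param x a [MarkerSeries-class]
#' @return numeric array `rows x cols x nFrames`
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Acquisition parameters of a series
#' @param x a [MarkerSeries-class]
#' @return an [AcquisitionParams-class]
#' @export
setGeneric("acqParams", function(x) standardGeneric("acqParams"))

#' Guidewire of a series (NULL for reference series)
#' @param x a [MarkerSeries-class]
#' @return a [GuidewireSpec-class] or NULL
#' @export
setGeneric("wireSpec", function(x) standardGeneric("wireSpec"))

#' ROI set of a series
#' @param x a [MarkerSeries-class]
#' @return an [ROISet-class]
#' @export
setGeneric("roiSet", function(x) standardGeneric("roiSet"))

#' Ground-truth marker centres in pixels
#' @param x a [MarkerSeries-class]
#' @return integer matrix `nMarkers x 2` of (row, col)
#' @export
setGeneric("markerCentresPx", function(x) standardGeneric("markerCentresPx"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "MarkerSeries", function(x) dim(x@frames)[3])

#' @rdname frames
#' @export
setMethod("frames", "MarkerSeries", function(x) x@frames)

#' @rdname acqParams
#' @export
setMethod("acqParams", "MarkerSeries", function(x) x@acq)

#' @rdname wireSpec
#' @export
setMethod("wireSpec", "MarkerSeries", function(x) x@wire)

#' @rdname roiSet
#' @export
setMethod("roiSet", "MarkerSeries", function(x) x@rois)

#' @rdname markerCentresPx
#' @export
setMethod("markerCentresPx", "MarkerSeries", function(x) x@centresPx)

setMethod("show", "MarkerSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("MarkerSeries: %d frames of %dx%d (%s, TE %.2f ms)\n",
              d[3], d[1], d[2], object@acq@sequence, object@acq@te))
  if (is.null(object@wire)) cat("  reference series (no wire)\n")
  else cat(sprintf("  wire: %g mg/mL IONP, %d markers\n",
                   object@wire@ionpConcentration, nrow(object@centresPx)))
})

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: %s TE/TR %.2f/%.2f ms, flip %g deg, ST %g mm, PED %s\n",
              object@sequence, object@te, object@tr, object@flipAngle,
              object@sliceThickness, object@ped))
  cat(sprintf("  matrix %dx%d, pixel %.2fx%.2f mm, %.1f frames/s\n",
              object@matrixSize[1], object@matrixSize[2],
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@frameRate))
})

setMethod("show", "GuidewireSpec", function(object) {
  cat(sprintf("GuidewireSpec: %g mg/mL IONP, %d markers, gaps %s mm\n",
              object@ionpConcentration, length(object@intermarkerGaps) + 1L,
              paste(object@intermarkerGaps, collapse = "/")))
})

setMethod("show", "DetectorModel", function(object) {
  cat(sprintf("DetectorModel: depth-%d U-Net, %d base channels\n",
              object@depth, object@baseChannels))
  if (nrow(object@log))
    cat(sprintf("  best epoch %d, val MSE %.3g\n", object@bestEpoch,
                object@log$val_mse[object@bestEpoch]))
})

setMethod("show", "DetectionMetrics", function(object) {
  s <- object@summary
  cat(sprintf("DetectionMetrics over %d (frame, threshold) pairs\n",
              nrow(object@perFrame)))
  cat(sprintf("  correctly detected: median %.1f (IQR %.1f-%.1f)\n",
              s$tp_median, s$tp_q1, s$tp_q3))
  cat(sprintf("  false positives:    median %.1f (IQR %.1f-%.1f)\n",
              s$fp_median, s$fp_q1, s$fp_q3))
})

setMethod("show", "ArtifactQuant", function(object) {
  s <- object@summary
  cat(sprintf("ArtifactQuant: %d frames (%d excluded)\n",
              nrow(object@perFrame), sum(object@perFrame$excluded)))
  cat(sprintf("  median width %.1f mm (IQR %.1f-%.1f)\n",
              s$width_median, s$width_q1, s$width_q3))
})
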