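#' @import methods
NULL

# ---- PhantomSpec -----------------------------------------------------------

#' Pulsatile flow phantom description
#'
#' Describes the vascular flow phantom: an 8-mm "blood" tube running along
#' the image row axis (the main-field direction) embedded in homogeneous
#' agar, with an air margin on the left of the field of view where the noise
#' ROI lives.  Signal levels are in arbitrary units; the blood signal is
#' modulated by a pulsatile waveform at `pulseRate` beats/min.
#'
#' @slot tubeDiameter tube inner diameter (mm)
#' @slot flowRate pump flow (L/min; metadata, does not enter the signal model)
#' @slot pulseRate pulse rate (beats/min)
#' @slot bloodBase baseline blood signal (arbitrary units)
#' @slot agarBase baseline agar signal (arbitrary units)
#' @slot noiseSigma per-channel Gaussian noise SD before magnitude (a.u.)
#' @slot pulsatility pulsatile modulation amplitude, fraction of `bloodBase`
#' @slot tubeCentre column position of the tube axis (mm from left pixel centre)
#' @slot airMargin columns with centre < `airMargin` mm are air (zero signal)
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    tubeDiameter = "numeric", flowRate = "numeric", pulseRate = "numeric",
    bloodBase = "numeric", agarBase = "numeric", noiseSigma = "numeric",
    pulsatility = "numeric", tubeCentre = "numeric", airMargin = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@tubeDiameter <= 0) msg <- c(msg, "tubeDiameter must be > 0")
  if (object@pulseRate <= 0) msg <- c(msg, "pulseRate must be > 0")
  if (object@pulsatility < 0 || object@pulsatility >= 1)
    msg <- c(msg, "pulsatility must be in [0, 1)")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@bloodBase < 0 || object@agarBase < 0)
    msg <- c(msg, "signal bases must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults reproduce the study conditions: an 8-mm tube with 0.4 L/min
#' pulsatile flow at 60 beats/min.  Absolute signal levels and the noise
#' floor are free parameters of the simulator (see the methods vignette).
#'
#' @param tubeDiameter tube diameter (mm)
#' @param flowRate flow (L/min, metadata)
#' @param pulseRate beats per minute
#' @param bloodBase,agarBase signal levels (arbitrary units)
#' @param noiseSigma per-channel noise SD (arbitrary units)
#' @param pulsatility fractional pulsatile amplitude in `[0, 1)`
#' @param tubeCentre tube axis column position (mm)
#' @param airMargin left air margin width (mm)
#' @return a [PhantomSpec-class] object
#' @examples
#' PhantomSpec()
#' @export
PhantomSpec <- function(tubeDiameter = 8, flowRate = 0.4, pulseRate = 60,
                        bloodBase = 100, agarBase = 60, noiseSigma = 1,
                        pulsatility = 0.15, tubeCentre = 122.4,
                        airMargin = 55.3) {
  new("PhantomSpec", tubeDiameter = tubeDiameter, flowRate = flowRate,
      pulseRate = pulseRate, bloodBase = bloodBase, agarBase = agarBase,
      noiseSigma = noiseSigma, pulsatility = pulsatility,
      tubeCentre = tubeCentre, airMargin = airMargin)
}

# ---- GuidewireSpec ---------------------------------------------------------

#' Guidewire with passive paramagnetic markers
#'
#' Five identical cylindrical iron-oxide nanoparticle (IONP) markers sit on
#' the wire, the first at the exact tip, subsequent ones separated by
#' `intermarkerGaps` (centre to centre).  The marker magnetic moment scales
#' with `ionpConcentration * markerVolume`.
#'
#' @slot ionpConcentration IONP concentration (mg/mL)
#' @slot markerLength marker length (mm)
#' @slot markerVolume marker volume (microlitre)
#' @slot intermarkerGaps centre-to-centre gaps (mm), ordered from the tip
#' @slot tipPosition physical (row, col) position of the tip marker (mm)
#' @slot axis image axis the wire runs along ("rows" or "cols")
#'
#' @exportClass GuidewireSpec
setClass("GuidewireSpec",
  representation(
    ionpConcentration = "numeric", markerLength = "numeric",
    markerVolume = "numeric", intermarkerGaps = "numeric",
    tipPosition = "numeric", axis = "character"
  )
)

setValidity("GuidewireSpec", function(object) {
  msg <- character()
  if (object@ionpConcentration <= 0) msg <- c(msg, "ionpConcentration must be > 0")
  if (object@markerVolume <= 0) msg <- c(msg, "markerVolume must be > 0")
  if (length(object@intermarkerGaps) && any(object@intermarkerGaps <= 0))
    msg <- c(msg, "intermarkerGaps must all be > 0")
  if (length(object@tipPosition) != 2) msg <- c(msg, "tipPosition must be (row, col) mm")
  if (!object@axis %in% c("rows", "cols")) msg <- c(msg, "axis must be 'rows' or 'cols'")
  if (length(msg)) msg else TRUE
})

#' Construct a GuidewireSpec
#'
#' Defaults match the study wire: 1.5-mm, 0.036-uL markers at 20/15/10/5 mm
#' gaps with the tip marker first, wire aligned with the main field (image
#' rows) inside the tube.
#'
#' @param ionpConcentration mg/mL (study values 6.25, 12.5, 25, 50)
#' @param markerLength mm
#' @param markerVolume microlitre
#' @param intermarkerGaps mm, ordered from the tip
#' @param tipPosition (row, col) of the tip in mm
#' @param axis "rows" or "cols"
#' @return a [GuidewireSpec-class] object
#' @examples
#' markerCentres(GuidewireSpec(ionpConcentration = 6.25))
#' @export
GuidewireSpec <- function(ionpConcentration = 6.25, markerLength = 1.5,
                          markerVolume = 0.036,
                          intermarkerGaps = c(20, 15, 10, 5),
                          tipPosition = c(40, 122.4), axis = "rows") {
  new("GuidewireSpec", ionpConcentration = ionpConcentration,
      markerLength = markerLength, markerVolume = markerVolume,
      intermarkerGaps = as.numeric(intermarkerGaps),
      tipPosition = as.numeric(tipPosition), axis = axis)
}

# ---- AcquisitionParams -----------------------------------------------------

#' Acquisition parameters of a 2-D interventional sequence
#'
#' Sequence timing and geometry for the GRE- and bSSFP-like contrast models.
#' `bandwidth` is carried as metadata only.  Named presets a-h reproduce the
#' evaluated parameter grid (see [acquisitionPreset()]).
#'
#' @slot sequence "GRE" or "bSSFP"
#' @slot te echo time (ms)
#' @slot tr repetition time (ms)
#' @slot flipAngle degrees (metadata for the simplified signal model)
#' @slot sliceThickness mm
#' @slot ped phase-encoding direction: "perpendicular" or "parallel" to B0
#' @slot matrixSize (rows, cols)
#' @slot pixelSpacing (row mm, col mm)
#' @slot frameRate frames per second
#' @slot bandwidth Hz/pixel (metadata only)
#'
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    sequence = "character", te = "numeric", tr = "numeric",
    flipAngle = "numeric", sliceThickness = "numeric", ped = "character",
    matrixSize = "integer", pixelSpacing = "numeric", frameRate = "numeric",
    bandwidth = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (!object@sequence %in% c("GRE", "bSSFP")) msg <- c(msg, "sequence must be GRE or bSSFP")
  if (!(object@te > 0 && object@te < object@tr)) msg <- c(msg, "need 0 < te < tr")
  if (length(object@matrixSize) != 2 || any(object@matrixSize <= 0L))
    msg <- c(msg, "matrixSize must be two positive integers")
  if (length(object@pixelSpacing) != 2 || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive lengths (mm)")
  if (!object@ped %in% c("perpendicular", "parallel"))
    msg <- c(msg, "ped must be 'perpendicular' or 'parallel'")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct AcquisitionParams
#'
#' @param sequence "GRE" or "bSSFP"
#' @param te,tr echo/repetition time (ms); requires `0 < te < tr`
#' @param flipAngle degrees
#' @param sliceThickness mm (study presets use 5 or 10)
#' @param ped "perpendicular" or "parallel"
#' @param matrixSize (rows, cols)
#' @param pixelSpacing (row, col) mm
#' @param frameRate frames/s
#' @param bandwidth Hz/pixel, metadata
#' @return an [AcquisitionParams-class] object
#' @seealso [acquisitionPreset()] for the named study presets
#' @examples
#' AcquisitionParams(te = 2.48, tr = 4.6)
#' @export
AcquisitionParams <- function(sequence = "GRE", te = 2.48, tr = 4.6,
                              flipAngle = 12, sliceThickness = 5,
                              ped = "perpendicular",
                              matrixSize = c(144L, 144L),
                              pixelSpacing = c(1.74, 1.7),
                              frameRate = 3.3, bandwidth = NA_real_) {
  new("AcquisitionParams", sequence = sequence, te = te, tr = tr,
      flipAngle = flipAngle, sliceThickness = sliceThickness, ped = ped,
      matrixSize = as.integer(matrixSize),
      pixelSpacing = as.numeric(pixelSpacing), frameRate = frameRate,
      bandwidth = as.numeric(bandwidth))
}

# ---- ROISet ----------------------------------------------------------------

#' Rectangular regions of interest for ROI statistics
#'
#' Each ROI is `c(row0, col0, nrows, ncols)` with 1-based top-left corner.
#' Defaults place a 17x2 blood ROI inside the tube (away from the markers),
#' a 54x6 agar ROI in background, and a 141x31 noise ROI in the air margin:
#' the study's 2x17 / 6x54 / 31x141-voxel ROIs, oriented along the
#' row-aligned tube.
#'
#' @slot blood,agar,noise integer(4) rectangles `c(row0, col0, nrows, ncols)`
#' @exportClass ROISet
setClass("ROISet",
  representation(blood = "integer", agar = "integer", noise = "integer")
)

.validRect <- function(r) length(r) == 4 && all(r[1:2] >= 1L) && all(r[3:4] >= 1L)

setValidity("ROISet", function(object) {
  msg <- character()
  if (!.validRect(object@blood)) msg <- c(msg, "blood ROI must be c(row0, col0, nrows, ncols)")
  if (!.validRect(object@agar)) msg <- c(msg, "agar ROI must be c(row0, col0, nrows, ncols)")
  if (!.validRect(object@noise)) msg <- c(msg, "noise ROI must be c(row0, col0, nrows, ncols)")
  if (length(msg)) msg else TRUE
})

#' Construct an ROISet
#'
#' @param blood,agar,noise integer(4) rectangles `c(row0, col0, nrows, ncols)`
#' @return an [ROISet-class] object
#' @examples
#' ROISet()
#' @export
ROISet <- function(blood = c(100L, 72L, 17L, 2L),
                   agar = c(45L, 100L, 54L, 6L),
                   noise = c(2L, 1L, 141L, 31L)) {
  new("ROISet", blood = as.integer(blood), agar = as.integer(agar),
      noise = as.integer(noise))
}

# ---- MarkerSeries ----------------------------------------------------------

setClassUnion("GuidewireSpecOrNULL", c("GuidewireSpec", "NULL"))

#' An ordered series of 2-D magnitude frames
#'
#' Container for a simulated (or loaded) image series: frames stacked as an
#' `rows x cols x n` array, the acquisition parameters, the wire description
#' (absent for reference series), the ROI set, ground-truth marker centres
#' in pixels (present iff the wire is), and the simulation seed.
#'
#' @slot frames numeric array `rows x cols x nFrames`, nonnegative
#' @slot acq an [AcquisitionParams-class]
#' @slot wire a [GuidewireSpec-class] or NULL
#' @slot rois an [ROISet-class]
#' @slot centresPx integer matrix `nMarkers x 2` of (row, col), or 0-row
#' @slot seed integer seed the series was generated with (NA if loaded)
#' @exportClass MarkerSeries
setClass("MarkerSeries",
  representation(
    frames = "array", acq = "AcquisitionParams",
    wire = "GuidewireSpecOrNULL", rois = "ROISet",
    centresPx = "matrix", seed = "integer"
  )
)

setValidity("MarkerSeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "frames must be a 3-D array (rows x cols x n)")
  else {
    if (d[3] < 1) msg <- c(msg, "need at least one frame")
    if (!all(d[1:2] == object@acq@matrixSize))
      msg <- c(msg, "frame shape must match acq matrixSize")
    if (any(!is.finite(object@frames)) || any(object@frames < 0))
      msg <- c(msg, "frames must be finite and nonnegative")
    cp <- object@centresPx
    if (nrow(cp)) {
      if (ncol(cp) != 2) msg <- c(msg, "centresPx must have 2 columns (row, col)")
      else if (any(cp < 1) || any(cp[, 1] > d[1]) || any(cp[, 2] > d[2]))
        msg <- c(msg, "centresPx must lie inside the frame")
    }
    if (is.null(object@wire) && nrow(cp))
      msg <- c(msg, "centresPx must be empty when wire is absent")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerSeries
#'
#' Normally produced by [simulateSeries()] or [readSeries()]; the
#' constructor is exported so conforming series can be built directly
#' (e.g. for fixtures).
#'
#' @param frames numeric array `rows x cols x nFrames`
#' @param acq [AcquisitionParams-class]
#' @param wire [GuidewireSpec-class] or NULL
#' @param rois [ROISet-class]
#' @param centresPx integer matrix of (row, col) marker centres
#' @param seed integer
#' @return a [MarkerSeries-class]
#' @export
MarkerSeries <- function(frames, acq = AcquisitionParams(), wire = NULL,
                         rois = ROISet(),
                         centresPx = matrix(integer(), 0L, 2L),
                         seed = NA_integer_) {
  new("MarkerSeries", frames = frames, acq = acq, wire = wire, rois = rois,
      centresPx = matrix(as.integer(centresPx), ncol = 2L),
      seed = as.integer(seed))
}

# ---- DetectionConfig -------------------------------------------------------

#' Configuration of the heatmap marker detector
#'
#' Bundles the label construction, training, extraction, and evaluation
#' parameters.  Defaults follow the study protocol: Gaussian labels with
#' sigma = (1,1) px, MSE loss, Adam at learning rate 1e-4, 400 epochs,
#' rotation/translation/scale/crop augmentation, 8-connected local maxima,
#' likelihood thresholds 0.1-0.9 in 0.05 steps and a 2-voxel match
#' tolerance.  [deskDetectionConfig()] gives the scaled-down preset used in
#' examples and tests.
#'
#' @slot sigma Gaussian label SD (row, col) in pixels
#' @slot connectivity pixel connectivity for maxima extraction (8)
#' @slot thresholds strictly increasing likelihood thresholds in (0,1)
#' @slot matchTolerance max Euclidean distance (voxels) for a true positive
#' @slot epochs training epochs
#' @slot learningRate Adam learning rate
#' @slot augment logical: apply random affine augmentation during training
#' @slot augmentRanges list(rotate deg, translate px, scale, crop fraction)
#' @slot depth U-Net depth (number of resolution levels)
#' @slot baseChannels channels of the first encoder block
#' @slot patchSize side length of random training tiles (0 = whole frames);
#'   tile training takes more optimiser steps per pass over the data, the
#'   classic U-Net regime
#' @slot patchesPerImage tiles sampled per image per epoch when tiling
#' @slot seed integer seed for weight init, shuffling and augmentation
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(
    sigma = "numeric", connectivity = "integer", thresholds = "numeric",
    matchTolerance = "numeric", epochs = "integer", learningRate = "numeric",
    augment = "logical", augmentRanges = "list", depth = "integer",
    baseChannels = "integer", patchSize = "integer",
    patchesPerImage = "integer", seed = "integer"
  )
)

setValidity("DetectionConfig", function(object) {
  msg <- character()
  th <- object@thresholds
  if (length(th) < 1 || any(th <= 0) || any(th >= 1) || any(diff(th) <= 0))
    msg <- c(msg, "thresholds must be strictly increasing in (0,1)")
  if (object@matchTolerance < 0) msg <- c(msg, "matchTolerance must be >= 0")
  if (object@connectivity != 8L) msg <- c(msg, "only 8-connectivity is supported")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@patchSize < 0L) msg <- c(msg, "patchSize must be >= 0")
  if (object@patchSize > 0L && object@patchesPerImage < 1L)
    msg <- c(msg, "patchesPerImage must be >= 1 when tiling")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionConfig
#'
#' @param sigma label Gaussian SD (pixels), length 2
#' @param connectivity 8 (the only supported value)
#' @param thresholds likelihood thresholds, default `seq(0.1, 0.9, 0.05)`
#' @param matchTolerance voxels, default 2
#' @param epochs default 400
#' @param learningRate default 1e-4
#' @param augment default TRUE
#' @param augmentRanges rotation (deg), translation (px), scale range,
#'   minimum crop fraction
#' @param depth U-Net depth, default 3
#' @param baseChannels default 16
#' @param patchSize training-tile side length (0 trains on whole frames)
#' @param patchesPerImage tiles per image per epoch
#' @param seed integer
#' @return a [DetectionConfig-class]
#' @examples
#' detectionConfig(epochs = 10)
#' @export
detectionConfig <- function(sigma = c(1, 1), connectivity = 8L,
                            thresholds = seq(0.1, 0.9, by = 0.05),
                            matchTolerance = 2, epochs = 400L,
                            learningRate = 1e-4, augment = TRUE,
                            augmentRanges = list(rotate = 15, translate = 10,
                                                 scale = c(0.9, 1.1),
                                                 crop = 0.85),
                            depth = 3L, baseChannels = 16L,
                            patchSize = 72L, patchesPerImage = 4L,
                            seed = 1L) {
  new("DetectionConfig", sigma = as.numeric(sigma),
      connectivity = as.integer(connectivity),
      thresholds = as.numeric(thresholds),
      matchTolerance = as.numeric(matchTolerance),
      epochs = as.integer(epochs), learningRate = learningRate,
      augment = augment, augmentRanges = augmentRanges,
      depth = as.integer(depth), baseChannels = as.integer(baseChannels),
      patchSize = as.integer(patchSize),
      patchesPerImage = as.integer(patchesPerImage),
      seed = as.integer(seed))
}

#' Scaled-down detector preset for CPU desk runs
#'
#' Depth-2 network with 8 base channels, 60 epochs of 72-px tile training,
#' no augmentation: trains in about two minutes on a single CPU core for
#' 144x144 frames while the evaluation frames share the training
#' acquisition geometry.  See the methods vignette for the rationale.
#'
#' @param seed integer seed
#' @param epochs default 60
#' @return a [DetectionConfig-class]
#' @export
deskDetectionConfig <- function(seed = 1L, epochs = 60L) {
  detectionConfig(epochs = epochs, depth = 2L, baseChannels = 8L,
                  augment = FALSE, seed = seed)
}

# ---- DetectorModel ---------------------------------------------------------

#' A trained heatmap detector
#'
#' Holds the U-Net weights (those with best validation loss), architecture,
#' the training configuration and the per-epoch loss log.
#'
#' @slot weights list of conv weight matrices and bias vectors
#' @slot depth,baseChannels architecture
#' @slot config the [DetectionConfig-class] used
#' @slot log data.frame(epoch, train_mse, val_mse)
#' @slot bestEpoch epoch whose weights are stored
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(weights = "list", depth = "integer",
                 baseChannels = "integer", config = "DetectionConfig",
                 log = "data.frame", bestEpoch = "integer")
)

# ---- DetectionMetrics ------------------------------------------------------

#' Threshold-sweep detection metrics
#'
#' Per (frame, threshold) true/false positive counts and the dataset-level
#' median/IQR summary over all (frame, threshold) pairs.
#'
#' @slot perFrame data.frame(frame, threshold, tp, fp, n_annotated)
#' @slot summary named list: tp_median, tp_q1, tp_q3, fp_median, fp_q1, fp_q3
#' @slot thresholds the thresholds swept
#' @exportClass DetectionMetrics
setClass("DetectionMetrics",
  representation(perFrame = "data.frame", summary = "list",
                 thresholds = "numeric")
)

# ---- ArtifactQuant ---------------------------------------------------------

#' Per-frame artifact quantification results
#'
#' One row per analysed frame pair: the subtraction threshold, mean artifact
#' width (mm), blood-artifact and agar-artifact CNR, and the exclusion flag.
#' The summary holds median and IQR over non-excluded frames.
#'
#' @slot perFrame data.frame(frame, reference, threshold, width_mm,
#'   cnr_blood, cnr_agar, excluded, reason)
#' @slot summary named list of medians and quartiles
#' @slot masks list of binary masks (kept only if requested)
#' @exportClass ArtifactQuant
setClass("ArtifactQuant",
  representation(perFrame = "data.frame", summary = "list", masks = "list")
)
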