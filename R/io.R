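# Series I/O (NIfTI + JSON sidecar) and the reproducible experiment grid.

.acqToList <- function(acq) list(
  sequence = acq@sequence, te = acq@te, tr = acq@tr,
  flipAngle = acq@flipAngle, sliceThickness = acq@sliceThickness,
  ped = acq@ped, matrixSize = acq@matrixSize,
  pixelSpacing = acq@pixelSpacing, frameRate = acq@frameRate,
  bandwidth = acq@bandwidth)

.acqFromList <- function(x) AcquisitionParams(
  sequence = x$sequence, te = x$te, tr = x$tr, flipAngle = x$flipAngle,
  sliceThickness = x$sliceThickness, ped = x$ped,
  matrixSize = unlist(x$matrixSize), pixelSpacing = unlist(x$pixelSpacing),
  frameRate = x$frameRate,
  bandwidth = if (is.null(x$bandwidth)) NA_real_ else as.numeric(x$bandwidth))

.wireToList <- function(wire) if (is.null(wire)) NULL else list(
  ionpConcentration = wire@ionpConcentration,
  markerLength = wire@markerLength, markerVolume = wire@markerVolume,
  intermarkerGaps = wire@intermarkerGaps, tipPosition = wire@tipPosition,
  axis = wire@axis)

.wireFromList <- function(x) if (is.null(x)) NULL else GuidewireSpec(
  ionpConcentration = x$ionpConcentration, markerLength = x$markerLength,
  markerVolume = x$markerVolume, intermarkerGaps = unlist(x$intermarkerGaps),
  tipPosition = unlist(x$tipPosition), axis = x$axis)

#' Write a series as NIfTI plus a JSON sidecar
#'
#' Frames are stacked on the third NIfTI axis and written as float64 (the
#' round trip is lossless); acquisition parameters, wire, ROIs, ground-truth
#' centres and the seed go to `<path>.json` next to `<path>.nii.gz`.
#'
#' @param series a [MarkerSeries-class]
#' @param path output path without extension
#' @return invisibly, the two file paths
#' @export
writeSeries <- function(series, path) {
  nii <- paste0(path, ".nii.gz")
  js <- paste0(path, ".json")
  img <- RNifti::asNifti(series@frames,
                         pixdim = c(series@acq@pixelSpacing, 1),
                         datatype = "double")
  RNifti::writeNifti(img, nii)
  sidecar <- list(acq = .acqToList(series@acq),
                  wire = .wireToList(series@wire),
                  rois = list(blood = series@rois@blood,
                              agar = series@rois@agar,
                              noise = series@rois@noise),
                  centresPx = series@centresPx,
                  seed = series@seed)
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(nifti = nii, sidecar = js))
}

#' Read a series written by [writeSeries()]
#'
#' Accepts 3-D volumes (frames on axis 3) and 4-D volumes with a singleton
#' third axis (squeezed).  A missing sidecar is an error naming the
#' expected file.
#'
#' @param path path without extension (as given to [writeSeries()])
#' @return a [MarkerSeries-class]
#' @export
readSeries <- function(path) {
  nii <- paste0(path, ".nii.gz")
  if (!file.exists(nii)) nii <- paste0(path, ".nii")
  js <- paste0(path, ".json")
  if (!file.exists(nii)) stop("NIfTI file not found: ", paste0(path, ".nii.gz"))
  if (!file.exists(js)) stop("sidecar file not found: ", js)
  vol <- RNifti::readNifti(nii)
  vol <- array(as.numeric(vol), dim(vol))
  d <- dim(vol)
  if (length(d) == 4 && d[3] == 1) { vol <- vol[, , 1, ]; d <- dim(vol) }
  if (length(d) == 2) { vol <- array(vol, c(d, 1)); d <- dim(vol) }
  if (length(d) != 3) stop("expected a 3-D frame stack, got ",
                           length(d), " dimensions")
  sc <- jsonlite::read_json(js, simplifyVector = TRUE)
  acq <- .acqFromList(sc$acq)
  if (!all(dim(vol)[1:2] == acq@matrixSize))
    stop("NIfTI shape does not match the sidecar matrixSize")
  centres <- matrix(as.integer(unlist(sc$centresPx)), ncol = 2)
  MarkerSeries(frames = vol, acq = acq, wire = .wireFromList(sc$wire),
               rois = ROISet(blood = unlist(sc$rois$blood),
                             agar = unlist(sc$rois$agar),
                             noise = unlist(sc$rois$noise)),
               centresPx = centres,
               seed = if (is.null(sc$seed)) NA_integer_ else sc$seed)
}

#' Run the simulate-and-quantify experiment grid
#'
#' For each requested preset and IONP concentration: simulates a reference
#' and a marker series, runs [quantifyDataset()], and writes the series
#' (optional), the per-frame CSV and a JSON summary into
#' `outDir/<preset>_<conc>/`.  A provenance manifest (configuration, seed,
#' package version) is written at the top level.  Fully deterministic for a
#' fixed seed.
#'
#' @param presets character vector of preset names (see [listPresets()])
#' @param concentrations IONP concentrations (mg/mL)
#' @param seed integer; each dataset derives its own sub-seed from it
#' @param nFrames frames per series
#' @param outDir output directory
#' @param phantom a [PhantomSpec-class]
#' @param writeSeriesFiles also write the NIfTI/JSON series files
#' @param ... passed to [quantifyDataset()]
#' @return named list of [ArtifactQuant-class] results, invisibly; names
#'   are `<preset>_<conc>`
#' @export
runExperimentGrid <- function(presets = "a", concentrations = 6.25,
                              seed = 1L, nFrames = 30L, outDir = tempfile(),
                              phantom = PhantomSpec(),
                              writeSeriesFiles = FALSE, ...) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  bad <- setdiff(presets, listPresets())
  if (length(bad)) stop("unresolvable preset(s): ", paste(bad, collapse = ", "))
  results <- list()
  sub <- 0L
  for (p in presets) for (conc in concentrations) {
    sub <- sub + 1L
    acq <- acquisitionPreset(p)
    wire <- GuidewireSpec(ionpConcentration = conc)
    sRef <- as.integer(seed) + 2L * sub - 1L
    sMark <- as.integer(seed) + 2L * sub
    ref <- simulateSeries(phantom, NULL, acq, nFrames, seed = sRef)
    mark <- simulateSeries(phantom, wire, acq, nFrames, seed = sMark)
    q <- quantifyDataset(mark, ref, ...)
    label <- sprintf("%s_%g", p, conc)
    d <- file.path(outDir, label)
    dir.create(d, showWarnings = FALSE)
    if (writeSeriesFiles) {
      writeSeries(ref, file.path(d, "reference"))
      writeSeries(mark, file.path(d, "marker"))
    }
    utils::write.csv(q@perFrame, file.path(d, "per_frame.csv"),
                     row.names = FALSE)
    jsonlite::write_json(q@summary, file.path(d, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results[[label]] <- q
  }
  manifest <- list(presets = presets, concentrations = concentrations,
                   seed = seed, nFrames = nFrames,
                   package = as.character(utils::packageVersion("MarkerVis")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
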