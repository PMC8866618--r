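# Named acquisition presets shipped as a YAML profile file.

.presetTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- yaml::read_yaml(system.file("extdata", "presets.yaml",
                                            package = "MarkerVis"))
    cache
  }
})

#' Names of the shipped acquisition presets
#'
#' @return character vector ("a" through "h")
#' @export
listPresets <- function() names(.presetTable())

#' Acquisition preset by name
#'
#' Presets a-d are GRE profiles at increasing echo time (TE/TR 2.48/4.6,
#' 2.54/4.8, 3.05/5.8, 6.49/12.1 ms); e-h are bSSFP profiles (1.47/2.9,
#' 1.54/3.1, 1.96/3.9, 4.85/9.6 ms).  `sliceThickness` and `ped` override
#' the baseline values to form the thickness and phase-encoding variants.
#'
#' @param name one of [listPresets()]
#' @param sliceThickness mm, default the preset's (5)
#' @param ped "perpendicular" (default) or "parallel"
#' @return an [AcquisitionParams-class]
#' @examples
#' acquisitionPreset("a")
#' acquisitionPreset("a", ped = "parallel")
#' @export
acquisitionPreset <- function(name, sliceThickness = NULL, ped = NULL) {
  tab <- .presetTable()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  AcquisitionParams(sequence = p$sequence, te = p$te, tr = p$tr,
                    flipAngle = p$flipAngle,
                    sliceThickness = if (is.null(sliceThickness)) p$sliceThickness else sliceThickness,
                    ped = if (is.null(ped)) p$ped else ped,
                    frameRate = p$frameRate, bandwidth = p$bandwidth)
}
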