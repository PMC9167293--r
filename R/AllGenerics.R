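## Accessor generics. Slots are never reached into from user code.

#' @rdname SpectralCube-class
#' @param x an object.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname SpectralCube-class
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectralCube-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname RegionAnnotation-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname RegionAnnotation-class
#' @export
setGeneric("classTable", function(x) standardGeneric("classTable"))

#' @rdname RegionAnnotation-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname PCBasis-class
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname PCBasis-class
#' @export
setGeneric("meanSpectrum", function(x) standardGeneric("meanSpectrum"))

#' @rdname PCBasis-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname PCBasis-class
#' @export
setGeneric("pcaMode", function(x) standardGeneric("pcaMode"))

#' @rdname SphericalField-class
#' @export
setGeneric("azimuth", function(x) standardGeneric("azimuth"))

#' @rdname SphericalField-class
#' @export
setGeneric("elevation", function(x) standardGeneric("elevation"))

#' @rdname SphericalField-class
#' @export
setGeneric("sphRadius", function(x) standardGeneric("sphRadius"))

#' @rdname AngleHistogram2D-class
#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))

#' @rdname ProjectionField-class
#' @export
setGeneric("pcTriplet", function(x) standardGeneric("pcTriplet"))

setMethod("cubeData", "SpectralCube", function(x) x@data)
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)
setMethod("wavelengths", "PCBasis", function(x) x@wavelengths)
setMethod("validMask", "SpectralCube", function(x) x@validMask)
setMethod("validMask", "ProjectionField", function(x) x@validMask)
setMethod("validMask", "SphericalField", function(x) x@validMask)
setMethod("regionLabels", "RegionAnnotation", function(x) x@labels)
setMethod("classTable", "RegionAnnotation", function(x) x@classTable)
setMethod("patientId", "RegionAnnotation", function(x) x@patientId)
setMethod("pcLoadings", "PCBasis", function(x) x@loadings)
setMethod("meanSpectrum", "PCBasis", function(x) x@meanSpectrum)
setMethod("explainedVariance", "PCBasis", function(x) x@explainedVariance)
setMethod("pcaMode", "PCBasis", function(x) x@mode)
setMethod("azimuth", "SphericalField", function(x) x@azimuth)
setMethod("elevation", "SphericalField", function(x) x@elevation)
setMethod("sphRadius", "SphericalField", function(x) x@radius)
setMethod("histCounts", "AngleHistogram2D", function(x) x@counts)
setMethod("pcTriplet", "ProjectionField", function(x) x@triplet)
setMethod("pcTriplet", "SphericalField", function(x) x@triplet)
setMethod("pcTriplet", "StainScheme", function(x) x@triplet)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%s nm)\n",
              d[1], d[2], d[3], paste(object@wavelengths, collapse = ", ")))
  cat(sprintf("  valid pixels: %d / %d\n",
              sum(object@validMask), length(object@validMask)))
  if (length(object@provenance))
    cat("  provenance:", object@provenance[1], "\n")
})

setMethod("show", "RegionAnnotation", function(object) {
  cat(sprintf("RegionAnnotation: patient %s, %d labels over %d x %d pixels\n",
              object@patientId, nrow(object@classTable),
              nrow(object@labels), ncol(object@labels)))
  print(table(object@classTable$class))
})

setMethod("show", "PCBasis", function(object) {
  B <- ncol(object@loadings)
  cat(sprintf("PCBasis: %d bands (%s nm), mode = %s, fit on %d spectra\n",
              B, paste(object@wavelengths, collapse = ", "),
              object@mode, object@fitPixelCount))
  cat("  explained variance ratio:",
      paste(sprintf("%.4f", object@explainedVariance), collapse = " "), "\n")
})

setMethod("show", "ProjectionField", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProjectionField: %d x %d pixels, PC triplet (%s)\n",
              d[1], d[2], paste(object@triplet, collapse = ", ")))
})

setMethod("show", "SphericalField", function(object) {
  cat(sprintf("SphericalField: %d x %d pixels, PC triplet (%s)\n",
              nrow(object@azimuth), ncol(object@azimuth),
              paste(object@triplet, collapse = ", ")))
  ok <- object@validMask
  if (any(ok))
    cat(sprintf("  azimuth range [%.3f, %.3f] rad, median radius %.4f\n",
                min(object@azimuth[ok]), max(object@azimuth[ok]),
                stats::median(object@radius[ok])))
})

setMethod("show", "AngleHistogram2D", function(object) {
  cat(sprintf("AngleHistogram2D: %d x %d bins (azimuth x elevation), %s-weighted, %d pixels\n",
              nrow(object@counts), ncol(object@counts),
              object@weightKind, object@nPixels))
})

setMethod("show", "StainScheme", function(object) {
  hr <- if (anyNA(object@hueRange)) "auto [1st, 99th] percentile"
        else sprintf("[%.3f, %.3f] rad", object@hueRange[1], object@hueRange[2])
  cat(sprintf("StainScheme '%s': hue = %s over PCs (%s), hue range %s\n",
              object@name, object@hueSource,
              paste(object@triplet, collapse = ", "), hr))
})
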