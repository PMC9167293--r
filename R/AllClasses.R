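#' @import methods
NULL

## Central data containers. All image-shaped slots are row-major matrices /
## arrays with dim c(H, W[, B]); the validity mask travels with every object
## so that pixels invalidated upstream (flat-field failures, registration
## borders) never enter pooling, histograms or biomarkers.

#' SpectralCube: a multispectral transmission image cube
#'
#' An H x W x B array of dimensionless transmittance values together with the
#' band-center wavelengths (nm), an H x W validity mask, an optional pixel
#' size, and free-text provenance. Transmittance is expected to lie in
#' [0, 1.5]; the ceiling above unity accommodates shot noise on bright pixels
#' without letting outliers dominate downstream statistics.
#'
#' @slot data numeric array, dim H x W x B, transmittance.
#' @slot wavelengths numeric vector of B strictly increasing band centers (nm).
#' @slot validMask logical H x W matrix; FALSE pixels are excluded everywhere.
#' @slot pixelSize numeric scalar, micrometres per pixel (NA if unknown).
#' @slot provenance character free-text metadata.
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    validMask = "matrix",
    pixelSize = "numeric",
    provenance = "character"
  ),
  prototype(pixelSize = NA_real_, provenance = character(0))
)

setValidity("SpectralCube", function(object) {
  d <- object@data
  msg <- character(0)
  if (length(dim(d)) != 3L)
    msg <- c(msg, "data must be a 3-dimensional H x W x B array")
  else {
    B <- dim(d)[3L]
    if (B < 3L)
      msg <- c(msg, "cube must have at least 3 bands")
    if (length(object@wavelengths) != B)
      msg <- c(msg, "length(wavelengths) must equal the number of bands")
    if (!all(dim(object@validMask) == dim(d)[1:2]))
      msg <- c(msg, "validMask must be an H x W logical matrix")
    v <- d[rep(object@validMask, times = B)]
    v <- v[is.finite(v)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1.5 + 1e-9))
      msg <- c(msg, "valid transmittance values must lie in [0, 1.5]")
  }
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' RegionAnnotation: integer label mask with a class table
#'
#' Pixel labels (0 = unassigned) over a cube, a table mapping every nonzero
#' label present in the mask to a gland class, and the patient identifier.
#' Recognised classes: benign, G3, G4, G5, stroma, inflammation, exclude.
#'
#' @slot labels integer H x W matrix, 0 = background/unassigned.
#' @slot classTable data.frame with columns label (integer) and class.
#' @slot patientId character scalar.
#' @exportClass RegionAnnotation
setClass("RegionAnnotation",
  representation(
    labels = "matrix",
    classTable = "data.frame",
    patientId = "character"
  )
)

.duv_classes <- c("benign", "G3", "G4", "G5", "stroma", "inflammation", "exclude")

setValidity("RegionAnnotation", function(object) {
  msg <- character(0)
  ct <- object@classTable
  if (!all(c("label", "class") %in% names(ct)))
    msg <- c(msg, "classTable needs columns 'label' and 'class'")
  else {
    bad <- setdiff(unique(ct$class), .duv_classes)
    if (length(bad))
      msg <- c(msg, paste0("unknown class name(s): ", paste(bad, collapse = ", ")))
    present <- setdiff(unique(as.vector(object@labels)), 0L)
    missing <- setdiff(present, ct$label)
    if (length(missing))
      msg <- c(msg, paste0("labels present in mask but absent from classTable: ",
                           paste(missing, collapse = ", ")))
  }
  if (any(object@labels %% 1 != 0) || any(object@labels < 0))
    msg <- c(msg, "labels must be non-negative integers")
  if (length(object@patientId) != 1L)
    msg <- c(msg, "patientId must be a single identifier")
  if (length(msg)) msg else TRUE
})

#' PCBasis: sign-fixed principal components of pooled pixel spectra
#'
#' Orthonormal loadings (rows = PC1..PCB over wavelengths), the centering
#' mean spectrum, explained-variance ratios, and the domain the PCA was fit
#' in (transmittance or optical density). Eigenvector signs are fixed by
#' \code{\link{fixSigns}} so that downstream angles are deterministic.
#'
#' @slot loadings numeric B x B matrix, rows are principal components.
#' @slot meanSpectrum numeric length-B centering offset.
#' @slot explainedVariance numeric length-B ratios, non-increasing, sum 1.
#' @slot wavelengths numeric length-B band centers (nm).
#' @slot mode character, "transmittance" or "optical_density".
#' @slot fitPixelCount integer, number of spectra used in the fit.
#' @exportClass PCBasis
setClass("PCBasis",
  representation(
    loadings = "matrix",
    meanSpectrum = "numeric",
    explainedVariance = "numeric",
    wavelengths = "numeric",
    mode = "character",
    fitPixelCount = "integer"
  )
)

setValidity("PCBasis", function(object) {
  msg <- character(0)
  L <- object@loadings
  B <- ncol(L)
  if (nrow(L) != B)
    msg <- c(msg, "loadings must be square (B x B)")
  else if (max(abs(L %*% t(L) - diag(B))) > 1e-10)
    msg <- c(msg, "loadings must be orthonormal (L %*% t(L) == I within 1e-10)")
  evr <- object@explainedVariance
  if (length(evr) != B)
    msg <- c(msg, "explainedVariance must have one entry per PC")
  else {
    if (any(evr < -1e-12) || any(diff(evr) > 1e-12))
      msg <- c(msg, "explainedVariance must be non-negative and non-increasing")
    if (abs(sum(evr) - 1) > 1e-10)
      msg <- c(msg, "explainedVariance must sum to 1 within 1e-10")
  }
  if (length(object@meanSpectrum) != B)
    msg <- c(msg, "meanSpectrum must have one entry per band")
  if (length(object@wavelengths) != B)
    msg <- c(msg, "wavelengths must have one entry per band")
  if (!object@mode %in% c("transmittance", "optical_density"))
    msg <- c(msg, "mode must be 'transmittance' or 'optical_density'")
  if (length(msg)) msg else TRUE
})

#' ProjectionField: per-pixel scores on a PC triplet
#'
#' @slot data numeric H x W x 3 array of centered PC scores.
#' @slot triplet integer vector of 3 distinct PC indices (source order).
#' @slot validMask logical H x W matrix.
#' @exportClass ProjectionField
setClass("ProjectionField",
  representation(data = "array", triplet = "integer", validMask = "matrix")
)

setValidity("ProjectionField", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L || dim(object@data)[3L] != 3L)
    msg <- c(msg, "data must be H x W x 3")
  if (length(object@triplet) != 3L || anyDuplicated(object@triplet) ||
      any(object@triplet < 1L))
    msg <- c(msg, "triplet must be 3 distinct positive PC indices")
  if (!all(dim(object@validMask) == dim(object@data)[1:2]))
    msg <- c(msg, "validMask must match image dimensions")
  if (length(msg)) msg else TRUE
})

#' SphericalField: spherical coordinates of a 3-PC projection
#'
#' Azimuth in (-pi, pi], elevation in [-pi/2, pi/2], radius >= 0, per pixel.
#' The two angles encode spectral shape (molecular composition); the radius
#' is a relative measure of concentration. Azimuth is 0 by convention at the
#' poles and at the origin.
#'
#' @slot azimuth,elevation,radius numeric H x W matrices.
#' @slot triplet integer source PC indices.
#' @slot validMask logical H x W matrix.
#' @exportClass SphericalField
setClass("SphericalField",
  representation(
    azimuth = "matrix", elevation = "matrix", radius = "matrix",
    triplet = "integer", validMask = "matrix"
  )
)

setValidity("SphericalField", function(object) {
  msg <- character(0)
  ok <- object@validMask
  az <- object@azimuth[ok]; el <- object@elevation[ok]; r <- object@radius[ok]
  if (length(az) && (min(az) <= -pi - 1e-12 || max(az) > pi + 1e-12))
    msg <- c(msg, "azimuth must lie in (-pi, pi]")
  if (length(el) && (min(el) < -pi / 2 - 1e-12 || max(el) > pi / 2 + 1e-12))
    msg <- c(msg, "elevation must lie in [-pi/2, pi/2]")
  if (length(r) && min(r) < 0)
    msg <- c(msg, "radius must be non-negative")
  if (!all(dim(object@azimuth) == dim(object@elevation)) ||
      !all(dim(object@azimuth) == dim(object@radius)) ||
      !all(dim(object@azimuth) == dim(object@validMask)))
    msg <- c(msg, "azimuth, elevation, radius and validMask must share dimensions")
  if (length(msg)) msg else TRUE
})

#' AngleHistogram2D: joint azimuth x elevation histogram of a region
#'
#' Bin edges are uniform over (-pi, pi] x [-pi/2, pi/2]. With count
#' weighting the total mass equals the number of contributing pixels.
#'
#' @slot counts numeric azBins x elBins matrix (rows = azimuth bins).
#' @slot azEdges,elEdges numeric monotone bin edges (radians).
#' @slot weightKind character, "count" or "radius".
#' @slot nPixels integer number of contributing pixels.
#' @exportClass AngleHistogram2D
setClass("AngleHistogram2D",
  representation(
    counts = "matrix", azEdges = "numeric", elEdges = "numeric",
    weightKind = "character", nPixels = "integer"
  )
)

setValidity("AngleHistogram2D", function(object) {
  msg <- character(0)
  if (nrow(object@counts) != length(object@azEdges) - 1L ||
      ncol(object@counts) != length(object@elEdges) - 1L)
    msg <- c(msg, "counts dimensions must match bin edges")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (abs(object@azEdges[1] + pi) > 1e-12 ||
      abs(object@azEdges[length(object@azEdges)] - pi) > 1e-12)
    msg <- c(msg, "azimuth edges must span (-pi, pi]")
  if (abs(object@elEdges[1] + pi / 2) > 1e-12 ||
      abs(object@elEdges[length(object@elEdges)] - pi / 2) > 1e-12)
    msg <- c(msg, "elevation edges must span [-pi/2, pi/2]")
  if (!object@weightKind %in% c("count", "radius"))
    msg <- c(msg, "weightKind must be 'count' or 'radius'")
  if (object@weightKind == "count" &&
      abs(sum(object@counts) - object@nPixels) > 1e-6)
    msg <- c(msg, "with count weighting, sum(counts) must equal nPixels")
  if (length(msg)) msg else TRUE
})

#' StainScheme: parameters of one HSV optical stain
#'
#' Three schemes are provided (see \code{\link{stainScheme}}):
#' \code{elevation_123} (hue = elevation over PCs 1-2-3, nuclear contrast),
#' \code{azimuth_234} (hue = azimuth over PCs 2-3-4, stromal contrast), and
#' \code{malignancy_123} (hue = azimuth over PCs 1-2-3, the malignancy map).
#'
#' @slot name character scheme name.
#' @slot triplet integer PC indices.
#' @slot hueSource character, "azimuth" or "elevation".
#' @slot hueRange numeric length-2 angle range (radians) mapped linearly to
#'   hue; NA means the [1st, 99th] percentile of the rendered image's angles.
#' @slot valueClip numeric length-2 radius percentiles for value scaling.
#' @exportClass StainScheme
setClass("StainScheme",
  representation(
    name = "character", triplet = "integer", hueSource = "character",
    hueRange = "numeric", valueClip = "numeric"
  )
)

setValidity("StainScheme", function(object) {
  msg <- character(0)
  if (!object@hueSource %in% c("azimuth", "elevation"))
    msg <- c(msg, "hueSource must be 'azimuth' or 'elevation'")
  hr <- object@hueRange
  if (length(hr) != 2L || (!anyNA(hr) && hr[1] >= hr[2]))
    msg <- c(msg, "hueRange must be c(lo, hi) with lo < hi, or c(NA, NA)")
  vc <- object@valueClip
  if (length(vc) != 2L || vc[1] >= vc[2] || vc[1] < 0 || vc[2] > 100)
    msg <- c(msg, "valueClip must be two percentiles in [0, 100] with lo < hi")
  if (length(msg)) msg else TRUE
})
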