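## Spherical conversion of PC scores, HSV optical stains, and the joint
## azimuth x elevation histogram.

#' Convert a 3-PC projection to spherical coordinates
#'
#' With (x, y, z) the three scores in triplet order:
#' radius = sqrt(x^2 + y^2 + z^2), azimuth = atan2(y, x),
#' elevation = atan2(z, sqrt(x^2 + y^2)). The zero vector and the poles map
#' to azimuth 0 by convention, making the conversion a deterministic total
#' function. The angles carry the spectral-shape (compositional)
#' information; the radius is a relative concentration measure.
#'
#' @param proj a \linkS4class{ProjectionField}.
#' @return A \linkS4class{SphericalField}.
#' @export
toSpherical <- function(proj) {
  stopifnot(is(proj, "ProjectionField"))
  H <- dim(proj@data)[1]; W <- dim(proj@data)[2]
  x <- matrix(proj@data[, , 1], H, W)
  y <- matrix(proj@data[, , 2], H, W)
  z <- matrix(proj@data[, , 3], H, W)
  rho <- sqrt(x^2 + y^2)
  az <- atan2(y, x)
  el <- atan2(z, rho)
  r <- sqrt(rho^2 + z^2)
  zero <- !is.na(r) & r == 0
  az[zero] <- 0; el[zero] <- 0
  az[!is.na(rho) & rho == 0] <- 0          # poles: azimuth undefined -> 0
  bad <- !proj@validMask
  az[bad] <- NA_real_; el[bad] <- NA_real_; r[bad] <- NA_real_
  new("SphericalField", azimuth = az, elevation = el, radius = r,
      triplet = proj@triplet, validMask = proj@validMask)
}

#' Spherical to Cartesian scores (inverse of \code{\link{toSpherical}})
#'
#' @param field a \linkS4class{SphericalField}.
#' @return A \linkS4class{ProjectionField}.
#' @export
toCartesian <- function(field) {
  stopifnot(is(field, "SphericalField"))
  r <- field@radius; az <- field@azimuth; el <- field@elevation
  x <- r * cos(el) * cos(az)
  y <- r * cos(el) * sin(az)
  z <- r * sin(el)
  new("ProjectionField",
      data = array(c(x, y, z), c(nrow(r), ncol(r), 3)),
      triplet = field@triplet, validMask = field@validMask)
}

#' Construct an optical-stain scheme
#'
#' Three schemes reproduce the stains of the pipeline: hue from elevation
#' over PCs 1-2-3 (\code{elevation_123}; strongest nuclear contrast, nuclei
#' at negative elevation), hue from azimuth over PCs 2-3-4
#' (\code{azimuth_234}; protein-vs-nucleic-acid contrast without scattering,
#' stroma bright), and hue from azimuth over PCs 1-2-3
#' (\code{malignancy_123}; scattering relative to absorbers, the glandular
#' malignancy map). Saturation is always 1; value is the radius rescaled by
#' a percentile clip.
#'
#' @param name one of "elevation_123", "azimuth_234", "malignancy_123".
#' @param hueRange angle range (radians) mapped linearly to hue [0, 1];
#'   \code{NULL} (default) uses the [1st, 99th] percentile of the rendered
#'   image's angle distribution. Pass a fixed range when stains from
#'   different images must be comparable.
#' @param valueClip radius percentiles clipped before value scaling
#'   (default c(1, 99)).
#' @return A \linkS4class{StainScheme}.
#' @export
stainScheme <- function(name = c("elevation_123", "azimuth_234", "malignancy_123"),
                        hueRange = NULL, valueClip = c(1, 99)) {
  name <- match.arg(name)
  triplet <- switch(name,
    elevation_123 = c(1L, 2L, 3L),
    azimuth_234 = c(2L, 3L, 4L),
    malignancy_123 = c(1L, 2L, 3L))
  hueSource <- if (name == "elevation_123") "elevation" else "azimuth"
  if (is.null(hueRange)) hueRange <- c(NA_real_, NA_real_)
  new("StainScheme", name = name, triplet = triplet, hueSource = hueSource,
      hueRange = as.numeric(hueRange), valueClip = as.numeric(valueClip))
}

#' Render an HSV optical stain
#'
#' hue = clamp((angle - lo) / (hi - lo), 0, 1); saturation = 1 on every
#' valid pixel; value = radius rescaled to [0, 1] by the scheme's percentile
#' clip. Invalid pixels render black. HSV to RGB uses the standard hexcone
#' transform.
#'
#' @param field a \linkS4class{SphericalField} whose triplet matches the scheme.
#' @param scheme a \linkS4class{StainScheme}.
#' @return numeric H x W x 3 RGB array in [0, 1].
#' @export
renderStain <- function(field, scheme) {
  stopifnot(is(field, "SphericalField"), is(scheme, "StainScheme"))
  if (!identical(field@triplet, scheme@triplet))
    stop(sprintf("field triplet (%s) does not match scheme triplet (%s)",
                 paste(field@triplet, collapse = ","),
                 paste(scheme@triplet, collapse = ",")))
  ok <- field@validMask & is.finite(field@radius)
  angle <- if (scheme@hueSource == "azimuth") field@azimuth else field@elevation
  hr <- scheme@hueRange
  if (anyNA(hr))
    hr <- as.numeric(stats::quantile(angle[ok], c(0.01, 0.99), names = FALSE))
  if (hr[1] >= hr[2]) hr <- hr[1] + c(-1e-6, 1e-6)
  hue <- pmin(pmax((angle - hr[1]) / (hr[2] - hr[1]), 0), 1)
  r <- field@radius
  vc <- stats::quantile(r[ok], scheme@valueClip / 100, names = FALSE)
  if (vc[2] <= vc[1]) vc[2] <- vc[1] + 1e-12
  val <- pmin(pmax((r - vc[1]) / (vc[2] - vc[1]), 0), 1)
  val[ok & r == 0] <- 0                 # zero concentration stays black
  H <- nrow(r); W <- ncol(r)
  rgb <- array(0, c(H, W, 3))
  idx <- which(ok)
  if (length(idx)) {
    cols <- .hsv2rgb(hue[idx], 1, val[idx])
    rgb[idx] <- cols[, 1]
    rgb[idx + H * W] <- cols[, 2]
    rgb[idx + 2 * H * W] <- cols[, 3]
  }
  rgb
}

## Vectorized hexcone HSV -> RGB in double precision (the 8-bit path through
## grDevices::hsv()/col2rgb() would quantize hue, breaking the exact
## equal-angle => equal-color contract).
.hsv2rgb <- function(h, s, v) {
  h6 <- pmin(h, 1 - 1e-12) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  sel <- function(k) i == k
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- p[sel(5)]; b[sel(5)] <- q[sel(5)]
  cbind(r, g, b, deparse.level = 0)
}

#' Write an RGB stain image as 8-bit PNG
#'
#' @param rgb H x W x 3 array in [0, 1] from \code{\link{renderStain}}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeStain <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

## Map angles to 1-based uniform bin indices on (lo, hi]; values at lo (only
## the elevation minimum can sit there) are folded into bin 1.
.angleBin <- function(a, lo, hi, nbins) {
  i <- ceiling((a - lo) / (hi - lo) * nbins)
  pmin(pmax(i, 1L), nbins)
}

#' Joint azimuth x elevation histogram of a masked region
#'
#' Bin edges are uniform over (-pi, pi] x [-pi/2, pi/2]. With
#' \code{weight = "count"} the total mass equals the number of contributing
#' pixels exactly; with \code{weight = "radius"} each pixel contributes its
#' radius.
#'
#' @param field a \linkS4class{SphericalField}.
#' @param mask optional logical H x W matrix restricting the region.
#' @param azBins,elBins bin counts (defaults 360 x 180, one-degree bins).
#' @param weight "count" (default) or "radius".
#' @return An \linkS4class{AngleHistogram2D}.
#' @export
angleHistogram <- function(field, mask = NULL, azBins = 360L, elBins = 180L,
                           weight = c("count", "radius")) {
  stopifnot(is(field, "SphericalField"))
  weight <- match.arg(weight)
  azBins <- as.integer(azBins); elBins <- as.integer(elBins)
  if (azBins < 1L || elBins < 1L) stop("bin counts must be >= 1")
  keep <- field@validMask
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(keep))) stop("mask is not congruent with the field")
    keep <- keep & mask
  }
  idx <- which(keep & is.finite(field@azimuth))
  if (!length(idx)) stop("empty mask: no spectra to histogram")
  ai <- .angleBin(field@azimuth[idx], -pi, pi, azBins)
  ei <- .angleBin(field@elevation[idx], -pi / 2, pi / 2, elBins)
  flat <- (ei - 1L) * azBins + ai
  counts <- numeric(azBins * elBins)
  if (weight == "count") {
    tb <- tabulate(flat, nbins = azBins * elBins)
    counts <- as.numeric(tb)
  } else {
    agg <- rowsum(field@radius[idx], flat)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  new("AngleHistogram2D",
      counts = matrix(counts, azBins, elBins),
      azEdges = seq(-pi, pi, length.out = azBins + 1L),
      elEdges = seq(-pi / 2, pi / 2, length.out = elBins + 1L),
      weightKind = weight, nPixels = length(idx))
}

#' Write a 2D angle histogram as CSV (long format: az_lo, az_hi, el_lo, el_hi, mass)
#'
#' @param hist an \linkS4class{AngleHistogram2D}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeHistogram <- function(hist, path) {
  stopifnot(is(hist, "AngleHistogram2D"))
  az <- hist@azEdges; el <- hist@elEdges
  nA <- length(az) - 1L; nE <- length(el) - 1L
  df <- data.frame(
    az_lo = rep(az[-length(az)], times = nE),
    az_hi = rep(az[-1], times = nE),
    el_lo = rep(el[-length(el)], each = nA),
    el_hi = rep(el[-1], each = nA),
    mass = as.vector(hist@counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
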