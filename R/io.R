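## Cube, reference-frame and annotation I/O, flat-field correction, and
## translation-only channel registration.
##
## Cubes travel as multipage 32-bit float TIFFs with a JSON sidecar
## (<stem>.json) carrying wavelengths, pixel size, provenance and the scale
## factor the pages were divided by before writing (float TIFF storage is
## only defined on [0, 1], while transmittance may reach 1.5). A companion
## <stem>.mask.png is written when any pixel is invalid.

.sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".json")
.maskPath <- function(path) paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".mask.png")

#' Construct a SpectralCube
#'
#' @param data numeric H x W x B array of transmittance values.
#' @param wavelengths numeric vector of B strictly increasing band centers (nm).
#' @param validMask optional logical H x W matrix (default: all valid).
#' @param pixelSize micrometres per pixel, NA if unknown.
#' @param provenance free-text metadata.
#' @return A \linkS4class{SpectralCube}.
#' @export
SpectralCube <- function(data, wavelengths, validMask = NULL,
                         pixelSize = NA_real_, provenance = character(0)) {
  if (is.null(validMask))
    validMask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  new("SpectralCube", data = data, wavelengths = as.numeric(wavelengths),
      validMask = validMask, pixelSize = pixelSize, provenance = provenance)
}

#' Construct a RegionAnnotation
#'
#' @param labels integer H x W matrix of region labels (0 = unassigned).
#' @param classTable data.frame with columns \code{label} and \code{class}.
#' @param patientId patient identifier.
#' @return A \linkS4class{RegionAnnotation}.
#' @export
RegionAnnotation <- function(labels, classTable, patientId) {
  storage.mode(labels) <- "integer"
  classTable$label <- as.integer(classTable$label)
  classTable$class <- as.character(classTable$class)
  new("RegionAnnotation", labels = labels, classTable = classTable,
      patientId = as.character(patientId))
}

#' Read a multispectral cube from a multipage TIFF
#'
#' Pages are interpreted as bands in ascending wavelength order. If a JSON
#' sidecar written by \code{\link{writeCube}} is present, wavelengths, scale
#' and metadata are taken from it; \code{wavelengths} passed here must then
#' agree. The function fails on a channel-count mismatch rather than
#' reordering silently.
#'
#' @param path TIFF file path.
#' @param wavelengths band centers (nm) in the page order of the file;
#'   may be omitted when the sidecar exists.
#' @return A \linkS4class{SpectralCube}.
#' @export
readCube <- function(path, wavelengths = NULL) {
  if (!file.exists(path)) stop("cannot read cube: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  pixelSize <- NA_real_
  provenance <- character(0)
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$pixel_size_um)) {
      ps <- suppressWarnings(as.numeric(meta$pixel_size_um))
      if (length(ps) == 1L && is.finite(ps)) pixelSize <- ps
    }
    if (!is.null(meta$provenance)) provenance <- as.character(unlist(meta$provenance))
    if (!is.null(meta$wavelengths_nm)) {
      if (!is.null(wavelengths) &&
          !isTRUE(all.equal(as.numeric(wavelengths), as.numeric(meta$wavelengths_nm))))
        stop("wavelengths argument disagrees with the sidecar metadata")
      wavelengths <- meta$wavelengths_nm
    }
  }
  if (is.null(wavelengths))
    stop("no wavelengths given and no sidecar metadata found for ", path)
  if (length(pages) != length(wavelengths))
    stop(sprintf("channel-count mismatch: %d TIFF pages but %d wavelengths",
                 length(pages), length(wavelengths)))
  if (any(diff(as.numeric(wavelengths)) <= 0))
    stop("wavelengths must be strictly increasing; reorder the file pages explicitly")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey stored with channels
    p
  })
  d <- dim(pages[[1]])
  arr <- array(NA_real_, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  mask <- matrix(TRUE, d[1], d[2])
  mp <- .maskPath(path)
  if (file.exists(mp)) {
    m <- png::readPNG(mp)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mask <- m > 0.5
  }
  SpectralCube(arr, wavelengths, validMask = mask,
               pixelSize = pixelSize, provenance = provenance)
}

#' Write a multispectral cube as a multipage float TIFF plus JSON sidecar
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "SpectralCube"))
  d <- cubeData(cube)
  scale <- max(1, max(d[is.finite(d)]))
  pages <- lapply(seq_len(dim(d)[3]), function(i) {
    p <- d[, , i] / scale
    p[!is.finite(p)] <- 0
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(wavelengths_nm = wavelengths(cube), scale = scale,
         pixel_size_um = cube@pixelSize, provenance = cube@provenance),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  if (!all(validMask(cube)))
    png::writePNG(validMask(cube) * 1, .maskPath(path))
  invisible(path)
}

#' Flat-field correction of a raw intensity cube
#'
#' Converts raw counts to transmittance, T = (raw - dark) / (bright - dark),
#' per pixel and band, clipped to [0, ceiling]. Pixels where
#' bright <= dark in any band are marked invalid and excluded downstream.
#'
#' @param raw raw intensity cube: \linkS4class{SpectralCube} or H x W x B array.
#' @param bright,dark reference cubes/arrays of the same shape.
#' @param wavelengths band centers, required when \code{raw} is a bare array.
#' @param ceiling transmittance clip ceiling (default 1.5; values above unity
#'   tolerate shot noise on bright pixels).
#' @param maxInvalidFrac error if more than this fraction of pixels has
#'   bright <= dark (default 0.05).
#' @return A \linkS4class{SpectralCube} of transmittance with a validity mask.
#' @export
flatFieldCorrect <- function(raw, bright, dark, wavelengths = NULL,
                             ceiling = 1.5, maxInvalidFrac = 0.05) {
  if (is(raw, "SpectralCube")) {
    if (is.null(wavelengths)) wavelengths <- wavelengths(raw)
    raw <- cubeData(raw)
  }
  if (is(bright, "SpectralCube")) bright <- cubeData(bright)
  if (is(dark, "SpectralCube")) dark <- cubeData(dark)
  if (is.null(wavelengths)) stop("wavelengths are required")
  if (!all(dim(raw) == dim(bright)) || !all(dim(raw) == dim(dark)))
    stop("raw, bright and dark must share the same shape")
  denom <- bright - dark
  bad <- denom <= 0
  invalid <- apply(bad, c(1, 2), any)
  frac <- mean(invalid)
  if (frac > maxInvalidFrac)
    stop(sprintf("bright <= dark over %.1f%% of pixels (limit %.1f%%)",
                 100 * frac, 100 * maxInvalidFrac))
  denom[bad] <- 1
  T <- (raw - dark) / denom
  T[bad] <- NA_real_
  T <- pmin(pmax(T, 0), ceiling)
  SpectralCube(T, wavelengths, validMask = !invalid,
               provenance = "flat-field corrected")
}

## Phase correlation between two equally sized bands. Returns the (dy, dx)
## translation that moves `band` onto `ref`, plus the normalized peak height.
.phaseCorrelate <- function(ref, band, subpixel = FALSE) {
  if (stats::sd(ref) == 0 || stats::sd(band) == 0)
    return(list(shift = c(0, 0), peak = NA_real_, degenerate = TRUE))
  Fr <- stats::fft(ref)
  Fb <- stats::fft(band)
  R <- Fr * Conj(Fb)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- nrow(r); m <- ncol(r)
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > n / 2) dy <- dy - n
  if (dx > m / 2) dx <- dx - m
  shift <- c(dy, dx)
  if (subpixel) {
    ## parabolic interpolation of the correlation peak, per axis
    para <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (abs(den) < 1e-15) 0 else 0.5 * (cm - cp) / den
    }
    iy <- pk[1]; ix <- pk[2]
    ym <- r[(iy - 2) %% n + 1, ix]; yp <- r[iy %% n + 1, ix]
    xm <- r[iy, (ix - 2) %% m + 1]; xp <- r[iy, ix %% m + 1]
    shift <- shift + c(para(ym, r[iy, ix], yp), para(xm, r[iy, ix], xp))
  }
  list(shift = shift, peak = max(r), degenerate = FALSE)
}

## Translate a band by (dy, dx) (integer: index shift; fractional: Fourier
## shift theorem). Returns the shifted band; callers invalidate the border.
.translateBand <- function(band, shift) {
  n <- nrow(band); m <- ncol(band)
  if (all(shift == round(shift))) {
    dy <- as.integer(round(shift[1])); dx <- as.integer(round(shift[2]))
    out <- matrix(NA_real_, n, m)
    src_r <- seq_len(n) - dy
    src_c <- seq_len(m) - dx
    ok_r <- src_r >= 1 & src_r <= n
    ok_c <- src_c >= 1 & src_c <= m
    out[ok_r, ok_c] <- band[src_r[ok_r], src_c[ok_c]]
    return(out)
  }
  ky <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / n
  kx <- c(0:floor((m - 1) / 2), -(ceiling((m - 1) / 2):1)) / m
  ph <- exp(-2i * pi * (outer(ky * shift[1], rep(1, m)) +
                        outer(rep(1, n), kx * shift[2])))
  Re(stats::fft(stats::fft(band) * ph, inverse = TRUE)) / (n * m)
}

#' Register wavelength channels by phase correlation
#'
#' Chromatic shifts in a fixed transmission optical train are predominantly
#' translational, so each non-reference band is aligned to the reference by
#' a translation estimated from the phase-correlation peak. Pixels falling
#' off the border are invalidated. A constant (degenerate) band or a band
#' with no correlated structure yields a zero shift with a warning.
#'
#' @param cube a \linkS4class{SpectralCube} with at least 2 bands.
#' @param referenceBand index of the band others are aligned to (default 1).
#' @param subpixel logical; refine the integer shift by parabolic peak
#'   interpolation and apply it via the Fourier shift theorem (default FALSE).
#' @param minPeak minimum normalized correlation peak below which a band is
#'   treated as uncorrelated noise: zero shift, warning (default 0.1).
#' @return A list with \code{cube} (registered \linkS4class{SpectralCube})
#'   and \code{shifts} (B x 2 matrix of applied (dy, dx) translations).
#' @export
registerChannels <- function(cube, referenceBand = 1L, subpixel = FALSE,
                             minPeak = 0.1) {
  stopifnot(is(cube, "SpectralCube"))
  d <- cubeData(cube)
  B <- dim(d)[3]
  if (B < 2L) stop("registration needs at least 2 bands")
  ref <- d[, , referenceBand]
  shifts <- matrix(0, B, 2, dimnames = list(NULL, c("dy", "dx")))
  out <- d
  mask <- validMask(cube)
  for (b in seq_len(B)) {
    if (b == referenceBand) next
    pc <- .phaseCorrelate(ref, d[, , b], subpixel = subpixel)
    if (pc$degenerate) {
      warning(sprintf("band %d is constant; correlation undefined, using zero shift", b))
      next
    }
    if (is.finite(pc$peak) && pc$peak < minPeak) {
      warning(sprintf("band %d shows no correlated structure (peak %.3f); using zero shift",
                      b, pc$peak))
      next
    }
    shifts[b, ] <- pc$shift
    shifted <- .translateBand(d[, , b], pc$shift)
    lost <- is.na(shifted)
    shifted[lost] <- 0
    out[, , b] <- shifted
    mask <- mask & !lost
    ## fractional shifts contaminate a 1-px border via the periodic FFT wrap
    if (any(pc$shift != round(pc$shift))) {
      n <- nrow(mask); m <- ncol(mask)
      w_r <- seq_len(min(n, ceiling(abs(pc$shift[1])) + 1))
      w_c <- seq_len(min(m, ceiling(abs(pc$shift[2])) + 1))
      if (pc$shift[1] > 0) mask[w_r, ] <- FALSE else if (pc$shift[1] < 0) mask[n + 1 - w_r, ] <- FALSE
      if (pc$shift[2] > 0) mask[, w_c] <- FALSE else if (pc$shift[2] < 0) mask[, m + 1 - w_c] <- FALSE
    }
  }
  reg <- SpectralCube(pmin(pmax(out, 0), 1.5), wavelengths(cube),
                      validMask = mask, pixelSize = cube@pixelSize,
                      provenance = c(cube@provenance, "channel-registered"))
  list(cube = reg, shifts = shifts)
}

#' Read a region annotation (label image + class table)
#'
#' @param labelPath integer label image, 16-bit TIFF (as written by
#'   \code{\link{writeAnnotation}}) or PNG.
#' @param classTablePath CSV with columns \code{label,class,patient_id}.
#' @return A \linkS4class{RegionAnnotation}.
#' @export
readAnnotation <- function(labelPath, classTablePath) {
  ext <- tolower(tools::file_ext(labelPath))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(labelPath, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(labelPath)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 16L
    img <- round(img * (2^depth - 1))
  } else stop("unsupported label image format: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (any(img %% 1 != 0)) stop("label image must be integer-valued")
  ct <- utils::read.csv(classTablePath, stringsAsFactors = FALSE)
  need <- c("label", "class", "patient_id")
  if (!all(need %in% names(ct)))
    stop("class table must have columns label, class, patient_id")
  pid <- unique(ct$patient_id)
  if (length(pid) != 1L)
    stop("class table must describe exactly one patient")
  RegionAnnotation(img, ct[, c("label", "class")], pid)
}

#' Write a region annotation as 16-bit TIFF + CSV
#'
#' @param annotation a \linkS4class{RegionAnnotation}.
#' @param labelPath output TIFF path (labels must be < 65536).
#' @param classTablePath output CSV path.
#' @return \code{labelPath}, invisibly.
#' @export
writeAnnotation <- function(annotation, labelPath, classTablePath) {
  stopifnot(is(annotation, "RegionAnnotation"))
  lab <- regionLabels(annotation)
  if (max(lab) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(lab / 65535, labelPath, bits.per.sample = 16L)
  ct <- classTable(annotation)
  ct$patient_id <- patientId(annotation)
  utils::write.csv(ct, classTablePath, row.names = FALSE)
  invisible(labelPath)
}
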