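## Pooling of pixel spectra, the sign-fixed principal-component basis, and
## projection of cubes onto PC triplets.
##
## One basis is fit on pooled representative regions and then applied to
## every cube, mirroring the single-basis design of the imaging study the
## method derives from (a single cohort-level basis keeps azimuth/elevation
## angles comparable across patients).

#' Pool pixel spectra from one or more cubes
#'
#' Collects the spectra of all valid (and, if given, masked) pixels into an
#' N x B matrix, one row per pixel. If more pixels are available than
#' \code{maxPixels}, a seeded uniform subsample of exactly \code{maxPixels}
#' rows is returned, so fits stay reproducible at any pooling size.
#'
#' @param cubes a \linkS4class{SpectralCube} or list of them (shared wavelengths).
#' @param masks optional logical mask or list of masks, congruent with the cubes.
#' @param maxPixels cap on the number of returned spectra (default Inf).
#' @param seed integer seed used only when subsampling.
#' @return numeric N x B matrix of pixel spectra.
#' @export
poolSpectra <- function(cubes, masks = NULL, maxPixels = Inf, seed = 1L) {
  if (is(cubes, "SpectralCube")) cubes <- list(cubes)
  if (!is.null(masks) && is.matrix(masks)) masks <- list(masks)
  wl <- wavelengths(cubes[[1]])
  rows <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    cb <- cubes[[i]]
    if (!isTRUE(all.equal(wavelengths(cb), wl)))
      stop("all cubes must share the same wavelengths")
    keep <- validMask(cb)
    if (!is.null(masks)) {
      m <- masks[[i]]
      if (!all(dim(m) == dim(keep)))
        stop("mask ", i, " is not congruent with its cube")
      keep <- keep & m
    }
    d <- cubeData(cb)
    B <- dim(d)[3]
    idx <- which(keep)
    if (length(idx)) {
      sp <- matrix(NA_real_, length(idx), B)
      for (b in seq_len(B)) sp[, b] <- d[, , b][idx]
      rows[[i]] <- sp
    }
  }
  X <- do.call(rbind, rows)
  if (is.null(X) || nrow(X) == 0L)
    stop("no valid pixels to pool")
  if (nrow(X) > maxPixels) {
    old <- .seedSwap(seed)
    on.exit(.seedRestore(old))
    X <- X[sort(sample.int(nrow(X), maxPixels)), , drop = FALSE]
  }
  X
}

## Temporarily replace the RNG state; generators must never clobber a user's
## random stream.
.seedSwap <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.seedRestore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Fit the principal-component basis of pooled pixel spectra
#'
#' Mean-centered PCA of the N x B spectra matrix. With
#' \code{mode = "optical_density"} the spectra are first transformed to
#' OD = -log10(max(T, 1e-4)). Loadings are sign-fixed by
#' \code{\link{fixSigns}} so that every downstream angle is deterministic.
#' Rank-deficient inputs are allowed; trailing explained-variance ratios are
#' then zero.
#'
#' @param spectra numeric N x B matrix, N > B, finite entries.
#' @param wavelengths band centers (nm), default c(220, 255, 280, 300).
#' @param mode "transmittance" (default) or "optical_density".
#' @return A \linkS4class{PCBasis}.
#' @export
fitPCA <- function(spectra, wavelengths = c(220, 255, 280, 300),
                   mode = c("transmittance", "optical_density")) {
  mode <- match.arg(mode)
  spectra <- as.matrix(spectra)
  B <- ncol(spectra)
  if (nrow(spectra) <= B) stop("need more spectra than bands")
  if (!all(is.finite(spectra))) stop("spectra must be finite")
  if (length(wavelengths) != B) stop("wavelengths must match the band count")
  if (mode == "optical_density")
    spectra <- -log10(pmax(spectra, 1e-4))
  fit <- stats::prcomp(spectra, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  evr <- ev / sum(ev)
  loadings <- t(fit$rotation)          # rows = PCs over wavelengths
  dimnames(loadings) <- NULL
  ## prcomp can return fewer columns than B for exactly rank-deficient input;
  ## pad with an orthonormal completion and zero variance
  if (nrow(loadings) < B) {
    comp <- qr.Q(qr(t(loadings)), complete = TRUE)[, (nrow(loadings) + 1):B, drop = FALSE]
    loadings <- rbind(loadings, t(comp))
    evr <- c(evr, rep(0, B - length(evr)))
  }
  basis <- new("PCBasis", loadings = loadings, meanSpectrum = as.numeric(fit$center),
               explainedVariance = evr, wavelengths = as.numeric(wavelengths),
               mode = mode, fitPixelCount = nrow(spectra))
  fixSigns(basis)
}

#' Fix eigenvector signs to the package's deterministic convention
#'
#' Eigenvector sign is arbitrary, yet every azimuth and elevation angle
#' downstream depends on it, so a fixed convention is applied, anchored in
#' the characteristic shapes of the components on 4-band deep-UV spectra:
#' \itemize{
#'   \item PC1 is flipped if its loading sum is negative (unipolar,
#'     overall-attenuation component kept non-negative);
#'   \item PC2 is flipped if its loading nearest 280 nm is negative
#'     (protein absorption peak kept positive);
#'   \item PC3 is flipped if its loading nearest 255 nm is positive
#'     (nucleic-acid peak kept inverted, i.e. negative at 255 nm);
#'   \item PC4 is flipped if its loading nearest 280 nm is negative;
#'   \item any further PCs are flipped if their loading sum is negative.
#' }
#' Idempotent; a total function on orthonormal bases.
#'
#' @param basis a \linkS4class{PCBasis}.
#' @return The basis with the sign convention applied.
#' @export
fixSigns <- function(basis) {
  stopifnot(is(basis, "PCBasis"))
  L <- basis@loadings
  wl <- basis@wavelengths
  B <- ncol(L)
  near <- function(nm) which.min(abs(wl - nm))
  flip <- logical(nrow(L))
  flip[1] <- sum(L[1, ]) < 0
  if (B >= 2) flip[2] <- L[2, near(280)] < 0
  if (B >= 3) flip[3] <- L[3, near(255)] > 0
  if (B >= 4) flip[4] <- L[4, near(280)] < 0
  if (B >= 5) for (k in 5:B) flip[k] <- sum(L[k, ]) < 0
  L[flip, ] <- -L[flip, , drop = FALSE]
  basis@loadings <- L
  basis
}

#' Project a cube onto a PC triplet
#'
#' Per valid pixel, score_i = (spectrum - meanSpectrum) . PC_i for the three
#' requested components (set \code{center = FALSE} for uncentered projection).
#' A basis fit in optical-density mode transforms the cube the same way
#' before projecting. Invalid pixels propagate as NA scores.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param basis a \linkS4class{PCBasis} with matching wavelengths.
#' @param triplet ordered PC indices, typically c(1, 2, 3) or c(2, 3, 4).
#' @param center subtract the basis mean spectrum before projecting
#'   (default TRUE, standard PCA scores).
#' @return A \linkS4class{ProjectionField}.
#' @export
projectCube <- function(cube, basis, triplet = c(1L, 2L, 3L), center = TRUE) {
  stopifnot(is(cube, "SpectralCube"), is(basis, "PCBasis"))
  if (!isTRUE(all.equal(wavelengths(cube), wavelengths(basis))))
    stop("cube and basis wavelengths differ")
  triplet <- as.integer(triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet) ||
      any(triplet < 1L) || any(triplet > ncol(basis@loadings)))
    stop("triplet must be 3 distinct PC indices within the basis")
  d <- cubeData(cube)
  H <- dim(d)[1]; W <- dim(d)[2]; B <- dim(d)[3]
  X <- matrix(d, H * W, B)
  if (pcaMode(basis) == "optical_density")
    X <- -log10(pmax(X, 1e-4))
  if (center) X <- sweep(X, 2, meanSpectrum(basis))
  S <- X %*% t(basis@loadings[triplet, , drop = FALSE])
  S[!validMask(cube), ] <- NA_real_
  new("ProjectionField", data = array(S, c(H, W, 3)), triplet = triplet,
      validMask = validMask(cube))
}

#' Serialize a PCBasis to JSON
#'
#' @param basis a \linkS4class{PCBasis}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeBasis <- function(basis, path) {
  stopifnot(is(basis, "PCBasis"))
  jsonlite::write_json(list(
    loadings = basis@loadings, mean_spectrum = basis@meanSpectrum,
    explained_variance_ratio = basis@explainedVariance,
    wavelengths_nm = basis@wavelengths, mode = basis@mode,
    sign_rule_version = 1L, fit_pixel_count = basis@fitPixelCount
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PCBasis from JSON
#'
#' @param path JSON path written by \code{\link{writeBasis}}.
#' @return A \linkS4class{PCBasis}.
#' @export
readBasis <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PCBasis", loadings = as.matrix(j$loadings),
      meanSpectrum = as.numeric(j$mean_spectrum),
      explainedVariance = as.numeric(j$explained_variance_ratio),
      wavelengths = as.numeric(j$wavelengths_nm), mode = j$mode,
      fitPixelCount = as.integer(j$fit_pixel_count))
}
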