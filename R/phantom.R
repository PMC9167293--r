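## Seeded Beer-Lambert tissue phantoms with gland/lumen/stroma geometry.
##
## Pixel spectra are transmittance mixtures of a nucleic-acid-like absorber
## (255 nm peak), a protein-like absorber (280 nm peak) and a power-law
## scattering attenuation, T(lambda) = exp(-d * [c_NA*eps_NA + c_prot*eps_prot
## + s*(lambda/220)^-b]). Epithelium is nucleic-acid rich, stroma dark and
## protein rich, lumina empty. Grade phenotypes scale the benign epithelial
## composition: the non-aggressive preset raises absorber concentrations with
## grade, the aggressive preset shifts the composition toward scattering at a
## similar total attenuation (scattering up, absorbers down), reproducing the
## opposite-signed azimuth shifts of the two clinical phenotypes.

#' Deep-UV endmember attenuation table
#'
#' Relative attenuation coefficients of the two molecular endmembers over the
#' four bands, plus the scattering power-law exponent. The coefficient values
#' are package constants shaped to the known band assignments (nucleic-acid
#' peak at 255 nm, protein peak at 280 nm, both near zero at 300 nm,
#' scattering strictly decreasing in wavelength); their absolute scale is
#' arbitrary since concentrations multiply them.
#'
#' @param scatteringExponent power-law exponent b of the scattering
#'   attenuation (lambda/220)^-b; default 2, within the range typical of
#'   tissue power-law scattering.
#' @return list with \code{wavelengths}, \code{epsilon} (2 x 4 matrix, rows
#'   nucleic_acid and protein), \code{scattering} (length-4 attenuation) and
#'   \code{scatteringExponent}.
#' @export
uvEndmembers <- function(scatteringExponent = 2) {
  wl <- c(220, 255, 280, 300)
  eps <- rbind(
    nucleic_acid = c(0.60, 1.00, 0.55, 0.05),
    protein      = c(0.70, 0.45, 1.00, 0.05))
  colnames(eps) <- wl
  sc <- (wl / 220)^(-scatteringExponent)
  stopifnot(which.max(eps["nucleic_acid", ]) == 2L,
            which.max(eps["protein", ]) == 3L,
            all(diff(sc) < 0))
  list(wavelengths = wl, epsilon = eps, scattering = sc,
       scatteringExponent = scatteringExponent)
}

#' Beer-Lambert transmittance of concentration maps
#'
#' T(lambda) = exp(-d * [c_NA*eps_NA(lambda) + c_prot*eps_prot(lambda) +
#' s*(lambda/220)^-b]). Optical densities of the components add, so mixtures
#' multiply in transmittance.
#'
#' @param conc N x 3 matrix or H x W x 3 array of non-negative
#'   concentrations (c_NA, c_prot, s).
#' @param endmembers from \code{\link{uvEndmembers}}.
#' @param thickness relative path length d (default 1).
#' @return transmittance, N x B matrix or H x W x B array matching the input.
#' @export
beerLambertTransmittance <- function(conc, endmembers = uvEndmembers(),
                                     thickness = 1) {
  dims <- dim(conc)
  asArray <- length(dims) == 3L
  C <- if (asArray) matrix(conc, prod(dims[1:2]), 3) else as.matrix(conc)
  if (ncol(C) != 3L) stop("concentrations must have 3 components (c_NA, c_prot, s)")
  if (any(C < 0)) stop("concentrations must be non-negative")
  E <- rbind(endmembers$epsilon, scattering = endmembers$scattering)
  T <- exp(-thickness * (C %*% E))
  if (asArray) array(T, c(dims[1:2], ncol(E))) else T
}

#' Phenotype presets for the phantom generator
#'
#' Two documented presets with identical benign composition:
#' \code{non_aggressive} scales the absorber concentrations up with grade
#' (scattering unchanged), \code{aggressive} scales the scattering fraction
#' up relative to the absorbers (scattering x k, absorbers x 1/k) so that
#' the composition, not the total attenuation, changes. Multipliers per
#' grade: G3 1.12, G4 1.20, G5 1.30.
#'
#' @param preset "non_aggressive" or "aggressive".
#' @return list mapping class to (c_NA, c_prot, s) multipliers.
#' @export
phenotypePresets <- function(preset = c("non_aggressive", "aggressive")) {
  if (!is.character(preset) || !preset[1] %in% c("non_aggressive", "aggressive"))
    stop("unknown preset: ", preset[1])
  preset <- preset[1]
  k <- c(benign = 1, G3 = 1.12, G4 = 1.20, G5 = 1.30)
  lapply(k, function(ki) {
    if (preset == "non_aggressive") c(ki, ki, 1)
    else c(1 / ki, 1 / ki, ki)
  })
}

#' Phantom specification
#'
#' Defaults define the study conditions every test and example runs under:
#' a 192 x 192 canvas with 8 non-overlapping glands cycling through benign,
#' G3, G4 and G5, benign epithelium (c_NA, c_prot, s) = (0.55, 0.45, 0.50),
#' dark protein-rich stroma (0.40, 1.30, 0.90), empty lumina occupying half
#' of each gland radius, 4 percent per-pixel concentration jitter (cellular
#' heterogeneity) and 0.5 percent additive Gaussian transmittance noise.
#'
#' @param size c(H, W) canvas in pixels.
#' @param nGlands number of glands (0 gives a pure-stroma phantom).
#' @param radiusRange gland radius range in pixels.
#' @param lumenFraction lumen radius as a fraction of gland radius.
#' @param classes gland classes, recycled over glands.
#' @param preset phenotype preset name (see \code{\link{phenotypePresets}}).
#' @param benign benign epithelial concentrations (c_NA, c_prot, s).
#' @param stroma stromal concentrations.
#' @param thickness relative path length d.
#' @param noiseSd additive Gaussian noise sd on transmittance.
#' @param jitterSd per-pixel relative concentration jitter sd.
#' @param endmembers from \code{\link{uvEndmembers}}.
#' @param seed integer RNG seed.
#' @param patientId identifier stamped on the annotation.
#' @return validated spec (list of class "PhantomSpec").
#' @export
phantomSpec <- function(size = c(192L, 192L), nGlands = 8L,
                        radiusRange = c(14, 24), lumenFraction = 0.5,
                        classes = c("benign", "G3", "G4", "G5"),
                        preset = "non_aggressive",
                        benign = c(0.55, 0.45, 0.50),
                        stroma = c(0.40, 1.30, 0.90),
                        thickness = 1, noiseSd = 0.005, jitterSd = 0.04,
                        endmembers = uvEndmembers(), seed = 1L,
                        patientId = "phantom-01") {
  spec <- list(size = as.integer(size), nGlands = as.integer(nGlands),
               radiusRange = radiusRange, lumenFraction = lumenFraction,
               classes = classes, preset = preset, benign = benign,
               stroma = stroma, thickness = thickness, noiseSd = noiseSd,
               jitterSd = jitterSd, endmembers = endmembers,
               seed = as.integer(seed), patientId = patientId)
  stopifnot(length(spec$size) == 2L, all(spec$size >= 16L),
            spec$nGlands >= 0L, spec$lumenFraction > 0, spec$lumenFraction < 1,
            all(spec$benign >= 0), all(spec$stroma >= 0),
            spec$noiseSd >= 0, spec$jitterSd >= 0, spec$thickness > 0,
            all(spec$classes %in% c("benign", "G3", "G4", "G5")))
  phenotypePresets(spec$preset)      # validates the preset name
  class(spec) <- "PhantomSpec"
  spec
}

#' Generate a seeded multispectral tissue phantom
#'
#' Lays out non-overlapping circular glands (annular epithelium around an
#' empty lumen) on a stromal background, assigns each gland its class's
#' phenotype composition, renders transmittance through
#' \code{\link{beerLambertTransmittance}}, adds seeded Gaussian noise and
#' clips to [0, 1.5]. Identical seeds give bit-identical outputs; the
#' caller's RNG state is left untouched.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{cube} (\linkS4class{SpectralCube}),
#'   \code{annotation} (\linkS4class{RegionAnnotation}; gland labels 1..n
#'   carry their class, the stroma carries label n+1, lumina are label 0)
#'   and \code{truth} (per-gland table of true concentrations).
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old <- .seedSwap(spec$seed)
  on.exit(.seedRestore(old))
  H <- spec$size[1]; W <- spec$size[2]
  mult <- phenotypePresets(spec$preset)
  classes <- rep_len(spec$classes, max(spec$nGlands, 1L))
  ## gland placement by rejection sampling
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  attempts <- 0L
  while (nrow(centers) < spec$nGlands) {
    attempts <- attempts + 1L
    if (attempts > 200L * max(spec$nGlands, 1L))
      stop("gland geometry infeasible: cannot place ", spec$nGlands,
           " non-overlapping glands on a ", H, " x ", W, " canvas")
    r <- stats::runif(1, spec$radiusRange[1], spec$radiusRange[2])
    cy <- stats::runif(1, r + 1, H - r)
    cx <- stats::runif(1, r + 1, W - r)
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) > radii + r + 2)) {
      centers <- rbind(centers, c(cy, cx))
      radii <- c(radii, r)
    }
  }
  ## concentration maps: stroma background, then glands
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  conc <- array(rep(spec$stroma, each = H * W), c(H, W, 3))
  labels <- matrix(spec$nGlands + 1L, H, W)     # stroma label
  truth <- data.frame(label = integer(0), class = character(0),
                      c_na = numeric(0), c_prot = numeric(0), s = numeric(0))
  for (g in seq_len(spec$nGlands)) {
    d2 <- sqrt((yy - centers[g, 1])^2 + (xx - centers[g, 2])^2)
    rl <- spec$lumenFraction * radii[g]
    ring <- d2 <= radii[g] & d2 > rl
    lum <- d2 <= rl
    cvec <- spec$benign * mult[[classes[g]]]
    for (k in 1:3) {
      pl <- conc[, , k]
      pl[ring] <- cvec[k]
      pl[lum] <- 0
      conc[, , k] <- pl
    }
    labels[ring] <- g
    labels[lum] <- 0L
    truth <- rbind(truth, data.frame(label = g, class = classes[g],
                                     c_na = cvec[1], c_prot = cvec[2], s = cvec[3]))
  }
  ## per-pixel multiplicative jitter (truncated at zero), then forward model
  if (spec$jitterSd > 0)
    conc <- pmax(conc * (1 + array(stats::rnorm(H * W * 3, 0, spec$jitterSd),
                                   c(H, W, 3))), 0)
  T <- beerLambertTransmittance(conc, spec$endmembers, spec$thickness)
  if (spec$noiseSd > 0)
    T <- T + array(stats::rnorm(length(T), 0, spec$noiseSd), dim(T))
  T <- pmin(pmax(T, 0), 1.5)
  ct <- rbind(truth[, c("label", "class")],
              data.frame(label = spec$nGlands + 1L, class = "stroma"))
  list(
    cube = SpectralCube(T, spec$endmembers$wavelengths,
                        provenance = sprintf("phantom preset=%s seed=%d",
                                             spec$preset, spec$seed)),
    annotation = RegionAnnotation(labels, ct, spec$patientId),
    truth = truth)
}
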