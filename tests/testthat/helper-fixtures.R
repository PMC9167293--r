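## Shared in-code fixtures. Everything is generated at test time; no binary
## files ship with the package.

## A small deterministic cube with smooth spatial structure (registration
## and projection tests need correlated bands, not white noise).
makeTestCube <- function(H = 48, W = 48, seed = 11) {
  set.seed(seed)
  base <- outer(sin(seq(0, 4 * pi, length.out = H)),
                cos(seq(0, 3 * pi, length.out = W))) * 0.2 + 0.5
  arr <- array(NA_real_, c(H, W, 4))
  for (b in 1:4) arr[, , b] <- pmin(pmax(base * (0.7 + 0.1 * b) +
                                         matrix(rnorm(H * W, 0, 0.002), H, W), 0), 1.5)
  SpectralCube(arr, c(220, 255, 280, 300))
}

## Orthonormal 4x4 basis with a fixed rotation seed, sign rules applied.
makeTestBasis <- function(seed = 3) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  b <- new("PCBasis", loadings = t(Q), meanSpectrum = rep(0.5, 4),
           explainedVariance = c(0.7, 0.2, 0.08, 0.02),
           wavelengths = c(220, 255, 280, 300), mode = "transmittance",
           fitPixelCount = 100L)
  fixSigns(b)
}

## SphericalField built directly from given angle/radius matrices.
makeSphericalField <- function(az, el, r, triplet = c(1L, 2L, 3L)) {
  new("SphericalField", azimuth = az, elevation = el, radius = r,
      triplet = triplet, validMask = matrix(TRUE, nrow(az), ncol(az)))
}

## Small, fast phantom used across modules.
smallPhantom <- function(seed = 1, preset = "non_aggressive", size = 96L) {
  generatePhantom(phantomSpec(size = c(size, size), nGlands = 5L,
                              radiusRange = c(10, 15), preset = preset,
                              seed = seed))
}

## Full small-scale biomarker chain for one phantom; returns the shift table.
phantomShifts <- function(seed, preset, size = 128L, nGlands = 8L) {
  ph <- generatePhantom(phantomSpec(size = c(size, size), nGlands = nGlands,
                                    radiusRange = c(12, 18), preset = preset,
                                    seed = seed))
  basis <- fitPCA(poolSpectra(ph$cube), wavelengths = wavelengths(ph$cube))
  fld <- toSpherical(projectCube(ph$cube, basis, c(1L, 2L, 3L)))
  relativeShifts(perClassCoM(fld, ph$annotation))
}
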