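## Independent oracle: explicit covariance matrix + symmetric eigensolver.
bruteForcePCA <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors, mean = mu)
}

test_that("poolSpectra counts, masks and seeded subsampling behave", {
  c1 <- makeTestCube(10, 10, seed = 1)
  c2 <- makeTestCube(10, 10, seed = 2)
  X <- poolSpectra(list(c1, c2))
  expect_equal(dim(X), c(200, 4))

  m <- matrix(FALSE, 10, 10); m[1:37] <- TRUE
  expect_equal(nrow(poolSpectra(c1, masks = m)), 37)

  s1 <- poolSpectra(list(c1, c2), maxPixels = 50, seed = 42)
  s2 <- poolSpectra(list(c1, c2), maxPixels = 50, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 50)

  expect_error(poolSpectra(c1, masks = matrix(FALSE, 10, 10)), "no valid pixels")
  c3 <- SpectralCube(cubeData(c2), c(200, 255, 280, 300))
  expect_error(poolSpectra(list(c1, c3)), "wavelengths")
})

test_that("fitPCA matches brute-force covariance eigendecomposition", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(20:1000, 1)
    X <- matrix(rnorm(n * 4, mean = 0.5, sd = 0.2), n, 4)
    basis <- fitPCA(X)
    bf <- bruteForcePCA(X)
    expect_equal(meanSpectrum(basis), bf$mean, tolerance = 1e-12)
    expect_equal(explainedVariance(basis), bf$values / sum(bf$values),
                 tolerance = 1e-10)
    L <- pcLoadings(basis)
    for (k in 1:4) {
      v <- bf$vectors[, k]
      if (sum(v * L[k, ]) < 0) v <- -v       # align oracle sign
      expect_lt(max(abs(L[k, ] - v)), 1e-8)
    }
  }
})

test_that("rank-1 and rank-deficient spectra give clean variance ratios", {
  set.seed(2)
  v <- c(1, 2, 3, 4) / sqrt(30)
  m <- c(0.5, 0.4, 0.3, 0.6)
  X <- outer(rnorm(50), v) + matrix(m, 50, 4, byrow = TRUE)
  basis <- fitPCA(X)
  expect_equal(explainedVariance(basis), c(1, 0, 0, 0), tolerance = 1e-10)
  L1 <- pcLoadings(basis)[1, ]
  expect_lt(min(max(abs(L1 - v)), max(abs(L1 + v))), 1e-8)
  expect_false(anyNA(pcLoadings(basis)))

  # exact noiseless linear mixtures of 3 spectral endmembers: rank 3
  E <- uvEndmembers()
  S <- rbind(E$epsilon, E$scattering)            # 3 spectra over 4 bands
  C <- matrix(runif(300, 0, 1), 100, 3)
  b3 <- fitPCA(C %*% S / 3)
  expect_gt(sum(explainedVariance(b3)[1:3]), 1 - 1e-10)
})

test_that("PCBasis invariants hold after every fit and fixSigns is idempotent", {
  set.seed(31)
  for (rep in 1:10) {
    X <- matrix(runif(4 * sample(50:400, 1), 0, 1.2), ncol = 4)
    basis <- fitPCA(X)
    L <- pcLoadings(basis)
    expect_lt(max(abs(L %*% t(L) - diag(4))), 1e-10)
    evr <- explainedVariance(basis)
    expect_true(all(diff(evr) <= 1e-12))
    expect_equal(sum(evr), 1, tolerance = 1e-10)
    expect_identical(pcLoadings(fixSigns(basis)), L)
  }
})

test_that("the sign convention pins each component's characteristic shape", {
  # Hadamard-type orthonormal rows, each violating its sign rule:
  # PC1 sum < 0; PC2 negative at 280; PC3 positive at 255 (the +0.9-type
  # nucleic-acid case); PC4 negative at 280.
  L <- rbind(c(-1, -1, -1, -1),
             c( 1, -1, -1,  1),
             c(-1,  1, -1,  1),
             c( 1,  1, -1, -1)) / 2
  b <- new("PCBasis", loadings = L, meanSpectrum = rep(0, 4),
           explainedVariance = c(0.4, 0.3, 0.2, 0.1),
           wavelengths = c(220, 255, 280, 300), mode = "transmittance",
           fitPixelCount = 10L)
  f <- fixSigns(b)
  expect_equal(sum(pcLoadings(f)[1, ]), 2)          # PC1 unipolar positive
  expect_gt(pcLoadings(f)[2, 3], 0)                 # PC2 protein peak (280) positive
  expect_lt(pcLoadings(f)[3, 2], 0)                 # PC3 inverted at 255
  expect_gt(pcLoadings(f)[4, 3], 0)                 # PC4 positive at 280
  # applying twice equals applying once
  expect_identical(pcLoadings(fixSigns(f)), pcLoadings(f))
})

test_that("fitPCA is invariant to row order", {
  set.seed(12)
  X <- matrix(runif(600, 0, 1), 150, 4)
  b1 <- fitPCA(X)
  b2 <- fitPCA(X[sample(150), ])
  expect_equal(pcLoadings(b1), pcLoadings(b2), tolerance = 1e-8)
  expect_equal(explainedVariance(b1), explainedVariance(b2), tolerance = 1e-8)
})

test_that("projectCube equals brute-force per-pixel dot products", {
  cube <- makeTestCube(8, 8, seed = 5)
  basis <- makeTestBasis()
  pf <- projectCube(cube, basis, c(1L, 2L, 3L))
  d <- cubeData(cube)
  for (i in 1:8) for (j in 1:8) for (k in 1:3) {
    expected <- sum((d[i, j, ] - meanSpectrum(basis)) * pcLoadings(basis)[k, ])
    expect_equal(pf@data[i, j, k], expected, tolerance = 1e-12)
  }
})

test_that("projection centering and orthonormality identities", {
  basis <- makeTestBasis()
  mu <- meanSpectrum(basis)
  arr <- array(0, c(2, 2, 4))
  arr[1, 1, ] <- mu                                  # mean spectrum -> 0 scores
  arr[1, 2, ] <- mu + 0.4 * pcLoadings(basis)[2, ]   # mean + a*PC2 -> (0, a, 0)
  arr[2, 1, ] <- mu
  arr[2, 2, ] <- mu
  # amplitude 0.4 keeps every band inside [0, 1.5]: no clipping distortion
  stopifnot(all(arr >= 0 & arr <= 1.5))
  cube <- SpectralCube(arr, wavelengths(basis))
  pf <- projectCube(cube, basis, c(1L, 2L, 3L))
  expect_equal(pf@data[1, 1, ], c(0, 0, 0), tolerance = 1e-12)
  expect_equal(pf@data[1, 2, ], c(0, 0.4, 0), tolerance = 1e-12)

  cube5 <- SpectralCube(cubeData(cube), c(220, 260, 280, 300))
  expect_error(projectCube(cube5, basis), "wavelengths differ")
  expect_error(projectCube(cube, basis, c(1L, 1L, 2L)), "distinct")
})

test_that("basis JSON round-trip preserves the fit", {
  basis <- fitPCA(matrix(runif(400, 0, 1), 100, 4))
  path <- withr::local_tempfile(fileext = ".json")
  writeBasis(basis, path)
  back <- readBasis(path)
  expect_equal(pcLoadings(back), pcLoadings(basis), tolerance = 1e-12)
  expect_equal(meanSpectrum(back), meanSpectrum(basis), tolerance = 1e-12)
  expect_equal(explainedVariance(back), explainedVariance(basis), tolerance = 1e-12)
  expect_identical(pcaMode(back), pcaMode(basis))
})
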