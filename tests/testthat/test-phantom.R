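test_that("Beer-Lambert forward model satisfies its closed forms", {
  E <- uvEndmembers()
  # empty path: T = 1 everywhere
  expect_equal(as.vector(beerLambertTransmittance(matrix(0, 5, 3), E)),
               rep(1, 20))
  # single absorber with c*eps*d = ln 2 at the 255 nm band: T = 0.5 there
  cNA <- log(2) / E$epsilon["nucleic_acid", "255"]
  T1 <- beerLambertTransmittance(matrix(c(cNA, 0, 0), 1), E)
  expect_equal(unname(T1[1, 2]), 0.5, tolerance = 1e-12)
  # optical densities add: -ln T(mix) = -ln T(A) - ln T(B)
  A <- matrix(c(0.7, 0, 0), 1); B <- matrix(c(0, 1.2, 0.4), 1)
  Tmix <- beerLambertTransmittance(A + B, E)
  expect_equal(-log(Tmix), -log(beerLambertTransmittance(A, E)) +
               -log(beerLambertTransmittance(B, E)), tolerance = 1e-12)
  expect_error(beerLambertTransmittance(matrix(-1, 1, 3), E), "non-negative")
})

test_that("endmember table has the prescribed spectral shapes", {
  E <- uvEndmembers()
  expect_equal(E$wavelengths, c(220, 255, 280, 300))
  expect_equal(unname(which.max(E$epsilon["nucleic_acid", ])), 2L)
  expect_equal(unname(which.max(E$epsilon["protein", ])), 3L)
  expect_true(all(E$epsilon[, "300"] < 0.1))
  expect_true(all(diff(E$scattering) < 0))       # strictly decreasing in lambda
})

test_that("phantom generation is deterministic and leaves the caller's RNG alone", {
  spec <- phantomSpec(size = c(64L, 64L), nGlands = 3L, radiusRange = c(8, 12),
                      seed = 42L)
  set.seed(1); before <- runif(1)
  set.seed(1)
  p1 <- generatePhantom(spec)
  after <- runif(1)
  expect_identical(before, after)                # RNG stream untouched
  p2 <- generatePhantom(spec)
  expect_identical(cubeData(p1$cube), cubeData(p2$cube))
  expect_identical(regionLabels(p1$annotation), regionLabels(p2$annotation))
  expect_identical(p1$truth, p2$truth)
})

test_that("phantom geometry, labels and physicality invariants hold", {
  ph <- smallPhantom(seed = 3)
  lab <- regionLabels(ph$annotation)
  ct <- classTable(ph$annotation)
  expect_true(all(setdiff(unique(as.vector(lab)), 0L) %in% ct$label))
  expect_true("stroma" %in% ct$class)
  expect_true(all(cubeData(ph$cube) >= 0 & cubeData(ph$cube) <= 1.5))

  # noiseless phantom: transmittance in [0, 1] and pooled covariance rank <= 3
  ph0 <- generatePhantom(phantomSpec(size = c(64L, 64L), nGlands = 3L,
                                     radiusRange = c(8, 12), noiseSd = 0,
                                     jitterSd = 0, seed = 2L))
  T0 <- cubeData(ph0$cube)
  expect_true(all(T0 >= 0 & T0 <= 1))
  # in optical density the spectra are linear in the 3 endmembers, so the
  # pooled covariance has numerical rank <= 3
  X <- -log(pmax(poolSpectra(ph0$cube), 1e-6))
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[4] / ev[1], 1e-12)

  # monotone response: raising any concentration never raises transmittance
  E <- uvEndmembers()
  base <- matrix(c(0.5, 0.4, 0.3), 1)
  Tb <- beerLambertTransmittance(base, E)
  for (k in 1:3) {
    up <- base; up[k] <- up[k] + 0.2
    expect_true(all(beerLambertTransmittance(up, E) <= Tb))
  }
})

test_that("degenerate and infeasible geometries behave as contracted", {
  ph <- generatePhantom(phantomSpec(size = c(32L, 32L), nGlands = 0L, seed = 1L))
  ct <- classTable(ph$annotation)
  expect_equal(ct$class, "stroma")               # pure stroma phantom
  expect_true(all(regionLabels(ph$annotation) == ct$label))
  expect_equal(nrow(ph$truth), 0L)

  expect_error(generatePhantom(phantomSpec(size = c(48L, 48L), nGlands = 50L,
                                           radiusRange = c(10, 14), seed = 1L)),
               "infeasible")
})

test_that("phenotype presets are documented, benign-identical, and invalid names fail", {
  na <- phenotypePresets("non_aggressive")
  ag <- phenotypePresets("aggressive")
  expect_identical(na$benign, ag$benign)
  # non-aggressive raises absorbers with grade, scattering untouched
  expect_true(all(diff(sapply(na, `[`, 1)) > 0))
  expect_true(all(sapply(na, `[`, 3) == 1))
  # aggressive raises the scattering fraction relative to absorbers
  expect_true(all(diff(sapply(ag, `[`, 3)) > 0))
  expect_true(all(diff(sapply(ag, `[`, 1)) < 0))
  expect_error(phenotypePresets("very_aggressive"), "unknown preset")
})

test_that("presets drive opposite-signed shifts through the full pipeline", {
  shNA <- phantomShifts(seed = 101, preset = "non_aggressive")
  expect_true(all(shNA$relative_shift[shNA$gland_class != "benign"] > 0))
  shAG <- phantomShifts(seed = 101, preset = "aggressive")
  expect_true(all(shAG$relative_shift[shAG$gland_class != "benign"] < 0))
})
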