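test_that("azimuth marginal equals loop-computed column sums and conserves mass", {
  set.seed(14)
  counts <- matrix(rpois(36 * 18, 3), 36, 18)
  h <- new("AngleHistogram2D", counts = counts,
           azEdges = seq(-pi, pi, length.out = 37),
           elEdges = seq(-pi / 2, pi / 2, length.out = 19),
           weightKind = "count", nPixels = sum(counts))
  m <- azimuthMarginal(h)
  oracle <- numeric(36)
  for (j in 1:36) for (k in 1:18) oracle[j] <- oracle[j] + counts[j, k]
  expect_equal(m$mass, oracle)
  expect_equal(sum(m$mass), sum(counts))

  # delta histogram -> delta marginal at the same azimuth bin
  d <- matrix(0, 36, 18); d[17, 5] <- 7
  hd <- new("AngleHistogram2D", counts = d, azEdges = h@azEdges,
            elEdges = h@elEdges, weightKind = "count", nPixels = 7L)
  md <- azimuthMarginal(hd)
  expect_equal(which(md$mass > 0), 17)
  expect_equal(md$mass[17], 7)

  # mass spread over all elevation bins at one azimuth bin keeps its mass
  s <- matrix(0, 36, 18); s[9, ] <- 2
  hs <- new("AngleHistogram2D", counts = s, azEdges = h@azEdges,
            elEdges = h@elEdges, weightKind = "count", nPixels = 36L)
  expect_equal(azimuthMarginal(hs)$mass[9], 36)
})

test_that("center of mass equals the brute-force weighted mean to 1e-12", {
  deg <- function(x) x * pi / 180
  # equal mass at bins centered 10 and 30 degrees
  expect_equal(centerOfMass(c(1, 1), centers = deg(c(10, 30))), deg(20),
               tolerance = 1e-12)
  set.seed(6)
  for (rep in 1:20) {
    centers <- seq(-pi + pi / 360, pi - pi / 360, length.out = 360)
    w <- rexp(360) * rbinom(360, 1, 0.3)
    w[180] <- w[180] + 1              # ensure mass, away from the seam
    oracle <- sum(w * centers) / sum(w)
    # random mass can land near the +/-pi seam; the seam advisory is not
    # under test here, the numeric equality is
    com <- suppressWarnings(centerOfMass(w, centers = centers))
    expect_equal(com, oracle, tolerance = 1e-12)
  }
  # symmetric histogram about theta0 -> CoM at theta0
  w <- c(1, 2, 3, 2, 1)
  th <- deg(c(10, 20, 30, 40, 50))
  expect_equal(centerOfMass(w, centers = th), deg(30), tolerance = 1e-12)

  expect_error(centerOfMass(c(0, 0), centers = c(0, 1)), "zero total mass")
  expect_warning(centerOfMass(c(5, 1), centers = c(pi - 0.01, 0)), "seam")
})

test_that("per-class CoM pools cumulative histograms, not per-region means", {
  set.seed(19)
  H <- 30; W <- 30
  mkfld <- function(azshift) makeSphericalField(
    matrix(runif(H * W, -1, 1) + azshift, H, W),
    matrix(runif(H * W, -0.5, 0.5), H, W),
    matrix(1, H, W))
  # two disjoint same-class regions with different angle distributions
  f1 <- mkfld(0.4); f2 <- mkfld(-0.2)
  lab <- matrix(0L, H, W); lab[1:300] <- 1L
  lab2 <- matrix(0L, H, W); lab2[1:600] <- 1L   # different sizes on purpose
  ct <- data.frame(label = 1L, class = "G3")
  a1 <- RegionAnnotation(lab, ct, "p1")
  a2 <- RegionAnnotation(lab2, ct, "p1")
  suppressWarnings({
    rec <- perClassCoM(list(f1, f2), list(a1, a2), classes = "G3")
  })
  # oracle: bin the concatenated pixels and take the weighted mean
  az <- c(f1@azimuth[lab == 1L], f2@azimuth[lab2 == 1L])
  bins <- ceiling((az + pi) / (2 * pi) * 360)
  cnt <- tabulate(bins, 360)
  centers <- seq(-pi + pi / 360, pi - pi / 360, length.out = 360)
  expect_equal(rec$com_azimuth, sum(cnt * centers) / sum(cnt), tolerance = 1e-12)
  expect_equal(rec$n_pixels, 900L)

  # one class covering everything equals the whole-image histogram CoM
  labAll <- matrix(1L, H, W)
  aAll <- RegionAnnotation(labAll, data.frame(label = 1L, class = "benign"), "p1")
  suppressWarnings(recAll <- perClassCoM(f1, aAll, classes = "benign"))
  hAll <- angleHistogram(f1, azBins = 360, elBins = 180)
  expect_equal(recAll$com_azimuth, centerOfMass(azimuthMarginal(hAll)),
               tolerance = 1e-12)
})

test_that("relative shifts are benign-referenced and translation invariant", {
  rec <- data.frame(
    patient_id = rep(c("p1", "p2"), each = 3),
    gland_class = rep(c("benign", "G3", "G4"), 2),
    com_azimuth = c(0.50, 0.60, 0.45, -0.80, -0.70, -0.85),
    n_pixels = rep(100L, 6))
  sh <- relativeShifts(rec)
  expect_equal(sh$relative_shift[sh$gland_class == "benign"], c(0, 0))
  expect_equal(sh$relative_shift[sh$patient_id == "p1"], c(0, 0.1, -0.05),
               tolerance = 1e-12)
  # two patients with different benign CoMs but identical within-patient
  # offsets have identical shifts
  expect_equal(sh$relative_shift[sh$patient_id == "p1"],
               sh$relative_shift[sh$patient_id == "p2"], tolerance = 1e-12)

  expect_error(relativeShifts(rec[rec$gland_class != "benign", ]),
               "no benign reference")
})

test_that("phenotype call follows the sign rule with threshold dead band", {
  mk <- function(...) {
    s <- c(...)
    data.frame(patient_id = "p", gland_class = names(s),
               relative_shift = unname(s))
  }
  expect_equal(classifyPhenotype(mk(benign = 0, G3 = -0.05, G4 = -0.08)),
               "aggressive_phenotype")
  expect_equal(classifyPhenotype(mk(benign = 0, G3 = 0.05)),
               "non_aggressive_phenotype")
  expect_equal(classifyPhenotype(mk(benign = 0, G3 = 0.05, G4 = -0.05)),
               "indeterminate")
  expect_equal(classifyPhenotype(mk(benign = 0, G3 = 0.05), threshold = 0.1),
               "indeterminate")
  expect_error(classifyPhenotype(mk(benign = 0)), "no cancerous")
})

test_that("phantom ground truth orders the class CoMs as composition orders them", {
  sh <- phantomShifts(seed = 5, preset = "non_aggressive")
  sh <- sh[match(c("benign", "G3", "G4", "G5"), sh$gland_class), ]
  # absorber concentration rises with grade, so the CoM must too
  expect_true(all(diff(sh$com_azimuth) > 0))
})
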