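test_that("EHI sampler matches the dextral mass and stays in range", {
  e <- sampleEHI(10000, seed = 42)
  expect_true(all(e >= -100 & e <= 100))
  expect_lt(abs(mean(e > 0) - 0.90), 0.01)
  # right-heavy J-shape: mode well above +50
  h <- hist(e, breaks = seq(-100, 100, 10), plot = FALSE)
  expect_gt(h$mids[which.max(h$counts)], 50)
  expect_identical(sampleEHI(5, seed = 7), sampleEHI(5, seed = 7))
  expect_error(sampleEHI(10, ehiModel = list(dextralMass = 1.2)), "mass")
})

test_that("hemisphere covariances plant the requested block offsets", {
  am <- data.frame(netA = "LN", netB = "DMN", offset = 0.15)
  spec <- cohortSpec(nSubjects = 5, parcelsPerHemi = 20, timepoints = 50,
                     asymmetryMap = am)
  cL <- buildHemisphereCovariance(spec, ehi = 100, "LH")
  cR <- buildHemisphereCovariance(spec, ehi = 100, "RH")
  netOf <- rep(names(spec@networks), spec@networks)
  ln <- which(netOf == "LN"); dmn <- which(netOf == "DMN")
  planted <- mean(cL[ln, dmn]) - mean(cR[ln, dmn])
  expect_equal(planted, 0.15 * asymmetryScale(100, spec@distanceModel),
               tolerance = 1e-12)
  # untouched blocks identical
  smn <- which(netOf == "SMN")
  expect_equal(cL[smn, smn], cR[smn, smn], tolerance = 1e-12)

  spec0 <- cohortSpec(nSubjects = 5, parcelsPerHemi = 20, timepoints = 50,
                      asymmetryMap = nullAsymmetry())
  expect_equal(buildHemisphereCovariance(spec0, 80, "LH"),
               buildHemisphereCovariance(spec0, 80, "RH"), tolerance = 1e-14)
})

test_that("constructed covariances are symmetric PD with unit diagonal", {
  for (s in 1:3) {
    spec <- cohortSpec(nSubjects = 5, parcelsPerHemi = c(15L, 20L, 30L)[s],
                       timepoints = 50,
                       networks = defaultNetworkCounts(c(15L, 20L, 30L)[s]))
    C <- buildHemisphereCovariance(spec, ehi = 90, "LH")
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_equal(unname(diag(C)), rep(1, nrow(C)))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(
    cohortSpec(nSubjects = 5, parcelsPerHemi = 20, timepoints = 50,
               asymmetryMap = data.frame(netA = "LN", netB = "DMN",
                                         offset = 0.95)))
})

test_that("simulated timeseries converge to the target correlation", {
  C <- diag(2); C[1, 2] <- C[2, 1] <- 0.5
  X <- simulateTimeseries(C, 50000, seed = 3)
  expect_lt(abs(cor(X[1, ], X[2, ]) - 0.5), 0.02)
  I5 <- diag(5)
  XI <- simulateTimeseries(I5, 20000, seed = 4)
  offdiag <- cor(t(XI))[upper.tri(I5)]
  expect_lt(mean(abs(offdiag)), 0.02)
  expect_identical(simulateTimeseries(C, 30, seed = 9),
                   simulateTimeseries(C, 30, seed = 9))
  expect_warning(simulateTimeseries(diag(10), 5), "rank deficient")
})

test_that("cohorts have the declared shape, handedness rule and determinism", {
  co <- tinyCohort(n = 20, P = 20, T = 60, seed = 5)
  md <- cohortMetadata(co)
  expect_identical(nrow(md), 20L)
  ts1 <- subjectTimeseries(co, 1)
  expect_identical(dim(ts1$LH), c(20L, 60L))
  expect_identical(dim(ts1$RH), c(20L, 60L))
  expect_identical(md$handedness, ifelse(md$ehi > 0, "dextral", "sinistral"))
  co2 <- tinyCohort(n = 20, P = 20, T = 60, seed = 5)
  expect_identical(cohortMetadata(co2), md)
  expect_identical(subjectTimeseries(co2, 7), subjectTimeseries(co, 7))
})

test_that("a default 1000-subject cohort is about 10 percent sinistral", {
  co <- generateCohort(cohortSpec(nSubjects = 1000, parcelsPerHemi = 12,
                                  timepoints = 30, seed = 13))
  nSin <- sum(cohortMetadata(co)$handedness == "sinistral")
  expect_true(nSin > 70 && nSin < 130)  # binomial(1000, .1) within ~3 SD
})

test_that("asymmetry scale is monotone below the breakpoint and flat above", {
  dm <- cohortSpec()@distanceModel
  below <- asymmetryScale(seq(-100, 75, 5), dm)
  expect_true(all(diff(below) > 0))
  above <- asymmetryScale(seq(75, 100, 5), dm)
  expect_true(all(abs(diff(above)) < 1e-12))
  expect_true(all(asymmetryScale(c(-100, 0, 100), dm) >= 0))
  expect_equal(asymmetryScale(100, dm), 1)
})
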