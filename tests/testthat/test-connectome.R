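test_that("pearsonMatrix matches a brute-force elementwise oracle", {
  set.seed(11)
  lh <- matrix(rnorm(2 * 6), 2, 6)
  rh <- matrix(rnorm(2 * 6), 2, 6)
  C <- pearsonMatrix(lh, rh)
  expect_equal(C, oraclePearson(rbind(lh, rh)), tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_true(all(C >= -1 & C <= 1))
  # identical rows correlate perfectly
  rh2 <- rh; rh2[1, ] <- lh[1, ]
  expect_equal(pearsonMatrix(lh, rh2)[1, 3], 1)
})

test_that("zero-variance parcels are rejected by name", {
  lh <- matrix(rnorm(12), 2, 6)
  rh <- matrix(rnorm(12), 2, 6)
  rh[2, ] <- 3
  expect_error(pearsonMatrix(lh, rh), "R002")
  expect_error(pearsonMatrix(lh[, 1:2], rh[, 1:2]), "3 timepoints")
})

test_that("Fisher-Z is atanh with clipping and a zero diagonal", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), atanh(0.5))   # 0.549306...
  expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-6)
  z1 <- fisherZ(matrix(c(1, 1, 1, 1), 2))
  expect_true(all(is.finite(z1)))
  expect_equal(z1[1, 2], atanh(1 - 1e-7))
  expect_equal(unname(diag(z1)), c(0, 0))
  expect_error(fisherZ(1.5), "must lie in")
})

test_that("feature set sizes obey the counting identities", {
  for (P in c(3L, 12L, 20L)) {
    at <- if (P >= 12L) makeAtlas(defaultNetworkCounts(P)) else
      symmetrizeNetworks(parcelAtlas(rep("A", P)))
    nHC <- nrow(featureIndexMap(at, "HC-LH"))
    nTC <- nrow(featureIndexMap(at, "TC"))
    nFC <- nrow(featureIndexMap(at, "FC"))
    expect_equal(nHC, P * (P - 1L) / 2L)
    expect_equal(nTC, P * P - P)
    expect_equal(nFC, 2L * nHC + nTC)
  }
})

test_that("feature extraction round-trips and aligns homologues", {
  at <- makeAtlas(defaultNetworkCounts(12))
  set.seed(2)
  M <- matrix(rnorm(24 * 24), 24); M <- (M + t(M)) / 2; diag(M) <- 0
  fc <- extractFeatures(M, at, "FC")
  back <- reassembleMatrix(fc, at)
  # all off-diagonal entries except homotopic pairs are covered
  covered <- !is.na(back)
  expect_equal(back[covered], M[covered])
  homotopic <- cbind(1:12, 13:24)
  expect_true(all(is.na(back[homotopic])))
  expect_identical(sum(is.na(back)) , 2L * 12L)

  # perfectly mirror-symmetric matrix -> identical hemisphere feature vectors
  Msym <- M
  Msym[13:24, 13:24] <- M[1:12, 1:12]
  expect_identical(extractFeatures(Msym, at, "HC-LH")@values,
                   extractFeatures(Msym, at, "HC-RH")@values)
  expect_error(extractFeatures(M[1:10, 1:10], at, "TC"), "dimensions")
})

test_that("cohort feature sets carry aligned metadata", {
  co <- tinyCohort(n = 6, P = 12, T = 40, seed = 3)
  fs <- buildFeatureSet(co, "HC")
  expect_s4_class(fs, "HemiFeatureSet")
  expect_identical(featureKind(fs), "HC")
  expect_identical(dim(fs), c(66L, 12L))
  cd <- SummarizedExperiment::colData(fs)
  expect_identical(as.character(cd$hemisphere), rep(c("LH", "RH"), 6))
  fsTC <- buildFeatureSet(co, "TC")
  expect_identical(dim(fsTC), c(132L, 6L))
  fsFC <- buildFeatureSet(co, "FC")
  expect_identical(nrow(fsFC), 2L * 66L + 132L)
})
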