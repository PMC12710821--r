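test_that("empirical two-sided p follows brute-force tail counting", {
  set.seed(1)
  null <- rnorm(10000)
  # observed beyond all replicates -> the 3/reps floor
  expect_equal(empiricalPTwoSided(100, null), 0.0003)
  # observed larger than 198 of 200: both tails countable by hand
  null200 <- c(seq_len(198), 500, 600)
  expect_equal(empiricalPTwoSided(300, null200), 2 * (2 / 200))
  # observed at the median of a symmetric null
  sym <- c(-(1:50), 1:50)
  expect_equal(empiricalPTwoSided(0, sym), 1)
  expect_error(empiricalPTwoSided(1, numeric(0)), "empty")
  expect_error(empiricalPTwoSided(1, 1:10), "100")
  # floor invariant on random cases
  for (i in 1:20) {
    nn <- rnorm(200)
    expect_gte(empiricalPTwoSided(rnorm(1, sd = 3), nn), 3 / 200)
  }
})

test_that("network group counts are k(k+1)/2 and skip dropped parcels", {
  at8 <- makeAtlas(defaultNetworkCounts(40))
  gm <- networkGroupMap(at8)
  expect_identical(nlevels(gm), 36L)
  # connections touching dropped networks are ungrouped
  map <- featureIndexMap(at8, "HC-LH")
  touchesDropped <- at8@excluded[map$i] | at8@excluded[map$j]
  expect_identical(is.na(gm), touchesDropped)

  at1 <- mergeAndDropNetworks(symmetrizeNetworks(parcelAtlas(rep("A", 5))),
                              list(), character())
  expect_identical(nlevels(networkGroupMap(at1)), 1L)
  at4 <- mergeAndDropNetworks(
    symmetrizeNetworks(parcelAtlas(rep(c("A", "B", "C", "D"), each = 3))),
    list(), character())
  expect_identical(nlevels(networkGroupMap(at4)), 10L)
})

test_that("group enrichment handles empty and saturated masks", {
  at <- mergeAndDropNetworks(
    symmetrizeNetworks(parcelAtlas(rep(c("A", "B"), each = 4))),
    list(), character())
  gm <- networkGroupMap(at)
  none <- groupEnrichment(rep(FALSE, length(gm)), gm, reps = 200, seed = 1)
  expect_true(all(none$count == 0L))
  expect_true(all(none$p == 1))
  all_ <- groupEnrichment(rep(TRUE, length(gm)), gm, reps = 200, seed = 1)
  expect_identical(all_$count, all_$size)
  expect_true(all(all_$p == 1))
})

test_that("BH correction matches the hand step-up oracle", {
  three <- c(rep(0.0003, 3), rep(1, 33))
  expect_equal(fdrCorrect(three)[1:3], rep(0.0036, 3))
  hand <- c(0.01, 0.02, 0.03, 0.04, 0.5)
  expect_equal(fdrCorrect(hand), oracleBH(hand))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1))
    expect_equal(fdrCorrect(p), oracleBH(p), tolerance = 1e-12)
  }
  expect_equal(fdrCorrect(rep(1, 10)), rep(1, 10))
  expect_error(fdrCorrect(c(0, 0.5)))
})

test_that("sign summary partitions by aligned scaling sign", {
  obs <- c(-2, -1, 3, 0.5, -0.2)
  mask <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  sc <- signSummary(obs, mask)
  expect_identical(sc, c(LHgtRH = 3L, RHgtLH = 1L))
  flipped <- signSummary(-obs, mask)
  expect_identical(unname(flipped), unname(rev(sc)))
  oneSign <- signSummary(c(-1, -2, -3), rep(TRUE, 3))
  expect_identical(oneSign[["RHgtLH"]], 0L)
})

test_that("mask matrices are symmetric and p floors hold on a real run", {
  co <- generateCohort(cohortSpec(nSubjects = 30, parcelsPerHemi = 20,
                                  timepoints = 150, handedness = "dextral",
                                  seed = 77))
  fs <- buildFeatureSet(co, "HC")
  enr <- networkEnrichment(fs, cohortAtlas(co), reps = 200, groupReps = 500,
                           alpha = 0.05, seed = 3)
  M <- maskToMatrix(significanceMask(enr), cohortAtlas(co))
  expect_identical(M, t(M))
  expect_true(all(connectionP(enr) >= 3 / 200))
  expect_true(all(connectionP(enr) <= 1))
  expect_true(all(groupTable(enr)$p >= 3 / 500))
  expect_true(all(groupTable(enr)$pCor <= 1))
  # planted LH offsets land predominantly in the LH>RH bucket
  sc <- signCounts(enr)
  expect_gt(sc[["LHgtRH"]], sc[["RHgtLH"]])
  # a reps floor coarser than alpha warns
  expect_warning(connectionSignificance(fs[1:40, ], reps = 100, alpha = 0.01,
                                        seed = 1),
                 "floor")
})

test_that("planted network groups are recovered across seeds", {
  # desk-scale recovery conditions: P=40, 40 dextral subjects, T=300,
  # 500 label-shuffle refits, 10,000 position shuffles
  recovered <- vapply(1:8, function(s) {
    co <- generateCohort(cohortSpec(nSubjects = 40, parcelsPerHemi = 40,
                                    timepoints = 300, handedness = "dextral",
                                    seed = 800 + s))
    fs <- buildFeatureSet(co, "HC")
    enr <- networkEnrichment(fs, cohortAtlas(co), reps = 500, seed = s)
    gt <- groupTable(enr)
    planted <- gt$group %in% c("DMN-DMN", "DMN-LN", "FPN-LN")
    all(gt$pCor[planted] < 0.05) &&
      max(gt$count[!planted]) <= stats::median(gt$count[planted])
  }, logical(1))
  expect_gte(sum(recovered), 7L)
})
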