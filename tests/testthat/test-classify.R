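test_that("stratified folds balance classes and keep subjects whole", {
  md <- data.frame(subjectId = sprintf("S%03d", 1:875),
                   handedness = "dextral", stringsAsFactors = FALSE)
  plan <- makeFolds(md, 5, seed = 2)
  expect_identical(as.integer(table(plan$fold)), rep(175L, 5L))
  expect_identical(makeFolds(md, 5, seed = 2), plan)

  md2 <- data.frame(subjectId = sprintf("S%03d", 1:97),
                    handedness = rep(c("dextral", "sinistral"), c(87, 10)),
                    stringsAsFactors = FALSE)
  plan2 <- makeFolds(md2, 5, seed = 3)
  perFold <- table(plan2$fold, plan2$handedness)
  expect_true(max(perFold[, "sinistral"]) - min(perFold[, "sinistral"]) <= 1)
  expect_true(max(perFold[, "dextral"]) - min(perFold[, "dextral"]) <= 1)
  expect_error(makeFolds(data.frame(subjectId = c("a", "b"),
                                    handedness = c("dextral", "sinistral")), 5),
               "smaller than")
})

test_that("MCC follows the standard formula and its zero conventions", {
  expect_equal(mcc(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(mcc(matrix(c(45, 5, 5, 45), 2, byrow = TRUE)), 0.8)
  # all-majority prediction on a 90/10 split
  allMaj <- matrix(c(90, 0, 10, 0), 2, byrow = TRUE)
  expect_equal(mcc(allMaj), 0)
  expect_equal(accuracy(allMaj), 0.90)
  expect_equal(accuracy(matrix(c(45, 5, 5, 45), 2)), 0.9)
  expect_equal(accuracy(diag(c(3, 7))), 1)
  expect_error(mcc(matrix(0, 2, 2)), "all-zero")
  expect_error(accuracy(matrix(0, 2, 2)), "all-zero")
  expect_error(mcc(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("mcc agrees with the indicator-correlation oracle", {
  set.seed(4)
  for (i in 1:200) {
    cm <- matrix(rpois(4, sample(1:30, 1)), 2)
    if (sum(cm) == 0) cm[1, 1] <- 1
    expect_equal(mcc(cm), oracleMccBinary(cm), tolerance = 1e-12)
  }
})

test_that("all three classifier families separate separable clouds", {
  d <- separableClouds(n = 25, p = 5, gap = 6, seed = 9)
  test <- separableClouds(n = 15, p = 5, gap = 6, seed = 10)
  for (m in c("lda", "svc", "nn")) {
    pr <- trainAndPredict(d$x, d$y, test$x, m)$pred
    cm <- table(factor(test$y, c("A", "B")), factor(pr, c("A", "B")))
    expect_equal(mcc(cm), 1)
  }
  expect_error(trainAndPredict(d$x, rep("A", 50), test$x, "lda"),
               "single class")
})

test_that("shuffled labels on null data give MCC near zero", {
  set.seed(5)
  vals <- replicate(15, {
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- sample(rep(c("A", "B"), 30))
    pr <- trainAndPredict(X[1:40, ], y[1:40], X[41:60, ], "lda")$pred
    mcc(table(factor(y[41:60], c("A", "B")), factor(pr, c("A", "B"))))
  })
  expect_lt(abs(mean(vals)), 0.2)
})

test_that("bootstrap MCC intervals behave at the extremes", {
  y <- rep(c("A", "B"), 40)
  ci <- bootstrapMccCi(y, y, reps = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1, 1))
  set.seed(2)
  yp <- sample(y)   # predictions independent of truth
  ci2 <- bootstrapMccCi(y, yp, reps = 500, seed = 3)
  expect_lt(ci2[["low"]], 0)
  expect_gt(ci2[["high"]], 0)
  expect_identical(bootstrapMccCi(y, yp, reps = 100, seed = 5),
                   bootstrapMccCi(y, yp, reps = 100, seed = 5))
})

test_that("MCC calibration reproduces the balanced closed form 2a - 1", {
  cal <- mccAccuracyCalibration(c(A = 500, B = 500), 0.8, reps = 400, seed = 6)
  expect_equal(cal$mean, 0.6, tolerance = 0.02)
  cal9 <- mccAccuracyCalibration(c(A = 500, B = 500), 0.9, reps = 400, seed = 6)
  expect_equal(cal9$mean, 0.8, tolerance = 0.02)
  perfect <- mccAccuracyCalibration(c(A = 50, B = 50), 1.0, reps = 50, seed = 7)
  expect_true(all(perfect$values == 1))
  # under the study's 875/92 imbalance, 80% per-class accuracy maps to the
  # "good" benchmark MCC of about 0.4
  imb <- mccAccuracyCalibration(c(dextral = 875, sinistral = 92), 0.8,
                                reps = 400, seed = 8)
  expect_equal(imb$mean, 0.4, tolerance = 0.05)
  expect_lt(imb$mean, cal$mean)
})

test_that("oversampling duplicates minority rows up to the majority count", {
  X <- matrix(seq_len(967 * 2), 967, 2)
  y <- rep(c("dextral", "sinistral"), c(875, 92))
  os <- oversampleMinority(X, y, seed = 4)
  expect_identical(as.integer(table(os$y)), c(875L, 875L))
  # minority rows are copies of input minority rows, majority untouched
  minRows <- os$x[os$y == "sinistral", 1]
  expect_true(all(minRows %in% X[y == "sinistral", 1]))
  expect_identical(os$x[1:875, ], X[1:875, ])
  bal <- oversampleMinority(X[1:20, ], rep(c("a", "b"), 10), seed = 1)
  expect_identical(bal$x, X[1:20, ])
})

test_that("size-matched subsampling uses the 4/5 rule", {
  expect_identical(defaultSubsampleTarget(92), 74L)
  pool <- sprintf("S%03d", 1:400)
  s <- subsampleTraining(pool, 74, seed = 2)
  expect_length(s, 74)
  expect_false(anyDuplicated(s) > 0)
  expect_identical(subsampleTraining(pool, 74, seed = 2), s)
  expect_identical(subsampleTraining(pool, 0), character(0))
  expect_error(subsampleTraining(pool[1:10], 74), "exceeds")
})

test_that("four-way labels compose and decompose exactly", {
  expect_identical(fourwayLabels("LH", "dextral"), "rightyLH")
  for (h in c("LH", "RH")) for (hd in c("dextral", "sinistral")) {
    d <- decomposeFourway(fourwayLabels(h, hd))
    expect_identical(d$hemi, h)
    expect_identical(d$handedness, hd)
  }
  expect_error(decomposeFourway("ambiLH"), "unknown")
  expect_error(fourwayLabels("XX", "dextral"), "unknown")
  # 4 classes -> 3 discriminant axes
  set.seed(3)
  X <- matrix(rnorm(80 * 6), 80, 6) +
    rep(c(0, 2, 4, 6), each = 20)
  y <- fourwayLabels(rep(c("LH", "RH"), 40),
                     rep(rep(c("dextral", "sinistral"), each = 20), 2))
  fit <- trainAndPredict(X, y, X[1:4, ], "lda")$model
  expect_identical(ncol(fit$scaling), 3L)
})

test_that("paired MCC comparison matches the brute-force t formula", {
  a <- c(0.9, 0.8, 0.85)
  b <- c(0.7, 0.75, 0.7)
  res <- compareMccPaired(a, b)
  d <- a - b
  tBrute <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, tBrute, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$meanDiff, mean(d))
  expect_equal(res$d, mean(d) / sd(d))

  same <- compareMccPaired(a, a)
  expect_equal(same$meanDiff, 0)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compareMccPaired(a, a - 0.1), "zero variance")

  set.seed(9)
  base <- runif(15, 0.9, 1)
  sub <- base - 0.012 + rnorm(15, 0, 0.002)
  res2 <- compareMccPaired(sub, base)
  expect_lt(abs(res2$meanDiff - (-0.012)), 0.003)
  expect_lt(res2$p, 0.01)
})

test_that("cross-validation covers every sample exactly once without leaks", {
  co <- tinyCohort(n = 20, P = 12, T = 60, seed = 8, handedness = "dextral")
  fs <- buildFeatureSet(co, "HC")
  run <- crossValidate(fs, "chirality", "lda", bootReps = 100, seed = 2)
  pd <- runPredictions(run)
  expect_identical(nrow(pd), 40L)
  expect_true(all(pd$pred %in% c("LH", "RH")))
  # both hemisphere samples of a subject share a fold
  expect_true(all(tapply(pd$fold, pd$subjectId,
                         function(f) length(unique(f)) == 1L)))
  expect_identical(sum(confusionMatrices(run)$pooled), 40L)
  expect_true(mccValue(run) >= -1 && mccValue(run) <= 1)
  ci <- mccCI(run)
  expect_lte(ci[["low"]], mccValue(run))
  expect_gte(ci[["high"]], mccValue(run))
})

test_that("chirality MCC orders dextral >= sinistral >= null cohorts", {
  meanMcc <- function(handed, am, seedOff) {
    mean(vapply(1:5, function(s) {
      co <- generateCohort(cohortSpec(nSubjects = 24, parcelsPerHemi = 20,
                                      timepoints = 120, handedness = handed,
                                      asymmetryMap = am, seed = seedOff + s))
      fs <- buildFeatureSet(co, "HC")
      run <- crossValidate(fs, "chirality", "lda", bootReps = 50, seed = s)
      mean(foldMcc(run))
    }, numeric(1)))
  }
  dex <- meanMcc("dextral", defaultAsymmetryMap(), 100)
  sin <- meanMcc("sinistral", defaultAsymmetryMap(), 200)
  nul <- meanMcc("dextral", nullAsymmetry(), 300)
  expect_gte(dex, sin)
  expect_gte(sin, nul)
  expect_lt(abs(nul), 0.25)
  expect_gt(dex, 0.6)
})
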