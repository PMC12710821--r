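test_that("LD1 distance is |LH| + |RH| with its symmetries", {
  expect_equal(ld1Dist(-5, 5), 10)
  expect_equal(ld1Dist(0, 0), 0)
  expect_equal(ld1Dist(-3, 4), 7)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(ld1Dist(a, b), ld1Dist(b, a))        # hemisphere swap
  expect_equal(ld1Dist(a, b), ld1Dist(-a, -b))      # global sign flip
  expect_true(all(ld1Dist(a, b) >= 0))
  expect_error(ld1Dist(NA_real_, 1))
})

test_that("within-group z-scoring uses the sample SD per group", {
  expect_equal(zWithinGroup(c(1, 2, 3), rep("g", 3)), c(-1, 0, 1))
  v <- c(1, 2, 3, 10, 20, 30)
  g <- rep(c("a", "b"), each = 3)
  z <- zWithinGroup(v, g)
  expect_equal(as.numeric(tapply(z, g, mean)), c(0, 0))
  expect_equal(as.numeric(tapply(z, g, sd)), c(1, 1))
  expect_error(zWithinGroup(c(2, 2, 2), rep("g", 3)), "zero within-group")
  expect_error(zWithinGroup(1, "g"), "fewer than 2")
})

test_that("LD1 correlation matches a brute-force computation", {
  lh <- c(-5.1, -4.2, -6.0, -4.8, -5.5)
  rh <- c(5.0, 4.1, 6.2, 4.6, 5.2)
  res <- ld1Correlation(lh, rh)
  num <- sum((lh - mean(lh)) * (rh - mean(rh)))
  den <- sqrt(sum((lh - mean(lh))^2) * sum((rh - mean(rh))^2))
  expect_equal(res$r, num / den, tolerance = 1e-12)
  exact <- ld1Correlation(lh, -lh)
  expect_equal(exact$r, -1)
  expect_error(ld1Correlation(rep(1, 5), rh), "constant")
  expect_error(ld1Correlation(lh[1:2], rh[1:2]), "3 subjects")
})

test_that("LD1 scores cluster LH negative, RH positive by convention", {
  co <- generateCohort(cohortSpec(nSubjects = 30, parcelsPerHemi = 20,
                                  timepoints = 200, handedness = "dextral",
                                  seed = 5))
  fs <- buildFeatureSet(co, "HC")
  hs <- hemisphereScores(fs)
  expect_lt(mean(hs$scores$ld1LH), 0)
  expect_gt(mean(hs$scores$ld1RH), 0)
  expect_equal(hs$scores$ld1Dist,
               abs(hs$scores$ld1LH) + abs(hs$scores$ld1RH))
  # Z(LD1) is standardized within hemisphere groups
  expect_equal(mean(hs$scores$zLd1LH), 0, tolerance = 1e-10)
  expect_equal(sd(hs$scores$zLd1LH), 1, tolerance = 1e-10)
})

test_that("noiseless segmented data identifies its breakpoint exactly", {
  x <- seq(-90, 95, length.out = 120)
  y <- 2 + 0.05 * pmin(x, 40)
  fm <- fitDistanceModels(x, y, kinds = c("linear", "segmented1"),
                          bootReps = 0)
  expect_equal(fm$fits$segmented1@breakpoints, 40, tolerance = 1e-6)
  expect_lt(fm$fits$segmented1@rss, 1e-10)
  cmpRow <- fm$comparisons[fm$comparisons$modelB == "segmented1", ]
  expect_lt(cmpRow$p, 1e-10)
})

test_that("an exact parabola yields its vertex and curvature", {
  x <- seq(-100, 100, 5)
  y <- -0.001 * (x - 30)^2 + 8
  fm <- fitDistanceModels(x, y, kinds = c("linear", "quadratic"), bootReps = 0)
  q <- fm$fits$quadratic
  expect_equal(q@vertex, c(30, 8), tolerance = 1e-6)
  expect_true(q@opensDownward)
  expect_gt(q@r2, 0.999)
})

test_that("two breakpoints do not improve on one-breakpoint data", {
  set.seed(11)
  x <- runif(300, -100, 100)
  y <- 5 + 0.04 * pmin(x, 50) + rnorm(300, 0, 0.8)
  fm <- fitDistanceModels(x, y, bootReps = 0)
  cmp <- fm$comparisons
  expect_lt(cmp$p[cmp$modelA == "linear" & cmp$modelB == "segmented1"], 0.001)
  expect_gt(cmp$p[cmp$modelA == "segmented1" & cmp$modelB == "segmented2"], 0.05)
})

test_that("AIC prefers the segmented model on segmented data across seeds", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    x <- runif(250, -100, 100)
    y <- 5 + 0.04 * pmin(x, 60) + rnorm(250, 0, 1)
    # boundary warnings can fire on noisy seeds; only the AIC order matters
    fm <- suppressWarnings(
      fitDistanceModels(x, y, kinds = c("linear", "segmented1"), bootReps = 0))
    fm$fits$segmented1@aic < fm$fits$linear@aic
  }, logical(1))
  expect_gte(sum(wins), 9L)
})

test_that("two-group ANOVA equals the squared pooled t", {
  set.seed(3)
  v <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  res <- groupDistanceTest(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_error(groupDistanceTest(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("a one-SD group shift is detected with high power", {
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    v <- c(rnorm(100), rnorm(100, 1))
    groupDistanceTest(v, rep(c("a", "b"), each = 100))$p < 0.001
  }, logical(1))
  expect_gte(sum(hits), 19L)
})
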