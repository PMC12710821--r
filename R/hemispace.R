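#' @include AllClasses.R AllGenerics.R classify.R
NULL

#' LD1 scores under the fixed sign convention
#'
#' Projects feature rows onto the first linear discriminant of a fitted LDA
#' model and aligns the global sign so that the class mean of the LH class
#' (or, for the four-way model, of the LH classes jointly) is negative.
#' LD1 then separates the hemispheres with LH clustering negative and RH
#' positive, and downstream quantities are invariant to the arbitrary sign
#' of the raw discriminant.
#'
#' @param model a fitted \code{MASS::lda} model.
#' @param X samples x features matrix in the model's feature space.
#' @return numeric LD1 score per row of \code{X}.
#' @export
ld1Scores <- function(model, X) {
  if (ncol(X) != nrow(model$scaling))
    stop("feature dimension does not match the fitted model")
  sc <- predict(model, X)$x[, 1]
  mu <- (model$means %*% model$scaling)[, 1]
  lhClasses <- grepl("LH$", rownames(model$means))
  if (!any(lhClasses)) return(sc)
  if (mean(mu[lhClasses]) > mean(mu[!lhClasses])) sc <- -sc
  sc
}

#' Inter-hemisphere distance in discriminant space
#'
#' \code{|LD1_LH| + |LD1_RH|}: how far apart a subject's two hemispheres sit
#' on the LD1 axis. Symmetric under swapping hemispheres and invariant to
#' the global LDA sign flip.
#'
#' @param ld1LH,ld1RH per-subject LD1 scores.
#' @return non-negative distances.
#' @export
ld1Dist <- function(ld1LH, ld1RH) {
  stopifnot(all(is.finite(ld1LH)), all(is.finite(ld1RH)))
  abs(ld1LH) + abs(ld1RH)
}

#' Standardize values within groups
#'
#' Z-scores computed independently within each group (sample SD, n - 1),
#' so each group has mean 0 and SD 1.
#'
#' @param values numeric vector.
#' @param groups group labels, one per value (>= 2 values per group).
#' @return standardized values.
#' @export
zWithinGroup <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- numeric(length(values))
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < 2L) stop("group '", g, "' has fewer than 2 values")
    s <- stats::sd(values[idx])
    if (s == 0) stop("zero within-group variance in group '", g, "'")
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

#' Correlation of per-hemisphere LD1 values
#'
#' Pearson correlation (with the standard two-sided test) of the paired
#' (LD1_LH, LD1_RH) subject scores.
#'
#' @param ld1LH,ld1RH per-subject scores (>= 3 subjects).
#' @return list: r, p, n.
#' @export
ld1Correlation <- function(ld1LH, ld1RH) {
  stopifnot(length(ld1LH) == length(ld1RH))
  if (length(ld1LH) < 3L) stop("need at least 3 subjects")
  if (stats::sd(ld1LH) == 0 || stats::sd(ld1RH) == 0)
    stop("constant LD1 input")
  ct <- stats::cor.test(ld1LH, ld1RH)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ld1LH))
}

#' Per-subject hemisphere-space scores
#'
#' Fits a maximal chirality LDA on all hemiconnectome samples and derives
#' the per-subject hemisphere-space quantities: LD1 per hemisphere,
#' within-hemisphere Z(LD1), and the distance \code{|LD1_LH| + |LD1_RH|}.
#'
#' @param fs a hemiconnectome \code{\link{HemiFeatureSet}}.
#' @return list: \code{scores} (data.frame subjectId, ehi, handedness,
#'   ld1LH, ld1RH, zLd1LH, zLd1RH, ld1Dist) and \code{model} (the maximal
#'   LDA).
#' @export
hemisphereScores <- function(fs) {
  stopifnot(is(fs, "HemiFeatureSet"), featureKind(fs) == "HC")
  cd <- SummarizedExperiment::colData(fs)
  X <- t(SummarizedExperiment::assay(fs, "z"))
  y <- as.character(cd$hemisphere)
  model <- suppressWarnings(MASS::lda(X, grouping = factor(y)))
  sc <- ld1Scores(model, X)
  z <- zWithinGroup(sc, y)
  lh <- y == "LH"
  subj <- as.character(cd$subjectId)
  ord <- match(unique(subj), subj[lh])
  df <- data.frame(
    subjectId = subj[lh][ord],
    ehi = cd$ehi[lh][ord],
    handedness = as.character(cd$handedness)[lh][ord],
    ld1LH = sc[lh][ord],
    ld1RH = sc[!lh][match(unique(subj), subj[!lh])],
    zLd1LH = z[lh][ord],
    zLd1RH = z[!lh][match(unique(subj), subj[!lh])],
    stringsAsFactors = FALSE)
  df$ld1Dist <- ld1Dist(df$ld1LH, df$ld1RH)
  list(scores = df, model = model)
}

#' Two-group comparison of hemisphere-space values
#'
#' One-way ANOVA of a hemisphere-space quantity (Z(LD1) or LD1 distance)
#' across handedness groups; on two groups the F statistic equals the
#' squared pooled-variance two-sample t.
#'
#' @param values numeric vector.
#' @param groups group labels (each group >= 2 values).
#' @return list: means (named), F, df, p.
#' @export
groupDistanceTest <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  list(means = tapply(values, groups, mean),
       F = an$`F value`[1],
       df = c(an$Df[1], an$Df[2]),
       p = an$`Pr(>F)`[1])
}

# profiled RSS of a continuous segmented fit with fixed breakpoints
.segRss <- function(x, y, bps) {
  B <- cbind(1, x)
  for (b in bps) B <- cbind(B, pmax(x - b, 0))
  fit <- stats::lm.fit(B, y)
  sum(fit$residuals^2)
}

.segCoef <- function(x, y, bps) {
  B <- cbind(1, x)
  for (b in bps) B <- cbind(B, pmax(x - b, 0))
  fit <- stats::lm.fit(B, y)
  cf <- fit$coefficients
  names(cf) <- c("intercept", "slope",
                 paste0("slopeChange", seq_along(bps)))
  cf
}

# one-breakpoint profiled search: coarse grid + Brent refinement
.fitSeg1 <- function(x, y, gridN = 50L) {
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  if (diff(qs) <= 0) stop("EHI values do not span a breakpoint search interval")
  grid <- seq(qs[1], qs[2], length.out = gridN)
  rss <- vapply(grid, function(b) .segRss(x, y, b), numeric(1))
  k <- which.min(rss)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(gridN, k + 1L)]
  opt <- stats::optimize(function(b) .segRss(x, y, b), c(lo, hi), tol = 1e-8)
  bp <- opt$minimum
  boundary <- (bp - qs[1] < 1e-6 * diff(qs)) || (qs[2] - bp < 1e-6 * diff(qs))
  list(bp = bp, rss = opt$objective, boundary = boundary)
}

# two-breakpoint search: coarse pair grid + coordinate-wise refinement
.fitSeg2 <- function(x, y, gridN = 20L) {
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = gridN)
  best <- list(rss = Inf)
  for (a in seq_len(gridN - 1L)) for (b in (a + 1L):gridN) {
    r <- .segRss(x, y, c(grid[a], grid[b]))
    if (r < best$rss) best <- list(rss = r, bps = c(grid[a], grid[b]))
  }
  bps <- best$bps
  step <- diff(grid[1:2])
  for (it in 1:3) {
    o1 <- stats::optimize(function(b) .segRss(x, y, sort(c(b, bps[2]))),
                          c(max(qs[1], bps[1] - step), min(bps[2], bps[1] + step)),
                          tol = 1e-7)
    bps[1] <- o1$minimum
    o2 <- stats::optimize(function(b) .segRss(x, y, sort(c(bps[1], b))),
                          c(max(bps[1], bps[2] - step), min(qs[2], bps[2] + step)),
                          tol = 1e-7)
    bps[2] <- o2$minimum
  }
  bps <- sort(bps)
  boundary <- (bps[1] - qs[1] < 1e-6 * diff(qs)) || (qs[2] - bps[2] < 1e-6 * diff(qs))
  list(bps = bps, rss = .segRss(x, y, bps), boundary = boundary)
}

# Gaussian AIC comparable across all model kinds; breakpoints count as
# parameters (+1 for sigma)
.gaussAic <- function(rss, n, nPar) {
  n * (log(2 * pi * rss / n) + 1) + 2 * (nPar + 1)
}

.makeFit <- function(kind, coefs, bps, bpSE, rss, n, tss, nPar,
                     vertex = c(NA_real_, NA_real_), opensDownward = NA,
                     boundary = FALSE) {
  new("DistanceFit", kind = kind, coefficients = coefs,
      breakpoints = bps, breakpointSE = bpSE,
      aic = .gaussAic(rss, n, nPar), r2 = 1 - rss / tss, rss = rss,
      n = as.integer(n), vertex = vertex,
      opensDownward = as.logical(opensDownward), boundary = boundary)
}

#' Fit and compare EHI-vs-distance models
#'
#' Fits the candidate functional forms linking continuous handedness (EHI)
#' to inter-hemisphere distance: ordinary linear and quadratic regressions,
#' and continuous segmented (broken-stick) regressions with one or two
#' breakpoints estimated by a profiled grid search with Brent refinement.
#' Breakpoint standard errors come from a nonparametric bootstrap. Nested
#' models are compared with F-tests, and every fit reports AIC (breakpoints
#' counted as parameters) and R-squared; the quadratic additionally reports
#' its vertex and whether the parabola opens downward (required before any
#' "peak" interpretation).
#'
#' @param ehi numeric EHI scores (>= 10 observations spanning the
#'   candidate breakpoints).
#' @param dist non-negative distances, same length.
#' @param kinds subset of \code{c("linear", "segmented1", "segmented2",
#'   "quadratic")}.
#' @param bootReps bootstrap repetitions for breakpoint SEs (default 500;
#'   0 skips the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @return list: \code{fits} (named list of \code{\link{DistanceFit}}) and
#'   \code{comparisons} (data.frame of nested F-tests: modelA, modelB, F,
#'   df1, df2, p, deltaAic).
#' @export
fitDistanceModels <- function(ehi, dist,
                              kinds = c("linear", "segmented1", "segmented2",
                                        "quadratic"),
                              bootReps = 500L, seed = 1L) {
  stopifnot(length(ehi) == length(dist))
  kinds <- match.arg(kinds, several.ok = TRUE)
  n <- length(ehi)
  if (n < 10L) stop("need at least 10 observations")
  tss <- sum((dist - mean(dist))^2)
  fits <- list()
  if ("linear" %in% kinds) {
    fit <- stats::lm(dist ~ ehi)
    fits$linear <- .makeFit("linear",
                            c(intercept = unname(stats::coef(fit)[1]),
                              slope = unname(stats::coef(fit)[2])),
                            numeric(0), numeric(0),
                            sum(stats::resid(fit)^2), n, tss, nPar = 2L)
  }
  if ("quadratic" %in% kinds) {
    fit <- stats::lm(dist ~ ehi + I(ehi^2))
    cf <- stats::coef(fit)
    vx <- -cf[2] / (2 * cf[3])
    vy <- cf[1] + cf[2] * vx + cf[3] * vx^2
    fits$quadratic <- .makeFit("quadratic",
                               c(intercept = unname(cf[1]), slope = unname(cf[2]),
                                 quad = unname(cf[3])),
                               numeric(0), numeric(0),
                               sum(stats::resid(fit)^2), n, tss, nPar = 3L,
                               vertex = c(unname(vx), unname(vy)),
                               opensDownward = unname(cf[3] < 0))
  }
  bootSE <- function(fitFun, nBp) {
    if (bootReps <= 0) return(rep(NA_real_, nBp))
    .setSeedIfGiven(seed)
    bps <- matrix(NA_real_, bootReps, nBp)
    for (r in seq_len(bootReps)) {
      idx <- sample.int(n, n, replace = TRUE)
      bps[r, ] <- tryCatch(fitFun(ehi[idx], dist[idx]),
                           error = function(e) rep(NA_real_, nBp))
    }
    apply(bps, 2, stats::sd, na.rm = TRUE)
  }
  if ("segmented1" %in% kinds) {
    s1 <- .fitSeg1(ehi, dist)
    if (s1$boundary)
      warning("segmented1 breakpoint search hit the data boundary")
    se <- bootSE(function(x, y) .fitSeg1(x, y, gridN = 30L)$bp, 1L)
    fits$segmented1 <- .makeFit("segmented1", .segCoef(ehi, dist, s1$bp),
                                s1$bp, se, s1$rss, n, tss,
                                nPar = 4L, boundary = s1$boundary)
  }
  if ("segmented2" %in% kinds) {
    s2 <- .fitSeg2(ehi, dist)
    if (s2$boundary)
      warning("segmented2 breakpoint search hit the data boundary")
    se <- bootSE(function(x, y) .fitSeg2(x, y, gridN = 12L)$bps, 2L)
    fits$segmented2 <- .makeFit("segmented2", .segCoef(ehi, dist, s2$bps),
                                s2$bps, se, s2$rss, n, tss,
                                nPar = 6L, boundary = s2$boundary)
  }
  nested <- list(c("linear", "segmented1"), c("segmented1", "segmented2"),
                 c("linear", "quadratic"), c("linear", "segmented2"))
  cmp <- list()
  for (pair in nested) {
    a <- pair[1]; b <- pair[2]
    if (!is.null(fits[[a]]) && !is.null(fits[[b]])) {
      kA <- switch(a, linear = 2L, segmented1 = 4L, quadratic = 3L)
      kB <- switch(b, segmented1 = 4L, segmented2 = 6L, quadratic = 3L)
      df1 <- kB - kA; df2 <- n - kB
      Fv <- ((fits[[a]]@rss - fits[[b]]@rss) / df1) / (fits[[b]]@rss / df2)
      Fv <- max(Fv, 0)
      cmp[[length(cmp) + 1L]] <- data.frame(
        modelA = a, modelB = b, F = Fv, df1 = df1, df2 = df2,
        p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
        deltaAic = fits[[b]]@aic - fits[[a]]@aic,
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits,
       comparisons = if (length(cmp)) do.call(rbind, cmp)
                     else data.frame())
}
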