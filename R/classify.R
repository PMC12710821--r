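#' @include AllClasses.R AllGenerics.R connectome.R
NULL

#' Handedness-stratified subject-level folds
#'
#' Assigns every subject to exactly one of \code{nFolds} folds, stratified
#' by handedness so per-fold class proportions deviate by at most one
#' subject from the global proportions. Both hemisphere samples of a
#' subject inherit the subject's fold, so no subject's data ever appears on
#' both sides of a train/test split.
#'
#' @param metadata data.frame with \code{subjectId} and \code{handedness}.
#' @param nFolds number of folds (default 5).
#' @param seed fold-shuffling seed.
#' @return data.frame: subjectId, handedness, fold (factor A, B, ...).
#' @export
makeFolds <- function(metadata, nFolds = 5L, seed = 1L) {
  stopifnot(all(c("subjectId", "handedness") %in% names(metadata)))
  counts <- table(metadata$handedness)
  if (any(counts < nFolds))
    stop("handedness class smaller than the number of folds: ",
         paste(names(counts)[counts < nFolds], collapse = ", "))
  .setSeedIfGiven(seed)
  foldLabels <- LETTERS[seq_len(nFolds)]
  fold <- character(nrow(metadata))
  for (cl in names(counts)) {
    idx <- which(metadata$handedness == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(foldLabels, length(idx))
  }
  data.frame(subjectId = metadata$subjectId,
             handedness = metadata$handedness,
             fold = factor(fold, levels = foldLabels),
             stringsAsFactors = FALSE)
}

#' Matthews correlation coefficient of a confusion matrix
#'
#' Binary MCC by the standard formula
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}};
#' any zero factor in the denominator yields MCC = 0, so all-majority
#' assignment on an imbalanced sample scores 0 while its accuracy can still
#' look high. Larger matrices are scored with the generalized multiclass
#' form (rows = truth, columns = prediction).
#'
#' @param cm square matrix of non-negative counts.
#' @return score in [-1, 1].
#' @export
#' @examples
#' mcc(matrix(c(45, 5, 5, 45), 2))   # 0.8
#' mcc(matrix(c(90, 10, 0, 0), 2))   # 0: one class entirely missed
mcc <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || any(cm != floor(cm))) stop("counts must be non-negative integers")
  storage.mode(cm) <- "double"   # keep denominator products out of integer range
  s <- sum(cm)
  if (s == 0) stop("all-zero confusion matrix")
  if (nrow(cm) == 2L) {
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) return(0)
    return((tp * tn - fp * fn) / sqrt(den))
  }
  tk <- rowSums(cm); pk <- colSums(cm); tr <- sum(diag(cm))
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  (tr * s - sum(tk * pk)) / den
}

#' Accuracy of a confusion matrix
#'
#' @param cm square matrix of non-negative counts (rows = truth).
#' @return trace / total.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("all-zero confusion matrix")
  sum(diag(cm)) / sum(cm)
}

# confusion matrix with a fixed, shared level set (rows = truth)
.confusion <- function(truth, pred, levels) {
  table(factor(truth, levels = levels), factor(pred, levels = levels))
}

#' Bootstrap confidence interval for MCC
#'
#' Resamples (truth, prediction) pairs jointly with replacement, computes
#' MCC per replicate (degenerate replicates score 0 by the MCC convention
#' and are kept, not redrawn), and reports the distribution mean with the
#' 2.5th and 97.5th percentiles.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param reps bootstrap repetitions (default 1000).
#' @param seed optional RNG seed.
#' @return named numeric: mean, low, high.
#' @export
bootstrapMccCi <- function(yTrue, yPred, reps = 1000L, seed = NULL) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 1L)
  .setSeedIfGiven(seed)
  lev <- sort(unique(c(as.character(yTrue), as.character(yPred))))
  ti <- match(as.character(yTrue), lev)
  pi <- match(as.character(yPred), lev)
  n <- length(ti); k <- length(lev)
  vals <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    cm <- matrix(tabulate((ti[idx] - 1L) * k + pi[idx], nbins = k * k),
                 k, k, byrow = TRUE)
    mcc(cm)
  }, numeric(1))
  c(mean = mean(vals),
    low = unname(stats::quantile(vals, 0.025, type = 7)),
    high = unname(stats::quantile(vals, 0.975, type = 7)))
}

#' Simulation-based MCC/accuracy calibration
#'
#' Simulates confusion outcomes at a stated per-class accuracy - per class,
#' correct counts are binomial and misclassifications spread uniformly over
#' the remaining classes - and summarizes the resulting MCC distribution.
#' This is the calibration behind the "good"/"excellent" MCC benchmarks:
#' for balanced binary classes, per-class accuracies of 0.8 and 0.9
#' correspond to MCC about 0.6 and 0.8 (closed form 2a - 1), while under
#' heavy class imbalance the same per-class accuracy maps to a lower MCC.
#'
#' @param classSizes named integer vector.
#' @param perClassAccuracy scalar or per-class accuracies in (0, 1].
#' @param reps simulation repetitions.
#' @param seed optional RNG seed.
#' @return list: mean, quantiles (2.5/50/97.5 percent), values.
#' @export
mccAccuracyCalibration <- function(classSizes, perClassAccuracy,
                                   reps = 1000L, seed = NULL) {
  stopifnot(all(classSizes >= 1), all(perClassAccuracy > 0),
            all(perClassAccuracy <= 1))
  k <- length(classSizes)
  acc <- rep_len(perClassAccuracy, k)
  .setSeedIfGiven(seed)
  vals <- vapply(seq_len(reps), function(r) {
    cm <- matrix(0L, k, k)
    for (ci in seq_len(k)) {
      good <- stats::rbinom(1L, classSizes[ci], acc[ci])
      cm[ci, ci] <- good
      bad <- classSizes[ci] - good
      if (bad > 0 && k > 1) {
        spread <- stats::rmultinom(1L, bad, rep(1 / (k - 1), k - 1))[, 1]
        cm[ci, -ci] <- spread
      }
    }
    mcc(cm)
  }, numeric(1))
  list(mean = mean(vals),
       quantiles = stats::quantile(vals, c(0.025, 0.5, 0.975)),
       values = vals)
}

#' Oversample minority classes by row duplication
#'
#' Duplicates minority-class rows (sampled with replacement) until every
#' class count matches the majority count; majority rows are untouched and
#' no synthetic rows are created.
#'
#' @param X samples x features matrix.
#' @param y class labels, one per row.
#' @param seed optional RNG seed.
#' @return list with \code{x}, \code{y} and the row \code{indices} used.
#' @export
oversampleMinority <- function(X, y, seed = NULL) {
  stopifnot(nrow(X) == length(y))
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least 2 classes to oversample")
  .setSeedIfGiven(seed)
  target <- max(counts)
  idx <- seq_len(nrow(X))
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need > 0) {
      pool <- which(y == cl)
      idx <- c(idx, sample(pool, need, replace = TRUE))
    }
  }
  list(x = X[idx, , drop = FALSE], y = y[idx], indices = idx)
}

#' Size-matched training subsample
#'
#' Uniform sample without replacement of training subjects, used for the
#' size-matched dextral control: when a sinistral cohort of size m is
#' analyzed with 5 folds, its training sets hold 4/5 of m subjects, so the
#' default target is \code{round(4/5 * m)} - 74 for m = 92.
#'
#' @param subjects character vector of candidate subject ids.
#' @param targetN subsample size.
#' @param seed optional RNG seed.
#' @return character vector of sampled ids.
#' @export
subsampleTraining <- function(subjects, targetN = 74L, seed = NULL) {
  if (targetN > length(subjects))
    stop("targetN exceeds the number of available subjects")
  .setSeedIfGiven(seed)
  if (targetN == 0L) return(character(0))
  sample(subjects, targetN)
}

#' @rdname subsampleTraining
#' @param sinistralN size of the sinistral cohort being matched.
#' @export
defaultSubsampleTarget <- function(sinistralN) as.integer(round(4 / 5 * sinistralN))

#' Four-way outcome labels
#'
#' Combines handedness and hemisphere chirality into the four prediction
#' classes (\code{rightyLH}, \code{rightyRH}, \code{leftyLH},
#' \code{leftyRH}); \code{decomposeFourway} is the exact inverse, splitting
#' predicted labels back into their chirality and handedness components.
#'
#' @param hemi \code{"LH"} or \code{"RH"}.
#' @param handedness \code{"dextral"} or \code{"sinistral"}.
#' @return character labels.
#' @export
fourwayLabels <- function(hemi, handedness) {
  if (!all(hemi %in% c("LH", "RH"))) stop("unknown hemisphere label")
  if (!all(handedness %in% c("dextral", "sinistral")))
    stop("unknown handedness label")
  paste0(ifelse(handedness == "dextral", "righty", "lefty"), hemi)
}

#' @rdname fourwayLabels
#' @param labels four-way labels to decompose.
#' @export
decomposeFourway <- function(labels) {
  ok <- labels %in% c("rightyLH", "rightyRH", "leftyLH", "leftyRH")
  if (!all(ok)) stop("unknown four-way label(s): ",
                     paste(unique(labels[!ok]), collapse = ", "))
  list(hemi = substr(labels, nchar(labels) - 1L, nchar(labels)),
       handedness = ifelse(startsWith(labels, "righty"), "dextral", "sinistral"))
}

# per-feature standardization fitted on the training rows only
.standardizeTrainTest <- function(trainX, testX) {
  mu <- colMeans(trainX)
  sd <- apply(trainX, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(trainX, 2, mu), 2, sd, "/"),
       test = sweep(sweep(testX, 2, mu), 2, sd, "/"))
}

#' Train a classifier and predict test labels
#'
#' The three classifier families: LDA (no feature scaling, keeping the
#' discriminant scalings interpretable), linear-kernel SVM, and a
#' single-hidden-layer neural net (the latter two on per-feature
#' standardization fitted on the training rows). LDA additionally returns
#' the fitted model, exposing its per-feature scalings and discriminant
#' scores.
#'
#' @param trainX,testX samples x features matrices.
#' @param trainY training labels (at least 2 classes).
#' @param modelKind \code{"lda"}, \code{"svc"} or \code{"nn"}.
#' @param nnSize,nnDecay,nnMaxit neural-net hyperparameters.
#' @return list: \code{pred} (character labels) and, for LDA, \code{model}.
#' @export
trainAndPredict <- function(trainX, trainY, testX,
                            modelKind = c("lda", "svc", "nn"),
                            nnSize = 4L, nnDecay = 0.1, nnMaxit = 200L) {
  modelKind <- match.arg(modelKind)
  if (nrow(trainX) != length(trainY)) stop("feature/label dimension mismatch")
  if (ncol(trainX) != ncol(testX)) stop("train/test feature dimension mismatch")
  yf <- factor(trainY)
  if (nlevels(yf) < 2L) stop("training labels contain a single class")
  if (modelKind == "lda") {
    fit <- suppressWarnings(MASS::lda(trainX, grouping = yf))
    pred <- as.character(predict(fit, testX)$class)
    return(list(pred = pred, model = fit))
  }
  std <- .standardizeTrainTest(trainX, testX)
  if (modelKind == "svc") {
    fit <- e1071::svm(std$train, yf, kernel = "linear", scale = FALSE)
    return(list(pred = as.character(predict(fit, std$test)), model = NULL))
  }
  targets <- nnet::class.ind(yf)
  fit <- nnet::nnet(std$train, targets, size = nnSize, decay = nnDecay,
                    maxit = nnMaxit, softmax = TRUE, trace = FALSE,
                    MaxNWts = 1e6)
  probs <- predict(fit, std$test)
  list(pred = colnames(probs)[max.col(probs, ties.method = "first")],
       model = NULL)
}

# outcome labels for a HemiFeatureSet's samples
.outcomeLabels <- function(fs, outcome) {
  cd <- SummarizedExperiment::colData(fs)
  switch(outcome,
         chirality = {
           if (anyNA(cd$hemisphere))
             stop("chirality outcome requires hemisphere samples (kind = 'HC')")
           as.character(cd$hemisphere)
         },
         handedness = ifelse(cd$handedness == "dextral", "righty", "lefty"),
         fourway = {
           if (anyNA(cd$hemisphere))
             stop("four-way outcome requires hemisphere samples (kind = 'HC')")
           fourwayLabels(as.character(cd$hemisphere), as.character(cd$handedness))
         },
         stop("unknown outcome: ", outcome))
}

#' Cross-validated classification experiment
#'
#' Runs one classifier over a subject-level fold plan: for every fold, the
#' model is trained on the remaining folds' samples and tested on the
#' held-out fold, with an explicit leak check that no subject contributes
#' to both sides. Optional training-set manipulations mirror the study's
#' controls: minority oversampling by row duplication, and a size-matched
#' dextral training subsample. Scores are per-fold and pooled MCC with a
#' bootstrap 95 percent CI; the four-way outcome additionally reports the
#' decomposed chirality and handedness sub-problems.
#'
#' @param fs a \code{\link{HemiFeatureSet}}.
#' @param outcome \code{"chirality"}, \code{"handedness"} or \code{"fourway"}.
#' @param modelKind \code{"lda"}, \code{"svc"} or \code{"nn"}.
#' @param foldPlan from \code{\link{makeFolds}}; defaults to 5 folds.
#' @param oversample oversample minority training classes.
#' @param subsampleDextral if non-NULL, number of dextral training subjects
#'   to keep per fold (sinistral training subjects are kept as-is).
#' @param bootReps bootstrap repetitions for the CI.
#' @param seed seed for folds (when defaulted), oversampling, subsampling
#'   and the bootstrap.
#' @return a \code{\link{ClassificationRun}}.
#' @export
crossValidate <- function(fs, outcome = c("chirality", "handedness", "fourway"),
                          modelKind = c("lda", "svc", "nn"),
                          foldPlan = NULL, oversample = FALSE,
                          subsampleDextral = NULL, bootReps = 1000L,
                          seed = 1L) {
  outcome <- match.arg(outcome)
  modelKind <- match.arg(modelKind)
  cd <- SummarizedExperiment::colData(fs)
  X <- t(SummarizedExperiment::assay(fs, "z"))
  y <- .outcomeLabels(fs, outcome)
  subj <- as.character(cd$subjectId)
  if (is.null(foldPlan)) {
    md <- unique(data.frame(subjectId = subj,
                            handedness = as.character(cd$handedness),
                            stringsAsFactors = FALSE))
    foldPlan <- makeFolds(md, seed = .deriveSeed(seed, "folds"))
  }
  sampleFold <- foldPlan$fold[match(subj, foldPlan$subjectId)]
  if (anyNA(sampleFold)) stop("fold plan does not cover all subjects")
  lev <- sort(unique(y))
  preds <- character(length(y))
  confusion <- list()
  foldMccs <- numeric(0)
  for (f in levels(foldPlan$fold)) {
    testIdx <- which(sampleFold == f)
    trainIdx <- which(sampleFold != f)
    if (!is.null(subsampleDextral)) {
      trainSubj <- unique(subj[trainIdx])
      dex <- trainSubj[foldPlan$handedness[match(trainSubj, foldPlan$subjectId)] ==
                         "dextral"]
      keep <- c(subsampleTraining(dex, subsampleDextral,
                                  seed = .deriveSeed(seed, paste0("sub", f))),
                setdiff(trainSubj, dex))
      trainIdx <- trainIdx[subj[trainIdx] %in% keep]
    }
    if (length(intersect(subj[trainIdx], subj[testIdx])) > 0)
      stop("fold hygiene violation: subject in both train and test")
    trX <- X[trainIdx, , drop = FALSE]; trY <- y[trainIdx]
    if (oversample) {
      os <- oversampleMinority(trX, trY, seed = .deriveSeed(seed, paste0("os", f)))
      trX <- os$x; trY <- os$y
    }
    fit <- trainAndPredict(trX, trY, X[testIdx, , drop = FALSE], modelKind)
    preds[testIdx] <- fit$pred
    cmF <- .confusion(y[testIdx], fit$pred, lev)
    confusion[[f]] <- cmF
    foldMccs <- c(foldMccs, mcc(cmF))
  }
  pooled <- .confusion(y, preds, lev)
  confusion$pooled <- pooled
  ci <- bootstrapMccCi(y, preds, reps = bootReps,
                       seed = .deriveSeed(seed, "boot"))
  predDf <- data.frame(sample = rownames(cd), subjectId = subj,
                       fold = as.character(sampleFold), truth = y, pred = preds,
                       stringsAsFactors = FALSE)
  decomposed <- list()
  if (outcome == "fourway") {
    dt <- decomposeFourway(y); dp <- decomposeFourway(preds)
    for (part in c("hemi", "handedness")) {
      plev <- sort(unique(dt[[part]]))
      cmParts <- lapply(levels(foldPlan$fold), function(f) {
        k <- predDf$fold == f
        .confusion(dt[[part]][k], dp[[part]][k], plev)
      })
      names(cmParts) <- levels(foldPlan$fold)
      cmParts$pooled <- .confusion(dt[[part]], dp[[part]], plev)
      decomposed[[if (part == "hemi") "chirality" else "handedness"]] <- list(
        confusion = cmParts,
        foldMcc = vapply(cmParts[levels(foldPlan$fold)], mcc, numeric(1)),
        ci = bootstrapMccCi(dt[[part]], dp[[part]], reps = bootReps,
                            seed = .deriveSeed(seed, paste0("boot", part))))
    }
  }
  new("ClassificationRun", modelKind = modelKind, outcome = outcome,
      foldPlan = foldPlan, predictions = predDf, confusion = confusion,
      foldMcc = foldMccs, mccPoint = ci[["mean"]], mccCiLow = ci[["low"]],
      mccCiHigh = ci[["high"]], decomposed = decomposed)
}

#' Per-class accuracy of a classification run
#'
#' @param run a \code{\link{ClassificationRun}}.
#' @param pooled use the pooled confusion matrix instead of per-fold ones.
#' @return matrix folds x classes (or a named vector when pooled) of
#'   per-class accuracies diag/rowSums.
#' @export
perClassAccuracy <- function(run, pooled = FALSE) {
  acc1 <- function(cm) diag(as.matrix(cm)) / rowSums(as.matrix(cm))
  if (pooled) return(acc1(run@confusion$pooled))
  folds <- setdiff(names(run@confusion), "pooled")
  t(vapply(folds, function(f) acc1(run@confusion[[f]]),
           numeric(nrow(run@confusion$pooled))))
}

#' Paired comparison of matched MCC lists
#'
#' Standard paired t-test between two matched lists of MCC values (e.g.
#' folds x models of two training regimes), with Cohen's d of the
#' differences. Identical lists return t = 0, p = 1; constant non-zero
#' differences (zero variance) are an error since t is undefined.
#'
#' @param mccA,mccB equal-length matched numeric vectors, n >= 2.
#' @return list: meanDiff, t, df, p, d.
#' @export
compareMccPaired <- function(mccA, mccB) {
  stopifnot(length(mccA) == length(mccB), length(mccA) >= 2L)
  d <- mccA - mccB
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(meanDiff = 0, t = 0, df = length(d) - 1L, p = 1, d = 0))
    stop("zero variance of non-zero differences: paired t undefined")
  }
  tt <- stats::t.test(mccA, mccB, paired = TRUE)
  list(meanDiff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       d = mean(d) / stats::sd(d))
}
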