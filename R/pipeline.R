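#' @include AllClasses.R AllGenerics.R synthetic.R connectome.R classify.R enrichment.R hemispace.R
NULL

#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run. All stochastic stages
#' derive their seeds from the single master seed, so partial reruns
#' reproduce the corresponding stages of a full run. The configuration
#' round-trips through YAML unchanged (\code{readRunConfig} /
#' \code{writeRunConfig}).
#'
#' @param cohort list of \code{\link{cohortSpec}} arguments (or an already
#'   built \code{CohortSpec} passed to \code{runAnalysis} directly).
#' @param analyses subset of \code{c(1, 2, 3)}.
#' @param models classifier kinds to run.
#' @param nFolds cross-validation folds.
#' @param permReps enrichment permutations per stage.
#' @param bootReps bootstrap repetitions for MCC CIs.
#' @param alpha connection-level significance threshold.
#' @param seed master seed.
#' @return a named list of class \code{hemiconnConfig}.
#' @export
runConfig <- function(cohort = list(), analyses = c(1, 2, 3),
                      models = c("lda", "svc", "nn"), nFolds = 5L,
                      permReps = 500L, bootReps = 1000L, alpha = 0.01,
                      seed = 1L) {
  stopifnot(all(analyses %in% 1:3), all(models %in% c("lda", "svc", "nn")))
  structure(list(cohort = cohort, analyses = analyses, models = models,
                 nFolds = as.integer(nFolds), permReps = as.integer(permReps),
                 bootReps = as.integer(bootReps), alpha = alpha,
                 seed = as.integer(seed)),
            class = "hemiconnConfig")
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(runConfig, x)
}

#' @rdname runConfig
#' @param config a \code{hemiconnConfig}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Reporting operation: checks the atlas homologue bijection, symmetry and
#' finiteness of connectivity matrices, and completeness/range of the
#' subject metadata, and returns every violation found (a zero-row frame
#' means all inputs are valid).
#'
#' @param atlas a \code{\link{ParcelAtlas}} or NULL.
#' @param matrices named list of connectivity matrices or NULL.
#' @param metadata subject metadata data.frame or NULL.
#' @return data.frame: component, message.
#' @export
validateInputs <- function(atlas = NULL, matrices = NULL, metadata = NULL) {
  bad <- list()
  note <- function(component, message)
    bad[[length(bad) + 1L]] <<- data.frame(component = component,
                                           message = message,
                                           stringsAsFactors = FALSE)
  if (!is.null(atlas)) {
    v <- tryCatch({ validObject(atlas); TRUE },
                  error = function(e) conditionMessage(e))
    if (!isTRUE(v)) note("atlas", v)
  }
  for (nm in names(matrices)) {
    M <- matrices[[nm]]
    if (!all(is.finite(M)))
      note(nm, "non-finite connectivity values")
    asym <- abs(M - t(M))
    if (any(is.finite(asym)) && max(asym, na.rm = TRUE) > 1e-8) {
      ij <- which(asym == max(asym, na.rm = TRUE), arr.ind = TRUE)[1, ]
      note(nm, sprintf("matrix not symmetric (max at [%d, %d])",
                       ij[1], ij[2]))
    }
  }
  if (!is.null(metadata)) {
    for (col in c("subjectId", "ehi", "handedness"))
      if (!col %in% names(metadata)) note("metadata", paste("missing column", col))
    if ("ehi" %in% names(metadata)) {
      if (anyNA(metadata$ehi)) note("metadata", "missing EHI value(s)")
      out <- stats::na.omit(metadata$ehi)
      if (any(out < -100 | out > 100)) note("metadata", "EHI outside [-100, 100]")
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(component = character(), message = character())
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.runsToTable <- function(runs) {
  do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    data.frame(run = nm, model = r@modelKind, outcome = r@outcome,
               mcc = r@mccPoint, ciLow = r@mccCiLow, ciHigh = r@mccCiHigh,
               minFoldMcc = min(r@foldMcc), stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the three analyses end-to-end on one cohort:
#' \enumerate{
#'   \item Chirality classification on the dextral subjects (per model),
#'     network enrichment of the dextral maximal model, and the maximal
#'     LD1 exploration (per-hemisphere scores and their correlation).
#'   \item The same chirality classification on the sinistral subjects,
#'     plus the size-matched dextral control (training subsampled to
#'     4/5 of the sinistral cohort size) and the paired fold-by-model MCC
#'     comparison of full vs subsampled dextral training.
#'   \item Four-way hemisphere-by-handedness classification on the
#'     hemiconnectome (plus its oversampled variant) with decomposed
#'     chirality/handedness scores, handedness-only classification on the
#'     full and trans-connectome, and the hemisphere-space analyses:
#'     Z(LD1) group test and the linear/segmented/quadratic EHI-distance
#'     model comparison.
#' }
#'
#' @param config from \code{\link{runConfig}}.
#' @param cohort optional pre-built \code{\link{SyntheticCohort}};
#'   otherwise generated from \code{config$cohort}.
#' @return list: manifest, cohortSummary, analysis1, analysis2, analysis3.
#' @export
runAnalysis <- function(config = runConfig(), cohort = NULL) {
  seed <- config$seed
  if (is.null(cohort)) {
    spec <- .stage("cohort", do.call(cohortSpec, c(config$cohort,
      if (!"seed" %in% names(config$cohort)) list(seed = .deriveSeed(seed, "cohort")))))
    cohort <- .stage("cohort", generateCohort(spec))
  }
  md <- cohortMetadata(cohort)
  atlas <- cohortAtlas(cohort)
  fsHC <- .stage("features", buildFeatureSet(cohort, "HC"))
  report <- list(
    manifest = list(package = "hemiconn",
                    version = as.character(utils::packageVersion("hemiconn")),
                    seed = seed, models = config$models,
                    nFolds = config$nFolds, permReps = config$permReps,
                    bootReps = config$bootReps, alpha = config$alpha,
                    spec = specAsList(cohort@spec)),
    cohortSummary = list(n = nrow(md),
                         nDextral = sum(md$handedness == "dextral"),
                         nSinistral = sum(md$handedness == "sinistral")))
  subsetFs <- function(fs, keep) {
    idx <- SummarizedExperiment::colData(fs)$subjectId %in% keep
    fs2 <- fs[, idx]
    new("HemiFeatureSet", fs2, kind = featureKind(fs))
  }
  dexIds <- md$subjectId[md$handedness == "dextral"]
  sinIds <- md$subjectId[md$handedness == "sinistral"]

  if (1 %in% config$analyses) {
    report$analysis1 <- .stage("analysis1", {
      fsDex <- subsetFs(fsHC, dexIds)
      mdDex <- md[md$handedness == "dextral", ]
      plan <- makeFolds(mdDex, config$nFolds, seed = .deriveSeed(seed, "a1folds"))
      runs <- lapply(config$models, function(m)
        crossValidate(fsDex, "chirality", m, foldPlan = plan,
                      bootReps = config$bootReps,
                      seed = .deriveSeed(seed, paste0("a1", m))))
      names(runs) <- config$models
      enr <- networkEnrichment(fsDex, atlas, reps = config$permReps,
                               alpha = config$alpha,
                               seed = .deriveSeed(seed, "a1enrich"))
      hs <- hemisphereScores(fsDex)
      list(classification = .runsToTable(runs), runs = runs,
           enrichment = enr,
           ld1Correlation = ld1Correlation(hs$scores$ld1LH, hs$scores$ld1RH),
           scores = hs$scores)
    })
  }
  if (2 %in% config$analyses) {
    report$analysis2 <- .stage("analysis2", {
      if (length(sinIds) < config$nFolds)
        stop("too few sinistral subjects for ", config$nFolds, " folds")
      fsSin <- subsetFs(fsHC, sinIds)
      mdSin <- md[md$handedness == "sinistral", ]
      planS <- makeFolds(mdSin, config$nFolds, seed = .deriveSeed(seed, "a2folds"))
      runsSin <- lapply(config$models, function(m)
        crossValidate(fsSin, "chirality", m, foldPlan = planS,
                      bootReps = config$bootReps,
                      seed = .deriveSeed(seed, paste0("a2sin", m))))
      names(runsSin) <- config$models
      # size-matched dextral control: training subsampled to 4/5 of the
      # sinistral cohort, tested on the full held-out dextral fold
      target <- defaultSubsampleTarget(length(sinIds))
      fsDex <- subsetFs(fsHC, dexIds)
      mdDex <- md[md$handedness == "dextral", ]
      planD <- makeFolds(mdDex, config$nFolds, seed = .deriveSeed(seed, "a2dfolds"))
      runsFull <- lapply(config$models, function(m)
        crossValidate(fsDex, "chirality", m, foldPlan = planD,
                      bootReps = config$bootReps,
                      seed = .deriveSeed(seed, paste0("a2full", m))))
      runsSub <- lapply(config$models, function(m)
        crossValidate(fsDex, "chirality", m, foldPlan = planD,
                      subsampleDextral = target, bootReps = config$bootReps,
                      seed = .deriveSeed(seed, paste0("a2sub", m))))
      names(runsFull) <- names(runsSub) <- config$models
      paired <- compareMccPaired(unlist(lapply(runsSub, foldMcc)),
                                 unlist(lapply(runsFull, foldMcc)))
      list(sinistral = .runsToTable(runsSin), runsSinistral = runsSin,
           control = .runsToTable(c(stats::setNames(runsFull,
                       paste0("full.", names(runsFull))),
                     stats::setNames(runsSub, paste0("hc", target, ".",
                       names(runsSub))))),
           subsampleTarget = target, pairedComparison = paired)
    })
  }
  if (3 %in% config$analyses) {
    report$analysis3 <- .stage("analysis3", {
      plan <- makeFolds(md, config$nFolds, seed = .deriveSeed(seed, "a3folds"))
      runs <- list()
      for (m in config$models) {
        runs[[paste0("HC.", m)]] <- crossValidate(
          fsHC, "fourway", m, foldPlan = plan, bootReps = config$bootReps,
          seed = .deriveSeed(seed, paste0("a3hc", m)))
        runs[[paste0("HCO.", m)]] <- crossValidate(
          fsHC, "fourway", m, foldPlan = plan, oversample = TRUE,
          bootReps = config$bootReps,
          seed = .deriveSeed(seed, paste0("a3hco", m)))
      }
      fsFC <- buildFeatureSet(cohort, "FC")
      fsTC <- buildFeatureSet(cohort, "TC")
      for (m in config$models) {
        runs[[paste0("FC.", m)]] <- crossValidate(
          fsFC, "handedness", m, foldPlan = plan, bootReps = config$bootReps,
          seed = .deriveSeed(seed, paste0("a3fc", m)))
        runs[[paste0("TC.", m)]] <- crossValidate(
          fsTC, "handedness", m, foldPlan = plan, bootReps = config$bootReps,
          seed = .deriveSeed(seed, paste0("a3tc", m)))
      }
      handedMcc <- vapply(runs, function(r) {
        if (r@outcome == "fourway") mean(r@decomposed$handedness$foldMcc)
        else mean(r@foldMcc)
      }, numeric(1))
      chiralMcc <- vapply(runs, function(r) {
        if (r@outcome == "fourway") mean(r@decomposed$chirality$foldMcc)
        else NA_real_
      }, numeric(1))
      hs <- hemisphereScores(fsHC)
      zTest <- groupDistanceTest(c(hs$scores$zLd1LH, hs$scores$zLd1RH),
                                 rep(hs$scores$handedness, 2))
      dm <- fitDistanceModels(hs$scores$ehi, hs$scores$ld1Dist,
                              seed = .deriveSeed(seed, "a3seg"))
      list(classification = data.frame(run = names(runs),
                                       handednessMcc = unname(handedMcc),
                                       chiralityMcc = unname(chiralMcc),
                                       stringsAsFactors = FALSE),
           runs = runs, scores = hs$scores, zTest = zTest,
           distanceModels = dm)
    })
  }
  report
}
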