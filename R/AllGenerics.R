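#' @include AllClasses.R
NULL

#' Accessors for hemiconn classes
#'
#' Small accessor generics: \code{parcelsPerHemi} (parcels per hemisphere),
#' \code{keptNetworks} (network labels retained for enrichment grouping),
#' \code{discordantPairs} (homologue pairs whose raw network labels differ),
#' \code{cohortMetadata}, \code{cohortAtlas}, \code{subjectTimeseries},
#' \code{featureKind}, \code{mccValue}, \code{mccCI}, \code{foldMcc},
#' \code{confusionMatrices}, \code{runPredictions}, \code{groupTable},
#' \code{signCounts}, \code{connectionP}, \code{significanceMask}.
#'
#' @param x an object of the documented class.
#' @param i subject index (for \code{subjectTimeseries}).
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("parcelsPerHemi", function(x) standardGeneric("parcelsPerHemi"))
#' @rdname accessors
#' @export
setGeneric("keptNetworks", function(x) standardGeneric("keptNetworks"))
#' @rdname accessors
#' @export
setGeneric("discordantPairs", function(x) standardGeneric("discordantPairs"))
#' @rdname accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))
#' @rdname accessors
#' @export
setGeneric("cohortAtlas", function(x) standardGeneric("cohortAtlas"))
#' @rdname accessors
#' @export
setGeneric("subjectTimeseries", function(x, i) standardGeneric("subjectTimeseries"))
#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
#' @rdname accessors
#' @export
setGeneric("mccValue", function(x) standardGeneric("mccValue"))
#' @rdname accessors
#' @export
setGeneric("mccCI", function(x) standardGeneric("mccCI"))
#' @rdname accessors
#' @export
setGeneric("foldMcc", function(x) standardGeneric("foldMcc"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrices", function(x) standardGeneric("confusionMatrices"))
#' @rdname accessors
#' @export
setGeneric("runPredictions", function(x) standardGeneric("runPredictions"))
#' @rdname accessors
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))
#' @rdname accessors
#' @export
setGeneric("signCounts", function(x) standardGeneric("signCounts"))
#' @rdname accessors
#' @export
setGeneric("connectionP", function(x) standardGeneric("connectionP"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname accessors
setMethod("parcelsPerHemi", "ParcelAtlas", function(x) x@parcelsPerHemi)
#' @rdname accessors
setMethod("keptNetworks", "ParcelAtlas", function(x) {
  if (anyNA(x@networkSym)) stop("networks not symmetrized yet; run symmetrizeNetworks()")
  sort(unique(x@networkSym[!x@excluded]))
})
#' @rdname accessors
setMethod("discordantPairs", "ParcelAtlas", function(x) {
  lh <- which(x@hemisphere == "LH")
  sum(x@networkRaw[lh] != x@networkRaw[x@homologue[lh]])
})
#' @rdname accessors
setMethod("cohortMetadata", "SyntheticCohort", function(x) x@metadata)
#' @rdname accessors
setMethod("cohortAtlas", "SyntheticCohort", function(x) x@atlas)
#' @rdname accessors
setMethod("subjectTimeseries", "SyntheticCohort", function(x, i) x@timeseries[[i]])
#' @rdname accessors
setMethod("featureKind", "HemiFeatureSet", function(x) x@kind)
#' @rdname accessors
setMethod("featureKind", "FeatureVectorSet", function(x) x@kind)
#' @rdname accessors
setMethod("mccValue", "ClassificationRun", function(x) x@mccPoint)
#' @rdname accessors
setMethod("mccCI", "ClassificationRun", function(x) c(low = x@mccCiLow, high = x@mccCiHigh))
#' @rdname accessors
setMethod("foldMcc", "ClassificationRun", function(x) x@foldMcc)
#' @rdname accessors
setMethod("confusionMatrices", "ClassificationRun", function(x) x@confusion)
#' @rdname accessors
setMethod("runPredictions", "ClassificationRun", function(x) x@predictions)
#' @rdname accessors
setMethod("groupTable", "EnrichmentResult", function(x) x@groupTable)
#' @rdname accessors
setMethod("signCounts", "EnrichmentResult", function(x) x@signCounts)
#' @rdname accessors
setMethod("connectionP", "EnrichmentResult", function(x) x@pConnection)
#' @rdname accessors
setMethod("significanceMask", "EnrichmentResult", function(x) x@mask)

setMethod("show", "ParcelAtlas", function(object) {
  cat("ParcelAtlas:", 2L * object@parcelsPerHemi, "parcels (",
      object@parcelsPerHemi, "per hemisphere )\n")
  if (!anyNA(object@networkSym)) {
    kn <- keptNetworks(object)
    cat("  kept networks (", length(kn), "):", paste(kn, collapse = ", "), "\n")
    cat("  excluded parcels:", sum(object@excluded), "\n")
  } else {
    cat("  raw networks:", paste(sort(unique(object@networkRaw)), collapse = ", "), "\n")
  }
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects,",
      object@parcelsPerHemi, "parcels/hemi,", object@timepoints, "timepoints\n")
  cat("  networks:", paste(sprintf("%s=%d", names(object@networks), object@networks),
                           collapse = " "), "\n")
  if (nrow(object@asymmetryMap))
    cat("  planted asymmetries:",
        paste(sprintf("%s-%s %+0.2f", object@asymmetryMap$netA,
                      object@asymmetryMap$netB, object@asymmetryMap$offset),
              collapse = ", "), "\n")
  else cat("  planted asymmetries: none (null cohort)\n")
  cat("  dextral mass:", object@ehiModel$dextralMass,
      " breakpoint:", object@distanceModel$breakpoint, " seed:", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  md <- object@metadata
  cat("SyntheticCohort:", nrow(md), "subjects (",
      sum(md$handedness == "dextral"), "dextral /",
      sum(md$handedness == "sinistral"), "sinistral )\n")
  cat("  parcels/hemi:", object@spec@parcelsPerHemi,
      " timepoints:", object@spec@timepoints, "\n")
})

setMethod("show", "ClassificationRun", function(object) {
  cat(sprintf("ClassificationRun [%s, %s]: MCC = %.3f (95%% CI %.3f-%.3f)\n",
              object@modelKind, object@outcome, object@mccPoint,
              object@mccCiLow, object@mccCiHigh))
  cat("  per-fold MCC:", paste(sprintf("%.3f", object@foldMcc), collapse = " "), "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", sum(object@mask), "of", length(object@mask),
      "connections significant at alpha =", object@alpha, "\n")
  sig <- object@groupTable[object@groupTable$pCor < 0.05, , drop = FALSE]
  cat("  groups with FDR-corrected p < .05:", nrow(sig), "of",
      nrow(object@groupTable), "\n")
  if (nrow(sig)) cat("   ", paste(sig$group, collapse = ", "), "\n")
  cat("  sign split: LH>RH", object@signCounts[["LHgtRH"]],
      "/ RH>LH", object@signCounts[["RHgtLH"]], "\n")
})

setMethod("show", "DistanceFit", function(object) {
  cat(sprintf("DistanceFit [%s]: AIC = %.1f, R2 = %.3f\n",
              object@kind, object@aic, object@r2))
  if (length(object@breakpoints))
    cat("  breakpoints:", paste(sprintf("%.1f (SE %.1f)", object@breakpoints,
                                        object@breakpointSE), collapse = ", "),
        if (object@boundary) "[at data boundary]" else "", "\n")
  if (!anyNA(object@vertex))
    cat(sprintf("  vertex: (%.1f, %.1f)%s\n", object@vertex[1], object@vertex[2],
                if (object@opensDownward) " (opens downward)" else " (opens upward)"))
})
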