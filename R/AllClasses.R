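#' @import methods
NULL

#' Parcel atlas with hemisphere, homologue and network assignments
#'
#' A \code{ParcelAtlas} describes the \code{2P} cortical parcels used to build
#' connectomes: \code{P} parcels per hemisphere, a perfect homologue matching
#' between hemispheres, a raw per-parcel network label (possibly discordant
#' between the members of a homologue pair) and, after
#' \code{\link{symmetrizeNetworks}}, a symmetrized per-pair label. Parcels of
#' dropped networks stay in the feature vectors; \code{excluded} only removes
#' them from enrichment grouping.
#'
#' @slot parcelsPerHemi integer, parcels per hemisphere (P).
#' @slot parcelId character of length 2P; LH parcels first.
#' @slot hemisphere character, \code{"LH"} or \code{"RH"} per parcel.
#' @slot homologue integer of length 2P; index of the homologous parcel.
#' @slot networkRaw character, per-parcel network label as assigned.
#' @slot networkSym character, per-pair label after symmetrization (the LH
#'   member's label), \code{NA} until \code{symmetrizeNetworks} is applied.
#' @slot excluded logical, parcels of dropped networks.
#'
#' @seealso \code{\link{parcelAtlas}}, \code{\link{makeAtlas}},
#'   \code{\link{mergeAndDropNetworks}}, \code{\link{keptNetworks}}
#' @export
setClass("ParcelAtlas",
  representation(
    parcelsPerHemi = "integer",
    parcelId = "character",
    hemisphere = "character",
    homologue = "integer",
    networkRaw = "character",
    networkSym = "character",
    excluded = "logical"
  )
)

setValidity("ParcelAtlas", function(object) {
  P <- object@parcelsPerHemi
  n <- 2L * P
  msg <- character()
  if (length(object@parcelId) != n) msg <- c(msg, "parcelId must have length 2P")
  if (length(object@hemisphere) != n || !all(object@hemisphere %in% c("LH", "RH")))
    msg <- c(msg, "hemisphere must be 'LH'/'RH' of length 2P")
  if (sum(object@hemisphere == "LH") != P)
    msg <- c(msg, "exactly P parcels must be LH")
  h <- object@homologue
  if (length(h) != n || anyNA(h) || !all(sort(h) == seq_len(n)) ||
      !all(h[h] == seq_len(n)))
    msg <- c(msg, "homologue must be an involutive perfect matching")
  else if (any(object@hemisphere[h] == object@hemisphere))
    msg <- c(msg, "homologue pairs must span both hemispheres")
  if (length(object@networkRaw) != n) msg <- c(msg, "networkRaw length != 2P")
  if (length(object@networkSym) != n) msg <- c(msg, "networkSym length != 2P")
  if (!anyNA(object@networkSym) && length(msg) == 0L &&
      !all(object@networkSym == object@networkSym[h]))
    msg <- c(msg, "networkSym must agree within homologue pairs")
  if (length(object@excluded) != n) msg <- c(msg, "excluded length != 2P")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic cohort
#'
#' Defines the generative conditions for a synthetic cohort: cohort size,
#' parcels and timepoints, the per-network parcel counts, the planted
#' LH-minus-RH connectivity offsets (Fisher-Z/correlation units) per network
#' pair, the J-shaped EHI sampler, and the piecewise-linear link from EHI to
#' asymmetry scale. See \code{\link{cohortSpec}} for defaults and units.
#'
#' @slot nSubjects integer.
#' @slot parcelsPerHemi integer.
#' @slot timepoints integer, samples per scan.
#' @slot networks named integer, parcels per network (one hemisphere).
#' @slot asymmetryMap data.frame with columns \code{netA}, \code{netB},
#'   \code{offset}: LH-minus-RH connectivity offset for that network block.
#' @slot ehiModel list: \code{dextralMass}, \code{dextralMean},
#'   \code{dextralSD}, \code{sinistralMean}, \code{sinistralSD}.
#' @slot distanceModel list: \code{slopeBelow}, \code{breakpoint},
#'   \code{slopeAbove}, \code{noiseSD} (EHI units).
#' @slot baseWithin,baseBetween numeric, baseline within/between-network
#'   correlations of the latent block model.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    parcelsPerHemi = "integer",
    timepoints = "integer",
    networks = "integer",
    asymmetryMap = "data.frame",
    ehiModel = "list",
    distanceModel = "list",
    baseWithin = "numeric",
    baseBetween = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  for (s in c("nSubjects", "parcelsPerHemi", "timepoints"))
    if (!.isCount(slot(object, s))) msg <- c(msg, paste(s, "must be a positive count"))
  if (is.null(names(object@networks)) || any(object@networks < 1L))
    msg <- c(msg, "networks must be a named vector of positive counts")
  if (length(msg) == 0L && sum(object@networks) != object@parcelsPerHemi)
    msg <- c(msg, "per-network parcel counts must sum to parcelsPerHemi")
  am <- object@asymmetryMap
  if (!all(c("netA", "netB", "offset") %in% names(am)))
    msg <- c(msg, "asymmetryMap needs columns netA, netB, offset")
  else if (nrow(am) > 0 &&
           !all(c(am$netA, am$netB) %in% names(object@networks)))
    msg <- c(msg, "asymmetryMap references unknown networks")
  em <- object@ehiModel
  if (is.null(em$dextralMass) || em$dextralMass < 0 || em$dextralMass > 1)
    msg <- c(msg, "ehiModel$dextralMass must lie in [0, 1]")
  dm <- object@distanceModel
  if (!all(c("slopeBelow", "breakpoint", "slopeAbove", "noiseSD") %in% names(dm)))
    msg <- c(msg, "distanceModel needs slopeBelow, breakpoint, slopeAbove, noiseSD")
  if (object@baseWithin <= 0 || object@baseWithin >= 1)
    msg <- c(msg, "baseWithin must lie in (0, 1)")
  if (abs(object@baseBetween) >= object@baseWithin)
    msg <- c(msg, "|baseBetween| must be smaller than baseWithin")
  # planted offsets must keep all latent correlations inside (-1, 1) and the
  # network factor-correlation matrix positive semidefinite at full scale
  if (length(msg) == 0L && nrow(am) > 0) {
    chk <- tryCatch(.networkPhi(object, scale = 1, hemi = "LH"),
                    error = function(e) conditionMessage(e))
    if (is.character(chk)) msg <- c(msg, chk)
  }
  if (length(msg)) msg else TRUE
})

#' Feature vector extracted from one connectivity matrix
#'
#' Holds one of the canonical feature sets of a subject's Fisher-Z
#' connectivity matrix, together with its total and injective map from
#' feature index to parcel pair.
#'
#' @slot kind \code{"HC-LH"}, \code{"HC-RH"}, \code{"TC"} or \code{"FC"}.
#' @slot values numeric feature vector.
#' @slot indexMap data.frame with global parcel indices \code{i}, \code{j}
#'   (into the 2P x 2P matrix) and the originating \code{part}.
#' @export
setClass("FeatureVectorSet",
  representation(kind = "character", values = "numeric", indexMap = "data.frame")
)

setValidity("FeatureVectorSet", function(object) {
  msg <- character()
  if (!object@kind %in% c("HC-LH", "HC-RH", "TC", "FC"))
    msg <- c(msg, "unknown feature kind")
  if (length(object@values) != nrow(object@indexMap))
    msg <- c(msg, "values and indexMap lengths differ")
  key <- paste(object@indexMap$i, object@indexMap$j)
  if (anyDuplicated(key)) msg <- c(msg, "indexMap must be injective")
  if (length(msg)) msg else TRUE
})

#' Cohort-level feature container
#'
#' A \code{SummarizedExperiment} holding one feature kind for a whole cohort:
#' assay \code{"z"} is features x samples (samples are hemispheres for the
#' hemiconnectome, subjects for trans-/full-connectome features), rowData
#' carries the feature-to-parcel-pair map and colData the subject metadata.
#'
#' @slot kind \code{"HC"}, \code{"TC"} or \code{"FC"}.
#' @export
setClass("HemiFeatureSet",
  contains = "SummarizedExperiment",
  representation(kind = "character")
)

#' Cohort of synthetic subjects
#'
#' Container returned by \code{\link{generateCohort}}: the generating
#' \code{\link{CohortSpec}}, per-subject metadata (EHI, handedness, realized
#' asymmetry scale), per-subject LH/RH parcel timeseries, and a matching
#' \code{\link{ParcelAtlas}}.
#'
#' @slot spec the generating CohortSpec.
#' @slot metadata data.frame: subjectId, ehi, handedness, asymmetryScale.
#' @slot timeseries list per subject of list(LH=, RH=) parcel x time matrices.
#' @slot atlas ParcelAtlas consistent with the spec's network counts.
#' @export
setClass("SyntheticCohort",
  representation(
    spec = "CohortSpec",
    metadata = "data.frame",
    timeseries = "list",
    atlas = "ParcelAtlas"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  n <- object@spec@nSubjects
  if (nrow(object@metadata) != n) msg <- c(msg, "metadata rows != nSubjects")
  if (length(object@timeseries) != n) msg <- c(msg, "timeseries entries != nSubjects")
  md <- object@metadata
  if (!all(c("subjectId", "ehi", "handedness") %in% names(md)))
    msg <- c(msg, "metadata needs subjectId, ehi, handedness")
  else {
    if (any(md$ehi < -100 | md$ehi > 100)) msg <- c(msg, "ehi outside [-100, 100]")
    want <- ifelse(md$ehi > 0, "dextral", "sinistral")
    if (!all(md$handedness == want))
      msg <- c(msg, "handedness inconsistent with the EHI <= 0 cutoff")
  }
  if (length(msg)) msg else TRUE
})

#' Result of one cross-validated classification experiment
#'
#' @slot modelKind \code{"lda"}, \code{"svc"} or \code{"nn"}.
#' @slot outcome \code{"chirality"}, \code{"handedness"} or \code{"fourway"}.
#' @slot foldPlan data.frame: subjectId, handedness, fold.
#' @slot predictions data.frame: sample, subjectId, fold, truth, pred.
#' @slot confusion list of per-fold confusion matrices plus \code{pooled}.
#' @slot foldMcc numeric, MCC per fold.
#' @slot mccPoint,mccCiLow,mccCiHigh bootstrap mean and 95 percent interval.
#' @slot decomposed list; for the four-way outcome, the chirality and
#'   handedness sub-results after label decomposition.
#' @export
setClass("ClassificationRun",
  representation(
    modelKind = "character",
    outcome = "character",
    foldPlan = "data.frame",
    predictions = "data.frame",
    confusion = "list",
    foldMcc = "numeric",
    mccPoint = "numeric",
    mccCiLow = "numeric",
    mccCiHigh = "numeric",
    decomposed = "list"
  )
)

setValidity("ClassificationRun", function(object) {
  msg <- character()
  if (length(object@mccPoint) == 1L && is.finite(object@mccPoint)) {
    if (object@mccPoint < -1 - 1e-9 || object@mccPoint > 1 + 1e-9)
      msg <- c(msg, "MCC outside [-1, 1]")
    if (object@mccCiLow > object@mccPoint + 1e-9 ||
        object@mccCiHigh < object@mccPoint - 1e-9)
      msg <- c(msg, "CI must bracket the point estimate")
  }
  tot <- vapply(object@confusion, sum, numeric(1))
  if ("pooled" %in% names(object@confusion) &&
      tot[["pooled"]] != nrow(object@predictions))
    msg <- c(msg, "pooled confusion total != number of predictions")
  if (length(msg)) msg else TRUE
})

#' Result of the two-stage permutation enrichment analysis
#'
#' @slot pConnection numeric, per-connection empirical p (floored at 3/reps).
#' @slot mask logical, \code{pConnection < alpha}.
#' @slot observedScaling numeric, sign-aligned LD1 scalings of the maximal
#'   model (negative = stronger in LH under the sign convention).
#' @slot groupTable data.frame: group, size, count, p, pCor.
#' @slot signCounts named integer: \code{LHgtRH}, \code{RHgtLH}.
#' @slot reps,groupReps integer permutation counts of the two stages.
#' @slot alpha numeric connection-level threshold.
#' @export
setClass("EnrichmentResult",
  representation(
    pConnection = "numeric",
    mask = "logical",
    observedScaling = "numeric",
    groupTable = "data.frame",
    signCounts = "integer",
    reps = "integer",
    groupReps = "integer",
    alpha = "numeric"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  floorP <- 3 / object@reps
  if (any(object@pConnection < floorP - 1e-12))
    msg <- c(msg, "connection p below the 3/reps floor")
  if (any(object@pConnection > 1 + 1e-12)) msg <- c(msg, "p above 1")
  if (length(object@mask) != length(object@pConnection))
    msg <- c(msg, "mask length != p length")
  if (nrow(object@groupTable) > 0 &&
      any(object@groupTable$p < 3 / object@groupReps - 1e-12))
    msg <- c(msg, "group p below the 3/reps floor")
  if (length(msg)) msg else TRUE
})

#' One fitted EHI-vs-distance model
#'
#' @slot kind \code{"linear"}, \code{"segmented1"}, \code{"segmented2"} or
#'   \code{"quadratic"}.
#' @slot coefficients named numeric.
#' @slot breakpoints numeric, estimated breakpoints (EHI units).
#' @slot breakpointSE numeric, bootstrap standard errors.
#' @slot aic,r2,rss,n fit summaries (AIC counts breakpoints as parameters).
#' @slot vertex numeric(2), quadratic vertex (location, value) or NA.
#' @slot opensDownward logical, quadratic curvature check.
#' @slot boundary logical, TRUE when a breakpoint search hit the data edge.
#' @export
setClass("DistanceFit",
  representation(
    kind = "character",
    coefficients = "numeric",
    breakpoints = "numeric",
    breakpointSE = "numeric",
    aic = "numeric",
    r2 = "numeric",
    rss = "numeric",
    n = "integer",
    vertex = "numeric",
    opensDownward = "logical",
    boundary = "logical"
  )
)
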