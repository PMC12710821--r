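#' @include AllClasses.R AllGenerics.R atlas.R
NULL

#' Pearson connectivity matrix of one subject
#'
#' Stacks the LH and RH parcel timeseries (LH parcels first) and computes
#' all pairwise Pearson correlations, giving a symmetric 2P x 2P matrix with
#' unit diagonal. A constant (zero-variance) parcel row makes its
#' correlations undefined and raises an error naming the parcel.
#'
#' @param timeseriesLH,timeseriesRH P x T numeric matrices.
#' @return 2P x 2P correlation matrix; LH parcels occupy rows/cols 1..P.
#' @export
pearsonMatrix <- function(timeseriesLH, timeseriesRH) {
  stopifnot(is.matrix(timeseriesLH), is.matrix(timeseriesRH))
  if (nrow(timeseriesLH) != nrow(timeseriesRH))
    stop("hemisphere timeseries must have the same number of parcels")
  if (ncol(timeseriesLH) != ncol(timeseriesRH))
    stop("hemisphere timeseries must have the same number of timepoints")
  if (ncol(timeseriesLH) < 3) stop("need at least 3 timepoints")
  X <- rbind(timeseriesLH, timeseriesRH)
  P <- nrow(timeseriesLH)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    ids <- ifelse(bad <= P, sprintf("L%03d", bad), sprintf("R%03d", bad - P))
    stop("constant (zero-variance) parcel timeseries: ",
         paste(ids, collapse = ", "))
  }
  C <- stats::cor(t(X))
  diag(C) <- 1
  C
}

#' Fisher-Z transform a correlation matrix
#'
#' Elementwise \code{atanh} of the off-diagonal entries, after clipping
#' \code{|r|} to \code{1 - eps} so that perfect correlations stay finite.
#' The diagonal is set to 0 (self-connections carry no information and are
#' excluded from every feature set).
#'
#' @param r matrix of correlations in [-1, 1].
#' @param eps clipping margin (default 1e-7).
#' @return matrix of Fisher-Z values.
#' @export
fisherZ <- function(r, eps = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  z <- atanh(.clamp(r, -1 + eps, 1 - eps))
  if (is.matrix(z) && nrow(z) == ncol(z)) diag(z) <- 0
  z
}

#' Canonical feature index maps
#'
#' Fixed feature orderings shared by every subject. Within-hemisphere
#' features are the upper triangle in row-major order (i < j, ascending
#' parcel index), identical for both hemispheres so homologous connections
#' share a feature index. Transconnectome features are all heterotopic
#' LH x RH pairs in row-major order; homotopic (homologue) pairs are
#' excluded, so the full connectome has 2 P(P-1)/2 + (P^2 - P) features -
#' 64,440 at P = 180.
#'
#' @param atlas a \code{\link{ParcelAtlas}}.
#' @param kind \code{"HC-LH"}, \code{"HC-RH"}, \code{"TC"} or \code{"FC"}.
#' @return data.frame with global parcel indices \code{i}, \code{j} into the
#'   2P x 2P matrix and the originating \code{part}.
#' @export
featureIndexMap <- function(atlas, kind = c("HC-LH", "HC-RH", "TC", "FC")) {
  kind <- match.arg(kind)
  P <- atlas@parcelsPerHemi
  hcLocal <- cbind(rep(seq_len(P - 1L), times = (P - 1L):1L),
                   unlist(lapply(seq_len(P - 1L), function(i) (i + 1L):P)))
  hcMap <- function(offset, part)
    data.frame(i = hcLocal[, 1] + offset, j = hcLocal[, 2] + offset,
               part = part, stringsAsFactors = FALSE)
  tcMap <- function() {
    i <- rep(seq_len(P), each = P)              # LH parcel (global index)
    j <- rep(P + seq_len(P), times = P)         # RH parcel (global index)
    keep <- atlas@homologue[i] != j             # drop homotopic pairs
    data.frame(i = i[keep], j = j[keep], part = "TC", stringsAsFactors = FALSE)
  }
  switch(kind,
         "HC-LH" = hcMap(0L, "HC-LH"),
         "HC-RH" = hcMap(P, "HC-RH"),
         "TC" = tcMap(),
         "FC" = rbind(hcMap(0L, "HC-LH"), hcMap(P, "HC-RH"), tcMap()))
}

#' Extract a feature vector from a connectivity matrix
#'
#' Pulls one of the canonical feature sets out of a subject's 2P x 2P
#' Fisher-Z matrix under the fixed ordering of
#' \code{\link{featureIndexMap}}. At P = 180 the hemiconnectome has 16,110
#' features and the full connectome 64,440.
#'
#' @param conn 2P x 2P symmetric matrix (LH parcels first).
#' @param atlas a \code{\link{ParcelAtlas}}.
#' @param kind \code{"HC-LH"}, \code{"HC-RH"}, \code{"TC"} or \code{"FC"}.
#' @return a \code{\link{FeatureVectorSet}}.
#' @export
extractFeatures <- function(conn, atlas, kind = c("HC-LH", "HC-RH", "TC", "FC")) {
  kind <- match.arg(kind)
  P <- atlas@parcelsPerHemi
  if (!is.matrix(conn) || nrow(conn) != 2L * P || ncol(conn) != 2L * P)
    stop("connectivity matrix dimensions do not match the atlas (need ",
         2L * P, " x ", 2L * P, ")")
  map <- featureIndexMap(atlas, kind)
  new("FeatureVectorSet", kind = kind,
      values = conn[cbind(map$i, map$j)], indexMap = map)
}

#' Reassemble a feature vector into a matrix
#'
#' Inverse of \code{\link{extractFeatures}} on the covered entries: places
#' each feature value at its (i, j) and (j, i) positions of a 2P x 2P
#' matrix; uncovered entries are NA and the diagonal 0.
#'
#' @param fvs a \code{\link{FeatureVectorSet}} (or any numeric vector with a
#'   matching \code{map}).
#' @param atlas the atlas the features were extracted with.
#' @param values optional replacement values (e.g. a significance mask).
#' @return 2P x 2P matrix.
#' @export
reassembleMatrix <- function(fvs, atlas, values = NULL) {
  map <- fvs@indexMap
  v <- if (is.null(values)) fvs@values else values
  stopifnot(length(v) == nrow(map))
  n <- 2L * atlas@parcelsPerHemi
  M <- matrix(NA_real_, n, n)
  M[cbind(map$i, map$j)] <- v
  M[cbind(map$j, map$i)] <- v
  diag(M) <- 0
  M
}

#' Build a cohort-level feature set
#'
#' Runs the connectome stage for every subject of a cohort - Pearson
#' correlation, Fisher-Z, feature extraction - and assembles the results
#' into a \code{\link{HemiFeatureSet}}. For \code{kind = "HC"} each subject
#' contributes two samples (its LH and RH hemiconnectomes, homologous
#' connections aligned on the same feature index); for \code{"TC"} and
#' \code{"FC"} one sample per subject.
#'
#' @param cohort a \code{\link{SyntheticCohort}} (or a list with the same
#'   timeseries/metadata shape).
#' @param kind \code{"HC"}, \code{"TC"} or \code{"FC"}.
#' @param atlas defaults to the cohort's atlas.
#' @return a \code{\link{HemiFeatureSet}}.
#' @export
buildFeatureSet <- function(cohort, kind = c("HC", "TC", "FC"),
                            atlas = cohortAtlas(cohort)) {
  kind <- match.arg(kind)
  md <- cohortMetadata(cohort)
  n <- nrow(md)
  zs <- lapply(seq_len(n), function(i) {
    tsi <- subjectTimeseries(cohort, i)
    fisherZ(pearsonMatrix(tsi$LH, tsi$RH))
  })
  if (kind == "HC") {
    mapL <- featureIndexMap(atlas, "HC-LH")
    mapR <- featureIndexMap(atlas, "HC-RH")
    X <- matrix(NA_real_, nrow(mapL), 2L * n)
    for (i in seq_len(n)) {
      X[, 2L * i - 1L] <- zs[[i]][cbind(mapL$i, mapL$j)]
      X[, 2L * i] <- zs[[i]][cbind(mapR$i, mapR$j)]
    }
    cd <- S4Vectors::DataFrame(
      subjectId = rep(md$subjectId, each = 2L),
      hemisphere = rep(c("LH", "RH"), n),
      ehi = rep(md$ehi, each = 2L),
      handedness = rep(md$handedness, each = 2L))
    colnames(X) <- paste(cd$subjectId, cd$hemisphere, sep = ".")
    rd <- S4Vectors::DataFrame(iLocal = mapL$i, jLocal = mapL$j)
  } else {
    map <- featureIndexMap(atlas, kind)
    X <- vapply(zs, function(z) z[cbind(map$i, map$j)], numeric(nrow(map)))
    cd <- S4Vectors::DataFrame(
      subjectId = md$subjectId,
      hemisphere = NA_character_,
      ehi = md$ehi,
      handedness = md$handedness)
    colnames(X) <- md$subjectId
    rd <- S4Vectors::DataFrame(i = map$i, j = map$j, part = map$part)
  }
  rownames(cd) <- colnames(X)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = X), colData = cd, rowData = rd)
  new("HemiFeatureSet", se, kind = kind)
}
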