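#' @include AllClasses.R AllGenerics.R classify.R
NULL

#' Two-sided empirical (rank-proportion) p-value
#'
#' \code{p = min(1, 2 min(frac(null <= obs), frac(null >= obs)))}, floored
#' at \code{3/reps}: a simulated p of 0 only means the observation fell
#' outside all permutations, and the smallest resolvable simulated p scales
#' with 3 over the number of repetitions (.0003 at 10,000).
#'
#' @param observed scalar statistic.
#' @param null numeric vector of permutation replicates (>= 100).
#' @return empirical p in [3/reps, 1].
#' @export
empiricalPTwoSided <- function(observed, null) {
  reps <- length(null)
  if (reps < 1L) stop("empty null distribution")
  if (reps < 100L) stop("need at least 100 permutation replicates")
  p <- 2 * min(mean(null <= observed), mean(null >= observed))
  max(min(1, p), 3 / reps)
}

# vectorized two-sided empirical p: null is reps x nFeatures, obs length nFeatures
.empiricalPMatrix <- function(obs, null) {
  reps <- nrow(null)
  le <- colMeans(sweep(null, 2, obs, "<=") * 1)
  ge <- colMeans(sweep(null, 2, obs, ">=") * 1)
  pmax(pmin(1, 2 * pmin(le, ge)), 3 / reps)
}

# two-class LDA scaling, sign-aligned so the LH class mean score is negative
.ldaScaling <- function(X, y) {
  fit <- suppressWarnings(MASS::lda(X, grouping = factor(y)))
  s <- fit$scaling[, 1]
  mu <- fit$means %*% fit$scaling
  if (mu["LH", 1] > mu["RH", 1]) s <- -s
  s
}

#' Connection-level permutation significance
#'
#' Stage one of the enrichment procedure. The observed per-connection LDA
#' scalings come from a maximal model on all samples; the null distribution
#' refits the LDA on data whose hemisphere labels were shuffled within
#' subject pairs (each subject's LH/RH labels swapped with probability 1/2,
#' preserving the two-samples-per-subject structure). Each connection gets
#' a two-sided empirical p against its null scalings and is marked
#' significant below \code{alpha}.
#'
#' @param fs a hemiconnectome \code{\link{HemiFeatureSet}}.
#' @param reps permutation repetitions (10,000 at full scale; reduced-scale
#'   runs use 500-1,000).
#' @param alpha connection-level threshold (default .01). A warning is
#'   issued when \code{3/reps >= alpha} (floor not resolvable).
#' @param seed RNG seed.
#' @return list: observed (sign-aligned scalings), p, mask, reps.
#' @export
connectionSignificance <- function(fs, reps = 10000L, alpha = 0.01, seed = 1L) {
  stopifnot(is(fs, "HemiFeatureSet"), featureKind(fs) == "HC")
  if (3 / reps >= alpha)
    warning("3/reps >= alpha: permutation floor cannot resolve the threshold")
  cd <- SummarizedExperiment::colData(fs)
  X <- t(SummarizedExperiment::assay(fs, "z"))
  y <- as.character(cd$hemisphere)
  subj <- as.character(cd$subjectId)
  obs <- .ldaScaling(X, y)
  .setSeedIfGiven(seed)
  subjects <- unique(subj)
  null <- matrix(NA_real_, reps, ncol(X))
  for (r in seq_len(reps)) {
    flip <- subjects[stats::runif(length(subjects)) < 0.5]
    yr <- ifelse(subj %in% flip, ifelse(y == "LH", "RH", "LH"), y)
    fit <- suppressWarnings(MASS::lda(X, grouping = factor(yr, c("LH", "RH"))))
    null[r, ] <- fit$scaling[, 1]
  }
  p <- .empiricalPMatrix(obs, null)
  list(observed = obs, p = p, mask = p < alpha, reps = as.integer(reps))
}

#' Map hemiconnectome features to network groups
#'
#' Assigns every within-hemisphere connection between two kept-network
#' parcels to one unordered network-pair (or within-network) group; with k
#' kept networks there are k(k+1)/2 groups - 36 at k = 8. Connections
#' touching a dropped network are excluded (NA) and sit outside the
#' enrichment shuffle space.
#'
#' @param atlas a merged/symmetrized \code{\link{ParcelAtlas}}.
#' @return factor of length P(P-1)/2 with the full group level set.
#' @export
networkGroupMap <- function(atlas) {
  kept <- keptNetworks(atlas)
  map <- featureIndexMap(atlas, "HC-LH")
  netA <- atlas@networkSym[map$i]
  netB <- atlas@networkSym[map$j]
  exA <- atlas@excluded[map$i] | atlas@excluded[map$j]
  grp <- ifelse(exA, NA_character_,
                paste(pmin(netA, netB), pmax(netA, netB), sep = "-"))
  pairs <- outer(kept, kept, function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-"))
  levels <- sort(unique(pairs[upper.tri(pairs, diag = TRUE)]))
  factor(grp, levels = levels)
}

#' Network-pair enrichment of significant connections
#'
#' Stage two of the enrichment procedure: holds the number of significant
#' connections fixed and shuffles their positions uniformly over the grouped
#' upper-triangle features (mirrored back onto the symmetric matrix, which
#' the shuffle preserves by construction). Each group's one-sided empirical
#' p asks whether it holds more significant connections than such chance
#' placements, with the 3/reps floor.
#'
#' @param mask logical significance mask over hemiconnectome features.
#' @param groupMap from \code{\link{networkGroupMap}}.
#' @param reps shuffle repetitions.
#' @param seed RNG seed.
#' @return data.frame: group, size, count, p.
#' @export
groupEnrichment <- function(mask, groupMap, reps = 10000L, seed = 1L) {
  stopifnot(length(mask) == length(groupMap))
  grouped <- !is.na(groupMap)
  gInt <- as.integer(groupMap[grouped])
  G <- nlevels(groupMap)
  size <- tabulate(gInt, G)
  S <- sum(mask[grouped])
  obs <- tabulate(gInt[mask[grouped]], G)
  if (S == 0) {
    return(data.frame(group = levels(groupMap), size = size, count = obs,
                      p = rep(1, G), stringsAsFactors = FALSE))
  }
  .setSeedIfGiven(seed)
  M <- length(gInt)
  ge <- integer(G)
  for (r in seq_len(reps)) {
    cnt <- tabulate(gInt[sample.int(M, S)], G)
    ge <- ge + (cnt >= obs)
  }
  p <- pmax(ge / reps, 3 / reps)
  data.frame(group = levels(groupMap), size = size, count = obs, p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values over the enrichment groups (m = 36 under the
#' default 8 kept networks), monotone and capped at 1.
#'
#' @param p numeric p-values in (0, 1].
#' @return adjusted p-values.
#' @export
fdrCorrect <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Sign split of significant connections
#'
#' Partitions the significant connections by the sign of their aligned LDA
#' scaling. Under the sign convention (LD1 oriented so the LH class mean is
#' negative), negative scalings mark connections stronger in the LH,
#' positive ones connections stronger in the RH; the split is invariant to
#' a global LDA sign flip followed by re-alignment.
#'
#' @param observed sign-aligned scalings.
#' @param mask logical significance mask.
#' @return named integer: LHgtRH, RHgtLH.
#' @export
signSummary <- function(observed, mask) {
  stopifnot(length(observed) == length(mask))
  c(LHgtRH = sum(mask & observed < 0), RHgtLH = sum(mask & observed > 0))
}

#' Full two-stage network enrichment analysis
#'
#' Orchestrates both permutation stages plus FDR and the sign split:
#' connection-level significance of LDA scalings against
#' label-shuffled null models, then network-pair over-representation of the
#' significant connections against position-shuffled nulls, FDR-corrected
#' over the k(k+1)/2 groups.
#'
#' @param fs a hemiconnectome \code{\link{HemiFeatureSet}}.
#' @param atlas a merged \code{\link{ParcelAtlas}}.
#' @param reps connection-stage permutations (each one refits the LDA; this
#'   is the expensive stage and may be reduced at desk scale).
#' @param groupReps group-stage position shuffles. These cost no model
#'   refits, so they stay at the study's 10,000 by default even when
#'   \code{reps} is reduced; the group-level p floor (3/groupReps) then
#'   remains fine enough for FDR correction over 36 groups to resolve
#'   p < .05.
#' @param alpha connection-level threshold.
#' @param seed RNG seed.
#' @return an \code{\link{EnrichmentResult}}.
#' @export
networkEnrichment <- function(fs, atlas, reps = 10000L, groupReps = 10000L,
                              alpha = 0.01, seed = 1L) {
  cs <- connectionSignificance(fs, reps = reps, alpha = alpha,
                               seed = .deriveSeed(seed, "connection"))
  gm <- networkGroupMap(atlas)
  gt <- groupEnrichment(cs$mask, gm, reps = groupReps,
                        seed = .deriveSeed(seed, "group"))
  gt$pCor <- fdrCorrect(gt$p)
  new("EnrichmentResult",
      pConnection = cs$p, mask = cs$mask, observedScaling = cs$observed,
      groupTable = gt, signCounts = signSummary(cs$observed, cs$mask),
      reps = as.integer(reps), groupReps = as.integer(groupReps),
      alpha = alpha)
}

#' Map a significance mask back onto the parcel matrix
#'
#' Places hemiconnectome feature values (e.g. the significance mask) at
#' their (i, j) and (j, i) positions of the P x P within-hemisphere matrix;
#' the result is symmetric by construction.
#'
#' @param values numeric/logical vector over hemiconnectome features.
#' @param atlas the atlas defining the feature ordering.
#' @return P x P symmetric matrix (diagonal 0, no self-connections).
#' @export
maskToMatrix <- function(values, atlas) {
  map <- featureIndexMap(atlas, "HC-LH")
  P <- atlas@parcelsPerHemi
  M <- matrix(0, P, P)
  M[cbind(map$i, map$j)] <- as.numeric(values)
  M[cbind(map$j, map$i)] <- as.numeric(values)
  M
}
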