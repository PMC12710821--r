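#' @include AllClasses.R AllGenerics.R atlas.R
NULL

#' Default planted asymmetry map
#'
#' Plants LH-minus-RH connectivity offsets (correlation/Fisher-Z units) on
#' the language-default-mode and language-frontoparietal between-network
#' blocks and on within-default-mode connections; all other blocks are
#' symmetric. These are the three network groups the enrichment stage is
#' expected to recover.
#'
#' @param offset offset magnitude applied to each planted block.
#' @return data.frame with columns netA, netB, offset.
#' @export
defaultAsymmetryMap <- function(offset = 0.15) {
  data.frame(netA = c("LN", "LN", "DMN"),
             netB = c("DMN", "FPN", "DMN"),
             offset = offset,
             stringsAsFactors = FALSE)
}

#' Construct a cohort specification
#'
#' Bundles every generative choice of the synthetic cohort: size, parcel and
#' timepoint counts, per-network parcel counts, planted asymmetries, the
#' J-shaped EHI sampler and the piecewise-linear EHI-to-asymmetry link.
#' Defaults encode the study conditions the analysis is designed for: a
#' 90 percent dextral population, asymmetries concentrated in LN-DMN,
#' LN-FPN and within-DMN connections, and asymmetry growing with EHI up to
#' a breakpoint at EHI = 75 and flat above it.
#'
#' @param nSubjects cohort size.
#' @param parcelsPerHemi parcels per hemisphere (180 full scale; default 40
#'   for desk-scale work).
#' @param timepoints samples per scan.
#' @param networks named integer, parcels per network (one hemisphere).
#' @param asymmetryMap data.frame netA/netB/offset; empty for a null cohort.
#' @param handedness \code{"mixed"} (90 percent dextral), \code{"dextral"}
#'   or \code{"sinistral"} (single-handedness cohorts).
#' @param ehiModel list: dextralMass, dextralMean, dextralSD, sinistralMean,
#'   sinistralSD. The dextral component is a normal truncated to (0, 100],
#'   the sinistral/adextral component a broad normal truncated to [-100, 0].
#' @param distanceModel list: slopeBelow, breakpoint, slopeAbove, noiseSD
#'   (all in EHI units; the link is rescaled to [0, 1] over EHI in
#'   [-100, 100]).
#' @param baseWithin,baseBetween baseline within/between-network latent
#'   correlations.
#' @param seed master seed; every random stage derives from it.
#' @return a validated \code{\link{CohortSpec}}.
#' @export
#' @examples
#' cohortSpec(nSubjects = 20, parcelsPerHemi = 20, timepoints = 100)
cohortSpec <- function(nSubjects = 200L,
                       parcelsPerHemi = 40L,
                       timepoints = 300L,
                       networks = defaultNetworkCounts(parcelsPerHemi),
                       asymmetryMap = defaultAsymmetryMap(),
                       handedness = c("mixed", "dextral", "sinistral"),
                       ehiModel = list(dextralMass = 0.90, dextralMean = 80,
                                       dextralSD = 15, sinistralMean = -30,
                                       sinistralSD = 45),
                       distanceModel = list(slopeBelow = 0.01, breakpoint = 75,
                                            slopeAbove = 0, noiseSD = 2),
                       baseWithin = 0.35, baseBetween = 0.10,
                       seed = 1L) {
  handedness <- match.arg(handedness)
  if (handedness == "dextral") ehiModel$dextralMass <- 1
  if (handedness == "sinistral") ehiModel$dextralMass <- 0
  new("CohortSpec",
      nSubjects = as.integer(nSubjects),
      parcelsPerHemi = as.integer(parcelsPerHemi),
      timepoints = as.integer(timepoints),
      networks = structure(as.integer(networks), names = names(networks)),
      asymmetryMap = asymmetryMap,
      ehiModel = ehiModel,
      distanceModel = distanceModel,
      baseWithin = baseWithin,
      baseBetween = baseBetween,
      seed = as.integer(seed))
}

#' Sample Edinburgh Handedness Inventory scores
#'
#' Two-component truncated-normal mixture reproducing the J-shaped
#' population distribution: with probability \code{dextralMass} a score from
#' the dextral component (concentrated near +80, truncated to (0, 100]),
#' otherwise from a broad sinistral/adextral component truncated to
#' [-100, 0]. The expected fraction of scores above 0 therefore equals the
#' dextral mass exactly.
#'
#' @param n number of scores.
#' @param ehiModel mixture parameters, see \code{\link{cohortSpec}}.
#' @param seed optional; when NULL the current RNG stream is used.
#' @return numeric vector of n scores in [-100, 100].
#' @export
sampleEHI <- function(n, ehiModel = cohortSpec()@ehiModel, seed = NULL) {
  stopifnot(.isCount(n))
  m <- ehiModel$dextralMass
  if (!is.numeric(m) || m < 0 || m > 1)
    stop("dextral mass fraction must lie in [0, 1]")
  .setSeedIfGiven(seed)
  dex <- stats::runif(n) < m
  out <- numeric(n)
  if (any(dex))
    out[dex] <- .rtruncnorm(sum(dex), ehiModel$dextralMean, ehiModel$dextralSD,
                            lower = 1e-9, upper = 100)
  if (any(!dex))
    out[!dex] <- .rtruncnorm(sum(!dex), ehiModel$sinistralMean,
                             ehiModel$sinistralSD, lower = -100, upper = 0)
  out
}

#' Piecewise-linear asymmetry scale
#'
#' Maps an EHI score to the relative magnitude of the planted asymmetry:
#' slope \code{slopeBelow} per EHI unit up to the breakpoint,
#' \code{slopeAbove} beyond it, rescaled so the scale spans [0, 1] over EHI
#' in [-100, 100]. Under the defaults, asymmetry grows linearly with EHI up
#' to EHI = 75 and is flat above - more sinistral subjects get more similar
#' hemispheres.
#'
#' @param ehi numeric score(s) in [-100, 100].
#' @param distanceModel see \code{\link{cohortSpec}}.
#' @return numeric in [0, 1].
#' @export
asymmetryScale <- function(ehi, distanceModel = cohortSpec()@distanceModel) {
  dm <- distanceModel
  raw <- function(e) dm$slopeBelow * pmin(e, dm$breakpoint) +
    dm$slopeAbove * pmax(e - dm$breakpoint, 0)
  lo <- raw(-100); hi <- raw(100)
  if (hi - lo <= 0) return(rep(1, length(ehi)))
  .clamp((raw(ehi) - lo) / (hi - lo), 0, 1)
}

# Network factor-correlation matrix of the low-rank block model. Entries are
# (baseBetween + planted offset x scale) normalized by the within-network
# loadings; positive definiteness of the hemisphere covariance reduces to
# positive semidefiniteness of this K x K matrix, which is checked here.
.networkPhi <- function(spec, scale, hemi) {
  labs <- names(spec@networks)
  K <- length(labs)
  off <- matrix(0, K, K, dimnames = list(labs, labs))
  if (hemi == "LH" && nrow(spec@asymmetryMap) > 0) {
    for (r in seq_len(nrow(spec@asymmetryMap))) {
      a <- spec@asymmetryMap$netA[r]; b <- spec@asymmetryMap$netB[r]
      d <- spec@asymmetryMap$offset[r] * scale
      off[a, b] <- off[a, b] + d
      if (a != b) off[b, a] <- off[b, a] + d
    }
  }
  w <- spec@baseWithin + diag(off)          # per-network within correlation
  if (any(w <= 0 | w >= 1))
    stop("planted within-network offsets push correlations outside (0, 1)")
  btw <- spec@baseBetween + off
  diag(btw) <- w
  if (any(abs(btw) >= 1))
    stop("planted offsets push correlations outside (-1, 1)")
  phi <- btw / sqrt(outer(w, w))
  diag(phi) <- 1
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("planted offsets make the network factor structure non-PSD; ",
         "reduce offsets or raise baseWithin")
  list(phi = phi, w = w)
}

# Correlation matrix of one hemisphere at a given asymmetry scale:
# C = Lambda Phi Lambda' + Psi with loadings sqrt(w_k) on network factors
# and Psi = diag(1 - w_k), so C is positive definite by construction.
.buildCov <- function(spec, scale, hemi) {
  np <- .networkPhi(spec, scale, hemi)
  labs <- names(spec@networks)
  netIdx <- rep(seq_along(labs), spec@networks)
  lam <- sqrt(np$w)[netIdx]
  C <- outer(lam, lam) * np$phi[netIdx, netIdx]
  diag(C) <- 1
  C
}

#' Build the latent correlation matrix of one hemisphere
#'
#' Block-structured correlation matrix: \code{baseWithin} within networks,
#' \code{baseBetween} between, with the planted offsets of the asymmetry
#' map applied (LH only) scaled by \code{\link{asymmetryScale}(ehi)}. Built
#' as a network-factor model (loadings plus diagonal), so the result is
#' symmetric positive definite with unit diagonal whenever the offsets pass
#' the spec's validity check; offsets that break that structure raise an
#' error rather than returning a non-PD matrix.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @param ehi the subject's EHI score.
#' @param hemi \code{"LH"} or \code{"RH"}; offsets apply to LH only.
#' @return P x P correlation matrix.
#' @export
buildHemisphereCovariance <- function(spec, ehi, hemi = c("LH", "RH")) {
  hemi <- match.arg(hemi)
  validObject(spec)
  s <- if (hemi == "LH") asymmetryScale(ehi, spec@distanceModel) else 0
  .buildCov(spec, s, hemi)
}

#' Simulate parcel timeseries from a covariance
#'
#' Draws \code{timepoints} i.i.d. multivariate-normal samples with the given
#' covariance (Cholesky factorization), returned as a parcels x time matrix
#' with zero expected row means. The sample correlation of the output
#' converges to \code{cov} as the number of timepoints grows.
#'
#' @param cov symmetric positive-definite matrix.
#' @param timepoints number of samples; fewer than \code{nrow(cov) + 2}
#'   triggers a rank-deficiency warning.
#' @param seed optional; when NULL the current RNG stream is used.
#' @return parcels x time numeric matrix.
#' @export
simulateTimeseries <- function(cov, timepoints, seed = NULL) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov), .isCount(timepoints))
  if (max(abs(cov - t(cov))) > 1e-10) stop("cov must be symmetric")
  P <- nrow(cov)
  if (timepoints < P + 2)
    warning("timepoints < parcels + 2: sample correlation will be rank deficient")
  .setSeedIfGiven(seed)
  R <- chol(cov)   # fails informatively if cov is not PD
  crossprod(R, matrix(stats::rnorm(P * timepoints), P, timepoints))
}

#' Generate a synthetic cohort
#'
#' Samples EHI scores, realizes each subject's asymmetry scale through the
#' piecewise-linear link (with EHI-space jitter of SD
#' \code{distanceModel$noiseSD}), builds the LH (offset) and RH (symmetric)
#' latent correlation matrices, and simulates per-hemisphere parcel
#' timeseries. Identical specs (including seed) give byte-identical output.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @return a \code{\link{SyntheticCohort}}.
#' @export
#' @examples
#' co <- generateCohort(cohortSpec(nSubjects = 4, parcelsPerHemi = 20,
#'                                 timepoints = 60))
#' cohortMetadata(co)
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nSubjects
  set.seed(spec@seed)
  ehi <- sampleEHI(n, spec@ehiModel)
  effEhi <- .clamp(ehi + stats::rnorm(n, 0, spec@distanceModel$noiseSD), -100, 100)
  scl <- asymmetryScale(effEhi, spec@distanceModel)
  covRH <- .buildCov(spec, 0, "RH")
  ts <- vector("list", n)
  for (i in seq_len(n)) {
    covLH <- .buildCov(spec, scl[i], "LH")
    ts[[i]] <- list(LH = simulateTimeseries(covLH, spec@timepoints),
                    RH = simulateTimeseries(covRH, spec@timepoints))
  }
  md <- data.frame(
    subjectId = sprintf("S%04d", seq_len(n)),
    ehi = ehi,
    handedness = ifelse(ehi > 0, "dextral", "sinistral"),
    asymmetryScale = scl,
    stringsAsFactors = FALSE)
  names(ts) <- md$subjectId
  new("SyntheticCohort", spec = spec, metadata = md, timeseries = ts,
      atlas = makeAtlas(spec@networks))
}
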