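#' @include AllClasses.R AllGenerics.R
NULL

# Per-hemisphere parcel counts of the 12-network partition used as the
# default template (LH counts of the Cole-Anticevic assignment of the
# 360-parcel Glasser atlas; the two visual networks are kept separate here
# and merged by mergeAndDropNetworks()).
.templateCounts <- c(
  AudN = 8L, CON = 27L, DMN = 40L, DAN = 12L, FPN = 22L, LN = 14L,
  OAN = 3L, PMN = 3L, SMN = 19L, VMN = 2L, VisN = 3L, Visual2 = 27L
)

# networks merged / dropped by default: 12 raw labels -> 8 kept
.defaultMergeRules <- list(Visual = c("VisN", "Visual2"))
.defaultDropRules <- c("OAN", "PMN", "VMN")

#' Default per-network parcel counts for a reduced-scale atlas
#'
#' Scales the 12-network template (180 parcels per hemisphere) down to
#' \code{P} parcels per hemisphere by largest-remainder apportionment,
#' guaranteeing at least one parcel per network so the merge/drop rules stay
#' exercisable at desk scale. At \code{P = 180} the template counts are
#' returned unchanged.
#'
#' @param P parcels per hemisphere.
#' @return named integer vector summing to \code{P}.
#' @export
#' @examples
#' sum(defaultNetworkCounts(40)) == 40
defaultNetworkCounts <- function(P = 180L) {
  stopifnot(.isCount(P), P >= length(.templateCounts))
  tpl <- .templateCounts
  if (P == sum(tpl)) return(tpl)
  quota <- P * tpl / sum(tpl)
  counts <- structure(pmax(1L, as.integer(floor(quota))), names = names(tpl))
  while (sum(counts) < P) {
    frac <- quota - counts
    k <- which.max(frac)
    counts[k] <- counts[k] + 1L
  }
  while (sum(counts) > P) {
    over <- which(counts > 1L)
    k <- over[which.min((quota - counts)[over])]
    counts[k] <- counts[k] - 1L
  }
  counts
}

#' Construct a parcel atlas
#'
#' \code{parcelAtlas} builds an atlas from explicit per-parcel network labels;
#' \code{makeAtlas} is the convenience constructor used by the synthetic
#' cohort generator: it expands named per-network counts into labels,
#' symmetrizes them, and applies the default merge/drop rules.
#'
#' @param networksLH character, network label per LH parcel (length P).
#' @param networksRH character, RH labels; defaults to the LH labels
#'   (concordant atlas).
#' @param parcelId optional character of length 2P.
#' @return a \code{\link{ParcelAtlas}}; \code{parcelAtlas} leaves
#'   \code{networkSym} unset.
#' @export
parcelAtlas <- function(networksLH, networksRH = networksLH, parcelId = NULL) {
  P <- length(networksLH)
  stopifnot(P >= 1L, length(networksRH) == P)
  if (is.null(parcelId))
    parcelId <- c(sprintf("L%03d", seq_len(P)), sprintf("R%03d", seq_len(P)))
  new("ParcelAtlas",
      parcelsPerHemi = as.integer(P),
      parcelId = parcelId,
      hemisphere = rep(c("LH", "RH"), each = P),
      homologue = as.integer(c(P + seq_len(P), seq_len(P))),
      networkRaw = c(networksLH, networksRH),
      networkSym = rep(NA_character_, 2L * P),
      excluded = rep(FALSE, 2L * P))
}

#' @rdname parcelAtlas
#' @param counts named integer, parcels per network for one hemisphere.
#' @export
makeAtlas <- function(counts = defaultNetworkCounts(180L)) {
  labels <- rep(names(counts), counts)
  at <- symmetrizeNetworks(parcelAtlas(labels))
  mergeAndDropNetworks(at, .defaultMergeRules, .defaultDropRules)
}

#' Symmetrize network labels across homologue pairs
#'
#' When the two members of a homologue pair carry different raw network
#' labels, the LH member's label is adopted for the pair. The number of
#' discordant pairs is afterwards available via
#' \code{\link{discordantPairs}}.
#'
#' @param atlas a \code{\link{ParcelAtlas}}.
#' @return the atlas with \code{networkSym} filled in.
#' @export
symmetrizeNetworks <- function(atlas) {
  stopifnot(is(atlas, "ParcelAtlas"))
  sym <- atlas@networkRaw
  lh <- which(atlas@hemisphere == "LH")
  sym[atlas@homologue[lh]] <- sym[lh]
  atlas@networkSym <- sym
  validObject(atlas)
  atlas
}

#' Merge and drop networks
#'
#' Applies merge rules (a named list: new label -> labels it replaces) and
#' drop rules (labels whose parcels are flagged excluded) to the symmetrized
#' network labels. Excluded parcels stay in all feature vectors; exclusion
#' only removes them from enrichment grouping. The default rules merge the
#' two visual networks and drop the three smallest networks, yielding 8 kept
#' networks and hence 36 enrichment groups.
#'
#' @param atlas a symmetrized \code{\link{ParcelAtlas}}.
#' @param mergeRules named list of character vectors.
#' @param dropRules character of labels to exclude.
#' @return the updated atlas.
#' @seealso \code{\link{keptNetworks}}
#' @export
mergeAndDropNetworks <- function(atlas, mergeRules = .defaultMergeRules,
                                 dropRules = .defaultDropRules) {
  stopifnot(is(atlas, "ParcelAtlas"))
  if (anyNA(atlas@networkSym)) atlas <- symmetrizeNetworks(atlas)
  sym <- atlas@networkSym
  known <- unique(sym)
  for (newLab in names(mergeRules)) {
    old <- mergeRules[[newLab]]
    if (!all(old %in% known))
      stop("merge rule references unknown network label(s): ",
           paste(setdiff(old, known), collapse = ", "))
    sym[sym %in% old] <- newLab
  }
  if (length(dropRules) && !all(dropRules %in% sym))
    stop("drop rule references unknown network label(s): ",
         paste(setdiff(dropRules, sym), collapse = ", "))
  atlas@networkSym <- sym
  atlas@excluded <- sym %in% dropRules
  validObject(atlas)
  atlas
}

#' Read or write a parcel table
#'
#' Plain-TSV interchange format with columns \code{parcel_id},
#' \code{hemisphere}, \code{homologue_id}, \code{network} (and, when
#' present, \code{network_sym} and \code{excluded}).
#'
#' @param path TSV file path.
#' @param atlas a \code{\link{ParcelAtlas}}.
#' @return \code{readParcelTable} returns a \code{ParcelAtlas}.
#' @export
readParcelTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("parcel_id", "hemisphere", "homologue_id", "network")
  if (!all(need %in% names(df)))
    stop("parcel table must have columns: ", paste(need, collapse = ", "))
  at <- new("ParcelAtlas",
            parcelsPerHemi = as.integer(sum(df$hemisphere == "LH")),
            parcelId = df$parcel_id,
            hemisphere = df$hemisphere,
            homologue = match(df$homologue_id, df$parcel_id),
            networkRaw = df$network,
            networkSym = if ("network_sym" %in% names(df)) df$network_sym
                         else rep(NA_character_, nrow(df)),
            excluded = if ("excluded" %in% names(df)) as.logical(df$excluded)
                       else rep(FALSE, nrow(df)))
  validObject(at)
  at
}

#' @rdname readParcelTable
#' @export
writeParcelTable <- function(atlas, path) {
  df <- data.frame(
    parcel_id = atlas@parcelId,
    hemisphere = atlas@hemisphere,
    homologue_id = atlas@parcelId[atlas@homologue],
    network = atlas@networkRaw,
    network_sym = atlas@networkSym,
    excluded = atlas@excluded,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
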