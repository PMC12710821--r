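#' @include AllClasses.R AllGenerics.R synthetic.R
NULL

#' Write a synthetic cohort to plain-text files
#'
#' Writes \code{subjects.tsv} (subject_id, ehi, handedness), one
#' parcels x time TSV per subject per hemisphere
#' (\code{<subject>_<hemi>.tsv}), \code{parcels.tsv} (the atlas) and
#' \code{cohort_spec.yaml} (full generative provenance including the seed).
#'
#' @param cohort a \code{\link{SyntheticCohort}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- cohortMetadata(cohort)
  utils::write.table(
    data.frame(subject_id = md$subjectId, ehi = md$ehi,
               handedness = md$handedness),
    file.path(dir, "subjects.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (i in seq_len(nrow(md))) {
    tsi <- subjectTimeseries(cohort, i)
    for (h in c("LH", "RH"))
      utils::write.table(tsi[[h]],
                         file.path(dir, sprintf("%s_%s.tsv", md$subjectId[i], h)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
  }
  writeParcelTable(cohortAtlas(cohort), file.path(dir, "parcels.tsv"))
  yaml::write_yaml(specAsList(cohort@spec), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' @rdname writeCohort
#' @param spec a \code{\link{CohortSpec}}.
#' @export
specAsList <- function(spec) {
  list(nSubjects = spec@nSubjects,
       parcelsPerHemi = spec@parcelsPerHemi,
       timepoints = spec@timepoints,
       networks = as.list(structure(as.integer(spec@networks),
                                    names = names(spec@networks))),
       asymmetryMap = if (nrow(spec@asymmetryMap)) unname(
         lapply(seq_len(nrow(spec@asymmetryMap)), function(r)
           as.list(spec@asymmetryMap[r, ]))) else list(),
       ehiModel = spec@ehiModel,
       distanceModel = spec@distanceModel,
       baseWithin = spec@baseWithin,
       baseBetween = spec@baseBetween,
       seed = spec@seed)
}

#' @rdname writeCohort
#' @param x a list as produced by \code{specAsList} (e.g. read from YAML).
#' @export
specFromList <- function(x) {
  am <- if (length(x$asymmetryMap))
    do.call(rbind, lapply(x$asymmetryMap, as.data.frame))
  else data.frame(netA = character(), netB = character(), offset = numeric())
  cohortSpec(nSubjects = x$nSubjects, parcelsPerHemi = x$parcelsPerHemi,
             timepoints = x$timepoints, networks = unlist(x$networks),
             asymmetryMap = am, ehiModel = x$ehiModel,
             distanceModel = x$distanceModel, baseWithin = x$baseWithin,
             baseBetween = x$baseBetween, seed = x$seed)
}

#' Read a cohort written by \code{writeCohort}
#'
#' @param dir directory produced by \code{\link{writeCohort}}.
#' @return a \code{\link{SyntheticCohort}}.
#' @export
readCohort <- function(dir) {
  spec <- specFromList(yaml::read_yaml(file.path(dir, "cohort_spec.yaml")))
  md <- utils::read.delim(file.path(dir, "subjects.tsv"),
                          stringsAsFactors = FALSE)
  ts <- lapply(md$subject_id, function(sid) {
    list(LH = readTimeseriesTSV(file.path(dir, paste0(sid, "_LH.tsv"))),
         RH = readTimeseriesTSV(file.path(dir, paste0(sid, "_RH.tsv"))))
  })
  names(ts) <- md$subject_id
  meta <- data.frame(subjectId = md$subject_id, ehi = md$ehi,
                     handedness = md$handedness,
                     asymmetryScale = NA_real_, stringsAsFactors = FALSE)
  new("SyntheticCohort", spec = spec, metadata = meta, timeseries = ts,
      atlas = readParcelTable(file.path(dir, "parcels.tsv")))
}

#' Read a parcels x time timeseries TSV
#'
#' @param path TSV file (no header, one row per parcel).
#' @return numeric matrix.
#' @export
readTimeseriesTSV <- function(path) {
  as.matrix(utils::read.delim(path, header = FALSE))
}

#' Write a cohort feature set to TSV with a JSON index-map sidecar
#'
#' The TSV holds samples as columns and features as rows; the sidecar JSON
#' records the feature kind and the feature-to-parcel-pair index map.
#'
#' @param fs a \code{\link{HemiFeatureSet}}.
#' @param path output TSV path; the sidecar is \code{<path>.map.json}.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(fs, path) {
  X <- SummarizedExperiment::assay(fs, "z")
  utils::write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(kind = featureKind(fs),
               samples = colnames(X),
               indexMap = as.data.frame(SummarizedExperiment::rowData(fs)))
  jsonlite::write_json(side, paste0(path, ".map.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
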