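#' @importFrom BiocGenerics counts strand
NULL

#' @rdname EndCountTrack-class
#' @param x,object an object from this package.
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname NmScoreTrack-class
#' @export
setGeneric("nmScores", function(x) standardGeneric("nmScores"))

#' @rdname QpcrPlate-class
#' @export
setGeneric("plateRecords", function(x) standardGeneric("plateRecords"))

#' @rdname SpliceEventTable-class
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))

#' @rdname PatientPairTable-class
#' @export
setGeneric("pairRecords", function(x) standardGeneric("pairRecords"))

#' @rdname ProbeExpressionExperiment-class
#' @export
setGeneric("probeClasses", function(x) standardGeneric("probeClasses"))

#' @rdname ProbeExpressionExperiment-class
#' @export
setGeneric("siteCategories", function(x) standardGeneric("siteCategories"))

#' @rdname ProbeExpressionExperiment-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("truthComponent", function(x) standardGeneric("truthComponent"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("truthParameters", function(x) standardGeneric("truthParameters"))

## -- accessors ---------------------------------------------------------------

#' @rdname ProbeExpressionExperiment-class
#' @export
setMethod("probeClasses", "ProbeExpressionExperiment", function(x)
  stats::setNames(rowData(x)$probe_class, rownames(x)))

#' @rdname ProbeExpressionExperiment-class
#' @export
setMethod("siteCategories", "ProbeExpressionExperiment", function(x)
  stats::setNames(colData(x)$site_category, colnames(x)))

#' @rdname ProbeExpressionExperiment-class
#' @export
setMethod("sampleGroups", "ProbeExpressionExperiment", function(x)
  stats::setNames(colData(x)$group_id, colnames(x)))

#' @rdname EndCountTrack-class
#' @export
setMethod("transcriptId", "EndCountTrack", function(x) x@transcript)

#' @rdname NmScoreTrack-class
#' @export
setMethod("transcriptId", "NmScoreTrack", function(x) x@transcript)

#' @rdname EndCountTrack-class
#' @export
setMethod("counts", "EndCountTrack", function(object, ...) object@counts)

#' @rdname NmScoreTrack-class
#' @export
setMethod("counts", "NmScoreTrack", function(object, ...) object@counts)

#' @rdname EndCountTrack-class
#' @export
setMethod("strand", "EndCountTrack", function(x, ...) x@strand)

#' @rdname EndCountTrack-class
#' @export
setMethod("length", "EndCountTrack", function(x) length(x@counts))

#' @rdname NmScoreTrack-class
#' @export
setMethod("nmScores", "NmScoreTrack", function(x) x@scores)

#' @rdname QpcrPlate-class
#' @export
setMethod("plateRecords", "QpcrPlate", function(x) x@records)

#' @rdname SpliceEventTable-class
#' @export
setMethod("eventCounts", "SpliceEventTable", function(x) x@events)

#' @rdname PatientPairTable-class
#' @export
setMethod("pairRecords", "PatientPairTable", function(x) x@records)

#' @rdname PlantedTruth-class
#' @export
setMethod("truthComponent", "PlantedTruth", function(x) x@component)

#' @rdname PlantedTruth-class
#' @export
setMethod("truthParameters", "PlantedTruth", function(x) x@parameters)

## -- show --------------------------------------------------------------------

setMethod("show", "ProbeExpressionExperiment", function(object) {
  cat("ProbeExpressionExperiment:", nrow(object), "probes x",
      ncol(object), "samples\n")
  cat("  site categories:",
      paste(sprintf("%s(%d)", names(table(colData(object)$site_category)),
                    table(colData(object)$site_category)), collapse = " "), "\n")
  cat("  snoRNA probes:", sum(rowData(object)$probe_class == "snoRNA"),
      "of", nrow(object), "\n")
})

setMethod("show", "EndCountTrack", function(object) {
  cat("EndCountTrack on", object@transcript, paste0("(", object@strand, ")"),
      "length", length(object@counts), "nt;",
      sum(object@counts), "read 3' ends\n")
})

setMethod("show", "NmScoreTrack", function(object) {
  cat("NmScoreTrack on", object@transcript, "-",
      length(object@scores), "interior positions; max score",
      format(max(object@scores), digits = 3), "\n")
})

setMethod("show", "QpcrPlate", function(object) {
  r <- object@records
  cat("QpcrPlate:", nrow(r), "Ct records,",
      length(unique(r$sample)), "samples,",
      length(unique(r$target)), "targets\n")
})

setMethod("show", "SpliceEventTable", function(object) {
  e <- object@events
  cat("SpliceEventTable:", length(unique(e$event_id)), "events,",
      length(unique(e$group)), "groups,", nrow(e), "count rows\n")
})

setMethod("show", "PatientPairTable", function(object) {
  r <- object@records
  complete <- sum(table(r$patient_id) == 2L)
  cat("PatientPairTable:", length(unique(r$patient_id)), "patients (",
      complete, "complete pairs ),",
      length(grep("^psi_", names(r))), "event(s)\n")
})

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth [", object@component, "]:",
      paste(names(object@parameters), collapse = ", "), "\n")
})
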