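#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.SITE_CATEGORIES <- c("baseline", "MFP", "AxLN", "AxLN-LuM")
.PROBE_CLASSES <- c("snoRNA", "other")

#' Probe-by-sample expression container for multi-site tumour microarrays
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one linear-scale
#' intensity assay (`"exprs"`), per-sample annotation (`group_id`,
#' `site_category`, one of `baseline`, `MFP`, `AxLN`, `AxLN-LuM`) and a
#' per-probe `probe_class` (`snoRNA` or `other`). Validity requires complete,
#' non-negative intensities, exactly one group per sample, and at least one
#' baseline sample.
#'
#' @export
setClass("ProbeExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ProbeExpressionExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- assay(object, "exprs")
    if (anyNA(v)) msg <- c(msg, "intensities must not contain missing values")
    else if (any(v < 0)) msg <- c(msg, "intensities must be non-negative")
  }
  cd <- colData(object)
  if (!all(c("group_id", "site_category") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'group_id' and 'site_category'")
  else {
    if (anyNA(cd$group_id)) msg <- c(msg, "every sample must have a group_id")
    bad <- setdiff(unique(cd$site_category), .SITE_CATEGORIES)
    if (length(bad))
      msg <- c(msg, paste0("unknown site_category: ", paste(bad, collapse = ", ")))
    if (!any(cd$site_category == "baseline"))
      msg <- c(msg, "at least one baseline sample is required")
  }
  rd <- rowData(object)
  if (!"probe_class" %in% colnames(rd))
    msg <- c(msg, "rowData must carry 'probe_class'")
  else if (length(setdiff(unique(rd$probe_class), .PROBE_CLASSES)))
    msg <- c(msg, "probe_class must be 'snoRNA' or 'other'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProbeExpressionExperiment-class Constructor.
#'
#' @param exprs numeric matrix of linear-scale intensities, probes in rows
#'   (rownames = probe ids) and samples in columns (colnames = sample ids).
#' @param groupId character vector, one replicate-group id per sample.
#' @param siteCategory character vector per sample; one of `"baseline"`,
#'   `"MFP"`, `"AxLN"`, `"AxLN-LuM"`.
#' @param probeClass character vector per probe; `"snoRNA"` or `"other"`.
#' @return A `ProbeExpressionExperiment`.
#' @examples
#' m <- matrix(100, 2, 3, dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' ProbeExpressionExperiment(m, c("b1", "b1", "ax1"),
#'                           c("baseline", "baseline", "AxLN"),
#'                           c("snoRNA", "other"))
#' @export
ProbeExpressionExperiment <- function(exprs, groupId, siteCategory, probeClass) {
  exprs <- as.matrix(exprs)
  se <- SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = DataFrame(group_id = as.character(groupId),
                        site_category = as.character(siteCategory),
                        row.names = colnames(exprs)),
    rowData = DataFrame(probe_class = as.character(probeClass),
                        row.names = rownames(exprs)))
  as(se, "ProbeExpressionExperiment")
}

#' Per-position read 3'-end counts over one transcript strand
#'
#' Holds the 1-based vector of alignment 3'-end counts over a single
#' reference transcript, as produced from RibOxi-seq style BED alignments.
#'
#' @slot transcript transcript identifier.
#' @slot strand `"+"` or `"-"`.
#' @slot counts non-negative integer vector, one element per nucleotide.
#' @export
setClass("EndCountTrack",
         representation(transcript = "character", strand = "character",
                        counts = "integer"),
         validity = function(object) {
           msg <- character()
           if (length(object@transcript) != 1L)
             msg <- c(msg, "transcript must be a single id")
           if (!object@strand %in% c("+", "-"))
             msg <- c(msg, "strand must be '+' or '-'")
           if (length(object@counts) < 1L)
             msg <- c(msg, "counts must be non-empty")
           if (anyNA(object@counts) || any(object@counts < 0L))
             msg <- c(msg, "counts must be non-negative integers")
           if (length(msg)) msg else TRUE
         })

#' @describeIn EndCountTrack-class Constructor.
#' @param transcript transcript id.
#' @param counts integer vector of per-position 3'-end counts (1-based).
#' @param strand alignment strand, `"+"` (default) or `"-"`.
#' @return An `EndCountTrack`.
#' @export
EndCountTrack <- function(transcript, counts, strand = "+") {
  new("EndCountTrack", transcript = as.character(transcript),
      strand = strand, counts = as.integer(counts))
}

#' Neighbour-normalised Nm-score track
#'
#' Per-position Nm scores (count at n over the mean of counts at n-1 and n+1,
#' zeros replaced by 1 before the ratio) at interior positions 2..length-1,
#' with the raw counts carried alongside.
#'
#' @slot transcript transcript identifier.
#' @slot scores numeric vector named by interior position.
#' @slot counts raw (unsubstituted) counts over the full transcript.
#' @export
setClass("NmScoreTrack",
         representation(transcript = "character", scores = "numeric",
                        counts = "integer"),
         validity = function(object) {
           msg <- character()
           if (length(object@counts) < 3L)
             msg <- c(msg, "a track of length >= 3 is required")
           if (length(object@scores) != length(object@counts) - 2L)
             msg <- c(msg, "scores must cover positions 2..length-1")
           if (any(!is.finite(object@scores)) || any(object@scores <= 0))
             msg <- c(msg, "scores must be finite and > 0")
           if (length(msg)) msg else TRUE
         })

#' qPCR plate of Ct replicate sets
#'
#' Long-format Ct records keyed by sample, target role (assay target or
#' reference gene) and RNase-H treatment status. `ct` is one cycle-threshold
#' value per row (replicates are repeated rows); `NA` marks an undetermined
#' (no-amplification) reaction.
#'
#' @slot records data.frame with columns `sample`, `target`, `role`
#'   (`"target"`/`"reference"`), `rnaseh` (`"plus"`/`"minus"`/`"na"`), `ct`.
#' @export
setClass("QpcrPlate", representation(records = "data.frame"),
         validity = function(object) {
           msg <- character()
           need <- c("sample", "target", "role", "rnaseh", "ct")
           if (!all(need %in% names(object@records)))
             return(paste("records need columns:", paste(need, collapse = ", ")))
           r <- object@records
           if (!all(r$role %in% c("target", "reference")))
             msg <- c(msg, "role must be 'target' or 'reference'")
           if (!all(r$rnaseh %in% c("plus", "minus", "na")))
             msg <- c(msg, "rnaseh must be 'plus', 'minus' or 'na'")
           ok <- is.na(r$ct) | (is.finite(r$ct) & r$ct > 0)
           if (!all(ok))
             msg <- c(msg, "ct must be finite and > 0, or NA (undetermined)")
           if (length(msg)) msg else TRUE
         })

#' @describeIn QpcrPlate-class Constructor.
#' @param records data.frame of Ct records (see slots).
#' @return A `QpcrPlate`.
#' @export
QpcrPlate <- function(records) new("QpcrPlate", records = as.data.frame(records))

#' Per-event, per-replicate splice junction counts
#'
#' Long-format inclusion/skipping junction counts for alternative splicing
#' events, as produced by junction-count tools. One row per event, group and
#' replicate; effective lengths default to 1.
#'
#' @slot events data.frame with columns `event_id`, `gene_id`, `event_type`
#'   (`CE`, `RI`, `A3SS`, `A5SS`, `MXE`), `group`, `replicate`, `inclusion`,
#'   `skipping`, `len_inc`, `len_skip`.
#' @export
setClass("SpliceEventTable", representation(events = "data.frame"),
         validity = function(object) {
           need <- c("event_id", "gene_id", "event_type", "group", "replicate",
                     "inclusion", "skipping", "len_inc", "len_skip")
           if (!all(need %in% names(object@events)))
             return(paste("events need columns:", paste(need, collapse = ", ")))
           e <- object@events
           msg <- character()
           if (!all(e$event_type %in% c("CE", "RI", "A3SS", "A5SS", "MXE")))
             msg <- c(msg, "event_type must be one of CE, RI, A3SS, A5SS, MXE")
           if (any(e$inclusion < 0) || any(e$skipping < 0) ||
               any(e$inclusion != round(e$inclusion)) ||
               any(e$skipping != round(e$skipping)))
             msg <- c(msg, "counts must be non-negative integers")
           if (any(e$len_inc <= 0) || any(e$len_skip <= 0))
             msg <- c(msg, "effective lengths must be > 0")
           if (length(msg)) msg else TRUE
         })

#' @describeIn SpliceEventTable-class Constructor.
#' @param events data.frame of junction counts (see slots); missing length
#'   columns are filled with 1.
#' @return A `SpliceEventTable`.
#' @export
SpliceEventTable <- function(events) {
  events <- as.data.frame(events)
  if (is.null(events$len_inc)) events$len_inc <- 1
  if (is.null(events$len_skip)) events$len_skip <- 1
  events$len_inc <- as.numeric(events$len_inc)
  events$len_skip <- as.numeric(events$len_skip)
  if (any(events$inclusion != round(events$inclusion)) ||
      any(events$skipping != round(events$skipping)))
    stop("junction counts must be integers", call. = FALSE)
  events$inclusion <- as.integer(events$inclusion)
  events$skipping <- as.integer(events$skipping)
  new("SpliceEventTable", events = events)
}

#' Matched primary/lymph-node patient records
#'
#' One row per patient and tissue, carrying the snoRNA qPCR Ct, the reference
#' gene Ct and the PSI of each splicing event of interest (columns named
#' `psi_<event>`). Paired analyses use only patients with both tissues.
#'
#' @slot records data.frame with columns `patient_id`, `tissue`
#'   (`"primary"`/`"LN"`), `ct_target`, `ct_reference` and one or more
#'   `psi_*` columns in \[0, 1\].
#' @export
setClass("PatientPairTable", representation(records = "data.frame"),
         validity = function(object) {
           need <- c("patient_id", "tissue", "ct_target", "ct_reference")
           if (!all(need %in% names(object@records)))
             return(paste("records need columns:", paste(need, collapse = ", ")))
           r <- object@records
           msg <- character()
           if (!all(r$tissue %in% c("primary", "LN")))
             msg <- c(msg, "tissue must be 'primary' or 'LN'")
           if (anyDuplicated(paste(r$patient_id, r$tissue)))
             msg <- c(msg, "each patient may have at most one record per tissue")
           psi <- grep("^psi_", names(r), value = TRUE)
           if (!length(psi)) msg <- c(msg, "at least one psi_<event> column is required")
           for (p in psi) {
             v <- r[[p]]
             if (any(!is.na(v) & (v < 0 | v > 1)))
               msg <- c(msg, paste0(p, " must lie in [0, 1]"))
           }
           if (length(msg)) msg else TRUE
         })

#' @describeIn PatientPairTable-class Constructor.
#' @param records data.frame of patient records (see slots).
#' @return A `PatientPairTable`.
#' @export
PatientPairTable <- function(records)
  new("PatientPairTable", records = as.data.frame(records))

#' Ground truth planted by a simulator
#'
#' Every simulator in the package returns, alongside its dataset, one
#' `PlantedTruth` recording the generating parameters so that each downstream
#' expected value can be computed without re-running the generator. The object
#' round-trips losslessly through [writePlantedTruth()]/[readPlantedTruth()].
#'
#' @slot component which simulator produced it; one of `microarray`, `nmvaq`,
#'   `riboxi`, `events`, `introns`, `pairs`.
#' @slot parameters named list of generating parameters.
#' @export
setClass("PlantedTruth",
         representation(component = "character", parameters = "list"),
         validity = function(object) {
           ok <- c("microarray", "nmvaq", "riboxi", "events", "introns", "pairs")
           if (length(object@component) != 1L || !object@component %in% ok)
             return(paste("component must be one of:", paste(ok, collapse = ", ")))
           if (is.null(names(object@parameters)) &&
               length(object@parameters) > 0)
             return("parameters must be a named list")
           TRUE
         })

#' @describeIn PlantedTruth-class Constructor.
#' @param component simulator name.
#' @param parameters named list of generating parameters.
#' @return A `PlantedTruth`.
#' @export
PlantedTruth <- function(component, parameters)
  new("PlantedTruth", component = component, parameters = parameters)
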