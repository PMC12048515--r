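# TSV/CSV readers and writers for every container, plus the planted-truth
# sidecar. Formats are plain text so datasets and fixtures stay portable.

#' Read / write a probe expression matrix with its annotations
#'
#' The matrix TSV has probe ids in the first column and sample ids in the
#' header; the sample annotation TSV has columns `sample`, `group`, `site`;
#' the probe annotation TSV has columns `probe`, `class`.
#'
#' @param matrixFile,sampleFile,probeFile file paths.
#' @return A [ProbeExpressionExperiment-class].
#' @export
readExpressionMatrix <- function(matrixFile, sampleFile, probeFile) {
  m <- utils::read.delim(matrixFile, check.names = FALSE)
  vals <- as.matrix(m[, -1, drop = FALSE])
  rownames(vals) <- m[[1]]
  samp <- utils::read.delim(sampleFile)
  prb <- utils::read.delim(probeFile)
  samp <- samp[match(colnames(vals), samp$sample), ]
  prb <- prb[match(rownames(vals), prb$probe), ]
  ProbeExpressionExperiment(vals, samp$group, samp$site, prb$class)
}

#' @rdname readExpressionMatrix
#' @param mat a [ProbeExpressionExperiment-class].
#' @export
writeExpressionMatrix <- function(mat, matrixFile, sampleFile, probeFile) {
  v <- assay(mat, "exprs")
  utils::write.table(data.frame(probe = rownames(v), v, check.names = FALSE),
                     matrixFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(mat),
                                group = sampleGroups(mat),
                                site = siteCategories(mat)),
                     sampleFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(probe = rownames(mat),
                                class = probeClasses(mat)),
                     probeFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrixFile, sampleFile, probeFile))
}

#' Read / write a qPCR plate CSV
#'
#' Columns `sample`, `target`, `role`, `rnaseh`, `ct` - one row per
#' replicate; empty `ct` marks an undetermined reaction.
#'
#' @param file file path.
#' @return A [QpcrPlate-class].
#' @export
readQpcrPlate <- function(file) QpcrPlate(utils::read.csv(file))

#' @rdname readQpcrPlate
#' @param plate a [QpcrPlate-class].
#' @export
writeQpcrPlate <- function(plate, file) {
  utils::write.csv(plateRecords(plate), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Read / write a splice-event junction count TSV
#'
#' Columns `event_id`, `gene_id`, `event_type`, `group`, `replicate`,
#' `inclusion`, `skipping`, `len_inc`, `len_skip`.
#'
#' @param file file path.
#' @return A [SpliceEventTable-class].
#' @export
readSpliceEventTable <- function(file)
  SpliceEventTable(utils::read.delim(file))

#' @rdname readSpliceEventTable
#' @param table a [SpliceEventTable-class].
#' @export
writeSpliceEventTable <- function(table, file) {
  utils::write.table(eventCounts(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write an intron count TSV
#'
#' Columns `intron_id`, `group`, `intron_reads`, `total_reads` and
#' optionally `pure`.
#'
#' @param file file path.
#' @return data.frame of intron counts.
#' @export
readIntronTable <- function(file) utils::read.delim(file)

#' @rdname readIntronTable
#' @param records intron count data.frame.
#' @export
writeIntronTable <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write a patient-pair CSV
#'
#' Columns `patient_id`, `tissue`, `ct_target`, `ct_reference` and one or
#' more `psi_<event>` columns.
#'
#' @param file file path.
#' @return A [PatientPairTable-class].
#' @export
readPatientPairTable <- function(file)
  PatientPairTable(utils::read.csv(file))

#' @rdname readPatientPairTable
#' @param table a [PatientPairTable-class].
#' @export
writePatientPairTable <- function(table, file) {
  utils::write.csv(pairRecords(table), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Read / write a per-position end-count TSV
#'
#' Columns `position`, `count`; the transcript id and strand are kept in a
#' header comment line.
#'
#' @param file file path.
#' @return An [EndCountTrack-class].
#' @export
readEndCountTrack <- function(file) {
  first <- readLines(file, n = 1L)
  meta <- strsplit(sub("^# *", "", first), "\t")[[1]]
  d <- utils::read.delim(file, comment.char = "#")
  counts <- integer(max(d$position))
  counts[d$position] <- d$count
  EndCountTrack(meta[1], counts, meta[2])
}

#' @rdname readEndCountTrack
#' @param track an [EndCountTrack-class].
#' @export
writeEndCountTrack <- function(track, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", transcriptId(track), "\t", strand(track)), con)
  utils::write.table(data.frame(position = seq_along(counts(track)),
                                count = counts(track)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write / read a planted-truth sidecar
#'
#' Serialises a [PlantedTruth-class] to structured JSON text at full numeric
#' precision, so the round trip is lossless.
#'
#' @param truth a [PlantedTruth-class].
#' @param file file path (conventionally `<dataset>.truth.json`).
#' @return `readPlantedTruth()` returns the reconstructed
#'   [PlantedTruth-class]; `writePlantedTruth()` returns `file` invisibly.
#' @examples
#' tr <- PlantedTruth("nmvaq", list(true_me = c(0, 0.5, 1)))
#' f <- tempfile(fileext = ".json")
#' writePlantedTruth(tr, f)
#' identical(truthParameters(readPlantedTruth(f)), truthParameters(tr))
#' @export
writePlantedTruth <- function(truth, file) {
  stopifnot(is(truth, "PlantedTruth"))
  jsonlite::write_json(list(component = truthComponent(truth),
                            parameters = truthParameters(truth)),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname writePlantedTruth
#' @export
readPlantedTruth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  PlantedTruth(x$component, as.list(x$parameters))
}
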