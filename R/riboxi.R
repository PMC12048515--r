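#' Build a 3'-end count track from BED alignments
#'
#' Tallies alignment 3' ends over one transcript strand. BED intervals use
#' 0-based half-open coordinates: on the `+` strand the 3' end falls at the
#' interval end (1-based inclusive = BED end); on the `-` strand at the
#' interval start (1-based = BED start + 1). Records on other transcripts or
#' the other strand are ignored; records whose 3' end falls outside
#' `[1, length]` are skipped and counted in the `skipped` attribute.
#'
#' @param alignments a BED file path, a data.frame with columns
#'   `chrom, start, end, name, score, strand` (BED conventions), or a
#'   [GenomicRanges::GRanges] (1-based, as returned by
#'   [rtracklayer::import()]).
#' @param transcript transcript (chrom) id of the track.
#' @param strand strand of the track, `"+"` or `"-"`.
#' @param length transcript length in nt.
#' @return An [EndCountTrack-class]; `attr(, "skipped")` counts rejected
#'   records.
#' @examples
#' bed <- data.frame(chrom = "U6", start = 0, end = 50, name = "r1",
#'                   score = 0, strand = "+")
#' counts(endCountTrackFromBed(bed, "U6", "+", 106))[50]  # 1
#' @export
endCountTrackFromBed <- function(alignments, transcript, strand = "+",
                                 length) {
  length <- .assertCount(length, "length", min = 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (is.character(alignments) && base::length(alignments) == 1L) {
    alignments <- rtracklayer::import(alignments, format = "BED")
  }
  if (is(alignments, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(alignments)),
      start = GenomicRanges::start(alignments) - 1L,  # back to BED 0-based
      end = GenomicRanges::end(alignments),
      strand = as.character(GenomicRanges::strand(alignments)))
  } else {
    df <- as.data.frame(alignments)
    if (!all(c("chrom", "start", "end", "strand") %in% names(df)))
      stop("BED data.frame needs chrom, start, end, strand", call. = FALSE)
  }
  df <- df[df$chrom == transcript & df$strand == strand, , drop = FALSE]
  pos <- if (strand == "+") df$end else df$start + 1L
  ok <- pos >= 1L & pos <= length
  nSkipped <- sum(!ok)
  if (nSkipped > 0L)
    warning(nSkipped, " alignment(s) outside [0, ", length, "] skipped",
            call. = FALSE)
  counts <- tabulate(pos[ok], nbins = length)
  track <- EndCountTrack(transcript, counts, strand)
  attr(track, "skipped") <- nSkipped
  track
}

#' Neighbour-normalised Nm scores from a 3'-end count track
#'
#' After replacing zero counts by 1 (making every ratio defined), the score
#' at interior position `n` is `c(n) / ((c(n-1) + c(n+1)) / 2)`. Endpoints
#' have no score. A flat track scores exactly 1 everywhere; a position
#' enriched for read 3' ends by site-protected ligation scores high.
#'
#' @param track an [EndCountTrack-class] of length >= 3.
#' @return An [NmScoreTrack-class].
#' @examples
#' t <- EndCountTrack("U6", c(10, 100, 10))
#' nmScores(nmScoreTrack(t))  # 10 at position 2
#' @export
nmScoreTrack <- function(track) {
  stopifnot(is(track, "EndCountTrack"))
  n <- length(track)
  if (n < 3L)
    stop("a track of length >= 3 is required for neighbour normalization",
         call. = FALSE)
  c0 <- counts(track)
  c1 <- pmax(c0, 1L)  # zero -> 1 substitution
  interior <- 2:(n - 1L)
  scores <- c1[interior] / ((c1[interior - 1L] + c1[interior + 1L]) / 2)
  names(scores) <- interior
  new("NmScoreTrack", transcript = transcriptId(track), scores = scores,
      counts = c0)
}

#' Call putative 2'-O-methylation sites from an Nm-score track
#'
#' A position is called when its Nm score and its raw 3'-end count both meet
#' their thresholds (conjunctive rule). Thresholds are artifact defaults and
#' fully configurable.
#'
#' @param scores an [NmScoreTrack-class].
#' @param scoreThreshold minimum Nm score (default 4).
#' @param countThreshold minimum raw 3'-end count (default 10).
#' @return data.frame of called sites, sorted by position, with columns
#'   `transcript`, `position`, `nm_score`, `count`.
#' @examples
#' s <- nmScoreTrack(EndCountTrack("U6", c(10, 100, 10)))
#' callSites(s, scoreThreshold = 4, countThreshold = 10)
#' @export
callSites <- function(scores, scoreThreshold = 4, countThreshold = 10L) {
  stopifnot(is(scores, "NmScoreTrack"))
  .assertPositive(scoreThreshold, "scoreThreshold")
  .assertPositive(countThreshold, "countThreshold")
  pos <- as.integer(names(nmScores(scores)))
  sc <- unname(nmScores(scores))
  ct <- counts(scores)[pos]
  keep <- sc >= scoreThreshold & ct >= countThreshold
  out <- data.frame(transcript = rep(transcriptId(scores), sum(keep)),
                    position = pos[keep], nm_score = sc[keep],
                    count = ct[keep])
  out[order(out$position), , drop = FALSE]
}

#' Sites differentially called between two genotypes
#'
#' Set difference of the called sites of two Nm-score tracks over the same
#' transcript, reported per direction: positions called in `a` but not in
#' `b` (`lostInB`, e.g. methylation lost in a knockout) and vice versa
#' (`gainedInB`).
#'
#' @param a,b [NmScoreTrack-class] objects over the same transcript and
#'   length.
#' @inheritParams callSites
#' @return List with integer vectors `lostInB` and `gainedInB`.
#' @examples
#' sim <- simulateEndCountTracks(seed = 1)
#' differentialSites(nmScoreTrack(sim$tracks$WT), nmScoreTrack(sim$tracks$KO))
#' @export
differentialSites <- function(a, b, scoreThreshold = 4, countThreshold = 10L) {
  stopifnot(is(a, "NmScoreTrack"), is(b, "NmScoreTrack"))
  if (transcriptId(a) != transcriptId(b) ||
      length(counts(a)) != length(counts(b)))
    stop("tracks must cover the same transcript and length", call. = FALSE)
  callsA <- callSites(a, scoreThreshold, countThreshold)$position
  callsB <- callSites(b, scoreThreshold, countThreshold)$position
  list(lostInB = setdiff(callsA, callsB), gainedInB = setdiff(callsB, callsA))
}
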