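#' Differential-probe selection thresholds
#'
#' The three tailored criteria applied to each sample triplet against the
#' pooled baselines: a fold-change of the triplet mean versus the baseline
#' mean at or beyond `foldUp`/`foldDown` ("at least 50% above or below"), a
#' per-probe range at or above the `rangePercentile`-th percentile of all
#' probes' ranges on the baseline + triplet submatrix, and an all-pairwise
#' strict ordering (consistency) between triplet and baseline replicates.
#'
#' @param foldUp up-regulation fold threshold (>= 1, boundary inclusive).
#' @param foldDown down-regulation fold threshold (<= 1, boundary inclusive).
#' @param rangePercentile percentile of per-probe ranges that must be met
#'   (linear interpolation), in \[0, 100\].
#' @param strictDirection if `TRUE` (default) the consistency relation must
#'   agree with the fold-change direction.
#' @return A list of class `SelectionCriteria`.
#' @examples
#' selectionCriteria()
#' @export
selectionCriteria <- function(foldUp = 1.5, foldDown = 0.5,
                              rangePercentile = 25, strictDirection = TRUE) {
  if (foldUp < 1 || foldDown > 1 || foldDown < 0)
    stop("need foldDown <= 1 <= foldUp (and foldDown >= 0)", call. = FALSE)
  if (rangePercentile < 0 || rangePercentile > 100)
    stop("rangePercentile must lie in [0, 100]", call. = FALSE)
  structure(list(foldUp = foldUp, foldDown = foldDown,
                 rangePercentile = rangePercentile,
                 strictDirection = isTRUE(strictDirection)),
            class = "SelectionCriteria")
}

.groupSamples <- function(mat, groupId) {
  which(sampleGroups(mat) == groupId)
}

.siteSamples <- function(mat, site) {
  which(siteCategories(mat) == site)
}

.checkTriplet <- function(mat, triplet) {
  idx <- .groupSamples(mat, triplet)
  if (!length(idx))
    stop("no samples belong to group '", triplet, "'", call. = FALSE)
  idx
}

#' Fold-change criterion of a sample triplet against the pooled baselines
#'
#' Per probe, the mean over the triplet's samples is compared with the mean
#' over all baseline samples: a ratio `>= foldUp` passes up-regulated (`"+"`),
#' `<= foldDown` passes down-regulated (`"-"`); both boundaries inclusive.
#' Probes with a zero baseline mean are flagged invalid and never pass.
#'
#' @param mat a [ProbeExpressionExperiment-class].
#' @param triplet group id of the sample triplet.
#' @param criteria a [selectionCriteria()] object.
#' @return data.frame with per-probe `pass`, `direction` (`"+"`, `"-"`,
#'   `"none"`), `fold` and `valid`.
#' @export
criterionFoldChange <- function(mat, triplet, criteria = selectionCriteria()) {
  idx <- .checkTriplet(mat, triplet)
  base <- .siteSamples(mat, "baseline")
  v <- assay(mat, "exprs")
  baseMean <- rowMeans(v[, base, drop = FALSE])
  tripMean <- rowMeans(v[, idx, drop = FALSE])
  valid <- baseMean > 0
  fold <- ifelse(valid, tripMean / baseMean, NA_real_)
  direction <- rep("none", nrow(v))
  direction[valid & fold >= criteria$foldUp] <- "+"
  direction[valid & fold <= criteria$foldDown] <- "-"
  data.frame(probe_id = rownames(v), pass = direction != "none",
             direction = direction, fold = fold, valid = valid,
             row.names = rownames(v))
}

#' Range-percentile criterion on the baseline + triplet submatrix
#'
#' Per probe, the range (max - min) over the baseline and triplet columns is
#' compared with the `rangePercentile`-th percentile (linear interpolation)
#' of all probes' ranges on the same submatrix; the boundary is inclusive.
#' Constant probes (range 0) never pass when the percentile is positive.
#'
#' @inheritParams criterionFoldChange
#' @return data.frame with per-probe `pass`, `range` and the applied
#'   `threshold`.
#' @export
criterionRangePercentile <- function(mat, triplet,
                                     criteria = selectionCriteria()) {
  idx <- .checkTriplet(mat, triplet)
  base <- .siteSamples(mat, "baseline")
  sub <- assay(mat, "exprs")[, c(base, idx), drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(probe_id = character(), pass = logical(),
                      range = numeric(), threshold = numeric()))
  rng <- apply(sub, 1L, function(x) max(x) - min(x))
  thr <- unname(stats::quantile(rng, criteria$rangePercentile / 100,
                                type = 7))
  pass <- rng >= thr
  if (criteria$rangePercentile > 0) pass <- pass & rng > 0
  data.frame(probe_id = rownames(sub), pass = pass, range = rng,
             threshold = thr, row.names = rownames(sub))
}

#' All-pairwise consistency relation between two replicate sets
#'
#' Returns `">"` when every value of `a` strictly exceeds every value of `b`,
#' `"<"` in the symmetric case, and `"none"` otherwise (any shared value
#' breaks the strict ordering).
#'
#' @param a,b non-empty numeric vectors of replicate intensities.
#' @return `">"`, `"<"` or `"none"`.
#' @examples
#' criterionConsistency(c(5, 6, 7), c(1, 2, 3, 4))  # ">"
#' @export
criterionConsistency <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both replicate sets must be non-empty", call. = FALSE)
  if (min(a) > max(b)) return(">")
  if (max(a) < min(b)) return("<")
  "none"
}

# Vectorised over probes: relation of rows of va vs rows of vb.
.rowConsistency <- function(va, vb) {
  aMin <- apply(va, 1L, min); aMax <- apply(va, 1L, max)
  bMin <- apply(vb, 1L, min); bMax <- apply(vb, 1L, max)
  out <- rep("none", nrow(va))
  out[aMin > bMax] <- ">"
  out[aMax < bMin] <- "<"
  out
}

#' Select probes with an AxLN-distinct expression pattern
#'
#' A probe is selected when (a) for at least one AxLN triplet all three
#' criteria hold against the pooled baselines - fold change
#' ([criterionFoldChange()]), range percentile
#' ([criterionRangePercentile()]) and all-pairwise consistency
#' ([criterionConsistency()], direction matching the fold direction when
#' `strictDirection`) - and (b) the pooled pairwise comparisons MFP vs AxLN
#' and AxLN vs AxLN-LuM each satisfy the consistency relation with AxLN on
#' the same side of both (the AxLN-distinct pattern). The MFP vs AxLN-LuM
#' comparison can additionally be required via `requireThirdComparison`.
#'
#' @inheritParams criterionFoldChange
#' @param requireThirdComparison also require consistency for MFP vs
#'   AxLN-LuM (default `FALSE`).
#' @return A [S4Vectors::DataFrame] with per-probe columns `any_triplet_pass`,
#'   `pattern_mfp_axln`, `pattern_axln_lum`, `pattern_ok` and `selected`;
#'   per-triplet criterion detail is kept in `metadata()$triplets`.
#' @examples
#' sim <- simulateMicroarray(microarrayDesign(nProbes = 100, noiseSd = 0))
#' res <- selectAxlnSignature(sim$matrix)
#' sum(res$selected)
#' @export
selectAxlnSignature <- function(mat, criteria = selectionCriteria(),
                                requireThirdComparison = FALSE) {
  site <- siteCategories(mat)
  for (s in c("baseline", "MFP", "AxLN", "AxLN-LuM"))
    if (!any(site == s))
      stop("matrix has no samples of site category '", s, "'", call. = FALSE)
  v <- assay(mat, "exprs")
  groups <- sampleGroups(mat)
  axlnTriplets <- unique(groups[site == "AxLN"])
  base <- .siteSamples(mat, "baseline")
  tripletDetail <- list()
  anyPass <- rep(FALSE, nrow(v))
  for (tg in axlnTriplets) {
    fc <- criterionFoldChange(mat, tg, criteria)
    rp <- criterionRangePercentile(mat, tg, criteria)
    cons <- .rowConsistency(v[, .groupSamples(mat, tg), drop = FALSE],
                            v[, base, drop = FALSE])
    consOk <- if (criteria$strictDirection)
      (cons == ">" & fc$direction == "+") |
      (cons == "<" & fc$direction == "-")
    else cons != "none"
    pass <- fc$pass & rp$pass & consOk
    tripletDetail[[tg]] <- data.frame(
      probe_id = rownames(v), pass_fold = fc$pass,
      fold_direction = fc$direction, pass_range = rp$pass,
      consistency = cons, pass = pass, row.names = rownames(v))
    anyPass <- anyPass | pass
  }
  mfp <- v[, .siteSamples(mat, "MFP"), drop = FALSE]
  axln <- v[, .siteSamples(mat, "AxLN"), drop = FALSE]
  lum <- v[, .siteSamples(mat, "AxLN-LuM"), drop = FALSE]
  mfpVsAxln <- .rowConsistency(mfp, axln)
  axlnVsLum <- .rowConsistency(axln, lum)
  # AxLN on the same side of both comparisons: high in both or low in both
  patternOk <- (mfpVsAxln == "<" & axlnVsLum == ">") |
               (mfpVsAxln == ">" & axlnVsLum == "<")
  if (requireThirdComparison) {
    mfpVsLum <- .rowConsistency(mfp, lum)
    patternOk <- patternOk & mfpVsLum != "none"
  }
  out <- DataFrame(probe_id = rownames(v), any_triplet_pass = anyPass,
                   pattern_mfp_axln = mfpVsAxln, pattern_axln_lum = axlnVsLum,
                   pattern_ok = patternOk,
                   selected = anyPass & patternOk,
                   row.names = rownames(v))
  metadata(out)$triplets <- tripletDetail
  metadata(out)$criteria <- criteria
  out
}

#' Upper-tail hypergeometric set enrichment
#'
#' Probability of observing at least `k` annotated members in a selection of
#' size `n` drawn without replacement from a background of `N` items of which
#' `K` are annotated, with the fold enrichment `(k/n) / (K/N)`. The tail sum
#' `P(X >= k) = sum_{j >= k} C(K,j) C(N-K,n-j) / C(N,n)` is evaluated in log
#' space via [stats::phyper()].
#'
#' @param N background size.
#' @param K annotated items in the background.
#' @param n selected items.
#' @param k annotated items among the selected.
#' @return List with `N`, `K`, `n`, `k`, `pUpper` and `fold`.
#' @examples
#' # snoRNA enrichment among differential ncRNA probes:
#' hypergeometricEnrichment(N = 10043, K = 1245, n = 30, k = 20)
#' @export
hypergeometricEnrichment <- function(N, K, n, k) {
  N <- .assertCount(N, "N"); K <- .assertCount(K, "K")
  n <- .assertCount(n, "n"); k <- .assertCount(k, "k")
  if (K > N || n > N || k > n || k > K || k < max(0L, n + K - N))
    stop("need 0 <= K <= N, 0 <= k <= n <= N, max(0, n+K-N) <= k <= K",
         call. = FALSE)
  pUpper <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0L && K > 0L) (k / n) / (K / N) else NA_real_
  list(N = N, K = K, n = n, k = k, pUpper = pUpper, fold = fold)
}

#' Log2 transform and per-probe mean centering
#'
#' The display transform used ahead of hierarchical clustering: each probe's
#' intensities over the chosen samples are log2-transformed and the probe's
#' mean log2 value subtracted, so every output row has mean zero.
#'
#' @param mat a [ProbeExpressionExperiment-class].
#' @param samples sample ids (or indices) to include; default all samples.
#' @return Numeric matrix of centred log2 intensities.
#' @examples
#' m <- matrix(c(2, 8), 1, 2, dimnames = list("p", c("a", "b")))
#' x <- ProbeExpressionExperiment(m, c("b1", "b1"),
#'                                c("baseline", "baseline"), "other")
#' log2MeanCenter(x)  # -1, +1
#' @export
log2MeanCenter <- function(mat, samples = seq_len(ncol(mat))) {
  v <- assay(mat, "exprs")[, samples, drop = FALSE]
  if (any(v <= 0))
    stop("all intensities must be > 0 for the log2 transform", call. = FALSE)
  lg <- log2(v)
  lg - rowMeans(lg)
}
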