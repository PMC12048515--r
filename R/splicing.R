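#' Percent spliced in from junction counts
#'
#' Effective-length-normalised PSI:
#' `PSI = (I/lI) / (I/lI + S/lS)`, reducing to `I/(I+S)` with equal lengths.
#' Events with no reads at all are undefined and reported as `NA`.
#'
#' @param I,S inclusion and skipping junction counts (vectorised).
#' @param lI,lS effective lengths of the inclusion and skipping forms.
#' @return PSI values in \[0, 1\] (`NA` where `I = S = 0`).
#' @examples
#' psiFromCounts(60, 20, lI = 3, lS = 1)  # 0.5
#' @export
psiFromCounts <- function(I, S, lI = 1, lS = 1) {
  if (any(I < 0) || any(S < 0)) stop("counts must be >= 0", call. = FALSE)
  .assertPositive(lI, "lI"); .assertPositive(lS, "lS")
  ni <- I / lI
  ns <- S / lS
  ifelse(I + S == 0, NA_real_, ni / (ni + ns))
}

# Binomial log-likelihood with 0*log(0) := 0; tolerates non-integer
# length-normalised counts.
.binLL <- function(i, s, p) {
  ll <- 0
  if (i > 0) ll <- ll + i * log(p)
  if (s > 0) ll <- ll + s * log(1 - p)
  ll
}

#' Two-group differential splicing test with the significance filter
#'
#' For each event, replicate counts are summed per group and the group PSI is
#' the length-normalised PSI of the summed counts. The p-value comes from a
#' two-proportion binomial likelihood-ratio test on the pooled
#' length-normalised counts (one degree of freedom); q-values are
#' Benjamini-Hochberg over all tested events. An event is flagged significant
#' when `|deltaPsi| >= 0.10`, `fdr < 0.05` and the total inclusion or total
#' skipping raw count (summed over all replicates of both groups) is >= 5.
#'
#' @param table a [SpliceEventTable-class] with exactly two groups.
#' @param deltaPsiMin,fdrMax,minReads filter thresholds (defaults 0.10,
#'   0.05, 5).
#' @return data.frame with one row per event: `event_id`, `gene_id`,
#'   `event_type`, `psi_A`, `psi_B` (groups in sorted order), `delta_psi`
#'   (`psi_B - psi_A`), `p_value`, `fdr`, `total_inclusion`,
#'   `total_skipping`, `significant`.
#' @examples
#' sim <- simulateSpliceEvents(10, psiPairs = cbind(0.9, 0.5), seed = 1)
#' head(testEvents(sim$table))
#' @export
testEvents <- function(table, deltaPsiMin = 0.10, fdrMax = 0.05,
                       minReads = 5L) {
  stopifnot(is(table, "SpliceEventTable"))
  e <- eventCounts(table)
  grp <- sort(unique(e$group))
  if (length(grp) != 2L)
    stop("exactly two groups are required (found ",
         length(grp), ")", call. = FALSE)
  chunks <- split(e, factor(e$event_id, levels = unique(e$event_id)))
  res <- lapply(chunks, function(ev) {
    id <- ev$event_id[1]
    li <- ev$len_inc[1]; ls <- ev$len_skip[1]
    sums <- lapply(grp, function(g) {
      gg <- ev[ev$group == g, , drop = FALSE]
      c(I = sum(gg$inclusion), S = sum(gg$skipping))
    })
    iA <- sums[[1]]["I"] / li; sA <- sums[[1]]["S"] / ls
    iB <- sums[[2]]["I"] / li; sB <- sums[[2]]["S"] / ls
    psiA <- psiFromCounts(sums[[1]]["I"], sums[[1]]["S"], li, ls)
    psiB <- psiFromCounts(sums[[2]]["I"], sums[[2]]["S"], li, ls)
    if (is.na(psiA) || is.na(psiB)) {
      p <- NA_real_
    } else {
      pA <- iA / (iA + sA); pB <- iB / (iB + sB)
      pPool <- (iA + iB) / (iA + sA + iB + sB)
      G <- 2 * (.binLL(iA, sA, pA) + .binLL(iB, sB, pB) -
                .binLL(iA + iB, sA + sB, pPool))
      p <- stats::pchisq(max(G, 0), df = 1L, lower.tail = FALSE)
    }
    data.frame(event_id = id, gene_id = ev$gene_id[1],
               event_type = ev$event_type[1],
               psi_A = unname(psiA), psi_B = unname(psiB),
               delta_psi = unname(psiB - psiA), p_value = p,
               total_inclusion = unname(sums[[1]]["I"] + sums[[2]]["I"]),
               total_skipping = unname(sums[[1]]["S"] + sums[[2]]["S"]))
  })
  res <- do.call(rbind, res)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$delta_psi) & !is.na(res$fdr) &
    abs(res$delta_psi) >= deltaPsiMin & res$fdr < fdrMax &
    (res$total_inclusion >= minReads | res$total_skipping >= minReads)
  rownames(res) <- NULL
  res[, c("event_id", "gene_id", "event_type", "psi_A", "psi_B",
          "delta_psi", "p_value", "fdr", "total_inclusion",
          "total_skipping", "significant")]
}

#' Apply the significance filter and summarise surviving events
#'
#' Keeps events satisfying `|deltaPsi| >= 0.10`, `fdr < 0.05` and total
#' inclusion or skipping reads >= 5 (the delta-PSI boundary inclusive, the
#' FDR boundary exclusive, the count rule disjunctive), then tallies
#' surviving events by class and lists the distinct genes.
#'
#' @param results data.frame as returned by [testEvents()] (or any table
#'   with columns `delta_psi`, `fdr`, `total_inclusion`, `total_skipping`,
#'   `event_type`, `gene_id`).
#' @inheritParams testEvents
#' @return List with `events` (surviving rows), `typeTally` (named counts
#'   over CE, RI, A3SS, A5SS, MXE) and `genes` (distinct gene ids).
#' @export
filterSignificant <- function(results, deltaPsiMin = 0.10, fdrMax = 0.05,
                              minReads = 5L) {
  if (nrow(results) == 0L)
    return(list(events = results,
                typeTally = stats::setNames(
                  integer(5), c("CE", "RI", "A3SS", "A5SS", "MXE")),
                genes = character()))
  keep <- !is.na(results$delta_psi) & !is.na(results$fdr) &
    abs(results$delta_psi) >= deltaPsiMin & results$fdr < fdrMax &
    (results$total_inclusion >= minReads |
       results$total_skipping >= minReads)
  surv <- results[keep, , drop = FALSE]
  tally <- table(factor(surv$event_type,
                        levels = c("CE", "RI", "A3SS", "A5SS", "MXE")))
  list(events = surv,
       typeTally = stats::setNames(as.integer(tally), names(tally)),
       genes = unique(surv$gene_id))
}

#' Hypergeometric enrichment of a gene-set overlap
#'
#' Significance of the overlap between two gene sets against a co-detected
#' background: delegates to [hypergeometricEnrichment()] with
#' `N = |background|`, `K = |setA|`, `n = |setB|`, `k = |setA intersect setB|`.
#'
#' @param setA,setB gene id vectors, both subsets of `background`.
#' @param background gene ids of the co-detected background set.
#' @return As [hypergeometricEnrichment()].
#' @examples
#' overlapEnrichment(letters[1:4], letters[3:6], letters)
#' @export
overlapEnrichment <- function(setA, setB, background) {
  setA <- unique(setA); setB <- unique(setB); background <- unique(background)
  if (!all(setA %in% background) || !all(setB %in% background))
    stop("both sets must be contained in the background", call. = FALSE)
  hypergeometricEnrichment(N = length(background), K = length(setA),
                           n = length(setB),
                           k = length(intersect(setA, setB)))
}

#' Intron retention ratios, splicing efficiency and the KS comparison
#'
#' Per intron, the retention ratio is `intron_reads / total_reads`; per
#' group, splicing efficiency is `1 - mean(IRR)`. Distributions of IRR are
#' compared between every pair of groups by the two-sample Kolmogorov-Smirnov
#' test (exact when either group has fewer than 25 introns, asymptotic
#' otherwise). Introns with zero total reads are dropped and counted; rows
#' with a `pure` flag column are restricted to `pure == TRUE`.
#'
#' @param records data.frame with columns `intron_id`, `group`,
#'   `intron_reads`, `total_reads` and optionally `pure`.
#' @return List with `irr` (per-intron data.frame), `efficiency` (named
#'   per-group), `ks` (data.frame of pairwise `group_a`, `group_b`,
#'   `statistic`, `p_value`) and `dropped` (introns with zero total reads).
#' @examples
#' sim <- simulateIntronCounts(200, c(A = 0.3, B = 0.15), seed = 1)
#' intronRetention(sim$table)$efficiency
#' @export
intronRetention <- function(records) {
  need <- c("intron_id", "group", "intron_reads", "total_reads")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("pure" %in% names(records))
    records <- records[as.logical(records$pure), , drop = FALSE]
  drop <- records$total_reads == 0
  dropped <- sum(drop)
  if (dropped > 0L) {
    message(dropped, " intron(s) with zero total reads dropped")
    records <- records[!drop, , drop = FALSE]
  }
  if (any(records$intron_reads > records$total_reads))
    stop("intron_reads cannot exceed total_reads", call. = FALSE)
  irr <- records$intron_reads / records$total_reads
  out <- data.frame(intron_id = records$intron_id, group = records$group,
                    irr = irr)
  eff <- vapply(split(out$irr, out$group), function(x) 1 - mean(x),
                numeric(1))
  grp <- sort(unique(out$group))
  ks <- NULL
  if (length(grp) >= 2L) {
    pairs <- utils::combn(grp, 2L)
    ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      x <- out$irr[out$group == pairs[1, j]]
      y <- out$irr[out$group == pairs[2, j]]
      exact <- min(length(x), length(y)) < 25L
      kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 statistic = unname(kt$statistic),
                 p_value = kt$p.value)
    }))
  }
  list(irr = out, efficiency = eff, ks = ks, dropped = dropped)
}

#' PSI from gel band densitometry
#'
#' `PSI = inclusion / (inclusion + exclusion)` from RT-PCR band intensities;
#' undefined (NA) when both bands are zero.
#'
#' @param inclusionIntensity,exclusionIntensity densitometry readings >= 0.
#' @return PSI in \[0, 1\] (vectorised; `NA` where both are zero).
#' @examples
#' gelPsi(300, 100)  # 0.75
#' @export
gelPsi <- function(inclusionIntensity, exclusionIntensity) {
  if (any(inclusionIntensity < 0) || any(exclusionIntensity < 0))
    stop("band intensities must be >= 0", call. = FALSE)
  tot <- inclusionIntensity + exclusionIntensity
  ifelse(tot == 0, NA_real_, inclusionIntensity / tot)
}
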