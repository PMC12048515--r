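# Independent oracles used across the suite. Each re-derives its quantity
# from first principles (enumeration or textbook formulas) so it never shares
# a code path with the implementation it checks.

# Exhaustive hypergeometric upper tail: enumerate every size-n subset of a
# background of N items whose first K are annotated, and count subsets with
# at least k annotated members.
enumHyperTail <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  annotated <- colSums(subsets <= K)
  mean(annotated >= k)
}

# Benjamini-Hochberg from the definition: sort ascending, q_(i) = running
# minimum from the largest rank of p_(i) * m / i.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Pearson r, two-tailed p and OLS line from the covariance formulas.
pearsonOracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tStat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tStat), df = n - 2),
       slope = sxy / sxx, intercept = my - (sxy / sxx) * mx)
}

# Equal-variance two-sample t-test p-value from the pooled-variance formula.
tTestOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  tStat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tStat), df = n1 + n2 - 2)
}

# Exhaustive lowest-p threshold search over every admissible midpoint.
thresholdSplitOracle <- function(expr, psi, minGroupSize = 3L) {
  u <- sort(unique(expr))
  mids <- (u[-length(u)] + u[-1]) / 2
  best <- NULL
  for (thr in mids) {
    low <- psi[expr < thr]; high <- psi[expr >= thr]
    if (length(low) < minGroupSize || length(high) < minGroupSize) next
    p <- tTestOracle(low, high)
    if (is.null(best) || p < best$p) best <- list(threshold = thr, p = p)
  }
  best
}

# The significance rule applied row by row with explicit conditionals.
filterRuleOracle <- function(results, deltaPsiMin = 0.10, fdrMax = 0.05,
                             minReads = 5L) {
  keep <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    row <- results[i, ]
    if (is.na(row$delta_psi) || is.na(row$fdr)) next
    if (abs(row$delta_psi) < deltaPsiMin) next
    if (row$fdr >= fdrMax) next
    if (row$total_inclusion < minReads && row$total_skipping < minReads) next
    keep[i] <- TRUE
  }
  keep
}

# A random splicing result table for property tests against the rule oracle.
randomResultTable <- function(nEvents) {
  data.frame(
    event_id = sprintf("E%03d", seq_len(nEvents)),
    gene_id = sprintf("G%03d", sample.int(max(1L, nEvents %/% 2), nEvents,
                                          replace = TRUE)),
    event_type = sample(c("CE", "RI", "A3SS", "A5SS", "MXE"), nEvents,
                        replace = TRUE),
    delta_psi = round(stats::runif(nEvents, -0.3, 0.3), 2),
    fdr = round(stats::runif(nEvents), 2),
    total_inclusion = sample(0:10, nEvents, replace = TRUE),
    total_skipping = sample(0:10, nEvents, replace = TRUE))
}
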