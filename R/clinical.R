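#' Reference-normalised expression on the -dCt scale
#'
#' `-dCt = -(Ct_target - Ct_reference)`; higher values mean higher target
#' expression.
#'
#' @param ctTarget,ctReference threshold cycles (vectorised).
#' @return -dCt values.
#' @examples
#' negDeltaCt(25, 20)  # -5
#' @export
negDeltaCt <- function(ctTarget, ctReference) {
  if (any(!is.finite(ctTarget)) || any(!is.finite(ctReference)))
    stop("Ct values must be finite", call. = FALSE)
  -(ctTarget - ctReference)
}

#' Paired expression change on the -ddCt scale
#'
#' `-ddCt = -dCt(LN) - (-dCt(primary))`: the change in normalised target
#' expression in the lymph-node tumour relative to the matched primary.
#'
#' @param lnValue,primaryValue -dCt values of the two tissues of one patient.
#' @return -ddCt values (vectorised).
#' @examples
#' negDeltaDeltaCt(-1, -3)  # +2
#' @export
negDeltaDeltaCt <- function(lnValue, primaryValue) lnValue - primaryValue

#' Pearson correlation with the two-tailed t-transform p-value
#'
#' Pearson's r, the two-tailed p-value via `t = r * sqrt((n-2) / (1-r^2))`
#' on `n - 2` degrees of freedom, and the ordinary least-squares line of
#' `y` on `x`.
#'
#' @param x,y paired numeric vectors, `n >= 3`, both with nonzero variance.
#' @return List with `n`, `r`, `p`, `slope`, `intercept`.
#' @examples
#' pearsonAssoc(1:5, c(2, 1, 4, 3, 5))
#' @export
pearsonAssoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete observations required", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  list(n = n, r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

# Equal-variance two-sample t-test returning p even for degenerate
# (zero-variance) groups: p = 1 when the means agree, 0 when they differ.
.pooledTTest <- function(a, b, welch = FALSE) {
  if (welch) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    return(list(t = unname(tt$statistic), p = tt$p.value))
  }
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  d <- mean(a) - mean(b)
  if (sp2 == 0)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  tStat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tStat, p = 2 * stats::pt(-abs(tStat), df = n1 + n2 - 2))
}

#' Dichotomise expression at the threshold with the lowest t-test p-value
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' expression values that leave at least `minGroupSize` observations on each
#' side. For each candidate, PSI is compared between the low and high groups
#' by a two-tailed two-sample t-test (Student's equal-variance by default,
#' Welch via `welch = TRUE`); the threshold minimising p is reported, ties
#' broken toward the lowest threshold. No multiplicity correction is applied
#' over candidates; the full candidate trace is always returned so the
#' optimisation is visible.
#'
#' @param expression -dCt expression values.
#' @param psi paired PSI values.
#' @param minGroupSize minimum size of each group (default 3).
#' @param welch use Welch's t-test instead of the pooled-variance test.
#' @return List with `threshold`, `p`, `t`, `nLow`, `nHigh`, `meanLow`,
#'   `meanHigh` and `candidates` (data.frame of every candidate's
#'   `threshold`, `t`, `p`, `n_low`, `n_high`).
#' @examples
#' thresholdSplit(c(1, 1, 1, 5, 5, 5), c(.2, .2, .2, .8, .8, .8))
#' @export
thresholdSplit <- function(expression, psi, minGroupSize = 3L,
                           welch = FALSE) {
  if (length(expression) != length(psi))
    stop("expression and psi must be paired", call. = FALSE)
  minGroupSize <- .assertCount(minGroupSize, "minGroupSize", min = 1L)
  if (length(expression) < 2L * minGroupSize)
    stop("need at least 2 * minGroupSize observations", call. = FALSE)
  u <- sort(unique(expression))
  if (length(u) < 2L)
    stop("no admissible threshold: all expression values identical",
         call. = FALSE)
  mids <- (u[-length(u)] + u[-1]) / 2
  cand <- do.call(rbind, lapply(mids, function(thr) {
    low <- psi[expression < thr]
    high <- psi[expression >= thr]
    if (length(low) < minGroupSize || length(high) < minGroupSize)
      return(NULL)
    tt <- .pooledTTest(low, high, welch = welch)
    data.frame(threshold = thr, t = tt$t, p = tt$p,
               n_low = length(low), n_high = length(high))
  }))
  if (is.null(cand) || nrow(cand) == 0L)
    stop("no admissible threshold satisfies the group-size constraint",
         call. = FALSE)
  cand <- cand[order(cand$threshold), , drop = FALSE]
  best <- which.min(cand$p)  # first minimum = lowest threshold on ties
  thr <- cand$threshold[best]
  low <- psi[expression < thr]; high <- psi[expression >= thr]
  list(threshold = thr, p = cand$p[best], t = cand$t[best],
       nLow = cand$n_low[best], nHigh = cand$n_high[best],
       meanLow = mean(low), meanHigh = mean(high), candidates = cand)
}

# Complete pairs of a PatientPairTable for one event; incomplete patients are
# excluded with a message listing their ids.
.completePairs <- function(table, event) {
  r <- pairRecords(table)
  col <- paste0("psi_", event)
  if (!col %in% names(r))
    stop("event '", event, "' not present (no column ", col, ")",
         call. = FALSE)
  wide <- merge(r[r$tissue == "primary", c("patient_id", "ct_target",
                                           "ct_reference", col)],
                r[r$tissue == "LN", c("patient_id", "ct_target",
                                      "ct_reference", col)],
                by = "patient_id", suffixes = c("_primary", "_ln"))
  complete <- stats::complete.cases(wide)
  all_ids <- unique(r$patient_id)
  excluded <- c(setdiff(all_ids, wide$patient_id),
                wide$patient_id[!complete])
  if (length(excluded))
    message("excluding patient(s) without both tissues: ",
            paste(sort(excluded), collapse = ", "))
  wide[complete, , drop = FALSE]
}

#' Association of exon inclusion with snoRNA expression across specimens
#'
#' Pearson correlation (with OLS line) between the event PSI and the
#' reference-normalised snoRNA expression (-dCt) over all specimens, both
#' tissues pooled. Records missing the PSI are dropped.
#'
#' @param table a [PatientPairTable-class].
#' @param event event id (matching a `psi_<event>` column).
#' @return As [pearsonAssoc()].
#' @examples
#' sim <- simulatePatientPairs(12, seed = 1)
#' psiExpressionAssoc(sim$table, "exon")
#' @export
psiExpressionAssoc <- function(table, event) {
  stopifnot(is(table, "PatientPairTable"))
  r <- pairRecords(table)
  col <- paste0("psi_", event)
  if (!col %in% names(r))
    stop("event '", event, "' not present (no column ", col, ")",
         call. = FALSE)
  pearsonAssoc(negDeltaCt(r$ct_target, r$ct_reference), r[[col]])
}

#' Paired-delta association of splicing change with expression change
#'
#' For each patient with both tissues, computes `dPSI = PSI(LN) -
#' PSI(primary)` and `-ddCt` of snoRNA expression, then returns their
#' Pearson association. Patients missing a tissue are excluded (with their
#' ids messaged).
#'
#' @inheritParams psiExpressionAssoc
#' @return As [pearsonAssoc()].
#' @examples
#' sim <- simulatePatientPairs(12, seed = 1)
#' pairedDeltaAssoc(sim$table, "exon")
#' @export
pairedDeltaAssoc <- function(table, event) {
  stopifnot(is(table, "PatientPairTable"))
  wide <- .completePairs(table, event)
  if (nrow(wide) < 3L)
    stop("at least 3 complete pairs are required", call. = FALSE)
  col <- paste0("psi_", event)
  dPsi <- wide[[paste0(col, "_ln")]] - wide[[paste0(col, "_primary")]]
  nddct <- negDeltaDeltaCt(
    negDeltaCt(wide$ct_target_ln, wide$ct_reference_ln),
    negDeltaCt(wide$ct_target_primary, wide$ct_reference_primary))
  pearsonAssoc(nddct, dPsi)
}
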