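# Replicate-mean Ct for one (sample, role, rnaseh) record; NA replicates mark
# undetermined reactions and make the whole record undetermined.
.meanCt <- function(plate, sample, role, rnaseh = "na") {
  r <- plateRecords(plate)
  sel <- r$sample == sample & r$role == role & r$rnaseh == rnaseh
  if (!any(sel)) return(NULL)
  ct <- r$ct[sel]
  if (anyNA(ct)) return(NA_real_)
  mean(ct)
}

.requireCt <- function(ct, what) {
  if (is.null(ct))
    stop("missing qPCR record: ", what, call. = FALSE)
  ct
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `RQ = 2^-ddCt` with
#' `ddCt = (Ct_target - Ct_reference)_sample - (Ct_target - Ct_reference)_calibrator`,
#' Ct replicates averaged before differencing. Amplification efficiency is
#' taken as exact doubling. An undetermined target Ct in the sample reports
#' below-detection with the limiting value `RQ = 0`.
#'
#' @param plate a [QpcrPlate-class] with `rnaseh = "na"` records.
#' @param sample,calibrator sample ids on the plate.
#' @return List with `rq`, `deltaDeltaCt` and `belowDetection`.
#' @examples
#' plate <- QpcrPlate(data.frame(
#'   sample = rep(c("s", "c"), each = 2),
#'   target = c("sno", "ref", "sno", "ref"),
#'   role = c("target", "reference", "target", "reference"),
#'   rnaseh = "na", ct = c(24, 20, 25, 20)))
#' relativeQuantification(plate, "s", "c")$rq  # 2
#' @export
relativeQuantification <- function(plate, sample, calibrator) {
  stopifnot(is(plate, "QpcrPlate"))
  ctT <- .requireCt(.meanCt(plate, sample, "target"),
                    paste0("target Ct for sample '", sample, "'"))
  ctR <- .requireCt(.meanCt(plate, sample, "reference"),
                    paste0("reference Ct for sample '", sample, "'"))
  calT <- .requireCt(.meanCt(plate, calibrator, "target"),
                     paste0("target Ct for calibrator '", calibrator, "'"))
  calR <- .requireCt(.meanCt(plate, calibrator, "reference"),
                     paste0("reference Ct for calibrator '", calibrator, "'"))
  if (is.na(calT) || is.na(calR) || is.na(ctR))
    stop("undetermined Ct in reference/calibrator records", call. = FALSE)
  if (is.na(ctT))
    return(list(rq = 0, deltaDeltaCt = Inf, belowDetection = TRUE))
  ddct <- (ctT - ctR) - (calT - calR)
  list(rq = 2 ^ (-ddct), deltaDeltaCt = ddct, belowDetection = FALSE)
}

#' Percent 2'-O-methylation from a paired +/- RNase-H (Nm-VAQ) assay
#'
#' The RNase-H protection estimate of site methylation:
#' `ddCt = (Ct_target,+H - Ct_ref,+H) - (Ct_target,-H - Ct_ref,-H)` and
#' `percentMe = clamp(100 * 2^-ddCt, 0, 100)`. Ct replicates are averaged
#' per record before differencing; reference-gene shifts common to both
#' treatments cancel exactly. An undetermined +H target Ct (no surviving
#' template) reports 0% with `belowDetection = TRUE`.
#'
#' @param plate a [QpcrPlate-class] with `plus`/`minus` records for both the
#'   target and the reference gene of this sample.
#' @param sample sample id.
#' @return List with `sample`, `percentMe`, `deltaDeltaCt`, `replicateSd`
#'   (pooled replicate standard deviation, cycles) and `belowDetection`.
#' @examples
#' sim <- simulateNmvaqPlate(c(s = 0.5), ctNoiseSd = 0, seed = 1)
#' nmvaqPercentMethylation(sim$plate, "s")$percentMe  # 50
#' @export
nmvaqPercentMethylation <- function(plate, sample) {
  stopifnot(is(plate, "QpcrPlate"))
  ct <- list(
    tPlus = .requireCt(.meanCt(plate, sample, "target", "plus"),
                       paste0("target/+RNaseH record for '", sample, "'")),
    tMinus = .requireCt(.meanCt(plate, sample, "target", "minus"),
                        paste0("target/-RNaseH record for '", sample, "'")),
    rPlus = .requireCt(.meanCt(plate, sample, "reference", "plus"),
                       paste0("reference/+RNaseH record for '", sample, "'")),
    rMinus = .requireCt(.meanCt(plate, sample, "reference", "minus"),
                        paste0("reference/-RNaseH record for '", sample, "'")))
  if (is.na(ct$tMinus) || is.na(ct$rPlus) || is.na(ct$rMinus))
    stop("undetermined Ct outside the +RNaseH target record", call. = FALSE)
  r <- plateRecords(plate)
  sel <- r$sample == sample & r$rnaseh %in% c("plus", "minus")
  reps <- split(r$ct[sel], paste(r$role[sel], r$rnaseh[sel]))
  vars <- vapply(reps, function(x)
    if (sum(!is.na(x)) > 1L) stats::var(x, na.rm = TRUE) else 0, numeric(1))
  repSd <- sqrt(mean(vars))
  if (is.na(ct$tPlus))
    return(list(sample = sample, percentMe = 0, deltaDeltaCt = Inf,
                replicateSd = repSd, belowDetection = TRUE))
  ddct <- (ct$tPlus - ct$rPlus) - (ct$tMinus - ct$rMinus)
  list(sample = sample,
       percentMe = min(max(100 * 2 ^ (-ddct), 0), 100),
       deltaDeltaCt = ddct, replicateSd = repSd, belowDetection = FALSE)
}

#' Linearity of percent methylation across known RNA mixtures
#'
#' Ordinary least squares of measured percent methylation on the known
#' methylated fraction (both in percent), as used to validate that the
#' RNase-H protection estimate responds linearly to the true fraction.
#'
#' @param knownFraction known methylated fractions, in percent.
#' @param percentMe measured percent methylation.
#' @return List with `slope`, `intercept` and `rSquared`.
#' @examples
#' mixtureLinearityFit(c(0, 50, 100), c(0, 50, 100))
#' @export
mixtureLinearityFit <- function(knownFraction, percentMe) {
  if (length(knownFraction) != length(percentMe))
    stop("knownFraction and percentMe must be paired", call. = FALSE)
  if (length(unique(knownFraction)) < 2L)
    stop("at least 2 distinct known fractions are required", call. = FALSE)
  fit <- stats::lm(percentMe ~ knownFraction)
  co <- unname(stats::coef(fit))
  ssTot <- sum((percentMe - mean(percentMe))^2)
  r2 <- if (ssTot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ssTot
  list(slope = co[2], intercept = co[1], rSquared = r2)
}
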