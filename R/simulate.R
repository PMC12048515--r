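#' Microarray study design for the multi-site tumour simulator
#'
#' Describes the probe panel, the replicate-group layout over tumour sites and
#' the planted AxLN-specific signature used by [simulateMicroarray()]. The
#' default layout mirrors the profiled study: two baseline quadruplicates
#' (8 samples), two mammary-fat-pad (MFP) triplets (6), three axillary
#' lymph-node (AxLN) triplets (9) and three AxLN-derived lung-metastasis
#' (AxLN-LuM) triplets (9) - 32 samples in all.
#'
#' @param nProbes number of probes on the array.
#' @param snoRnaFraction fraction of probes annotated as snoRNA (default
#'   0.124, i.e. 1245 of 10043 as on the profiled panel).
#' @param groups data.frame with columns `group_id`, `site_category`
#'   (`baseline`/`MFP`/`AxLN`/`AxLN-LuM`) and `replicates` (all >= 2).
#' @param plantedSignature data.frame with columns `probe_id`, `direction`
#'   (`"+"`/`"-"`) and `fold` (magnitude >= 1) naming the probes perturbed in
#'   AxLN samples only. `NULL` plants the default 30-probe signature (20
#'   snoRNA, 10 other probes, mostly up-regulated) at fold `plantedFold`.
#' @param plantedFold fold magnitude used for the default signature.
#' @param noiseSd standard deviation of the log2-scale intensity noise.
#' @param seed integer seed consumed by [simulateMicroarray()].
#' @return A list of class `MicroarrayDesign`.
#' @examples
#' d <- microarrayDesign(nProbes = 200)
#' sum(d$groups$replicates)  # 32 samples
#' @export
microarrayDesign <- function(nProbes = 1000,
                             snoRnaFraction = 0.124,
                             groups = NULL,
                             plantedSignature = NULL,
                             plantedFold = 2,
                             noiseSd = 0.05,
                             seed = 1L) {
  nProbes <- .assertCount(nProbes, "nProbes", min = 1L)
  .assertProportion(snoRnaFraction, "snoRnaFraction")
  if (snoRnaFraction <= 0 || snoRnaFraction >= 1)
    stop("snoRnaFraction must lie strictly in (0, 1)", call. = FALSE)
  if (is.null(groups)) {
    groups <- data.frame(
      group_id = c("base1", "base2", "mfp1", "mfp2",
                   "axln1", "axln2", "axln3", "lum1", "lum2", "lum3"),
      site_category = c("baseline", "baseline", "MFP", "MFP",
                        "AxLN", "AxLN", "AxLN",
                        "AxLN-LuM", "AxLN-LuM", "AxLN-LuM"),
      replicates = c(4L, 4L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L))
  }
  if (!all(c("group_id", "site_category", "replicates") %in% names(groups)))
    stop("groups needs columns group_id, site_category, replicates",
         call. = FALSE)
  if (any(groups$replicates < 2L))
    stop("replicates must be >= 2 for every group", call. = FALSE)
  if (!all(groups$site_category %in% .SITE_CATEGORIES))
    stop("site_category must be one of: ",
         paste(.SITE_CATEGORIES, collapse = ", "), call. = FALSE)
  probeIds <- sprintf("P%05d", seq_len(nProbes))
  nSno <- max(1L, round(snoRnaFraction * nProbes))
  probeClass <- rep("other", nProbes)
  probeClass[seq_len(nSno)] <- "snoRNA"
  if (is.null(plantedSignature)) {
    .assertPositive(plantedFold - 1, "plantedFold - 1", strict = FALSE)
    nSig <- min(30L, nProbes)
    nSigSno <- min(20L, nSno, nSig)
    ids <- c(probeIds[seq_len(nSigSno)],
             probeIds[probeClass == "other"][seq_len(nSig - nSigSno)])
    ids <- ids[!is.na(ids)]
    dirs <- rep(c("+", "-"), c(ceiling(0.8 * length(ids)),
                               length(ids) - ceiling(0.8 * length(ids))))
    plantedSignature <- data.frame(probe_id = ids, direction = dirs,
                                   fold = plantedFold)
  }
  if (!all(plantedSignature$probe_id %in% probeIds))
    stop("plantedSignature probes must be a subset of the probe ids",
         call. = FALSE)
  if (!all(plantedSignature$direction %in% c("+", "-")))
    stop("plantedSignature direction must be '+' or '-'", call. = FALSE)
  if (any(plantedSignature$fold < 1))
    stop("plantedSignature fold magnitudes must be >= 1", call. = FALSE)
  .assertPositive(noiseSd, "noiseSd", strict = FALSE)
  structure(list(nProbes = nProbes, snoRnaFraction = snoRnaFraction,
                 probeIds = probeIds, probeClass = probeClass,
                 groups = groups, plantedSignature = plantedSignature,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "MicroarrayDesign")
}

#' Simulate a multi-site tumour microarray with a planted AxLN signature
#'
#' Draws per-probe baseline intensities on a realistic linear scale, applies
#' the planted fold (up or down) to signature probes in AxLN samples only, and
#' multiplies by `2^noise` with `noise ~ Normal(0, noiseSd)` on the log2
#' scale. Identical designs (including seed) give bit-identical matrices.
#'
#' @param design a [microarrayDesign()] object.
#' @return A list with elements `matrix` (a
#'   [ProbeExpressionExperiment-class]) and `truth` (a
#'   [PlantedTruth-class] recording the signature and noise level).
#' @examples
#' sim <- simulateMicroarray(microarrayDesign(nProbes = 50, noiseSd = 0))
#' dim(sim$matrix)
#' @export
simulateMicroarray <- function(design) {
  if (!inherits(design, "MicroarrayDesign"))
    stop("design must come from microarrayDesign()", call. = FALSE)
  g <- design$groups
  sampleGroup <- rep(g$group_id, g$replicates)
  sampleSite <- rep(g$site_category, g$replicates)
  sampleIds <- paste0(sampleGroup, "_r", unlist(lapply(g$replicates, seq_len)))
  n <- design$nProbes
  m <- length(sampleIds)
  sig <- design$plantedSignature
  foldVec <- rep(1, n)
  names(foldVec) <- design$probeIds
  foldVec[sig$probe_id] <- ifelse(sig$direction == "+", sig$fold, 1 / sig$fold)
  values <- withSeed(design$seed, {
    base <- 2 ^ stats::runif(n, 5, 12)
    lin <- matrix(base, n, m)
    lin[, sampleSite == "AxLN"] <- lin[, sampleSite == "AxLN", drop = FALSE] *
      foldVec
    noise <- matrix(stats::rnorm(n * m, 0, design$noiseSd), n, m)
    lin * 2 ^ noise
  })
  dimnames(values) <- list(design$probeIds, sampleIds)
  mat <- ProbeExpressionExperiment(values, sampleGroup, sampleSite,
                                   design$probeClass)
  truth <- PlantedTruth("microarray", list(
    planted_probes = sig$probe_id, planted_direction = sig$direction,
    planted_fold = sig$fold, noise_sd = design$noiseSd,
    n_probes = n, snoRNA_fraction = design$snoRnaFraction,
    seed = design$seed))
  list(matrix = mat, truth = truth)
}

#' Simulate an Nm-VAQ RNase-H protection qPCR plate
#'
#' Emulates the paired +/- RNase-H assay: without RNase H a fixed template
#' amount amplifies at a basal Ct; with RNase H only the fraction
#' `m + (1 - m) * (1 - cleavageEfficiency)` of target templates survives
#' cleavage (methylated molecules are fully protected), shifting the target Ct
#' by `-log2(surviving fraction)`. The reference gene is untouched by RNase H.
#' Gaussian noise is added to every Ct replicate; each record carries
#' `nReplicates` technical replicates (default 3, standard qPCR triplicates).
#' A surviving fraction of zero yields an undetermined (`NA`) Ct.
#'
#' @param trueMe named numeric vector of true methylated fractions in
#'   \[0, 1\], one per sample.
#' @param cleavageEfficiency fraction of unmethylated templates cleaved by
#'   RNase H (1 = complete cleavage).
#' @param ctNoiseSd standard deviation of the per-replicate Ct noise (cycles).
#' @param seed integer seed.
#' @param nReplicates technical Ct replicates per record.
#' @param baseCtTarget,baseCtReference basal Ct of target and reference gene.
#' @return List with `plate` (a [QpcrPlate-class]) and `truth`
#'   (a [PlantedTruth-class] with the true fractions).
#' @examples
#' sim <- simulateNmvaqPlate(c(s1 = 1, s2 = 0.5), ctNoiseSd = 0, seed = 1)
#' nmvaqPercentMethylation(sim$plate, "s2")$percentMe  # 50
#' @export
simulateNmvaqPlate <- function(trueMe, cleavageEfficiency = 1,
                               ctNoiseSd = 0.1, seed = 1L,
                               nReplicates = 3L,
                               baseCtTarget = 22, baseCtReference = 18) {
  .assertProportion(trueMe, "trueMe")
  .assertProportion(cleavageEfficiency, "cleavageEfficiency")
  .assertPositive(ctNoiseSd, "ctNoiseSd", strict = FALSE)
  nReplicates <- .assertCount(nReplicates, "nReplicates", min = 1L)
  if (is.null(names(trueMe)))
    names(trueMe) <- sprintf("sample%02d", seq_along(trueMe))
  surviving <- trueMe + (1 - trueMe) * (1 - cleavageEfficiency)
  rows <- list()
  for (s in names(trueMe)) {
    ctPlus <- if (surviving[[s]] > 0)
      baseCtTarget - log2(surviving[[s]]) else NA_real_
    rows[[s]] <- data.frame(
      sample = s,
      target = rep(c("assay", "assay", "ref", "ref"), each = nReplicates),
      role = rep(c("target", "target", "reference", "reference"),
                 each = nReplicates),
      rnaseh = rep(c("minus", "plus", "minus", "plus"), each = nReplicates),
      ct = rep(c(baseCtTarget, ctPlus, baseCtReference, baseCtReference),
               each = nReplicates))
  }
  rec <- do.call(rbind, rows)
  rec$ct <- withSeed(seed, {
    noise <- stats::rnorm(nrow(rec), 0, ctNoiseSd)
    ifelse(is.na(rec$ct), NA_real_, rec$ct + noise)
  })
  rownames(rec) <- NULL
  truth <- PlantedTruth("nmvaq", list(
    true_me = unname(trueMe), sample = names(trueMe),
    cleavage_efficiency = cleavageEfficiency, ct_noise_sd = ctNoiseSd,
    n_replicates = nReplicates, seed = as.integer(seed)))
  list(plate = QpcrPlate(rec), truth = truth)
}

.DEFAULT_WT_SITES <- c(21L, 33L, 43L, 47L, 53L, 60L, 70L, 77L)

#' Simulate RibOxi-seq 3'-end count tracks with planted methylation sites
#'
#' Per-position counts are `Poisson(backgroundRate * depth)` at unmethylated
#' positions, multiplied by the site's enrichment fold at planted methylation
#' sites of that genotype. The default fixture is a 106-nt U6-like transcript
#' with eight methylated positions in the wild type (including position 60)
#' and seven in the knockout (position 60 absent), mirroring the loss of a
#' single snoRNA-guided site.
#'
#' @param length transcript length (nt).
#' @param backgroundRate expected 3'-end rate at unmethylated positions.
#' @param sites named list, one element per genotype, each a named numeric
#'   vector `position -> enrichment fold`. Positions must be interior
#'   (2..length-1).
#' @param depth depth multiplier; expected background count per position is
#'   `backgroundRate * depth` (0 gives all-zero tracks).
#' @param seed integer seed.
#' @return List with `tracks` (named list of [EndCountTrack-class], one per
#'   genotype) and `truth` (a [PlantedTruth-class]).
#' @examples
#' sim <- simulateEndCountTracks(seed = 7)
#' names(sim$tracks)  # "WT" "KO"
#' @export
simulateEndCountTracks <- function(length = 106L, backgroundRate = 5,
                                   sites = NULL, depth = 10, seed = 1L) {
  length <- .assertCount(length, "length", min = 3L)
  .assertPositive(backgroundRate, "backgroundRate")
  .assertPositive(depth, "depth", strict = FALSE)
  if (is.null(sites)) {
    wt <- stats::setNames(rep(20, length(.DEFAULT_WT_SITES)),
                          .DEFAULT_WT_SITES)
    sites <- list(WT = wt, KO = wt[names(wt) != "60"])
  }
  for (g in names(sites)) {
    pos <- as.integer(names(sites[[g]]))
    if (any(pos < 2L) || any(pos > length - 1L))
      stop("site positions must be interior (2..length-1); offending genotype: ",
           g, call. = FALSE)
  }
  tracks <- withSeed(seed, {
    lapply(sites, function(siteMap) {
      lambda <- rep(backgroundRate * depth, length)
      pos <- as.integer(names(siteMap))
      lambda[pos] <- lambda[pos] * unname(siteMap)
      EndCountTrack("U6-like", stats::rpois(length, lambda))
    })
  })
  truth <- PlantedTruth("riboxi", list(
    length = length, background_rate = backgroundRate, depth = depth,
    sites = lapply(sites, function(s)
      list(position = as.integer(names(s)), fold = unname(s))),
    seed = as.integer(seed)))
  list(tracks = tracks, truth = truth)
}

#' Simulate per-replicate splice-junction counts with planted group PSI
#'
#' Inclusion counts are `Binomial(coverage, PSI_group)` independently per
#' replicate; skipping counts are the complement. Effective lengths are 1
#' unless supplied.
#'
#' @param nEvents number of events (recycled over `psiPairs` rows if needed).
#' @param replicatesPerGroup replicates in each of the two groups.
#' @param coverage junction reads per replicate and event.
#' @param psiPairs two-column matrix/data.frame of per-event (PSI_A, PSI_B)
#'   in \[0, 1\]; a single row is recycled to all events.
#' @param seed integer seed.
#' @param eventTypes event class per event (recycled); default `"CE"`.
#' @param lenInc,lenSkip effective lengths of the inclusion/skipping forms.
#' @return List with `table` (a [SpliceEventTable-class]) and `truth`.
#' @examples
#' sim <- simulateSpliceEvents(5, psiPairs = cbind(0.9, 0.5), seed = 1)
#' head(eventCounts(sim$table))
#' @export
simulateSpliceEvents <- function(nEvents, replicatesPerGroup = 3L,
                                 coverage = 100L, psiPairs = cbind(0.5, 0.5),
                                 seed = 1L, eventTypes = "CE",
                                 lenInc = 1, lenSkip = 1) {
  nEvents <- .assertCount(nEvents, "nEvents", min = 1L)
  replicatesPerGroup <- .assertCount(replicatesPerGroup, "replicatesPerGroup",
                                     min = 1L)
  coverage <- .assertCount(coverage, "coverage", min = 0L)
  psiPairs <- as.matrix(psiPairs)
  .assertProportion(psiPairs, "psiPairs")
  if (nrow(psiPairs) == 1L)
    psiPairs <- psiPairs[rep(1L, nEvents), , drop = FALSE]
  if (nrow(psiPairs) != nEvents)
    stop("psiPairs must have one row, or one row per event", call. = FALSE)
  eventIds <- sprintf("E%04d", seq_len(nEvents))
  eventTypes <- rep_len(eventTypes, nEvents)
  rows <- withSeed(seed, {
    out <- vector("list", 2L)
    for (gi in 1:2) {
      incl <- matrix(stats::rbinom(nEvents * replicatesPerGroup, coverage,
                                   rep(psiPairs[, gi], replicatesPerGroup)),
                     nEvents, replicatesPerGroup)
      out[[gi]] <- data.frame(
        event_id = rep(eventIds, replicatesPerGroup),
        gene_id = rep(sub("^E", "G", eventIds), replicatesPerGroup),
        event_type = rep(eventTypes, replicatesPerGroup),
        group = c("A", "B")[gi],
        replicate = rep(seq_len(replicatesPerGroup), each = nEvents),
        inclusion = as.vector(incl),
        skipping = coverage - as.vector(incl),
        len_inc = lenInc, len_skip = lenSkip)
    }
    out
  })
  tab <- SpliceEventTable(do.call(rbind, rows))
  truth <- PlantedTruth("events", list(
    event_id = eventIds, psi_A = psiPairs[, 1], psi_B = psiPairs[, 2],
    coverage = coverage, replicates_per_group = replicatesPerGroup,
    seed = as.integer(seed)))
  list(table = tab, truth = truth)
}

#' Simulate intron read counts with group-level retention ratios
#'
#' Per-intron true retention ratios are Beta-distributed around each group
#' mean with concentration `1/dispersion` (dispersion -> 0 concentrates mass
#' at the mean); intron-included reads are `Binomial(totalReads, IRR)`.
#'
#' @param nIntrons introns per group.
#' @param groupIrr named numeric vector of group mean retention ratios in
#'   (0, 1).
#' @param dispersion Beta dispersion (inverse concentration), > 0.
#' @param totalReads reads covering each intron.
#' @param seed integer seed.
#' @return List with `table` (data.frame: `intron_id`, `group`,
#'   `intron_reads`, `total_reads`) and `truth`.
#' @examples
#' sim <- simulateIntronCounts(100, c(WT = 0.3, KO = 0.15), seed = 2)
#' head(sim$table)
#' @export
simulateIntronCounts <- function(nIntrons, groupIrr = c(A = 0.3, B = 0.15),
                                 dispersion = 0.05, totalReads = 100L,
                                 seed = 1L) {
  nIntrons <- .assertCount(nIntrons, "nIntrons", min = 1L)
  if (any(groupIrr <= 0) || any(groupIrr >= 1))
    stop("groupIrr means must lie strictly in (0, 1)", call. = FALSE)
  .assertPositive(dispersion, "dispersion")
  totalReads <- .assertCount(totalReads, "totalReads", min = 1L)
  if (is.null(names(groupIrr)))
    names(groupIrr) <- LETTERS[seq_along(groupIrr)]
  tab <- withSeed(seed, {
    do.call(rbind, lapply(names(groupIrr), function(g) {
      mu <- groupIrr[[g]]
      conc <- 1 / dispersion
      irr <- stats::rbeta(nIntrons, mu * conc, (1 - mu) * conc)
      data.frame(intron_id = sprintf("I%05d", seq_len(nIntrons)),
                 group = g,
                 intron_reads = stats::rbinom(nIntrons, totalReads, irr),
                 total_reads = totalReads)
    }))
  })
  rownames(tab) <- NULL
  truth <- PlantedTruth("introns", list(
    group = names(groupIrr), group_irr = unname(groupIrr),
    dispersion = dispersion, total_reads = totalReads,
    n_introns = nIntrons, seed = as.integer(seed)))
  list(table = tab, truth = truth)
}

#' Simulate matched primary/lymph-node patient pairs
#'
#' Each patient receives a primary and an LN record. SnoRNA expression
#' (-dCt) is drawn uniformly on `expressionRange` independently per tissue;
#' the event PSI follows the planted linear relation
#' `PSI = clamp(intercept + slope * (-dCt) + noise, 0, 1)`.
#'
#' @param nPatients number of patients (>= 3).
#' @param slope PSI change per -dCt unit.
#' @param intercept PSI at -dCt = 0.
#' @param noiseSd standard deviation of the PSI noise.
#' @param expressionRange length-2 range of -dCt values.
#' @param seed integer seed.
#' @param event event label used for the `psi_<event>` column.
#' @param ctReference reference-gene Ct (constant; the target Ct is derived
#'   from the drawn -dCt).
#' @return List with `table` (a [PatientPairTable-class]) and `truth`.
#' @examples
#' sim <- simulatePatientPairs(24, seed = 3)
#' pairRecords(sim$table)[1:4, ]
#' @export
simulatePatientPairs <- function(nPatients = 24L, slope = 0.05,
                                 intercept = 0.5, noiseSd = 0.05,
                                 expressionRange = c(-5, 5), seed = 1L,
                                 event = "exon", ctReference = 20) {
  nPatients <- .assertCount(nPatients, "nPatients", min = 3L)
  .assertPositive(noiseSd, "noiseSd", strict = FALSE)
  if (length(expressionRange) != 2L || diff(expressionRange) <= 0)
    stop("expressionRange must be an increasing length-2 interval",
         call. = FALSE)
  n <- 2L * nPatients
  tab <- withSeed(seed, {
    negDct <- stats::runif(n, expressionRange[1], expressionRange[2])
    psi <- pmin(pmax(intercept + slope * negDct +
                       stats::rnorm(n, 0, noiseSd), 0), 1)
    data.frame(patient_id = rep(sprintf("PT%02d", seq_len(nPatients)), 2L),
               tissue = rep(c("primary", "LN"), each = nPatients),
               ct_target = ctReference - negDct,
               ct_reference = ctReference,
               psi = psi)
  })
  names(tab)[names(tab) == "psi"] <- paste0("psi_", event)
  truth <- PlantedTruth("pairs", list(
    slope = slope, intercept = intercept, noise_sd = noiseSd,
    expression_range = expressionRange, n_patients = nPatients,
    event = event, seed = as.integer(seed)))
  list(table = PatientPairTable(tab), truth = truth)
}
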