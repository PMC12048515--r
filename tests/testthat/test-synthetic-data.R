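test_that("every generator is bit-identical under a repeated seed", {
  d <- microarrayDesign(nProbes = 60, seed = 11L)
  expect_identical(assay(simulateMicroarray(d)$matrix, "exprs"),
                   assay(simulateMicroarray(d)$matrix, "exprs"))
  expect_identical(
    plateRecords(simulateNmvaqPlate(c(a = .3, b = .7), seed = 4L)$plate),
    plateRecords(simulateNmvaqPlate(c(a = .3, b = .7), seed = 4L)$plate))
  expect_identical(
    lapply(simulateEndCountTracks(seed = 9L)$tracks, counts),
    lapply(simulateEndCountTracks(seed = 9L)$tracks, counts))
  expect_identical(
    eventCounts(simulateSpliceEvents(10, seed = 2L)$table),
    eventCounts(simulateSpliceEvents(10, seed = 2L)$table))
  expect_identical(simulateIntronCounts(50, seed = 3L)$table,
                   simulateIntronCounts(50, seed = 3L)$table)
  expect_identical(pairRecords(simulatePatientPairs(10, seed = 5L)$table),
                   pairRecords(simulatePatientPairs(10, seed = 5L)$table))
})

test_that("generators leave the session RNG state untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(simulateMicroarray(microarrayDesign(nProbes = 20, seed = 1L)))
  invisible(simulateIntronCounts(10, seed = 99L))
  expect_identical(.Random.seed, before)
})

test_that("noise-free microarray plants exact folds in AxLN samples only", {
  d <- microarrayDesign(nProbes = 80, noiseSd = 0, plantedFold = 2,
                        seed = 7L)
  sim <- simulateMicroarray(d)
  v <- assay(sim$matrix, "exprs")
  site <- siteCategories(sim$matrix)
  tr <- truthParameters(sim$truth)
  up <- tr$planted_probes[tr$planted_direction == "+"]
  down <- tr$planted_probes[tr$planted_direction == "-"]
  baseVal <- v[, site == "baseline"][, 1]
  for (s in which(site == "AxLN")) {
    expect_equal(v[up, s], baseVal[up] * 2)
    expect_equal(v[down, s], baseVal[down] / 2)
  }
  # non-AxLN samples carry the unperturbed base level
  for (s in which(site != "AxLN"))
    expect_equal(v[, s], baseVal)
})

test_that("the default design yields the study's 32-sample layout", {
  sim <- simulateMicroarray(microarrayDesign(nProbes = 30))
  site <- siteCategories(sim$matrix)
  expect_identical(ncol(sim$matrix), 32L)
  expect_identical(
    unname(c(table(site)[c("baseline", "MFP", "AxLN", "AxLN-LuM")])),
    c(8L, 6L, 9L, 9L))
})

test_that("design validation names offending fields", {
  expect_error(microarrayDesign(nProbes = 0), "nProbes")
  expect_error(microarrayDesign(snoRnaFraction = 0), "snoRnaFraction")
  g <- data.frame(group_id = "b", site_category = "baseline",
                  replicates = 1L)
  expect_error(microarrayDesign(groups = g), "replicates")
  expect_error(
    microarrayDesign(nProbes = 10,
                     plantedSignature = data.frame(probe_id = "NOPE",
                                                   direction = "+",
                                                   fold = 2)),
    "subset")
})

test_that("Nm-VAQ plate encodes protection in the +RNaseH target Ct", {
  # full protection: +H and -H target Ct equal
  full <- simulateNmvaqPlate(c(s = 1), cleavageEfficiency = 1,
                             ctNoiseSd = 0, seed = 1L)$plate
  r <- plateRecords(full)
  tPlus <- mean(r$ct[r$role == "target" & r$rnaseh == "plus"])
  tMinus <- mean(r$ct[r$role == "target" & r$rnaseh == "minus"])
  expect_equal(tPlus, tMinus)
  # half methylated, complete cleavage: exactly one extra cycle
  half <- simulateNmvaqPlate(c(s = 0.5), cleavageEfficiency = 1,
                             ctNoiseSd = 0, seed = 1L)$plate
  r <- plateRecords(half)
  expect_equal(mean(r$ct[r$role == "target" & r$rnaseh == "plus"]) -
                 mean(r$ct[r$role == "target" & r$rnaseh == "minus"]), 1)
  # reference gene untouched by RNase H
  expect_equal(r$ct[r$role == "reference" & r$rnaseh == "plus"],
               r$ct[r$role == "reference" & r$rnaseh == "minus"])
})

test_that("end-count simulator respects depth, edges and genotype sites", {
  zero <- simulateEndCountTracks(depth = 0, seed = 1L)
  expect_true(all(vapply(zero$tracks, function(t) sum(counts(t)),
                         numeric(1)) == 0))
  expect_error(simulateEndCountTracks(length = 50,
                                      sites = list(WT = c("50" = 10))),
               "interior")
  tr <- truthParameters(simulateEndCountTracks(seed = 1L)$truth)
  expect_setequal(setdiff(tr$sites$WT$position, tr$sites$KO$position), 60L)
  # enrichment fold 1 everywhere: nothing rises above the calling bar
  flat <- simulateEndCountTracks(sites = list(A = c("60" = 1)), seed = 8L)
  expect_identical(nrow(callSites(nmScoreTrack(flat$tracks$A))), 0L)
})

test_that("splice-event counts are binomial draws bounded by coverage", {
  sim <- simulateSpliceEvents(25, replicatesPerGroup = 2L, coverage = 50L,
                              psiPairs = cbind(0.8, 0.2), seed = 6L)
  e <- eventCounts(sim$table)
  expect_true(all(e$inclusion + e$skipping == 50L))
  expect_true(mean(e$inclusion[e$group == "A"]) >
                mean(e$inclusion[e$group == "B"]))
  expect_error(simulateSpliceEvents(5, psiPairs = cbind(1.2, 0)), "\\[0, 1\\]")
})

test_that("intron IRR concentrates at the group mean as dispersion vanishes", {
  tight <- simulateIntronCounts(400, c(A = 0.4), dispersion = 1e-4,
                                totalReads = 1000L, seed = 2L)$table
  loose <- simulateIntronCounts(400, c(A = 0.4), dispersion = 0.5,
                                totalReads = 1000L, seed = 2L)$table
  sdOf <- function(tab) sd(tab$intron_reads / tab$total_reads)
  expect_lt(sdOf(tight), 0.03)
  expect_gt(sdOf(loose), 5 * sdOf(tight))
  expect_error(simulateIntronCounts(10, c(A = 0)), "strictly")
})

test_that("patient pairs inherit the planted linear PSI-expression relation", {
  sim <- simulatePatientPairs(12, slope = 0.05, noiseSd = 0, seed = 3L)
  expect_equal(psiExpressionAssoc(sim$table, "exon")$r, 1)
  expect_equal(pairedDeltaAssoc(sim$table, "exon")$r, 1)
  # slope 0: no association on average across seeds
  rs <- vapply(1:20, function(s) {
    t0 <- simulatePatientPairs(24, slope = 0, noiseSd = 0.05, seed = s)$table
    psiExpressionAssoc(t0, "exon")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(simulatePatientPairs(2), "nPatients")
})

test_that("planted truth round-trips losslessly through its sidecar", {
  sims <- list(
    simulateMicroarray(microarrayDesign(nProbes = 20, seed = 2L))$truth,
    simulateNmvaqPlate(c(x = 0.25), seed = 2L)$truth,
    simulateEndCountTracks(seed = 2L)$truth,
    simulateSpliceEvents(4, seed = 2L)$truth,
    simulateIntronCounts(5, seed = 2L)$truth,
    simulatePatientPairs(5, seed = 2L)$truth)
  for (tr in sims) {
    f <- withr::local_tempfile(fileext = ".json")
    writePlantedTruth(tr, f)
    back <- readPlantedTruth(f)
    expect_identical(truthComponent(back), truthComponent(tr))
    expect_equal(truthParameters(back), truthParameters(tr))
  }
})

test_that("generated tables satisfy their consuming validity contracts", {
  expect_true(validObject(
    simulateMicroarray(microarrayDesign(nProbes = 15))$matrix))
  expect_true(validObject(simulateNmvaqPlate(c(a = 0.5))$plate))
  expect_true(all(vapply(simulateEndCountTracks()$tracks, validObject,
                         logical(1))))
  expect_true(validObject(simulateSpliceEvents(3)$table))
  expect_true(validObject(simulatePatientPairs(5)$table))
})
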