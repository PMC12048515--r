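test_that("PSI from counts honours effective-length normalisation", {
  expect_equal(psiFromCounts(50, 50), 0.5)
  expect_equal(psiFromCounts(0, 10), 0)
  expect_equal(psiFromCounts(60, 20, lI = 3, lS = 1), 0.5)
  expect_true(is.na(psiFromCounts(0, 0)))
  expect_error(psiFromCounts(-1, 5), ">= 0")
  set.seed(2)
  psi <- psiFromCounts(rpois(100, 20), rpois(100, 20),
                       runif(100, 0.5, 3), runif(100, 0.5, 3))
  expect_true(all(psi >= 0 & psi <= 1, na.rm = TRUE))
})

test_that("identical groups give zero delta PSI and no significance", {
  e <- eventCounts(simulateSpliceEvents(8, coverage = 100, seed = 4L)$table)
  e$inclusion <- rep(rep(c(40L, 70L), 4), length.out = nrow(e))
  e$skipping <- 100L - e$inclusion
  # force group B to mirror group A exactly
  e$inclusion[e$group == "B"] <- e$inclusion[e$group == "A"]
  e$skipping[e$group == "B"] <- e$skipping[e$group == "A"]
  res <- testEvents(SpliceEventTable(e))
  expect_true(all(res$delta_psi == 0))
  expect_true(all(!res$significant))
})

test_that("a planted strong event reaches significance at study-like depth", {
  sim <- simulateSpliceEvents(12, replicatesPerGroup = 3L, coverage = 200L,
                              psiPairs = cbind(0.9, 0.5), seed = 10L)
  res <- testEvents(sim$table)
  expect_true(all(res$significant))
  expect_true(all(abs(res$delta_psi - (-0.4)) < 0.1))
})

test_that("a shallow single-replicate event cannot satisfy the count rule", {
  sim <- simulateSpliceEvents(5, replicatesPerGroup = 1L, coverage = 2L,
                              psiPairs = cbind(0.9, 0.1), seed = 3L)
  res <- testEvents(sim$table)
  # total inclusion + skipping = 4 across both groups: both tallies < 5
  expect_true(all(res$total_inclusion < 5 & res$total_skipping < 5))
  expect_true(all(!res$significant))
})

test_that("reported FDR equals a from-scratch Benjamini-Hochberg", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
  }
  sim <- simulateSpliceEvents(30, psiPairs = cbind(runif(30), runif(30)),
                              seed = 12L)
  res <- testEvents(sim$table)
  expect_equal(res$fdr, bhOracle(res$p_value), tolerance = 1e-12)
})

test_that("swapping group labels negates delta PSI, preserving p, q, flags", {
  sim <- simulateSpliceEvents(15, psiPairs = cbind(runif(15), runif(15)),
                              coverage = 80L, seed = 9L)
  e <- eventCounts(sim$table)
  eSwap <- e
  eSwap$group <- ifelse(e$group == "A", "B", "A")
  a <- testEvents(sim$table)
  b <- testEvents(SpliceEventTable(eSwap))
  expect_equal(b$delta_psi, -a$delta_psi)
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$fdr, a$fdr)
  expect_identical(b$significant, a$significant)
})

test_that("the significance filter matches the hand-applied rule", {
  toy <- data.frame(
    event_id = paste0("E", 1:5), gene_id = paste0("G", 1:5),
    event_type = c("CE", "CE", "MXE", "RI", "A3SS"),
    delta_psi = c(0.15, 0.05, 0.15, 0.15, 0.10),
    fdr = c(0.01, 0.01, 0.10, 0.01, 0.049),
    total_inclusion = c(9, 9, 9, 4, 5),
    total_skipping = c(3, 9, 9, 4, 0))
  out <- filterSignificant(toy)
  expect_identical(out$events$event_id, c("E1", "E5"))
  expect_identical(out$typeTally[["CE"]], 1L)
  expect_identical(out$typeTally[["A3SS"]], 1L)
  expect_setequal(out$genes, c("G1", "G5"))
  # empty input and all-null q
  expect_identical(nrow(filterSignificant(toy[0, ])$events), 0L)
  toy$fdr <- 1
  expect_identical(nrow(filterSignificant(toy)$events), 0L)
})

test_that("the filter equals the rule oracle on random tables", {
  set.seed(123)
  for (i in 1:200) {
    tab <- randomResultTable(sample(1:30, 1))
    got <- filterSignificant(tab)
    expect_identical(got$events$event_id,
                     tab$event_id[filterRuleOracle(tab)])
  }
})

test_that("overlap enrichment delegates correctly and validates containment", {
  bg <- sprintf("g%03d", 1:60)
  expect_equal(overlapEnrichment(bg[1:10], bg[21:30], bg)$pUpper, 1)
  same <- overlapEnrichment(bg, bg, bg)
  expect_equal(same$fold, 1)
  # small instance against exhaustive enumeration
  got <- overlapEnrichment(bg[1:4], bg[c(1, 2, 5, 6, 7)], bg[1:12])
  expect_equal(got$pUpper, enumHyperTail(12, 4, 5, 2), tolerance = 1e-12)
  expect_error(overlapEnrichment(c(bg[1], "zzz"), bg[1:3], bg), "contained")
})

test_that("IRR, splicing efficiency and the KS comparison follow definitions", {
  tab <- data.frame(intron_id = c("i1", "i2", "i1", "i2"),
                    group = c("A", "A", "B", "B"),
                    intron_reads = c(20L, 20L, 10L, 10L),
                    total_reads = 100L)
  out <- intronRetention(tab)
  expect_equal(out$irr$irr, c(0.2, 0.2, 0.1, 0.1))
  expect_equal(unname(out$efficiency["A"]), 0.8)
  # identical group samples: D = 0, p = 1
  tab$intron_reads <- 15L
  same <- intronRetention(tab)
  expect_equal(same$ks$statistic, 0)
  expect_equal(same$ks$p_value, 1)
})

test_that("efficiency identity is exact and monotone in added intron reads", {
  sim <- simulateIntronCounts(300, c(A = 0.25, B = 0.4), seed = 6L)
  out <- intronRetention(sim$table)
  for (g in c("A", "B"))
    expect_identical(unname(out$efficiency[g]),
                     1 - mean(out$irr$irr[out$irr$group == g]))
  bumped <- sim$table
  bumped$intron_reads <- pmin(bumped$intron_reads + 5L, bumped$total_reads)
  out2 <- intronRetention(bumped)
  expect_true(all(out2$efficiency < out$efficiency))
})

test_that("zero-total introns are dropped with a count; pure flag respected", {
  tab <- data.frame(intron_id = paste0("i", 1:4),
                    group = c("A", "A", "B", "B"),
                    intron_reads = c(5L, 0L, 2L, 3L),
                    total_reads = c(10L, 0L, 10L, 10L))
  expect_message(out <- intronRetention(tab), "dropped")
  expect_identical(out$dropped, 1L)
  expect_identical(nrow(out$irr), 3L)
  tab$total_reads[2] <- 10L
  tab$pure <- c(TRUE, FALSE, TRUE, TRUE)
  expect_identical(nrow(intronRetention(tab)$irr), 3L)
})

test_that("a planted IRR shift is detected by the KS test", {
  sim <- simulateIntronCounts(2000, c(A = 0.30, B = 0.15), seed = 41L)
  out <- intronRetention(sim$table)
  expect_lt(out$ks$p_value, 1e-4)
  # lower-IRR group has the higher splicing efficiency
  expect_gt(out$efficiency[["B"]], out$efficiency[["A"]])
})

test_that("gel densitometry PSI is the inclusion band fraction", {
  expect_equal(gelPsi(300, 100), 0.75)
  expect_equal(gelPsi(50, 50), 0.5)
  expect_equal(gelPsi(10, 0), 1)
  expect_true(is.na(gelPsi(0, 0)))
  expect_error(gelPsi(-1, 5), ">= 0")
})
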