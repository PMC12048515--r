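# A small hand-built matrix: 8 baseline samples (two quadruplicate groups)
# plus one triplet per non-baseline site, with controlled probe profiles.
makeToyMatrix <- function(probes) {
  ids <- names(probes)
  v <- do.call(rbind, probes)
  colnames(v) <- c(paste0("b1_", 1:4), paste0("b2_", 1:4),
                   paste0("mfp_", 1:3), paste0("ax_", 1:3),
                   paste0("lum_", 1:3))
  rownames(v) <- ids
  ProbeExpressionExperiment(
    v,
    groupId = rep(c("b1", "b2", "mfp1", "ax1", "lum1"), c(4, 4, 3, 3, 3)),
    siteCategory = rep(c("baseline", "baseline", "MFP", "AxLN", "AxLN-LuM"),
                       c(4, 4, 3, 3, 3)),
    probeClass = rep("other", length(ids)))
}

test_that("fold-change criterion applies inclusive 1.5x / 0.5x boundaries", {
  m <- makeToyMatrix(list(
    up = c(rep(100, 8), rep(100, 3), rep(160, 3), rep(100, 3)),
    flat = c(rep(100, 8), rep(100, 3), rep(100, 3), rep(100, 3)),
    down = c(rep(100, 8), rep(100, 3), rep(50, 3), rep(100, 3))))
  fc <- criterionFoldChange(m, "ax1")
  expect_identical(fc["up", "direction"], "+")     # 1.6 >= 1.5
  expect_false(fc["flat", "pass"])                 # fold exactly 1
  expect_identical(fc["down", "direction"], "-")   # boundary 0.5 inclusive
  # exact boundary 1.5 passes too
  m2 <- makeToyMatrix(list(
    edge = c(rep(100, 8), rep(100, 3), rep(150, 3), rep(100, 3))))
  expect_true(criterionFoldChange(m2, "ax1")["edge", "pass"])
})

test_that("zero baseline mean flags the probe invalid, never passing", {
  m <- makeToyMatrix(list(
    dead = c(rep(0, 8), rep(5, 3), rep(5, 3), rep(5, 3))))
  fc <- criterionFoldChange(m, "ax1")
  expect_false(fc["dead", "valid"])
  expect_false(fc["dead", "pass"])
})

test_that("range criterion uses the interpolated percentile, inclusive", {
  # four probes with ranges 10, 20, 30, 40 over baselines+triplet:
  # 25th percentile (linear interpolation) = 17.5, so 20/30/40 pass
  mk <- function(rng) c(rep(100, 7), 100 + rng, rep(100, 3), rep(100, 3),
                        rep(100, 3))
  m <- makeToyMatrix(list(r10 = mk(10), r20 = mk(20), r30 = mk(30),
                          r40 = mk(40)))
  rp <- criterionRangePercentile(m, "ax1")
  expect_equal(rp$threshold[1], 17.5)
  expect_identical(unname(rp[c("r10", "r20", "r30", "r40"), "pass"]),
                   c(FALSE, TRUE, TRUE, TRUE))
})

test_that("constant probes fail the range criterion; equal ranges all pass", {
  mk <- function(rng) c(rep(100, 7), 100 + rng, rep(100, 9))
  m <- makeToyMatrix(list(flat = mk(0), a = mk(10), b = mk(10), c = mk(10)))
  rp <- criterionRangePercentile(m, "ax1")
  expect_false(rp["flat", "pass"])
  expect_true(all(rp[c("a", "b", "c"), "pass"]))
  # all probes share one positive range: boundary inclusive, all pass
  m2 <- makeToyMatrix(list(a = mk(10), b = mk(10)))
  expect_true(all(criterionRangePercentile(m2, "ax1")$pass))
})

test_that("consistency is the all-pairwise strict ordering", {
  expect_identical(criterionConsistency(c(5, 6, 7),
                                        c(1, 2, 3, 4, 1, 2, 3, 4)), ">")
  expect_identical(criterionConsistency(c(5, 3, 7), c(1, 2, 4)), "none")
  expect_identical(criterionConsistency(c(1, 2), c(2, 3)), "none")
  expect_identical(criterionConsistency(c(1, 2), c(3, 4)), "<")
  expect_error(criterionConsistency(numeric(), 1), "non-empty")
})

test_that("noise-free planted AxLN signature is recovered exactly", {
  sim <- simulateMicroarray(microarrayDesign(nProbes = 300, noiseSd = 0,
                                             plantedFold = 2, seed = 21L))
  sel <- selectAxlnSignature(sim$matrix)
  expect_setequal(rownames(sel)[sel$selected],
                  truthParameters(sim$truth)$planted_probes)
})

test_that("a probe elevated in all site categories is not selected", {
  m <- makeToyMatrix(list(
    everywhere = c(rep(100, 8), rep(200, 3), rep(200, 3), rep(200, 3)),
    axOnly = c(rep(100, 8), rep(100, 3), rep(200, 3), rep(100, 3))))
  sel <- selectAxlnSignature(m)
  expect_false(sel["everywhere", "selected"])
  expect_true(sel["axOnly", "selected"])
})

test_that("selection handles an empty probe set and missing sites", {
  m <- makeToyMatrix(list(p = rep(100, 17)))
  sel <- selectAxlnSignature(m[integer(0), ])
  expect_identical(nrow(sel), 0L)
  noMfp <- m[, siteCategories(m) != "MFP"]
  expect_error(selectAxlnSignature(noMfp), "MFP")
})

test_that("selection is invariant to permuting annotated sample columns", {
  sim <- simulateMicroarray(microarrayDesign(nProbes = 120, seed = 13L))
  sel <- selectAxlnSignature(sim$matrix)
  perm <- sample(ncol(sim$matrix))
  selPerm <- selectAxlnSignature(sim$matrix[, perm])
  expect_identical(as.logical(sel$selected), as.logical(selPerm$selected))
})

test_that("hypergeometric tail matches exhaustive enumeration on small cases", {
  got <- hypergeometricEnrichment(10, 4, 5, 3)
  expect_equal(got$pUpper, enumHyperTail(10, 4, 5, 3), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:25) {
    N <- sample(2:12, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    kk <- seq(max(0L, n + K - N), min(n, K))
    k <- kk[sample.int(length(kk), 1)]
    expect_equal(hypergeometricEnrichment(N, K, n, k)$pUpper,
                 enumHyperTail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment edge cases and monotonicity hold", {
  expect_equal(hypergeometricEnrichment(100, 10, 5, 0)$pUpper, 1)
  # K = N: every draw annotated, fold 1 and p 1 at k = n
  allK <- hypergeometricEnrichment(20, 20, 6, 6)
  expect_equal(allK$fold, 1)
  expect_equal(allK$pUpper, 1)
  p <- vapply(0:10, function(k)
    hypergeometricEnrichment(50, 20, 10, k)$pUpper, numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_error(hypergeometricEnrichment(10, 12, 5, 3), "<=")
})

test_that("log2 mean centering zeroes every row mean", {
  m <- matrix(c(2, 8, 5, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  x <- ProbeExpressionExperiment(m, c("b", "b"), c("baseline", "baseline"),
                                 c("other", "other"))
  cc <- log2MeanCenter(x)
  expect_equal(unname(cc["p1", ]), c(-1, 1))
  expect_equal(unname(cc["p2", ]), c(0, 0))
  sim <- simulateMicroarray(microarrayDesign(nProbes = 40, seed = 3L))
  expect_true(all(abs(rowMeans(log2MeanCenter(sim$matrix))) < 1e-9))
  m0 <- ProbeExpressionExperiment(matrix(c(0, 1), 1, 2), c("b", "b"),
                                  c("baseline", "baseline"), "other")
  expect_error(log2MeanCenter(m0), "> 0")
})
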