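test_that("allele frequencies count each individual once and drop empty loci", {
  a1 <- matrix(c("A", "A", NA, NA), 2, 2,
               dimnames = list(c("i1", "i2"), c("L1", "L2")))
  a2 <- matrix(c("A", "B", NA, NA), 2, 2, dimnames = dimnames(a1))
  expect_warning(f <- alleleFrequencies(multilocusGenotypes(a1, a2)),
                 "zero individuals")
  expect_equal(f$L1, c(A = 0.75, B = 0.25))
  expect_null(f$L2)

  ## a missing locus contributes no copies
  a1 <- matrix(c("A", NA), 2, 1, dimnames = list(c("i1", "i2"), "L1"))
  a2 <- matrix(c("B", NA), 2, 1, dimnames = dimnames(a1))
  f <- alleleFrequencies(multilocusGenotypes(a1, a2))
  expect_equal(f$L1, c(A = 0.5, B = 0.5))
})

test_that("estimated frequencies converge on the simulating frequencies", {
  cfg <- simConfig(nFounders = 500L, nGenerations = 0L, seed = 15L)
  g <- simulateGenotypes(simulatePedigree(cfg), cfg)
  f <- alleleFrequencies(g)
  se <- sqrt(0.125 * 0.875 / 1000)  # 1000 allele copies per locus
  for (l in names(f)) expect_true(all(abs(f[[l]] - 0.125) < 3.5 * se))
})

test_that("Queller-Goodnight estimator reproduces hand-computed cases", {
  f <- list(L1 = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25))
  x <- list(allele1 = c(L1 = "A"), allele2 = c(L1 = "B"))
  expect_equal(qgRelatedness(x, x, f), 1)

  f2 <- list(L1 = c(A = 0.5, B = 0.5))
  xa <- list(allele1 = c(L1 = "A"), allele2 = c(L1 = "A"))
  xb <- list(allele1 = c(L1 = "B"), allele2 = c(L1 = "B"))
  expect_equal(qgRelatedness(xa, xb, f2), -1)

  ## symmetry is exact when computed in both directions
  f3 <- list(L1 = c(A = 0.1, B = 0.3, C = 0.6),
             L2 = c(A = 0.2, B = 0.8))
  y1 <- list(allele1 = c(L1 = "A", L2 = "A"), allele2 = c(L1 = "B", L2 = "B"))
  y2 <- list(allele1 = c(L1 = "A", L2 = "B"), allele2 = c(L1 = "C", L2 = "B"))
  expect_identical(qgRelatedness(y1, y2, f3), qgRelatedness(y2, y1, f3))

  ## invariant to locus order and allele relabelling
  swapLoci <- function(g) list(allele1 = g$allele1[c("L2", "L1")],
                               allele2 = g$allele2[c("L2", "L1")])
  expect_equal(qgRelatedness(swapLoci(y1), swapLoci(y2), f3[c("L2", "L1")]),
               qgRelatedness(y1, y2, f3))
  relab <- function(v) chartr("ABC", "XYZ", v)
  f3r <- lapply(f3, function(p) setNames(p, relab(names(p))))
  y1r <- lapply(y1, relab)
  y2r <- lapply(y2, relab)
  expect_equal(qgRelatedness(y1r, y2r, f3r), qgRelatedness(y1, y2, f3))

  ## no shared resolved loci: masked
  z <- list(allele1 = c(L1 = NA, L2 = "A"), allele2 = c(L1 = NA, L2 = "B"))
  w <- list(allele1 = c(L1 = "A", L2 = NA), allele2 = c(L1 = "B", L2 = NA))
  expect_true(is.na(qgRelatedness(z, w, f3)))
})

test_that("estimator is calibrated for every simulated kin class", {
  expected <- c("parent-offspring" = 0.5, "full-sib" = 0.5,
                "half-sib" = 0.25, "first-cousin" = 0.125, "unrelated" = 0)
  for (rel in names(expected)) {
    r <- simulateDyadRelatedness(rel, 500L, seed = 17L)
    expect_lt(abs(mean(r) - expected[[rel]]), 0.05)
  }
})

test_that("relatedness matrix is symmetric with masked diagonal", {
  cfg <- simConfig(nFounders = 8L, nGenerations = 0L, seed = 19L)
  g <- simulateGenotypes(simulatePedigree(cfg), cfg)
  rmat <- relatednessMatrix(g)
  v <- as.matrix(rmat)
  expect_identical(v, t(v))
  expect_true(all(is.na(diag(v))))
  expect_equal(sum(!is.na(v[lower.tri(v)])), 8 * 7 / 2)

  ## three identical genotypes: equal off-diagonal entries
  a1 <- matrix("01", 3, 4, dimnames = list(c("a", "b", "c"),
                                           sprintf("L%02d", 1:4)))
  a2 <- matrix("02", 3, 4, dimnames = dimnames(a1))
  g3 <- multilocusGenotypes(a1, a2)
  f <- freqsFromSpec(tinySpec(4L, 8L))
  v3 <- as.matrix(relatednessMatrix(g3, f))
  off <- v3[lower.tri(v3)]
  expect_true(all(off == off[1]))
})

test_that("relatedness matrix on a field-scale population is fast", {
  cfg <- simConfig(nFounders = 33L, nGenerations = 0L, seed = 23L)
  g <- simulateGenotypes(simulatePedigree(cfg), cfg)
  t0 <- proc.time()[["elapsed"]]
  rmat <- relatednessMatrix(g)
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
  expect_identical(dim(as.matrix(rmat)), c(33L, 33L))
})

test_that("kin classes follow the canonical thresholds", {
  expect_identical(classifyKin(c(0.124, 0.125, 0.2, 0.375, 0.5, -0.3)),
                   c("unrelated", "third", "second", "first", "first",
                     "unrelated"))
  expect_true(is.na(classifyKin(NA_real_)))
  ## monotone: classes never decrease as R increases
  ord <- c(unrelated = 0, third = 1, second = 2, first = 3)
  cls <- ord[classifyKin(seq(-1, 1, by = 0.01))]
  expect_true(all(diff(cls) >= 0))
})

test_that("pair-group summary partitions pairs by sex combination", {
  a1 <- matrix("01", 3, 4, dimnames = list(c("a", "b", "c"),
                                           sprintf("L%02d", 1:4)))
  a2 <- matrix("02", 3, 4, dimnames = dimnames(a1))
  rmat <- relatednessMatrix(multilocusGenotypes(a1, a2),
                            freqsFromSpec(tinySpec(4L, 8L)))
  sex <- c(a = "M", b = "M", c = "F")
  out <- pairGroupSummary(rmat, sex)
  n <- setNames(out$summary$n, out$summary$group)
  expect_identical(n, c(MM = 1L, MF = 2L, FF = 0L))
  expect_identical(out$summary$nDefined[out$summary$group == "FF"], 0L)

  ## all pairs unrelated: zero relative proportions
  v <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(v) <- NA
  rm0 <- new("RelatednessMatrix", values = v,
             nLoci = matrix(4L, 3, 3, dimnames = dimnames(v)))
  out0 <- pairGroupSummary(rm0, sex)
  expect_true(all(out0$summary$propRelatives[out0$summary$nDefined > 0] == 0))

  ## unknown-sex individuals are excluded with a message
  expect_message(pairGroupSummary(rmat, c(a = "M", b = "unknown", c = "F")),
                 "unknown sex")
})

test_that("male-biased philopatry yields higher MM than FF relatedness", {
  cfg <- simConfig()
  wins <- vapply(1:60, function(k) {
    ped <- simulatePedigree(cfg, seed = 300L + k)
    tb <- pedigreeTable(ped)
    g <- simulateGenotypes(ped, cfg, seed = 900L + k)
    res <- tb$id[tb$resident]
    rmat <- suppressMessages(relatednessMatrix(g[res]))
    sx <- setNames(tb$sex, tb$id)[res]
    v <- as.matrix(rmat)
    mm <- v[sx == "M", sx == "M"]
    ff <- v[sx == "F", sx == "F"]
    mean(mm[lower.tri(mm)], na.rm = TRUE) > mean(ff[lower.tri(ff)], na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("low-confidence pairs are flagged by shared-locus count", {
  a1 <- matrix("01", 2, 10, dimnames = list(c("a", "b"), sprintf("L%02d", 1:10)))
  a2 <- matrix("02", 2, 10, dimnames = dimnames(a1))
  a1["b", 1:6] <- NA
  a2["b", 1:6] <- NA
  rmat <- relatednessMatrix(multilocusGenotypes(a1, a2),
                            freqsFromSpec(tinySpec(10L, 8L)))
  lc <- lowConfidencePairs(rmat, minLoci = 6L)
  expect_identical(nrow(lc), 1L)
  expect_identical(lc$nLoci, 4L)
})
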