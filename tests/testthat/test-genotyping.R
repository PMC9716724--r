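test_that("consensus accepts unanimous and threshold-supported genotypes", {
  ## unanimity
  g <- consensusGenotype(callsFromPairs(list(c("A", "B"), c("A", "B"),
                                             c("A", "B"))))
  expect_identical(unname(c(g$allele1, g$allele2)), c("A", "B"))

  ## heterozygote rule: each allele in >= 2 replicates
  g <- consensusGenotype(callsFromPairs(list(c("A", "A"), c("A", "B"),
                                             c("A", "B"))))
  expect_identical(unname(c(g$allele1, g$allele2)), c("A", "B"))

  ## homozygote needs >= 3 identical homozygous calls
  calls <- callsFromPairs(list(c("A", "A"), c("A", "A"), c(NA, NA)))
  g <- consensusGenotype(calls)
  expect_true(is.na(g$allele1))
  expect_identical(g$unresolved, "L1")

  ## two more A/A replicates resolve it
  calls5 <- rbind(calls, callsFromPairs(list(c("A", "A"), c("A", "A")))
                  [, names(calls)])
  calls5$replicate <- seq_len(5L)
  g <- consensusGenotype(calls5)
  expect_identical(unname(c(g$allele1, g$allele2)), c("A", "A"))

  ## fewer than 3 replicates is refused
  expect_error(consensusGenotype(callsFromPairs(list(c("A", "A"), c("A", "A")))),
               "at least 3 replicates")
})

test_that("consensus is invariant to replicate order", {
  pairs <- list(c("A", "A"), c("A", "B"), c("A", "B"), c("A", "A"), c("B", "B"))
  base <- consensusGenotype(callsFromPairs(pairs))
  for (k in 1:5) {
    shuffled <- callsFromPairs(pairs[sample(5L)])
    g <- consensusGenotype(shuffled)
    expect_identical(g$allele1, base$allele1)
    expect_identical(g$allele2, base$allele2)
  }
})

test_that("consensus error rate stays below 1% with 5 replicates at 20% dropout", {
  cfg <- simConfig(nFounders = 2L, nGenerations = 0L, dropoutRate = 0.2,
                   falseAlleleRate = 0, nReplicates = 5L, nSurveys = 350L,
                   detectionProb = 1, cubProb = 0, seed = 61L)
  ped <- simulatePedigree(cfg)
  truth <- simulateGenotypes(ped, cfg)
  sim <- simulateSamples(ped, truth, cfg)
  cons <- consensusGenotypes(sim$calls)
  m <- match(sim$samples$individual_id, individualIds(truth))
  t1 <- truth@allele1[m, , drop = FALSE]
  t2 <- truth@allele2[m, , drop = FALSE]
  c1 <- cons@allele1[sim$samples$sample_id, , drop = FALSE]
  c2 <- cons@allele2[sim$samples$sample_id, , drop = FALSE]
  resolved <- !is.na(c1)
  nLoci <- length(resolved)
  wrong <- resolved & (c1 != t1 | c2 != t2)
  expect_gt(nLoci, 10000L)
  expect_lt(sum(wrong) / nLoci, 0.01)
})

test_that("matching clusters samples correctly at threshold boundaries", {
  a1 <- matrix("01", 2, 15, dimnames = list(c("S1", "S2"), sprintf("L%02d", 1:15)))
  a2 <- matrix("02", 2, 15, dimnames = dimnames(a1))
  same <- matchIndividuals(multilocusGenotypes(a1, a2))
  expect_identical(nrow(same$individuals), 1L)

  ## one differing locus, zero tolerance: distinct individuals
  a2b <- a2
  a2b["S2", "L05"] <- "03"
  res <- matchIndividuals(multilocusGenotypes(a1, a2b), maxMismatchLoci = 0L,
                          reconcile = FALSE)
  expect_identical(nrow(res$individuals), 2L)
  ## same pair within tolerance 1: one individual
  res <- matchIndividuals(multilocusGenotypes(a1, a2b), maxMismatchLoci = 1L)
  expect_identical(nrow(res$individuals), 1L)
})

test_that("samples with too few resolved loci are excluded, not forced", {
  a1 <- matrix("01", 3, 15, dimnames = list(c("S1", "S2", "S3"),
                                            sprintf("L%02d", 1:15)))
  a2 <- a1
  a1["S3", 1:10] <- NA
  a2["S3", 1:10] <- NA
  expect_message(res <- matchIndividuals(multilocusGenotypes(a1, a2)),
                 "excluding 1 sample")
  expect_identical(res$excluded, "S3")
  expect_identical(nrow(res$individuals), 1L)
})

test_that("cluster count is monotone non-increasing in the mismatch tolerance", {
  sc <- zeroErrorScenario(nIndividuals = 12L, seed = 71L)
  cons <- consensusGenotypes(sc$sim$calls)
  counts <- vapply(0:3, function(mm) {
    nrow(matchIndividuals(cons, maxMismatchLoci = mm,
                          reconcile = FALSE)$individuals)
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("zero-error simulation is recovered perfectly", {
  sc <- zeroErrorScenario(nIndividuals = 12L, seed = 81L)
  id <- identifyIndividuals(sc$sim$calls, sc$sim$sexing, sc$sim$fragments)
  expect_identical(nrow(id$individuals), 12L)
  m <- merge(id$membership, sc$sim$samples, by = "sample_id")
  tab <- table(m$individual_id.x, m$individual_id.y)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  ## sexes recovered exactly
  truthSex <- setNames(pedigreeTable(sc$ped)$sex, pedigreeTable(sc$ped)$id)
  mapped <- unique(m[, c("individual_id.x", "individual_id.y")])
  got <- setNames(id$individuals$sex, id$individuals$individual_id)
  expect_identical(unname(got[mapped$individual_id.x]),
                   unname(truthSex[mapped$individual_id.y]))
})

test_that("sexing follows the two-band replicate rule", {
  expect_identical(determineSex(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE)),
                   "male")
  expect_identical(determineSex(rep(FALSE, 3), rep(TRUE, 3)), "female")
  ## one both-band replicate is not enough for male, and the 210 band
  ## excludes female: unknown
  expect_identical(determineSex(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE)),
                   "unknown")
  expect_warning(s <- determineSex(rep(FALSE, 3), rep(FALSE, 3)),
                 "no interpretable")
  expect_identical(s, "unknown")
})

test_that("age classification matches reference fragment profiles", {
  cal <- defaultAgeCalibration()
  set.seed(1)
  adult <- classifyAge(rnorm(45, 33.2, 0.7), rnorm(45, 8.2, 0.2), cal)
  expect_identical(adult, "adult")
  sub <- classifyAge(rnorm(45, 18.7, 0.4), rnorm(45, 6.1, 0.2), cal)
  expect_identical(sub, "subadult")
  ## markedly longer fragments flag elderly
  old <- classifyAge(rnorm(45, 40, 1), rnorm(45, 10, 0.5), cal)
  expect_identical(old, "elderly")
  ## no fragments: cub if unweaned, else unknown
  expect_identical(classifyAge(numeric(), numeric(), cal, unweaned = TRUE),
                   "cub")
  expect_identical(classifyAge(numeric(), numeric(), cal), "unknown")
  expect_warning(u <- classifyAge(rnorm(10, 30, 1), rnorm(10, 8, 0.5), cal),
                 "fewer than 40")
  expect_identical(u, "unknown")
})

test_that("GenePop and CSV genotype files round-trip", {
  sc <- zeroErrorScenario(nIndividuals = 5L, seed = 91L)
  path <- withr::local_tempfile(fileext = ".gen")
  writeGenepop(sc$truth, path)
  back <- readGenepop(path)
  expect_identical(back@allele1, sc$truth@allele1)
  expect_identical(back@allele2, sc$truth@allele2)

  csv <- withr::local_tempfile(fileext = ".csv")
  g <- sc$truth
  g@allele1[1, 1] <- g@allele2[1, 1] <- NA  # missing locus survives
  writeGenotypesCsv(g, csv)
  back2 <- readGenotypesCsv(csv)
  expect_identical(back2@allele1, g@allele1)
  expect_identical(back2@allele2, g@allele2)
})
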