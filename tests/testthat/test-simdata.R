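test_that("dispersal rules are enforced in the pedigree", {
  ## full female emigration: no resident female has a resident daughter
  cfg <- simConfig(femaleEmigrationProb = 1, nGenerations = 3L, seed = 2L)
  tb <- pedigreeTable(simulatePedigree(cfg))
  res <- tb$id[tb$resident]
  daughters <- tb[tb$sex == "F" & !is.na(tb$mother), ]
  expect_false(any(daughters$id %in% res & daughters$mother %in% res &
                     !daughters$immigrant))

  ## full philopatry + full emigration: all sons resident, no resident
  ## non-immigrant daughters at all
  cfg <- simConfig(malePhilopatryProb = 1, femaleEmigrationProb = 1, seed = 3L)
  tb <- pedigreeTable(simulatePedigree(cfg))
  sons <- tb[tb$sex == "M" & !is.na(tb$father), ]
  expect_true(all(sons$resident))
  expect_false(any(tb$resident & tb$sex == "F" & !is.na(tb$mother)))
})

test_that("pedigree simulation is deterministic and validates input", {
  cfg <- simConfig(seed = 5L)
  expect_identical(pedigreeTable(simulatePedigree(cfg)),
                   pedigreeTable(simulatePedigree(cfg)))
  expect_error(simConfig(nFounders = 1L), "nFounders")
  expect_error(simConfig(detectionProb = 1.5), "probabilities")
  expect_error(simConfig(lociSpec = list(L1 = list(
    alleles = c("A", "B"), freqs = c(0.7, 0.2)))), "sum to 1")
})

test_that("pedigree kinship oracle matches closed-form relationships", {
  R <- pedigreeRelatedness(handPedigree())
  expect_equal(R["M1", "C1"], 0.5)    # parent-offspring
  expect_equal(R["C1", "C2"], 0.5)    # full sibs
  expect_equal(R["C1", "C3"], 0.25)   # half sibs (shared mother)
  expect_equal(R["F1", "G1"], 0.25)   # grandmother
  expect_equal(R["C1", "G1"], 0.25)   # aunt/nephew via full sib C2
  expect_equal(R["C3", "G1"], 0.375)  # half-sib mother C2 + shared sire M2
  expect_equal(R["M1", "F1"], 0)      # founders unrelated
  expect_true(all(is.na(diag(R))))
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  cfg <- simConfig(seed = 9L)
  ped <- simulatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  expect_identical(g@allele1, simulateGenotypes(ped, cfg)@allele1)

  tb <- pedigreeTable(ped)
  off <- tb[!is.na(tb$mother), ]
  consistent <- TRUE
  for (i in seq_len(nrow(off))) {
    m <- off$mother[i]; f <- off$father[i]; id <- off$id[i]
    for (l in lociNames(g)) {
      a <- c(g@allele1[id, l], g@allele2[id, l])
      mo <- c(g@allele1[m, l], g@allele2[m, l])
      fa <- c(g@allele1[f, l], g@allele2[f, l])
      ok <- (a[1] %in% mo && a[2] %in% fa) || (a[1] %in% fa && a[2] %in% mo)
      if (!ok) consistent <- FALSE
    }
  }
  expect_true(consistent)
})

test_that("a fixed single-allele locus makes everyone homozygous", {
  cfg <- simConfig(lociSpec = list(L1 = list(alleles = c("A", "B"),
                                             freqs = c(1, 0))), seed = 4L)
  g <- simulateGenotypes(simulatePedigree(cfg), cfg)
  expect_true(all(g@allele1 == "A"))
  expect_true(all(g@allele2 == "A"))
})

test_that("Mendelian segregation gives near-equal quarters for A/B x C/D", {
  spec <- list(L1 = list(alleles = c("A", "B", "C", "D"), freqs = rep(0.25, 4)))
  n <- 10000L
  tb <- data.frame(
    id = c("M1", "F1", sprintf("C%05d", seq_len(n))),
    sex = c("M", "F", rep("M", n)),
    birthGen = c(0L, 0L, rep(1L, n)),
    mother = c(NA, NA, rep("F1", n)),
    father = c(NA, NA, rep("M1", n)),
    immigrant = FALSE, resident = TRUE, ageClass = "adult",
    stringsAsFactors = FALSE
  )
  ped <- new("Pedigree", table = tb)
  cfg <- simConfig(lociSpec = spec)
  ## find a seed whose founders are heterozygous with disjoint alleles
  g <- NULL
  for (s in 1:60) {
    cand <- simulateGenotypes(ped, cfg, seed = s)
    pm <- c(cand@allele1["M1", 1], cand@allele2["M1", 1])
    pf <- c(cand@allele1["F1", 1], cand@allele2["F1", 1])
    if (pm[1] != pm[2] && pf[1] != pf[2] && !any(pm %in% pf)) {
      g <- cand
      break
    }
  }
  expect_false(is.null(g))
  kids <- sprintf("C%05d", seq_len(n))
  combo <- paste(g@allele1[kids, 1], g@allele2[kids, 1])
  props <- table(combo) / n
  expect_length(props, 4L)
  expect_true(all(abs(props - 0.25) < 0.02))
})

test_that("resident male-male dyads are more related than female-female", {
  ## male philopatry + female emigration concentrate kin among resident
  ## males; pedigree-kinship oracle, sign test over replicate simulations
  cfg <- simConfig()
  wins <- vapply(1:100, function(k) {
    ped <- simulatePedigree(cfg, seed = 100L + k)
    tb <- pedigreeTable(ped)
    R <- pedigreeRelatedness(ped)
    res <- tb$id[tb$resident]
    sx <- setNames(tb$sex, tb$id)[res]
    mm <- R[res[sx == "M"], res[sx == "M"]]
    ff <- R[res[sx == "F"], res[sx == "F"]]
    mean(mm[lower.tri(mm)]) >= mean(ff[lower.tri(ff)])
  }, logical(1))
  ## one-sided sign test at alpha ~ 0.01 would need ~62/100; expect far more
  expect_gte(sum(wins), 62L)
})

test_that("samples: zero-error replicates equal truth; full detection detects all", {
  sc <- zeroErrorScenario(nIndividuals = 6L, seed = 21L)
  m <- merge(sc$sim$calls, sc$sim$samples, by = "sample_id")
  idx <- cbind(match(m$individual_id, individualIds(sc$truth)),
               match(m$locus, lociNames(sc$truth)))
  expect_identical(m$allele1, unname(sc$truth@allele1[idx]))
  expect_identical(m$allele2, unname(sc$truth@allele2[idx]))

  cfg <- simConfig(nFounders = 6L, nGenerations = 0L, detectionProb = 1,
                   nSurveys = 6L, cubProb = 0, seed = 8L)
  ped <- simulatePedigree(cfg)
  sim <- simulateSamples(ped, simulateGenotypes(ped, cfg), cfg)
  expect_identical(as.integer(table(sim$detections$individual_id)),
                   rep(6L, 6L))
})

test_that("heterozygous replicates appear homozygous at the closed-form rate", {
  p <- 0.2
  cfg <- simConfig(nFounders = 2L, nGenerations = 0L, dropoutRate = p,
                   falseAlleleRate = 0, nReplicates = 5L, nSurveys = 300L,
                   detectionProb = 1, cubProb = 0, seed = 31L)
  ped <- simulatePedigree(cfg)
  truth <- simulateGenotypes(ped, cfg)
  sim <- simulateSamples(ped, truth, cfg)
  m <- merge(sim$calls, sim$samples, by = "sample_id")
  idx <- cbind(match(m$individual_id, individualIds(truth)),
               match(m$locus, lociNames(truth)))
  trueHet <- truth@allele1[idx] != truth@allele2[idx]
  obsHom <- m$allele1[trueHet] == m$allele2[trueHet]
  expected <- 2 * p * (1 - p) + p^2
  n <- sum(trueHet)
  se <- sqrt(expected * (1 - expected) / n)
  expect_gt(n, 10000)
  expect_lt(abs(mean(obsHom) - expected), 4 * se)
})

test_that("fragment draws reproduce the configured age-class means", {
  cfg <- simConfig(nFounders = 4L, nGenerations = 0L, cubProb = 0,
                   detectionProb = 1, nSurveys = 1L, seed = 41L)
  ## founders in a 0-generation run are sub-adults by cohort age
  ped <- simulatePedigree(cfg)
  sim <- simulateSamples(ped, simulateGenotypes(ped, cfg), cfg)
  fp <- cfg@fragmentParams
  sub <- fp[fp$ageClass == "subadult", ]
  for (sid in unique(sim$fragments$sample_id)) {
    fr <- sim$fragments[sim$fragments$sample_id == sid, ]
    expect_gte(nrow(fr), 40L)
    expect_lt(abs(mean(fr$length_mm) - sub$lengthMean),
              3 * sub$lengthSD / sqrt(nrow(fr)) + 1e-9)
  }
})

test_that("sample simulation is deterministic and writes round-trippable files", {
  cfg <- simConfig(seed = 13L)
  ped <- simulatePedigree(cfg)
  truth <- simulateGenotypes(ped, cfg)
  s1 <- simulateSamples(ped, truth, cfg)
  s2 <- simulateSamples(ped, truth, cfg)
  expect_identical(s1, s2)

  dir <- withr::local_tempdir()
  paths <- writeSimData(s1, ped, truth, dir)
  expect_true(all(file.exists(paths)))
  back <- readGenepop(paths[["genepop"]])
  expect_identical(back@allele1, truth@allele1)
  expect_identical(back@allele2, truth@allele2)
})

test_that("dyad simulator hits the theoretical expectations", {
  ## full sibs: kinship x 2 = 0.5 expected allele-sharing relatedness
  r <- simulateDyadRelatedness("full-sib", 500L, seed = 51L)
  expect_length(r, 500L)
  expect_lt(abs(mean(r) - 0.5), 0.05)
  r0 <- simulateDyadRelatedness("unrelated", 500L, seed = 52L)
  expect_lt(abs(mean(r0)), 0.05)
  ## determinism
  expect_identical(r, simulateDyadRelatedness("full-sib", 500L, seed = 51L))
})
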