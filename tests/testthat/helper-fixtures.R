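## Shared fixtures and independent oracles used across test files.

## tiny locus panel
tinySpec <- function(nLoci = 2L, nAlleles = 4L) defaultLociSpec(nLoci, nAlleles)

## hand-built pedigree: two founders, two full-sib offspring, one
## half-sib via a second sire, and a grandchild
handPedigree <- function() {
  tb <- data.frame(
    id = c("M1", "F1", "M2", "C1", "C2", "C3", "F2", "G1"),
    sex = c("M", "F", "M", "M", "F", "M", "F", "M"),
    birthGen = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 2L),
    mother = c(NA, NA, NA, "F1", "F1", "F1", NA, "C2"),
    father = c(NA, NA, NA, "M1", "M1", "M2", NA, "M2"),
    immigrant = FALSE,
    resident = TRUE,
    ageClass = "adult",
    stringsAsFactors = FALSE
  )
  new("Pedigree", table = tb)
}

## zero-error identification scenario: n unrelated residents, ~200 samples
zeroErrorScenario <- function(nIndividuals = 30L, seed = 11L) {
  cfg <- simConfig(nFounders = nIndividuals, nGenerations = 0L,
                   dropoutRate = 0, falseAlleleRate = 0,
                   sexingErrorRate = 0, cubProb = 0,
                   nSurveys = 7L, detectionProb = 0.95, seed = seed)
  ped <- simulatePedigree(cfg)
  truth <- simulateGenotypes(ped, cfg)
  sim <- simulateSamples(ped, truth, cfg)
  list(cfg = cfg, ped = ped, truth = truth, sim = sim)
}

## build a replicate-calls data.frame for one sample from a list of
## per-replicate allele pairs, e.g. list(c("A","B"), c("A","B"), c("A","A"))
callsFromPairs <- function(pairs, locus = "L1", sample_id = "S1") {
  do.call(rbind, lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    data.frame(sample_id = sample_id, replicate = k, locus = locus,
               allele1 = p[1L], allele2 = p[2L], stringsAsFactors = FALSE)
  }))
}

## independent brute-force Wilcoxon rank-sum oracle: enumerates every
## assignment of pooled ranks to sample 1 (tie-free data only)
bruteWilcoxon <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  W <- sum(rank(c(x, y))[seq_len(n1)])
  Ws <- apply(utils::combn(N, n1), 2, sum)
  pLess <- mean(Ws <= W)
  pGreater <- mean(Ws >= W)
  list(W = W, p = min(1, 2 * min(pLess, pGreater)))
}

## frequency list from a lociSpec
freqsFromSpec <- function(spec) {
  lapply(spec, function(sp) setNames(sp$freqs, sp$alleles))
}
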