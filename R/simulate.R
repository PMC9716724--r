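## Synthetic population generator: pedigree, gene dropping, sampling.

#' Simulate a multigenerational pedigree with female-biased dispersal
#'
#' Founders are unrelated residents of alternating sex. Each generation,
#' every resident mature female produces one offspring sired by a resident
#' male chosen uniformly at random (promiscuous mating, no active
#' inbreeding avoidance). Daughters emigrate with
#' `femaleEmigrationProb`; sons remain resident with `malePhilopatryProb`.
#' Emigrants are flagged non-resident but retained in the pedigree so that
#' pedigree kinship remains computable. `immigrantFemalesPerGen` unrelated
#' adult females join the resident pool per generation. Age classes are
#' assigned from birth cohort: final-generation offspring are sub-adults
#' (or unweaned cubs with probability `cubProb`), founders in runs of three
#' or more generations are elderly, everyone else adult; immigrants are at
#' least adults.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed; defaults to `config@seed`.
#' @return a [Pedigree-class].
#' @export
#' @examples
#' ped <- simulatePedigree(simConfig(seed = 3L))
#' head(pedigreeTable(ped))
simulatePedigree <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nFounders < 2L) stop("degenerate scenario: nFounders < 2")
  set.seed(seed)

  n <- config@nFounders
  tb <- data.frame(
    id = sprintf("I%04d", seq_len(n)),
    sex = rep(c("M", "F"), length.out = n),
    birthGen = 0L,
    mother = NA_character_,
    father = NA_character_,
    immigrant = FALSE,
    resident = TRUE,
    stringsAsFactors = FALSE
  )
  counter <- n

  newId <- function(k) {
    ids <- sprintf("I%04d", counter + seq_len(k))
    counter <<- counter + k
    ids
  }

  for (g in seq_len(config@nGenerations)) {
    mothers <- tb$id[tb$resident & tb$sex == "F" & tb$birthGen < g]
    sires <- tb$id[tb$resident & tb$sex == "M" & tb$birthGen < g]
    if (length(mothers) > 0L && length(sires) > 0L) {
      k <- length(mothers)
      off <- data.frame(
        id = newId(k),
        sex = ifelse(stats::runif(k) < 0.5, "M", "F"),
        birthGen = g,
        mother = mothers,
        father = sires[sample.int(length(sires), k, replace = TRUE)],
        immigrant = FALSE,
        resident = TRUE,
        stringsAsFactors = FALSE
      )
      u <- stats::runif(k)
      isF <- off$sex == "F"
      off$resident[isF] <- u[isF] >= config@femaleEmigrationProb
      off$resident[!isF] <- u[!isF] < config@malePhilopatryProb
      tb <- rbind(tb, off)
    }
    if (config@immigrantFemalesPerGen > 0L) {
      k <- config@immigrantFemalesPerGen
      tb <- rbind(tb, data.frame(
        id = newId(k),
        sex = "F",
        birthGen = g,
        mother = NA_character_,
        father = NA_character_,
        immigrant = TRUE,
        resident = TRUE,
        stringsAsFactors = FALSE
      ))
    }
  }

  if (!any(tb$resident)) {
    stop("degenerate scenario: no residents left at the end of the simulation")
  }

  age <- config@nGenerations - tb$birthGen
  ageClass <- ifelse(age >= 3L & !tb$immigrant & tb$birthGen == 0L, "elderly",
                     ifelse(age >= 1L, "adult", "subadult"))
  young <- which(age == 0L & !tb$immigrant)
  if (length(young) && config@cubProb > 0) {
    cub <- stats::runif(length(young)) < config@cubProb
    ageClass[young[cub]] <- "cub"
  }
  ageClass[tb$immigrant] <- ifelse(age[tb$immigrant] >= 1L, "adult", "adult")
  tb$ageClass <- ageClass

  new("Pedigree", table = tb)
}

#' Pedigree kinship coefficients
#'
#' Kinship (coancestry) coefficients computed by the tabular method:
#' individuals are processed in generation order; for individual i with
#' parents (m, f), phi(i, j) = (phi(m, j) + phi(f, j)) / 2 for earlier j,
#' and phi(i, i) = (1 + phi(m, f)) / 2. Founders and immigrants are assumed
#' unrelated and non-inbred.
#'
#' @param pedigree a [Pedigree-class].
#' @return symmetric numeric matrix of kinship coefficients.
#' @seealso [pedigreeRelatedness()] for the relatedness scale (2 * phi).
#' @export
pedigreeKinship <- function(pedigree) {
  stopifnot(is(pedigree, "Pedigree"))
  tb <- pedigree@table
  ord <- order(tb$birthGen, tb$id)
  tb <- tb[ord, ]
  n <- nrow(tb)
  ids <- tb$id
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  idx <- setNames(seq_len(n), ids)
  for (i in seq_len(n)) {
    m <- tb$mother[i]
    f <- tb$father[i]
    mi <- if (is.na(m)) NA_integer_ else idx[[m]]
    fi <- if (is.na(f)) NA_integer_ else idx[[f]]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      km <- if (is.na(mi)) 0 else K[mi, j]
      kf <- if (is.na(fi)) 0 else K[fi, j]
      K[i, j] <- K[j, i] <- (km + kf) / 2
    }
    kmf <- if (is.na(mi) || is.na(fi)) 0 else K[mi, fi]
    K[i, i] <- (1 + kmf) / 2
  }
  K
}

#' Pedigree relatedness (numerator relationship)
#'
#' Twice the kinship coefficient; for non-inbred pairs this is the expected
#' fraction of alleles shared identical-by-descent (0.5 parent-offspring
#' and full sibs, 0.25 half sibs, 0.125 first cousins). Used as the
#' independent oracle for the genotype-based estimator.
#'
#' @param pedigree a [Pedigree-class].
#' @return symmetric numeric matrix with NA diagonal.
#' @export
pedigreeRelatedness <- function(pedigree) {
  R <- 2 * pedigreeKinship(pedigree)
  diag(R) <- NA_real_
  R
}

## order an allele pair matrix-wise (allele1 <= allele2 by label)
.orderPairs <- function(a1, a2) {
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  list(a1 = a1, a2 = a2)
}

#' Construct a MultilocusGenotypes object
#'
#' @param allele1,allele2 character matrices (individuals x loci) with
#'   identical dimnames; NA marks missing loci. Pairs are reordered so that
#'   allele1 <= allele2.
#' @return a [MultilocusGenotypes-class].
#' @export
multilocusGenotypes <- function(allele1, allele2) {
  p <- .orderPairs(allele1, allele2)
  new("MultilocusGenotypes", allele1 = p$a1, allele2 = p$a2)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders and immigrants draw both alleles from the configured locus
#' allele frequencies; every other individual inherits one uniformly chosen
#' allele from each parent per locus (Mendelian inheritance).
#'
#' @param pedigree a [Pedigree-class].
#' @param config a [SimConfig-class] (supplies `lociSpec`).
#' @param seed RNG seed; defaults to `config@seed + 1L`.
#' @return a [MultilocusGenotypes-class] for all pedigree members (no
#'   missing loci).
#' @export
simulateGenotypes <- function(pedigree, config, seed = config@seed + 1L) {
  stopifnot(is(pedigree, "Pedigree"), is(config, "SimConfig"))
  if (length(config@lociSpec) == 0L) stop("lociSpec must be non-empty")
  set.seed(seed)

  tb <- pedigree@table[order(pedigree@table$birthGen, pedigree@table$id), ]
  n <- nrow(tb)
  loci <- names(config@lociSpec)
  L <- length(loci)
  a1 <- matrix(NA_character_, n, L, dimnames = list(tb$id, loci))
  a2 <- a1

  founder <- is.na(tb$mother) & is.na(tb$father)
  nf <- sum(founder)
  for (l in seq_len(L)) {
    sp <- config@lociSpec[[l]]
    a1[founder, l] <- sample(sp$alleles, nf, replace = TRUE, prob = sp$freqs)
    a2[founder, l] <- sample(sp$alleles, nf, replace = TRUE, prob = sp$freqs)
  }

  for (i in which(!founder)) {
    m <- tb$mother[i]
    f <- tb$father[i]
    fromM <- stats::runif(L) < 0.5
    fromF <- stats::runif(L) < 0.5
    a1[i, ] <- ifelse(fromM, a1[m, ], a2[m, ])
    a2[i, ] <- ifelse(fromF, a1[f, ], a2[f, ])
  }

  multilocusGenotypes(a1, a2)
}

## Per-locus frequency lookup of an allele matrix against a lociSpec-style
## frequency list (named numeric vectors per locus).
.freqLookup <- function(alleles, freqs) {
  out <- matrix(NA_real_, nrow(alleles), ncol(alleles),
                dimnames = dimnames(alleles))
  for (l in seq_len(ncol(alleles))) {
    fl <- freqs[[colnames(alleles)[l]]]
    out[, l] <- unname(fl[alleles[, l]])
  }
  out
}

#' Simulate survey detections, replicate genotype calls, fragments, sexing
#'
#' Each resident is detected on each survey occasion with
#' `detectionProb`; every detection yields one fecal sample. A sample
#' carries (i) `nReplicates` replicate genotype calls, in which each allele
#' of a heterozygous locus drops out independently with `dropoutRate` (an
#' affected replicate appears homozygous, so a heterozygote appears
#' homozygous with probability 1 - (1 - dropoutRate)^2) and a false allele
#' replaces one allele with probability `falseAlleleRate`; (ii) at least 40 fragment
#' length/width measurements drawn from the individual's age-class
#' distribution (none for cubs); and (iii) `nSexReplicates` sexing-PCR band
#' patterns, erring with probability `sexingErrorRate` (an errored male
#' replicate loses the 210-bp band; an errored female replicate fails,
#' showing no bands).
#'
#' @param pedigree a [Pedigree-class]; only residents are sampled.
#' @param truth a [MultilocusGenotypes-class] covering the residents.
#' @param config a [SimConfig-class].
#' @param seed RNG seed; defaults to `config@seed + 2L`.
#' @return list with data.frames `detections` (survey_id, individual_id,
#'   sample_id), `calls` (sample_id, replicate, locus, allele1, allele2),
#'   `fragments` (sample_id, fragment_index, length_mm, width_mm),
#'   `sexing` (sample_id, replicate, band_210bp, band_130bp) and `samples`
#'   (sample_id, individual_id: the ground-truth sample map).
#' @export
simulateSamples <- function(pedigree, truth, config, seed = config@seed + 2L) {
  stopifnot(is(pedigree, "Pedigree"), is(truth, "MultilocusGenotypes"),
            is(config, "SimConfig"))
  tb <- pedigree@table
  res <- tb[tb$resident, ]
  if (nrow(res) == 0L) stop("no residents to sample")
  if (!all(res$id %in% individualIds(truth))) {
    stop("truth genotypes missing for some residents")
  }
  set.seed(seed)

  ## detections ---------------------------------------------------------
  nRes <- nrow(res)
  det <- expand.grid(individual_id = res$id,
                     survey_id = seq_len(config@nSurveys),
                     stringsAsFactors = FALSE)
  det <- det[stats::runif(nrow(det)) < config@detectionProb, , drop = FALSE]
  det <- det[order(det$survey_id, det$individual_id), , drop = FALSE]
  nS <- nrow(det)
  det$sample_id <- sprintf("S%04d", seq_len(nS))
  detections <- det[, c("survey_id", "individual_id", "sample_id")]
  rownames(detections) <- NULL

  samples <- data.frame(sample_id = detections$sample_id,
                        individual_id = detections$individual_id,
                        stringsAsFactors = FALSE)

  loci <- lociNames(truth)
  L <- length(loci)

  ## replicate genotype calls -------------------------------------------
  grid <- expand.grid(sample_idx = seq_len(nS),
                      replicate = seq_len(config@nReplicates),
                      locus_idx = seq_len(L))
  ind <- match(samples$individual_id[grid$sample_idx], individualIds(truth))
  flat <- cbind(ind, grid$locus_idx)
  a1 <- truth@allele1[flat]
  a2 <- truth@allele2[flat]

  ## Allelic dropout: each allele of a heterozygous replicate fails to
  ## amplify independently; the replicate then appears homozygous for the
  ## surviving allele (or, in the rare case both fall below detection, for
  ## a uniformly chosen allele), so a heterozygote appears homozygous with
  ## probability 1 - (1 - dropoutRate)^2.
  het <- a1 != a2
  d1 <- het & stats::runif(length(a1)) < config@dropoutRate
  d2 <- het & stats::runif(length(a1)) < config@dropoutRate
  keep2 <- stats::runif(length(a1)) < 0.5
  o1 <- a1
  o2 <- a2
  a1[d1 & !d2] <- o2[d1 & !d2]
  a2[d2 & !d1] <- o1[d2 & !d1]
  both <- d1 & d2
  a1[both] <- ifelse(keep2[both], o2[both], o1[both])
  a2[both] <- a1[both]

  fa <- stats::runif(length(a1)) < config@falseAlleleRate
  if (any(fa)) {
    slot2 <- stats::runif(length(a1)) < 0.5
    shift <- stats::runif(length(a1))  # consumed uniformly for determinism
    for (l in seq_len(L)) {
      sel <- fa & grid$locus_idx == l
      if (!any(sel)) next
      alleles <- config@lociSpec[[loci[l]]]$alleles
      nA <- length(alleles)
      cur <- ifelse(slot2[sel], a2[sel], a1[sel])
      ci <- match(cur, alleles)
      k <- 1L + as.integer(floor(shift[sel] * (nA - 1L)))
      newA <- alleles[((ci - 1L + k) %% nA) + 1L]
      a1[sel][!slot2[sel]] <- newA[!slot2[sel]]
      a2[sel][slot2[sel]] <- newA[slot2[sel]]
    }
  }

  p <- .orderPairs(a1, a2)
  calls <- data.frame(
    sample_id = samples$sample_id[grid$sample_idx],
    replicate = grid$replicate,
    locus = loci[grid$locus_idx],
    allele1 = p$a1,
    allele2 = p$a2,
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$sample_id, calls$replicate, calls$locus), ]
  rownames(calls) <- NULL

  ## fragment measurements ----------------------------------------------
  ageOf <- setNames(tb$ageClass, tb$id)
  fp <- config@fragmentParams
  fragList <- vector("list", nS)
  for (s in seq_len(nS)) {
    ac <- ageOf[[samples$individual_id[s]]]
    if (ac == "cub") next
    row <- fp[fp$ageClass == ac, ]
    if (nrow(row) == 0L) next
    nf <- 40L + stats::rpois(1L, 5)
    fragList[[s]] <- data.frame(
      sample_id = samples$sample_id[s],
      fragment_index = seq_len(nf),
      length_mm = pmax(stats::rnorm(nf, row$lengthMean, row$lengthSD), 0.5),
      width_mm = pmax(stats::rnorm(nf, row$widthMean, row$widthSD), 0.2),
      stringsAsFactors = FALSE
    )
  }
  fragments <- do.call(rbind, fragList[!vapply(fragList, is.null, logical(1))])
  if (is.null(fragments)) {
    fragments <- data.frame(sample_id = character(), fragment_index = integer(),
                            length_mm = numeric(), width_mm = numeric())
  }
  rownames(fragments) <- NULL

  ## sexing replicates ---------------------------------------------------
  sexOf <- setNames(tb$sex, tb$id)
  sg <- expand.grid(sample_idx = seq_len(nS),
                    replicate = seq_len(config@nSexReplicates))
  trueSex <- sexOf[samples$individual_id[sg$sample_idx]]
  err <- stats::runif(nrow(sg)) < config@sexingErrorRate
  band210 <- trueSex == "M" & !err
  band130 <- ifelse(trueSex == "M", TRUE, !err)
  sexing <- data.frame(
    sample_id = samples$sample_id[sg$sample_idx],
    replicate = sg$replicate,
    band_210bp = band210,
    band_130bp = band130,
    stringsAsFactors = FALSE
  )
  sexing <- sexing[order(sexing$sample_id, sexing$replicate), ]
  rownames(sexing) <- NULL

  list(detections = detections, calls = calls, fragments = fragments,
       sexing = sexing, samples = samples)
}

#' Write simulated data and ground truth to CSV/GenePop files
#'
#' @param sim output of [simulateSamples()].
#' @param pedigree the [Pedigree-class] ground truth.
#' @param truth the true [MultilocusGenotypes-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
writeSimData <- function(sim, pedigree, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    detections = file.path(dir, "detections.csv"),
    calls = file.path(dir, "replicate_calls.csv"),
    fragments = file.path(dir, "fragments.csv"),
    sexing = file.path(dir, "sexing.csv"),
    samples = file.path(dir, "sample_truth.csv"),
    pedigree = file.path(dir, "pedigree.csv"),
    genepop = file.path(dir, "true_genotypes.gen")
  )
  utils::write.csv(sim$detections, paths[["detections"]], row.names = FALSE)
  utils::write.csv(sim$calls, paths[["calls"]], row.names = FALSE)
  utils::write.csv(sim$fragments, paths[["fragments"]], row.names = FALSE)
  utils::write.csv(sim$sexing, paths[["sexing"]], row.names = FALSE)
  utils::write.csv(sim$samples, paths[["samples"]], row.names = FALSE)
  utils::write.csv(pedigree@table, paths[["pedigree"]], row.names = FALSE)
  writeGenepop(truth, paths[["genepop"]], title = "simulated true genotypes")
  invisible(paths)
}
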