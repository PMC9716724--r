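## Multi-tube consensus genotyping, individual matching, sexing, ageing.

## Resolve one locus from replicate allele-pair calls.
## a1s/a2s: allele vectors over replicates (NA = missing replicate call).
## A heterozygote is accepted iff each of its two alleles is observed in at
## least `hetMin` replicates; a homozygote iff the identical homozygous call
## occurs in at least `homMin` replicates; anything else is unresolved (NA).
.resolveLocus <- function(a1s, a2s, hetMin = 2L, homMin = 3L) {
  ok <- !is.na(a1s)
  if (!any(ok)) return(c(NA_character_, NA_character_))
  a1s <- a1s[ok]
  a2s <- a2s[ok]
  ## per-replicate distinct alleles
  obs <- c(a1s, a2s[a2s != a1s])
  counts <- table(obs)
  supported <- names(counts)[counts >= hetMin]
  if (length(supported) == 2L) {
    return(sort(supported))
  }
  if (length(supported) == 1L) {
    homCalls <- sum(a1s == supported & a2s == supported)
    if (homCalls >= homMin) return(c(supported, supported))
  }
  c(NA_character_, NA_character_)
}

#' Consensus genotype of one sample from replicate calls
#'
#' Multi-tube consensus over all supplied replicates: a heterozygote is
#' accepted at a locus iff each of its two alleles is seen in at least
#' `hetMin` replicates, and a homozygote iff the identical homozygous call
#' is seen in at least `homMin` replicates; anything else is unresolved.
#' The caller may supply further replicates for unresolved loci (up to
#' `maxReplicates`, mirroring the field practice of two top-up
#' amplifications) and re-run; loci still unresolved are reported missing.
#' The rule is count-based, hence invariant to replicate order.
#'
#' @param calls data.frame for a single sample with columns `replicate`,
#'   `locus`, `allele1`, `allele2` (NA = failed replicate at that locus).
#' @param loci locus panel; defaults to the loci present in `calls`.
#' @param minReplicates minimum replicates required before consensus is
#'   attempted (refuses otherwise).
#' @param hetMin,homMin replicate-support thresholds described above.
#' @param maxReplicates cap on replicates considered.
#' @return named list: `allele1`, `allele2` (named character vectors per
#'   locus, NA = unresolved) and `unresolved` (locus names unresolved after
#'   all replicates).
#' @export
#' @examples
#' calls <- data.frame(replicate = 1:3, locus = "L01",
#'                     allele1 = c("01", "01", "01"),
#'                     allele2 = c("01", "02", "02"))
#' consensusGenotype(calls)$allele1
consensusGenotype <- function(calls, loci = NULL, minReplicates = 3L,
                              hetMin = 2L, homMin = 3L, maxReplicates = 5L) {
  stopifnot(all(c("replicate", "locus", "allele1", "allele2") %in% names(calls)))
  reps <- sort(unique(calls$replicate))
  if (length(reps) < minReplicates) {
    stop("consensus requires at least ", minReplicates,
         " replicates; got ", length(reps))
  }
  reps <- reps[seq_len(min(length(reps), maxReplicates))]
  if (is.null(loci)) loci <- sort(unique(calls$locus))
  L <- length(loci)

  ## replicate x locus allele matrices
  m1 <- matrix(NA_character_, length(reps), L, dimnames = list(reps, loci))
  m2 <- m1
  keep <- calls$replicate %in% reps & calls$locus %in% loci
  cc <- calls[keep, ]
  ij <- cbind(match(cc$replicate, reps), match(cc$locus, loci))
  m1[ij] <- cc$allele1
  m2[ij] <- cc$allele2

  a1 <- setNames(rep(NA_character_, L), loci)
  a2 <- a1
  for (l in seq_len(L)) {
    g <- .resolveLocus(m1[, l], m2[, l], hetMin = hetMin, homMin = homMin)
    a1[l] <- g[1L]
    a2[l] <- g[2L]
  }
  list(allele1 = a1, allele2 = a2, unresolved = loci[is.na(a1)])
}

#' Consensus genotypes for a table of replicate calls
#'
#' Applies [consensusGenotype()] per sample.
#'
#' @param calls data.frame with columns `sample_id`, `replicate`, `locus`,
#'   `allele1`, `allele2`.
#' @param loci locus panel; defaults to all loci present.
#' @inheritParams consensusGenotype
#' @return a [MultilocusGenotypes-class] with one row per sample
#'   (unresolved loci are NA).
#' @export
consensusGenotypes <- function(calls, loci = NULL, minReplicates = 3L,
                               hetMin = 2L, homMin = 3L, maxReplicates = 5L) {
  if (is.null(loci)) loci <- sort(unique(calls$locus))
  samples <- sort(unique(calls$sample_id))
  a1 <- matrix(NA_character_, length(samples), length(loci),
               dimnames = list(samples, loci))
  a2 <- a1
  split_calls <- split(calls, calls$sample_id)
  for (s in samples) {
    g <- consensusGenotype(split_calls[[s]], loci = loci,
                           minReplicates = minReplicates, hetMin = hetMin,
                           homMin = homMin, maxReplicates = maxReplicates)
    a1[s, ] <- g$allele1
    a2[s, ] <- g$allele2
  }
  multilocusGenotypes(a1, a2)
}

## mismatch count and shared-locus count between two genotype rows
.pairMismatch <- function(a1, a2, b1, b2) {
  shared <- !is.na(a1) & !is.na(b1)
  if (!any(shared)) return(c(mismatch = 0L, shared = 0L))
  mm <- sum(!(a1[shared] == b1[shared] & a2[shared] == b2[shared]))
  c(mismatch = mm, shared = sum(shared))
}

## per-locus majority consensus across member samples; ties resolved toward
## the pair carried by the earliest (lowest) sample id
.clusterConsensus <- function(geno, members) {
  loci <- lociNames(geno)
  a1 <- setNames(rep(NA_character_, length(loci)), loci)
  a2 <- a1
  members <- sort(members)
  g1 <- geno@allele1[members, , drop = FALSE]
  g2 <- geno@allele2[members, , drop = FALSE]
  for (l in seq_along(loci)) {
    ok <- !is.na(g1[, l])
    if (!any(ok)) next
    pair <- paste(g1[ok, l], g2[ok, l], sep = "|")
    counts <- table(pair)
    best <- names(counts)[counts == max(counts)]
    if (length(best) > 1L) {
      best <- pair[match(TRUE, pair %in% best)]  # earliest sample's pair
    }
    al <- strsplit(best, "|", fixed = TRUE)[[1L]]
    a1[l] <- al[1L]
    a2[l] <- al[2L]
  }
  list(allele1 = a1, allele2 = a2)
}

#' Match samples into individuals by genotype similarity
#'
#' Samples are clustered by single linkage on the relation "the two
#' genotypes differ at no more than `maxMismatchLoci` of their jointly
#' resolved loci". Each cluster is one putative individual whose consensus
#' genotype is the per-locus majority over member samples. An optional
#' reconciliation pass then re-compares cluster consensuses at zero
#' mismatches (over at least `minSharedLoci` jointly resolved loci) and
#' merges clusters that are indistinguishable. Samples with fewer than
#' `minSharedLoci` resolved loci are excluded (reported, never
#' force-assigned). The number of clusters is the population-size estimate.
#'
#' @param genotypes a [MultilocusGenotypes-class] of per-sample consensus
#'   genotypes.
#' @param maxMismatchLoci maximum mismatching loci for two samples to match.
#' @param minSharedLoci minimum resolved loci for a sample to enter
#'   matching (and for the reconciliation comparison).
#' @param reconcile run the zero-mismatch consensus reconciliation pass.
#' @return list: `individuals` (data.frame individual_id, n_samples,
#'   n_loci), `genotypes` ([MultilocusGenotypes-class], one row per
#'   individual), `membership` (data.frame sample_id, individual_id), and
#'   `excluded` (sample ids dropped for having too few resolved loci).
#' @export
matchIndividuals <- function(genotypes, maxMismatchLoci = 2L,
                             minSharedLoci = 9L, reconcile = TRUE) {
  stopifnot(is(genotypes, "MultilocusGenotypes"))
  ids <- individualIds(genotypes)
  resolved <- rowSums(!is.na(genotypes@allele1))
  excluded <- ids[resolved < minSharedLoci]
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " sample(s) with < ", minSharedLoci, " resolved loci: ",
            paste(utils::head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ..." else "")
  }
  keep <- setdiff(ids, excluded)
  if (length(keep) == 0L) stop("no samples left after quality exclusion")
  g <- genotypes[keep]
  n <- length(keep)

  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        pm <- .pairMismatch(g@allele1[i, ], g@allele2[i, ],
                            g@allele1[j, ], g@allele2[j, ])
        adj[i, j] <- adj[j, i] <-
          pm[["shared"]] >= 1L && pm[["mismatch"]] <= maxMismatchLoci
      }
    }
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  clusters <- split(keep, comp)

  if (reconcile && length(clusters) > 1L) {
    repeat {
      cons <- lapply(clusters, function(m) .clusterConsensus(g, m))
      k <- length(clusters)
      merged <- FALSE
      for (i in seq_len(k - 1L)) {
        for (j in seq(i + 1L, k)) {
          pm <- .pairMismatch(cons[[i]]$allele1, cons[[i]]$allele2,
                              cons[[j]]$allele1, cons[[j]]$allele2)
          if (pm[["shared"]] >= minSharedLoci && pm[["mismatch"]] == 0L) {
            clusters[[i]] <- c(clusters[[i]], clusters[[j]])
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }

  ## order individuals by their lowest member sample id
  ord <- order(vapply(clusters, function(m) min(m), character(1)))
  clusters <- clusters[ord]
  indIds <- sprintf("IND%03d", seq_along(clusters))
  names(clusters) <- indIds

  loci <- lociNames(genotypes)
  a1 <- matrix(NA_character_, length(clusters), length(loci),
               dimnames = list(indIds, loci))
  a2 <- a1
  for (k in seq_along(clusters)) {
    cons <- .clusterConsensus(g, clusters[[k]])
    a1[k, ] <- cons$allele1
    a2[k, ] <- cons$allele2
  }
  consGeno <- multilocusGenotypes(a1, a2)

  membership <- data.frame(
    sample_id = unlist(clusters, use.names = FALSE),
    individual_id = rep(indIds, lengths(clusters)),
    stringsAsFactors = FALSE
  )
  membership <- membership[order(membership$sample_id), ]
  rownames(membership) <- NULL

  individuals <- data.frame(
    individual_id = indIds,
    n_samples = as.integer(lengths(clusters)),
    n_loci = as.integer(rowSums(!is.na(a1))),
    stringsAsFactors = FALSE
  )

  list(individuals = individuals, genotypes = consGeno,
       membership = membership, excluded = excluded)
}

#' Molecular sexing from replicate band patterns
#'
#' A replicate shows the 210-bp band (Y-linked) and/or the 130-bp band
#' (shared). The individual is male iff at least two replicates show both
#' bands; female iff no replicate shows the 210-bp band and at least two
#' replicates show the 130-bp band; otherwise unknown.
#'
#' @param band210,band130 logical vectors over replicates.
#' @return "male", "female" or "unknown".
#' @export
#' @examples
#' determineSex(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))   # male
#' determineSex(c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE)) # female
determineSex <- function(band210, band130) {
  stopifnot(length(band210) == length(band130))
  interpretable <- band210 | band130
  if (!any(interpretable)) {
    warning("no interpretable sexing replicates; sex unknown")
    return("unknown")
  }
  if (sum(band210 & band130) >= 2L) return("male")
  if (!any(band210) && sum(band130) >= 2L) return("female")
  "unknown"
}

#' Default age-classification calibration
#'
#' Reference (mean length, mean width, age class) points from fecal
#' fragment measurements of wild giant pandas of known or field-assigned
#' age class, shipped as `inst/extdata/age_calibration.csv`.
#'
#' @return data.frame with columns individual, lengthMean, widthMean,
#'   ageClass.
#' @export
defaultAgeCalibration <- function() {
  path <- system.file("extdata", "age_calibration.csv", package = "pandaNet")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Classify age class from fecal fragment sizes
#'
#' Nearest-centroid classification of the sample's mean fragment (length,
#' width) against per-class calibration centroids, after standardizing each
#' axis by the calibration mean and SD. Samples whose mean length exceeds
#' the (raw) adult centroid length by more than `elderlyFactor` are flagged
#' "elderly" (tooth wear leaves markedly longer fragments). Samples without
#' fragments are cubs if flagged unweaned, otherwise unknown. Fewer than
#' `minFragments` measurements yield "unknown" with a warning unless
#' `override = TRUE`.
#'
#' @param lengths,widths numeric fragment measurements (mm).
#' @param calibration data.frame with columns lengthMean, widthMean,
#'   ageClass (values "adult"/"subadult").
#' @param minFragments minimum measurements for a classifiable sample.
#' @param elderlyFactor multiple of the adult centroid length above which a
#'   sample is flagged elderly.
#' @param unweaned flag for samples known to come from unweaned cubs.
#' @param override classify even with fewer than `minFragments` fragments.
#' @return "cub", "subadult", "adult", "elderly" or "unknown".
#' @export
classifyAge <- function(lengths, widths, calibration = defaultAgeCalibration(),
                        minFragments = 40L, elderlyFactor = 1.3,
                        unweaned = FALSE, override = FALSE) {
  if (length(lengths) == 0L) {
    return(if (unweaned) "cub" else "unknown")
  }
  stopifnot(length(lengths) == length(widths),
            all(lengths > 0), all(widths > 0),
            nrow(calibration) > 0L)
  if (length(lengths) < minFragments && !override) {
    warning("fewer than ", minFragments,
            " fragments; age class set to unknown")
    return("unknown")
  }
  mu <- c(mean(calibration$lengthMean), mean(calibration$widthMean))
  sd2 <- c(stats::sd(calibration$lengthMean), stats::sd(calibration$widthMean))
  sd2[sd2 == 0 | is.na(sd2)] <- 1
  zcal <- cbind((calibration$lengthMean - mu[1]) / sd2[1],
                (calibration$widthMean - mu[2]) / sd2[2])
  classes <- unique(calibration$ageClass)
  centroids <- t(vapply(classes, function(cl) {
    colMeans(zcal[calibration$ageClass == cl, , drop = FALSE])
  }, numeric(2)))
  point <- c((mean(lengths) - mu[1]) / sd2[1],
             (mean(widths) - mu[2]) / sd2[2])
  d2 <- rowSums((centroids - matrix(point, nrow(centroids), 2, byrow = TRUE))^2)
  cls <- classes[which.min(d2)]
  if (cls == "adult") {
    adultLen <- mean(calibration$lengthMean[calibration$ageClass == "adult"])
    if (mean(lengths) > elderlyFactor * adultLen) cls <- "elderly"
  }
  cls
}

#' Identify individuals with sex and age from raw sample data
#'
#' End-to-end identification stage: per-sample consensus genotypes,
#' genotype matching into individuals, pooled molecular sexing and pooled
#' fragment-based age classification per individual.
#'
#' @param calls replicate genotype calls (sample_id, replicate, locus,
#'   allele1, allele2).
#' @param sexing sexing replicates (sample_id, replicate, band_210bp,
#'   band_130bp).
#' @param fragments fragment measurements (sample_id, length_mm, width_mm);
#'   may be NULL.
#' @param loci locus panel; defaults to loci present in `calls`.
#' @param calibration age calibration, see [classifyAge()].
#' @param maxMismatchLoci,minSharedLoci see [matchIndividuals()].
#' @param ... further arguments to [consensusGenotypes()].
#' @return list: `individuals` (data.frame individual_id, sex, ageClass,
#'   n_samples, n_loci, meanLength, meanWidth), `genotypes`
#'   ([MultilocusGenotypes-class] per individual), `membership`,
#'   `excluded`.
#' @export
identifyIndividuals <- function(calls, sexing, fragments = NULL, loci = NULL,
                                calibration = defaultAgeCalibration(),
                                maxMismatchLoci = 2L, minSharedLoci = 9L,
                                ...) {
  sampleGeno <- consensusGenotypes(calls, loci = loci, ...)
  matched <- matchIndividuals(sampleGeno, maxMismatchLoci = maxMismatchLoci,
                              minSharedLoci = minSharedLoci)
  ind <- matched$individuals
  memb <- matched$membership

  ind$sex <- "unknown"
  ind$ageClass <- "unknown"
  ind$meanLength <- NA_real_
  ind$meanWidth <- NA_real_
  for (k in seq_len(nrow(ind))) {
    sids <- memb$sample_id[memb$individual_id == ind$individual_id[k]]
    sx <- sexing[sexing$sample_id %in% sids, , drop = FALSE]
    if (nrow(sx) > 0L) {
      ind$sex[k] <- c(male = "M", female = "F", unknown = "unknown")[
        determineSex(sx$band_210bp, sx$band_130bp)]
    }
    if (!is.null(fragments)) {
      fr <- fragments[fragments$sample_id %in% sids, , drop = FALSE]
      if (nrow(fr) > 0L) {
        ind$ageClass[k] <- classifyAge(fr$length_mm, fr$width_mm,
                                       calibration = calibration)
        ind$meanLength[k] <- mean(fr$length_mm)
        ind$meanWidth[k] <- mean(fr$width_mm)
      }
    }
  }
  ind <- ind[, c("individual_id", "sex", "ageClass", "n_samples", "n_loci",
                 "meanLength", "meanWidth")]
  list(individuals = ind, genotypes = matched$genotypes,
       membership = memb, excluded = matched$excluded)
}
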