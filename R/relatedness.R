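## Allele frequencies, Queller-Goodnight pairwise relatedness, kin classes.

#' Allele frequencies from identified individuals
#'
#' Per locus, the frequency of each allele among all non-missing allele
#' copies, counting each identified individual once (never per sample).
#' Loci resolved in zero individuals are dropped with a warning. No
#' small-sample bias correction is applied: the focal pair's own alleles
#' are included, as is conventional when frequencies are estimated from all
#' identified individuals.
#'
#' @param genotypes a [MultilocusGenotypes-class], one row per individual.
#' @return named list (per locus) of named numeric frequency vectors.
#' @export
#' @examples
#' g <- multilocusGenotypes(
#'   matrix(c("A", "A"), 2, 1, dimnames = list(c("i1", "i2"), "L1")),
#'   matrix(c("A", "B"), 2, 1, dimnames = list(c("i1", "i2"), "L1")))
#' alleleFrequencies(g)$L1  # A: 0.75, B: 0.25
alleleFrequencies <- function(genotypes) {
  stopifnot(is(genotypes, "MultilocusGenotypes"))
  if (length(individualIds(genotypes)) < 2L) {
    stop("allele frequencies require at least 2 individuals")
  }
  loci <- lociNames(genotypes)
  out <- vector("list", length(loci))
  names(out) <- loci
  empty <- character()
  for (l in loci) {
    copies <- c(genotypes@allele1[, l], genotypes@allele2[, l])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0L) {
      empty <- c(empty, l)
      next
    }
    tab <- table(copies)
    out[[l]] <- setNames(as.numeric(tab) / length(copies), names(tab))
  }
  if (length(empty)) {
    warning("dropping loci resolved in zero individuals: ",
            paste(empty, collapse = ", "))
    out <- out[setdiff(loci, empty)]
  }
  out
}

## Core Queller-Goodnight computation on parallel matrices of allele labels
## and matching frequency lookups. Rows = dyads/pairs, columns = loci; NA
## cells are excluded locus-wise. Returns the symmetrized estimate per row.
.qgCore <- function(a, b, c_, d, pa, pb, pc, pd) {
  shared <- !(is.na(a) | is.na(c_))
  sim <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d))
  numx <- sim - pa - pb
  denx <- 1 + (a == b) - pa - pb
  numy <- sim - pc - pd
  deny <- 1 + (c_ == d) - pc - pd
  numx[!shared] <- denx[!shared] <- 0
  numy[!shared] <- deny[!shared] <- 0
  if (is.matrix(a)) {
    nShared <- rowSums(shared)
    sx <- rowSums(denx)
    sy <- rowSums(deny)
    r <- (rowSums(numx) / sx + rowSums(numy) / sy) / 2
    r[nShared == 0L | sx == 0 | sy == 0] <- NA_real_
    list(r = r, nShared = nShared)
  } else {
    nShared <- sum(shared)
    sx <- sum(denx)
    sy <- sum(deny)
    r <- if (nShared == 0L || sx == 0 || sy == 0) NA_real_ else
      (sum(numx) / sx + sum(numy) / sy) / 2
    list(r = r, nShared = nShared)
  }
}

## extract allele vectors from a one-row MultilocusGenotypes or an
## allele1/allele2 list
.genoVectors <- function(x) {
  if (is(x, "MultilocusGenotypes")) {
    stopifnot(nrow(x@allele1) == 1L)
    list(a1 = x@allele1[1L, ], a2 = x@allele2[1L, ])
  } else {
    list(a1 = x$allele1, a2 = x$allele2)
  }
}

#' Queller-Goodnight pairwise relatedness
#'
#' Moment estimator of pairwise relatedness from multilocus genotypes and
#' population allele frequencies. For a locus where x carries alleles
#' (a, b) and y carries (c, d), with I the allele-identity indicator and p
#' the population frequency:
#' \deqn{num_x = 0.5 (I_{ac} + I_{ad} + I_{bc} + I_{bd}) - p_a - p_b}
#' \deqn{den_x = 1 + I_{ab} - p_a - p_b}
#' Numerators and denominators are summed over the shared resolved loci,
#' r_x = sum(num_x) / sum(den_x), r_y symmetrically with y as focal, and
#' R = (r_x + r_y) / 2. With true allele frequencies the estimator is
#' unbiased: expected R is 0.5 for parent-offspring and full sibs, 0.25 for
#' half sibs, 0.125 for first cousins, 0 for unrelated pairs. Estimates can
#' fall slightly outside [-1, 1] with estimated frequencies and are
#' reported as-is.
#'
#' @param x,y single-row [MultilocusGenotypes-class] objects (or lists with
#'   named `allele1`/`allele2` vectors over loci).
#' @param freqs allele frequencies as from [alleleFrequencies()].
#' @return the relatedness estimate R, or NA if the pair shares no resolved
#'   locus or a pooled denominator is zero.
#' @export
#' @examples
#' f <- list(L1 = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25))
#' x <- list(allele1 = c(L1 = "A"), allele2 = c(L1 = "B"))
#' qgRelatedness(x, x, f)  # 1
qgRelatedness <- function(x, y, freqs) {
  gx <- .genoVectors(x)
  gy <- .genoVectors(y)
  loci <- intersect(names(gx$a1), names(freqs))
  if (length(loci) == 0L) return(NA_real_)
  a <- gx$a1[loci]; b <- gx$a2[loci]
  c_ <- gy$a1[loci]; d <- gy$a2[loci]
  lk <- function(al) {
    vapply(seq_along(loci), function(i) {
      if (is.na(al[i])) NA_real_ else unname(freqs[[loci[i]]][al[i]])
    }, numeric(1))
  }
  .qgCore(a, b, c_, d, lk(a), lk(b), lk(c_), lk(d))$r
}

#' Pairwise relatedness matrix over identified individuals
#'
#' Applies the Queller-Goodnight estimator to every unordered pair;
#' symmetric by construction, masked (NA) diagonal. Pairs with fewer than
#' `lowConfidenceLoci` jointly resolved loci remain in the matrix but are
#' flagged via the `nLoci` slot (see [lowConfidencePairs()]).
#'
#' @param genotypes a [MultilocusGenotypes-class], one row per individual.
#' @param freqs allele frequencies; default estimated from `genotypes`.
#' @return a [RelatednessMatrix-class].
#' @export
relatednessMatrix <- function(genotypes, freqs = alleleFrequencies(genotypes)) {
  stopifnot(is(genotypes, "MultilocusGenotypes"))
  ids <- individualIds(genotypes)
  n <- length(ids)
  loci <- intersect(lociNames(genotypes), names(freqs))
  a1 <- genotypes@allele1[, loci, drop = FALSE]
  a2 <- genotypes@allele2[, loci, drop = FALSE]
  flist <- freqs[loci]
  p1 <- .freqLookup(a1, flist)
  p2 <- .freqLookup(a2, flist)

  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nl <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- seq(i + 1L, n)
      res <- .qgCore(
        matrix(a1[i, ], length(j), length(loci), byrow = TRUE),
        matrix(a2[i, ], length(j), length(loci), byrow = TRUE),
        a1[j, , drop = FALSE], a2[j, , drop = FALSE],
        matrix(p1[i, ], length(j), length(loci), byrow = TRUE),
        matrix(p2[i, ], length(j), length(loci), byrow = TRUE),
        p1[j, , drop = FALSE], p2[j, , drop = FALSE])
      v[i, j] <- v[j, i] <- res$r
      nl[i, j] <- nl[j, i] <- as.integer(res$nShared)
    }
  }
  nMasked <- sum(is.na(v[lower.tri(v)]))
  if (nMasked > 0L) {
    message(nMasked, " pair(s) masked (no shared resolved loci or zero denominator)")
  }
  new("RelatednessMatrix", values = v, nLoci = nl)
}

#' Pairs estimated from few shared loci
#'
#' @param rmat a [RelatednessMatrix-class].
#' @param minLoci confidence threshold on jointly resolved loci.
#' @return data.frame id1, id2, nLoci for pairs below the threshold.
#' @export
lowConfidencePairs <- function(rmat, minLoci = 6L) {
  nl <- rmat@nLoci
  lt <- which(lower.tri(nl) & nl < minLoci, arr.ind = TRUE)
  data.frame(id1 = rownames(nl)[lt[, "row"]],
             id2 = colnames(nl)[lt[, "col"]],
             nLoci = nl[lt],
             stringsAsFactors = FALSE)
}

#' Kin class from a relatedness value
#'
#' Bins R against the canonical relatedness anchors (first-class relatives
#' 0.5, second-class 0.25, third-class 0.125): R < 0.125 is unrelated;
#' bins between classes are split at the midpoints 0.1875 and 0.375.
#'
#' @param R numeric vector of relatedness values.
#' @param edges ascending cut points: unrelated/third, third/second,
#'   second/first.
#' @return character vector in {"unrelated", "third", "second", "first"}
#'   (NA for masked input).
#' @export
#' @examples
#' classifyKin(c(0.124, 0.125, 0.2, 0.5))
classifyKin <- function(R, edges = c(0.125, 0.1875, 0.375)) {
  stopifnot(length(edges) == 3L, !is.unsorted(edges))
  out <- rep(NA_character_, length(R))
  ok <- is.finite(R)
  out[ok & R < edges[1L]] <- "unrelated"
  out[ok & R >= edges[1L] & R < edges[2L]] <- "third"
  out[ok & R >= edges[2L] & R < edges[3L]] <- "second"
  out[ok & R >= edges[3L]] <- "first"
  out
}

#' Relatedness summary by sex-pair group (MM / MF / FF)
#'
#' Partitions all defined pairs by the sexes of their members and reports
#' per group the pair count, relatedness mean/SD, the proportion of
#' relatives (R at or above the unrelated cutoff), and the per-kin-class
#' proportions. Individuals of unknown sex are excluded (reported via a
#' message).
#'
#' @param rmat a [RelatednessMatrix-class].
#' @param sex named character vector ("M"/"F"/"unknown") covering the
#'   matrix ids.
#' @param edges kin-class cut points, see [classifyKin()].
#' @return list: `pairs` (data.frame id1, id2, R, nLoci, sexPair,
#'   kinClass) and `summary` (one row per group: n, nDefined, meanR, sdR,
#'   propRelatives, propFirst, propSecond, propThird).
#' @export
pairGroupSummary <- function(rmat, sex, edges = c(0.125, 0.1875, 0.375)) {
  stopifnot(is(rmat, "RelatednessMatrix"))
  ids <- individualIds(rmat)
  sex <- sex[ids]
  known <- !is.na(sex) & sex %in% c("M", "F")
  if (any(!known)) {
    message("excluding ", sum(!known), " individual(s) of unknown sex")
  }
  ids <- ids[known]
  v <- rmat@values[ids, ids, drop = FALSE]
  nl <- rmat@nLoci[ids, ids, drop = FALSE]
  sx <- sex[ids]

  lt <- which(lower.tri(v), arr.ind = TRUE)
  pairSex <- vapply(seq_len(nrow(lt)), function(k) {
    s <- sort(c(sx[lt[k, "row"]], sx[lt[k, "col"]]), decreasing = TRUE)
    paste0(s, collapse = "")
  }, character(1))
  pairs <- data.frame(
    id1 = ids[lt[, "col"]],
    id2 = ids[lt[, "row"]],
    R = v[lt],
    nLoci = nl[lt],
    sexPair = pairSex,
    stringsAsFactors = FALSE
  )
  pairs$kinClass <- classifyKin(pairs$R, edges = edges)

  groups <- c("MM", "MF", "FF")
  summ <- do.call(rbind, lapply(groups, function(gp) {
    sub <- pairs[pairs$sexPair == gp, ]
    def <- sub[!is.na(sub$R), ]
    nDef <- nrow(def)
    if (nDef == 0L) {
      return(data.frame(group = gp, n = nrow(sub), nDefined = 0L,
                        meanR = NA_real_, sdR = NA_real_,
                        propRelatives = NA_real_, propFirst = NA_real_,
                        propSecond = NA_real_, propThird = NA_real_))
    }
    data.frame(
      group = gp, n = nrow(sub), nDefined = nDef,
      meanR = mean(def$R), sdR = stats::sd(def$R),
      propRelatives = mean(def$R >= edges[1L]),
      propFirst = mean(def$kinClass == "first"),
      propSecond = mean(def$kinClass == "second"),
      propThird = mean(def$kinClass == "third"))
  }))
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ)
}

#' Write a relatedness matrix as square CSV (masked cells empty)
#'
#' @param rmat a [RelatednessMatrix-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeRelatednessCsv <- function(rmat, path) {
  utils::write.csv(rmat@values, path, na = "")
  invisible(path)
}

#' Read a square relatedness CSV written by [writeRelatednessCsv()]
#'
#' @param path CSV file.
#' @return a [RelatednessMatrix-class] (shared-locus counts unknown, 0).
#' @export
readRelatednessCsv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  diag(m) <- NA_real_
  m[upper.tri(m)] <- t(m)[upper.tri(m)]  # enforce exact symmetry
  new("RelatednessMatrix", values = m,
      nLoci = matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m)))
}
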