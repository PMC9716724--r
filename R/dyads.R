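## Dyad simulator for estimator calibration: gene-drops small fixed
## pedigrees many times and returns the Queller-Goodnight estimate per
## replicate, computed with the true (configured) allele frequencies.

## draw founder genotypes for n replicates over a locus panel
.founderDraw <- function(n, lociSpec) {
  L <- length(lociSpec)
  a1 <- matrix(NA_character_, n, L, dimnames = list(NULL, names(lociSpec)))
  a2 <- a1
  for (l in seq_len(L)) {
    sp <- lociSpec[[l]]
    a1[, l] <- sample(sp$alleles, n, replace = TRUE, prob = sp$freqs)
    a2[, l] <- sample(sp$alleles, n, replace = TRUE, prob = sp$freqs)
  }
  list(a1 = a1, a2 = a2)
}

## one Mendelian child of two parent genotype matrices
.childOf <- function(m, f) {
  pickM <- matrix(stats::runif(length(m$a1)) < 0.5, nrow(m$a1))
  pickF <- matrix(stats::runif(length(f$a1)) < 0.5, nrow(f$a1))
  a1 <- ifelse(pickM, m$a1, m$a2)
  a2 <- ifelse(pickF, f$a1, f$a2)
  dimnames(a1) <- dimnames(a2) <- dimnames(m$a1)
  list(a1 = a1, a2 = a2)
}

#' Simulate relative dyads and estimate their relatedness
#'
#' Gene-drops `nDyads` independent replicates of a minimal pedigree for the
#' requested relationship (founders drawn from the configured allele
#' frequencies, offspring by Mendelian inheritance) and returns the
#' symmetrized Queller-Goodnight estimate for each dyad, computed with the
#' true allele frequencies. Expected values: parent-offspring and full sibs
#' 0.5, half sibs 0.25, first cousins 0.125 (offspring of full-sib parents
#' mated to unrelated partners), unrelated 0.
#'
#' @param relationship one of "parent-offspring", "full-sib", "half-sib",
#'   "first-cousin", "unrelated".
#' @param nDyads number of independent dyads.
#' @param lociSpec locus panel, see [defaultLociSpec()].
#' @param seed RNG seed.
#' @return numeric vector of length `nDyads` of relatedness estimates.
#' @export
#' @examples
#' r <- simulateDyadRelatedness("parent-offspring", 200, seed = 1L)
#' mean(r)  # close to 0.5
simulateDyadRelatedness <- function(relationship = c("parent-offspring",
                                                     "full-sib", "half-sib",
                                                     "first-cousin",
                                                     "unrelated"),
                                    nDyads = 500L,
                                    lociSpec = defaultLociSpec(),
                                    seed = 1L) {
  relationship <- match.arg(relationship)
  set.seed(seed)
  n <- nDyads

  dyad <- switch(relationship,
    "parent-offspring" = {
      m <- .founderDraw(n, lociSpec)
      f <- .founderDraw(n, lociSpec)
      list(x = m, y = .childOf(m, f))
    },
    "full-sib" = {
      m <- .founderDraw(n, lociSpec)
      f <- .founderDraw(n, lociSpec)
      list(x = .childOf(m, f), y = .childOf(m, f))
    },
    "half-sib" = {
      m <- .founderDraw(n, lociSpec)
      f1 <- .founderDraw(n, lociSpec)
      f2 <- .founderDraw(n, lociSpec)
      list(x = .childOf(m, f1), y = .childOf(m, f2))
    },
    "first-cousin" = {
      gm <- .founderDraw(n, lociSpec)
      gf <- .founderDraw(n, lociSpec)
      s1 <- .childOf(gm, gf)
      s2 <- .childOf(gm, gf)
      p1 <- .founderDraw(n, lociSpec)
      p2 <- .founderDraw(n, lociSpec)
      list(x = .childOf(s1, p1), y = .childOf(s2, p2))
    },
    "unrelated" = {
      list(x = .founderDraw(n, lociSpec), y = .founderDraw(n, lociSpec))
    }
  )

  freqs <- lapply(lociSpec, function(sp) setNames(sp$freqs, sp$alleles))
  lk <- function(m) .freqLookup(m, freqs)
  res <- .qgCore(dyad$x$a1, dyad$x$a2, dyad$y$a1, dyad$y$a2,
                 lk(dyad$x$a1), lk(dyad$x$a2),
                 lk(dyad$y$a1), lk(dyad$y$a2))
  res$r
}
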