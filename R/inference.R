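## Permutation inference layer: node-permutation null models, Mantel test,
## Wilcoxon rank-sum.

#' Label-permutation test for a difference in mean node values
#'
#' Core of the node-permutation null model: the observed statistic is the
#' difference in mean `values` between the two label levels (second level
#' minus first, levels sorted unless given); the null is built by shuffling
#' labels over nodes with the values (i.e. the network structure) held
#' fixed. The two-tailed p-value includes the observed statistic in the
#' reference set: p = (b + 1) / (nPerm + 1) with b the number of null
#' statistics at least as extreme in absolute value.
#'
#' @param values numeric node metric (e.g. strength).
#' @param labels binary attribute over nodes.
#' @param nPerm number of label permutations.
#' @param seed RNG seed (optional).
#' @param levels optional explicit level order c(reference, focal).
#' @param statistic descriptor stored in the result.
#' @return a [PermutationResult-class]. The `effect` slot holds the same
#'   statistic computed on z-scored values (standardized effect size).
#' @export
labelPermutationTest <- function(values, labels, nPerm = 1000L, seed = NULL,
                                 levels = NULL, statistic = "mean difference") {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels[keep])
  if (is.null(levels)) levels <- sort(unique(labels))
  if (length(levels) != 2L) {
    stop("degenerate attribute: exactly two label levels required, got ",
         length(unique(labels)))
  }
  if (!all(table(factor(labels, levels = levels)) >= 1L)) {
    stop("degenerate attribute: each level needs at least one node")
  }
  if (!is.null(seed)) set.seed(seed)

  stat <- function(v, lb) mean(v[lb == levels[2L]]) - mean(v[lb == levels[1L]])
  obs <- stat(values, labels)
  zv <- if (stats::sd(values) > 0) as.numeric(scale(values)) else values * 0
  eff <- stat(zv, labels)

  null <- vapply(seq_len(nPerm), function(k) stat(values, sample(labels)),
                 numeric(1))
  p <- (sum(abs(null) >= abs(obs)) + 1) / (nPerm + 1)

  new("PermutationResult", observed = obs, null = null, pValue = p,
      nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      statistic = statistic, effect = eff)
}

#' Node-permutation test of a binary attribute on a network metric
#'
#' Tests whether nodes of one attribute level (e.g. males) have a higher
#' mean metric (strength or degree) than the other, against a null built by
#' permuting node labels with the network fixed. For `ageClass`, elderly
#' adults count as adults and cubs as sub-adults; nodes with an "unknown"
#' attribute are dropped with a message.
#'
#' @param net an [AttributedNetwork-class].
#' @param attribute "sex" or "ageClass".
#' @param metric "strength" (weighted degree, default) or "degree".
#' @param nPerm number of permutations (1000 by default).
#' @param seed RNG seed (optional).
#' @return a [PermutationResult-class]; the observed statistic is
#'   mean(level 2) - mean(level 1) with levels sorted ("F" < "M",
#'   "adult" < "subadult" reversed to adult-minus-subadult).
#' @export
nodePermutationTest <- function(net, attribute = c("sex", "ageClass"),
                                metric = c("strength", "degree"),
                                nPerm = 1000L, seed = NULL) {
  attribute <- match.arg(attribute)
  metric <- match.arg(metric)
  stopifnot(is(net, "AttributedNetwork"))
  g <- net@graph
  vals <- switch(metric,
                 strength = igraph::strength(g),
                 degree = igraph::degree(g))
  lab <- igraph::vertex_attr(g, attribute)
  if (attribute == "ageClass") {
    lab <- ifelse(lab %in% c("adult", "elderly"), "adult",
                  ifelse(lab %in% c("subadult", "cub"), "subadult", NA))
    levels <- c("subadult", "adult")
  } else {
    lab[!lab %in% c("M", "F")] <- NA
    levels <- c("F", "M")
  }
  if (any(is.na(lab))) {
    message("dropping ", sum(is.na(lab)), " node(s) with unknown ", attribute)
  }
  labelPermutationTest(vals, lab, nPerm = nPerm, seed = seed,
                       levels = levels,
                       statistic = paste0(metric, " ~ ", attribute, " (",
                                          net@kind, " network)"))
}

#' Mantel test between two square association/relatedness matrices
#'
#' Correlates the strict lower triangles of two symmetric matrices over the
#' same node set (Spearman by default; cells masked NA in either matrix are
#' excluded pairwise) and builds the null by applying one random node
#' relabelling simultaneously to the rows and columns of the second matrix
#' per iteration. The two-tailed p-value includes the observed statistic:
#' (b + 1) / (nPerm + 1).
#'
#' @param A,B square symmetric matrices with identical node order (or
#'   [RelatednessMatrix-class] objects); at least 4 nodes.
#' @param method "spearman" (default) or "pearson".
#' @param nPerm number of node permutations.
#' @param seed RNG seed (optional).
#' @return a [MantelResult-class].
#' @export
mantelTest <- function(A, B, method = c("spearman", "pearson"),
                       nPerm = 1000L, seed = NULL) {
  method <- match.arg(method)
  if (is(A, "RelatednessMatrix")) A <- A@values
  if (is(B, "RelatednessMatrix")) B <- B@values
  stopifnot(is.matrix(A), is.matrix(B))
  n <- nrow(A)
  if (n != ncol(A) || nrow(B) != ncol(B) || nrow(B) != n) {
    stop("matrices must be square and of equal size")
  }
  if (n < 4L) stop("permutation space too small: at least 4 nodes required")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("matrices must share the same node ordering")
  }
  symOk <- function(m) {
    off <- m
    diag(off) <- 0
    offNA <- is.na(m)
    diag(offNA) <- FALSE
    identical(offNA, t(offNA)) &&
      isTRUE(all.equal(off[!is.na(off)], t(off)[!is.na(t(off))],
                       check.attributes = FALSE))
  }
  if (!symOk(A) || !symOk(B)) stop("matrices must be symmetric")
  if (!is.null(seed)) set.seed(seed)

  lt <- lower.tri(A)
  av <- A[lt]
  bv <- B[lt]
  valid <- !is.na(av) & !is.na(bv)
  if (sum(valid) < 3L) stop("too few defined pairs shared by both matrices")
  obs <- stats::cor(av[valid], bv[valid], method = method)

  noNA <- !anyNA(av) && !anyNA(bv)
  if (noNA) {
    ## Spearman = Pearson on ranks; under simultaneous row/col relabelling
    ## the off-diagonal multiset is invariant, so ranks can be precomputed.
    if (method == "spearman") {
      x <- rank(av)
      RB <- matrix(0, n, n)
      RB[lt] <- rank(bv)
      RB <- RB + t(RB)
    } else {
      x <- av
      RB <- B
      diag(RB) <- 0
    }
    null <- vapply(seq_len(nPerm), function(k) {
      p <- sample.int(n)
      stats::cor(x, RB[p, p][lt])
    }, numeric(1))
  } else {
    null <- vapply(seq_len(nPerm), function(k) {
      p <- sample.int(n)
      bp <- B[p, p][lt]
      ok <- !is.na(av) & !is.na(bp)
      stats::cor(av[ok], bp[ok], method = method)
    }, numeric(1))
  }
  p <- (sum(abs(null) >= abs(obs)) + 1) / (nPerm + 1)

  new("MantelResult", statistic = obs, null = null, pValue = p,
      nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      method = method, nPairs = as.integer(sum(valid)))
}

#' Wilcoxon rank-sum test
#'
#' W is the rank sum of the first sample under pooled mid-ranks. The
#' two-sided p-value is exact (full enumeration of rank assignments) when
#' n1 + n2 <= 12 and there are no ties, otherwise a normal approximation
#' with tie correction and (by default) continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force or forbid exact enumeration (default: automatic).
#' @param correct apply the continuity correction in the approximation.
#' @return a [RankSumResult-class].
#' @export
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5))
wilcoxonRankSum <- function(x, y, exact = NULL, correct = TRUE) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (N <= 12L) && !ties
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }

  if (exact) {
    Ws <- colSums(utils::combn(N, n1))
    pLess <- mean(Ws <= W + 1e-9)
    pGreater <- mean(Ws >= W - 1e-9)
    p <- min(1, 2 * min(pLess, pGreater))
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    tieTab <- table(r)
    tieTerm <- sum(tieTab^3 - tieTab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- W - mu
      cc <- if (correct) sign(d) * 0.5 else 0
      z <- (d - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }

  new("RankSumResult", W = W, pValue = p, n1 = as.integer(n1),
      n2 = as.integer(n2), method = method)
}
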