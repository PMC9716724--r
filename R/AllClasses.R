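## S4 classes for the core data containers.

#' Simulation configuration
#'
#' Parameters of the synthetic-population generator: pedigree structure
#' (founders, generations, male philopatry, female emigration, immigration),
#' the microsatellite panel, genotyping-error rates, survey design, and
#' fecal fragment-size distributions per age class.
#'
#' @slot nFounders number of unrelated founders (>= 2, mixed sexes).
#' @slot nGenerations number of breeding rounds after the founders.
#' @slot malePhilopatryProb probability a son stays resident.
#' @slot femaleEmigrationProb probability a daughter emigrates.
#' @slot immigrantFemalesPerGen unrelated adult females added per generation.
#' @slot lociSpec named list; each element a list with character `alleles`
#'   and numeric `freqs` summing to 1.
#' @slot dropoutRate per-allele allelic dropout probability per replicate
#'   (heterozygous loci only).
#' @slot falseAlleleRate per-locus false-allele probability per replicate.
#' @slot nReplicates PCR replicates genotyped per fecal sample (1-5).
#' @slot nSexReplicates sexing-PCR replicates per sample.
#' @slot nSurveys number of survey occasions.
#' @slot detectionProb per-resident per-survey detection probability.
#' @slot sexingErrorRate probability a sexing replicate mis-amplifies.
#' @slot cubProb probability a final-generation offspring is an unweaned cub.
#' @slot fragmentParams data.frame with columns ageClass, lengthMean,
#'   lengthSD, widthMean, widthSD (mm).
#' @slot seed integer RNG seed.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  slots = c(
    nFounders = "integer",
    nGenerations = "integer",
    malePhilopatryProb = "numeric",
    femaleEmigrationProb = "numeric",
    immigrantFemalesPerGen = "integer",
    lociSpec = "list",
    dropoutRate = "numeric",
    falseAlleleRate = "numeric",
    nReplicates = "integer",
    nSexReplicates = "integer",
    nSurveys = "integer",
    detectionProb = "numeric",
    sexingErrorRate = "numeric",
    cubProb = "numeric",
    fragmentParams = "data.frame",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  probs <- c(
    malePhilopatryProb = object@malePhilopatryProb,
    femaleEmigrationProb = object@femaleEmigrationProb,
    dropoutRate = object@dropoutRate,
    falseAlleleRate = object@falseAlleleRate,
    detectionProb = object@detectionProb,
    sexingErrorRate = object@sexingErrorRate,
    cubProb = object@cubProb
  )
  bad <- probs < 0 | probs > 1 | is.na(probs)
  if (any(bad)) {
    msg <- c(msg, paste0("probabilities outside [0,1]: ",
                         paste(names(probs)[bad], collapse = ", ")))
  }
  if (object@nFounders < 2L) {
    msg <- c(msg, "nFounders must be >= 2")
  }
  if (object@nGenerations < 0L) {
    msg <- c(msg, "nGenerations must be >= 0")
  }
  if (object@nReplicates < 1L || object@nReplicates > 5L) {
    msg <- c(msg, "nReplicates must be in 1..5")
  }
  if (length(object@lociSpec) == 0L || is.null(names(object@lociSpec))) {
    msg <- c(msg, "lociSpec must be a non-empty named list")
  } else {
    for (nm in names(object@lociSpec)) {
      sp <- object@lociSpec[[nm]]
      if (!is.list(sp) || is.null(sp$alleles) || is.null(sp$freqs)) {
        msg <- c(msg, paste0("locus ", nm, ": needs $alleles and $freqs"))
        next
      }
      if (length(sp$alleles) < 2L) {
        msg <- c(msg, paste0("locus ", nm, ": needs >= 2 alleles"))
      }
      if (length(sp$alleles) != length(sp$freqs)) {
        msg <- c(msg, paste0("locus ", nm, ": alleles/freqs length mismatch"))
      } else if (abs(sum(sp$freqs) - 1) > 1e-9 || any(sp$freqs < 0)) {
        msg <- c(msg, paste0("locus ", nm, ": freqs must be >= 0 and sum to 1"))
      }
      if (anyDuplicated(sp$alleles)) {
        msg <- c(msg, paste0("locus ", nm, ": duplicated allele labels"))
      }
    }
  }
  fp <- object@fragmentParams
  need <- c("ageClass", "lengthMean", "lengthSD", "widthMean", "widthSD")
  if (!all(need %in% names(fp))) {
    msg <- c(msg, paste0("fragmentParams must have columns: ",
                         paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Pedigree of a simulated population
#'
#' One row per individual: `id`, `sex` ("M"/"F"), `birthGen`, `mother`,
#' `father` (ids or NA for founders/immigrants), `immigrant`, `resident`
#' (FALSE for emigrated females and dispersed males), and `ageClass`
#' ("cub", "subadult", "adult", "elderly"). Emigrants stay in the table so
#' pedigree kinship can still be computed for oracles.
#'
#' @slot table data.frame as described above, parents before offspring.
#' @export
setClass("Pedigree", slots = c(table = "data.frame"))

setValidity("Pedigree", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("id", "sex", "birthGen", "mother", "father", "immigrant",
            "resident", "ageClass")
  if (!all(need %in% names(tb))) {
    return(paste0("pedigree table needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tb$id)) msg <- c(msg, "duplicated individual ids")
  if (!all(tb$sex %in% c("M", "F"))) msg <- c(msg, "sex must be 'M' or 'F'")
  gen <- setNames(tb$birthGen, tb$id)
  sex <- setNames(tb$sex, tb$id)
  for (col in c("mother", "father")) {
    ref <- tb[[col]][!is.na(tb[[col]])]
    if (!all(ref %in% tb$id)) {
      msg <- c(msg, paste0(col, " ids not present in pedigree"))
      next
    }
  }
  ok <- !is.na(tb$mother) & tb$mother %in% tb$id
  if (any(ok)) {
    if (!all(sex[tb$mother[ok]] == "F")) msg <- c(msg, "mothers must be female")
    if (!all(gen[tb$mother[ok]] < tb$birthGen[ok])) {
      msg <- c(msg, "mothers must precede offspring in generation order")
    }
  }
  ok <- !is.na(tb$father) & tb$father %in% tb$id
  if (any(ok)) {
    if (!all(sex[tb$father[ok]] == "M")) msg <- c(msg, "fathers must be male")
    if (!all(gen[tb$father[ok]] < tb$birthGen[ok])) {
      msg <- c(msg, "fathers must precede offspring in generation order")
    }
  }
  if (any(tb$immigrant & (!is.na(tb$mother) | !is.na(tb$father)))) {
    msg <- c(msg, "immigrants must have no in-pedigree parents")
  }
  if (length(msg)) msg else TRUE
})

#' Multilocus genotypes
#'
#' Diploid genotypes for a set of individuals (or samples) over a common
#' locus panel. Alleles are opaque string labels, stored unordered with the
#' convention allele1 <= allele2 (label order). Missing loci are NA in both
#' slots, never zero-filled.
#'
#' @slot allele1,allele2 character matrices, rows = individuals/samples,
#'   columns = loci, identical dimnames.
#' @export
setClass("MultilocusGenotypes",
  slots = c(allele1 = "matrix", allele2 = "matrix")
)

setValidity("MultilocusGenotypes", function(object) {
  a1 <- object@allele1
  a2 <- object@allele2
  msg <- character()
  if (!identical(dim(a1), dim(a2))) msg <- c(msg, "allele matrices differ in dim")
  if (is.null(rownames(a1)) || is.null(colnames(a1))) {
    msg <- c(msg, "allele matrices must have row (id) and column (locus) names")
  } else if (!identical(dimnames(a1), dimnames(a2))) {
    msg <- c(msg, "allele matrices differ in dimnames")
  }
  if (!identical(is.na(a1), is.na(a2))) {
    msg <- c(msg, "missingness must agree between the two allele matrices")
  }
  ok <- !is.na(a1)
  if (length(msg) == 0L && any(a1[ok] > a2[ok])) {
    msg <- c(msg, "allele pairs must be stored ordered (allele1 <= allele2)")
  }
  if (length(msg)) msg else TRUE
})

#' Pairwise relatedness matrix
#'
#' Symmetric matrix of pairwise relatedness estimates R with a masked (NA)
#' diagonal. Pairs with no shared resolved loci are NA. `nLoci` records the
#' number of jointly resolved loci per pair, used for low-confidence
#' flagging.
#'
#' @slot values numeric symmetric matrix, NA diagonal.
#' @slot nLoci integer matrix of shared-locus counts, same dimnames.
#' @export
setClass("RelatednessMatrix",
  slots = c(values = "matrix", nLoci = "matrix")
)

setValidity("RelatednessMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v))) {
    msg <- c(msg, "row and column names must be identical individual ids")
  }
  if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE)) &&
      !identical(v, t(v))) {
    msg <- c(msg, "matrix must be symmetric")
  }
  if (nrow(v) > 0L && !all(is.na(diag(v)))) {
    msg <- c(msg, "diagonal must be masked (NA)")
  }
  if (any(is.infinite(v))) msg <- c(msg, "values must be finite or NA")
  if (!identical(dim(object@nLoci), dim(v))) {
    msg <- c(msg, "nLoci must match values in dimension")
  }
  if (length(msg)) msg else TRUE
})

#' Attributed association network
#'
#' Undirected weighted graph over identified individuals with per-node sex
#' and age-class attributes; used for both the indirect-association social
#' network and the relatedness-based genetic network.
#'
#' @slot graph an igraph object (undirected, positively weighted, no
#'   self-loops) with vertex attributes `sex` and `ageClass`.
#' @slot kind "social" or "genetic".
#' @export
setClass("AttributedNetwork", slots = c(graph = "ANY", kind = "character"))

setValidity("AttributedNetwork", function(object) {
  msg <- character()
  g <- object@graph
  if (!inherits(g, "igraph")) return("graph must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "graph must have no self-loops")
  if (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    if (is.null(w) || any(!is.finite(w)) || any(w <= 0)) {
      msg <- c(msg, "all edges must carry finite positive weights")
    }
  }
  va <- igraph::vertex_attr_names(g)
  if (!all(c("sex", "ageClass") %in% va)) {
    msg <- c(msg, "vertices must carry 'sex' and 'ageClass' attributes")
  }
  if (!object@kind %in% c("social", "genetic")) {
    msg <- c(msg, "kind must be 'social' or 'genetic'")
  }
  if (length(msg)) msg else TRUE
})

#' Node-permutation test result
#'
#' @slot observed observed statistic (difference in mean node metric
#'   between the two attribute levels, second minus first).
#' @slot null null statistics from label permutations (length nPerm).
#' @slot pValue two-tailed p, observed included: (b+1)/(nPerm+1).
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot statistic human-readable descriptor of the statistic.
#' @slot effect standardized effect (statistic on z-scored metric values).
#' @export
setClass("PermutationResult",
  slots = c(observed = "numeric", null = "numeric", pValue = "numeric",
            nPerm = "integer", seed = "integer", statistic = "character",
            effect = "numeric")
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@null) != object@nPerm) {
    msg <- c(msg, "null distribution length must equal nPerm")
  }
  if (object@pValue <= 0 || object@pValue > 1) {
    msg <- c(msg, "p-value must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Mantel test result
#'
#' @slot statistic matrix correlation over unordered off-diagonal pairs.
#' @slot null null correlations from simultaneous row/column permutations.
#' @slot pValue two-tailed permutation p, observed included.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot method correlation method ("spearman" or "pearson").
#' @slot nPairs number of pairs entering the correlation.
#' @export
setClass("MantelResult",
  slots = c(statistic = "numeric", null = "numeric", pValue = "numeric",
            nPerm = "integer", seed = "integer", method = "character",
            nPairs = "integer")
)

setValidity("MantelResult", function(object) {
  msg <- character()
  if (!is.na(object@statistic) &&
      (object@statistic < -1 - 1e-12 || object@statistic > 1 + 1e-12)) {
    msg <- c(msg, "correlation must lie in [-1, 1]")
  }
  if (object@pValue <= 0 || object@pValue > 1) {
    msg <- c(msg, "p-value must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Wilcoxon rank-sum result
#'
#' @slot W rank sum of the first sample under pooled mid-ranks.
#' @slot pValue two-sided p (exact by enumeration for small tie-free
#'   samples, otherwise normal approximation with tie and continuity
#'   correction).
#' @slot n1,n2 group sizes.
#' @slot method "exact" or "normal approximation".
#' @export
setClass("RankSumResult",
  slots = c(W = "numeric", pValue = "numeric", n1 = "integer",
            n2 = "integer", method = "character")
)

setValidity("RankSumResult", function(object) {
  n1 <- object@n1; n2 <- object@n2
  lo <- n1 * (n1 + 1) / 2
  hi <- n1 * n2 + lo
  if (object@W < lo - 1e-9 || object@W > hi + 1e-9) {
    return("W outside its attainable range for the given group sizes")
  }
  TRUE
})
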