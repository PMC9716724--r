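## Generics and accessors.

#' Individual (or sample) identifiers of a container
#' @param x a MultilocusGenotypes, RelatednessMatrix or AttributedNetwork.
#' @return character vector of ids.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' Locus names of a genotype container or configuration
#' @param x a MultilocusGenotypes or SimConfig.
#' @return character vector of locus names.
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' Pedigree table accessor
#' @param x a Pedigree.
#' @return the underlying data.frame.
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))

#' Resident individual ids of a pedigree
#' @param x a Pedigree.
#' @return character vector of ids with `resident = TRUE`.
#' @export
setGeneric("residents", function(x) standardGeneric("residents"))

#' Underlying igraph of an attributed network
#' @param x an AttributedNetwork.
#' @return the igraph object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Network kind accessor
#' @param x an AttributedNetwork.
#' @return "social" or "genetic".
#' @export
setGeneric("networkKind", function(x) standardGeneric("networkKind"))

#' Observed statistic of a permutation-based result
#' @param x a PermutationResult or MantelResult.
#' @return numeric scalar.
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

#' Null distribution of a permutation-based result
#' @param x a PermutationResult or MantelResult.
#' @return numeric vector of null statistics.
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))

#' p-value accessor
#' @param x a PermutationResult, MantelResult or RankSumResult.
#' @return numeric scalar in (0, 1].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

## ---- methods -------------------------------------------------------------

#' @rdname individualIds
#' @export
setMethod("individualIds", "MultilocusGenotypes",
          function(x) rownames(x@allele1))

#' @rdname individualIds
#' @export
setMethod("individualIds", "RelatednessMatrix",
          function(x) rownames(x@values))

#' @rdname individualIds
#' @export
setMethod("individualIds", "AttributedNetwork",
          function(x) igraph::V(x@graph)$name)

#' @rdname lociNames
#' @export
setMethod("lociNames", "MultilocusGenotypes",
          function(x) colnames(x@allele1))

#' @rdname lociNames
#' @export
setMethod("lociNames", "SimConfig", function(x) names(x@lociSpec))

#' @rdname pedigreeTable
#' @export
setMethod("pedigreeTable", "Pedigree", function(x) x@table)

#' @rdname residents
#' @export
setMethod("residents", "Pedigree",
          function(x) x@table$id[x@table$resident])

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "AttributedNetwork", function(x) x@graph)

#' @rdname networkKind
#' @export
setMethod("networkKind", "AttributedNetwork", function(x) x@kind)

#' @rdname observedStat
#' @export
setMethod("observedStat", "PermutationResult", function(x) x@observed)

#' @rdname observedStat
#' @export
setMethod("observedStat", "MantelResult", function(x) x@statistic)

#' @rdname nullStats
#' @export
setMethod("nullStats", "PermutationResult", function(x) x@null)

#' @rdname nullStats
#' @export
setMethod("nullStats", "MantelResult", function(x) x@null)

#' @rdname pValue
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname pValue
#' @export
setMethod("pValue", "MantelResult", function(x) x@pValue)

#' @rdname pValue
#' @export
setMethod("pValue", "RankSumResult", function(x) x@pValue)

#' Extract rows (individuals/samples) of a genotype container
#'
#' @param x a MultilocusGenotypes.
#' @param i row index (ids, logical or integer).
#' @param j unused.
#' @param ... unused.
#' @param drop unused; the result is always a MultilocusGenotypes.
#' @return a MultilocusGenotypes with the selected rows.
#' @export
setMethod("[", "MultilocusGenotypes", function(x, i, j, ..., drop = FALSE) {
  new("MultilocusGenotypes",
      allele1 = x@allele1[i, , drop = FALSE],
      allele2 = x@allele2[i, , drop = FALSE])
})

#' Dimensions of a genotype container
#' @param x a MultilocusGenotypes.
#' @return integer vector: individuals, loci.
#' @export
setMethod("dim", "MultilocusGenotypes", function(x) dim(x@allele1))

#' Relatedness values as a plain matrix
#' @param x a RelatednessMatrix.
#' @param ... unused.
#' @return numeric symmetric matrix with NA diagonal.
#' @export
setMethod("as.matrix", "RelatednessMatrix", function(x, ...) x@values)

## ---- show methods --------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFounders, "founders,",
      object@nGenerations, "generations,",
      length(object@lociSpec), "loci\n")
  cat("  male philopatry", object@malePhilopatryProb,
      "| female emigration", object@femaleEmigrationProb,
      "| immigrants/gen", object@immigrantFemalesPerGen, "\n")
  cat("  dropout", object@dropoutRate, "| false allele",
      object@falseAlleleRate, "| replicates", object@nReplicates, "\n")
  cat("  surveys", object@nSurveys, "x detection", object@detectionProb,
      "| seed", object@seed, "\n")
})

setMethod("show", "Pedigree", function(object) {
  tb <- object@table
  cat("Pedigree:", nrow(tb), "individuals (",
      sum(tb$resident), "resident ),",
      max(tb$birthGen), "generations\n")
  cat("  sexes:", sum(tb$sex == "M"), "M /", sum(tb$sex == "F"), "F;",
      "immigrants:", sum(tb$immigrant), "\n")
})

setMethod("show", "MultilocusGenotypes", function(object) {
  cat("MultilocusGenotypes:", nrow(object@allele1), "individuals x",
      ncol(object@allele1), "loci;",
      sum(is.na(object@allele1)), "missing locus calls\n")
})

setMethod("show", "RelatednessMatrix", function(object) {
  v <- object@values
  off <- v[lower.tri(v)]
  cat("RelatednessMatrix:", nrow(v), "individuals;",
      sum(!is.na(off)), "defined /", length(off), "pairs\n")
  if (any(!is.na(off))) {
    cat("  R range:", sprintf("%.3f .. %.3f", min(off, na.rm = TRUE),
                              max(off, na.rm = TRUE)), "\n")
  }
})

setMethod("show", "AttributedNetwork", function(object) {
  g <- object@graph
  cat("AttributedNetwork (", object@kind, "): ",
      igraph::vcount(g), " nodes, ", igraph::ecount(g), " edges\n", sep = "")
})

setMethod("show", "PermutationResult", function(object) {
  cat("Node-permutation test:", object@statistic, "\n")
  cat(sprintf("  observed = %.4f, p = %.4g (%d permutations)\n",
              object@observed, object@pValue, object@nPerm))
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%d permutations, %d pairs)\n",
              object@method, object@statistic, object@pValue,
              object@nPerm, object@nPairs))
})

setMethod("show", "RankSumResult", function(object) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              object@W, object@pValue, object@n1, object@n2, object@method))
})
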