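## End-to-end orchestration: simulate (or read) -> identify -> relatedness
## -> networks -> inference, with a manifest and a report.

.subsetRelatedness <- function(rmat, ids) {
  new("RelatednessMatrix",
      values = rmat@values[ids, ids, drop = FALSE],
      nLoci = rmat@nLoci[ids, ids, drop = FALSE])
}

.permAsList <- function(x) {
  list(statistic = x@statistic, observed = x@observed,
       standardizedEffect = x@effect, pValue = x@pValue, nPerm = x@nPerm)
}

.mantelAsList <- function(x) {
  list(method = x@method, correlation = x@statistic, pValue = x@pValue,
       nPerm = x@nPerm, nPairs = x@nPairs)
}

.ranksumAsList <- function(x) {
  list(W = x@W, pValue = x@pValue, n1 = x@n1, n2 = x@n2, method = x@method)
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages: simulate a population (or read user-supplied
#' files), identify individuals with sex and age, estimate pairwise
#' relatedness and kin classes, build the social and genetic networks, and
#' run the inference layer (node-permutation tests of sex and age on both
#' networks, Mantel test of social vs genetic structure, Wilcoxon rank-sum
#' of MM vs FF relatedness among adults). Per-stage seeds are derived from
#' the master seed by fixed offsets, so a rerun with the same configuration
#' and seed reproduces identical outputs.
#'
#' @param config a [SimConfig-class] (or a YAML path readable by
#'   [readSimConfig()]).
#' @param outdir optional output directory; when given, all tables,
#'   networks, the JSON/Markdown report and the run manifest are written
#'   there.
#' @param seed master seed; defaults to `config@seed`.
#' @param nPerm permutations for the inference stage.
#' @param inputs optional named list of CSV paths (`calls`, `sexing`,
#'   `fragments`, `detections`, each in the column layout written by
#'   [writeSimData()]); when supplied, these replace the simulation stage.
#' @param quiet suppress stage logging to stderr.
#' @return list: `individuals`, `genotypes`, `relatedness`, `pairGroups`,
#'   `socialNetwork`, `geneticNetwork`, `report` (plain-list report with
#'   network summaries and test results) and `manifest`.
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL, nPerm = 1000L,
                        inputs = NULL, quiet = FALSE) {
  if (is.character(config)) config <- readSimConfig(config)
  stopifnot(is(config, "SimConfig"))
  if (is.null(seed)) seed <- config@seed
  seed <- as.integer(seed)

  timings <- c()
  log <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ## ---- data stage ------------------------------------------------------
  if (is.null(inputs)) {
    log("simulate", "generating synthetic population (seed ", seed, ")")
    sim <- stage("simulate", {
      ped <- simulatePedigree(config, seed = seed + 1L)
      truth <- simulateGenotypes(ped, config, seed = seed + 2L)
      c(simulateSamples(ped, truth, config, seed = seed + 3L),
        list(pedigree = ped, truth = truth))
    })
  } else {
    log("read", "reading user-supplied input files")
    sim <- stage("read", {
      list(
        calls = utils::read.csv(inputs$calls, stringsAsFactors = FALSE,
                                colClasses = c(allele1 = "character",
                                               allele2 = "character")),
        sexing = utils::read.csv(inputs$sexing, stringsAsFactors = FALSE),
        fragments = if (!is.null(inputs$fragments))
          utils::read.csv(inputs$fragments, stringsAsFactors = FALSE) else NULL,
        detections = utils::read.csv(inputs$detections,
                                     stringsAsFactors = FALSE)
      )
    })
  }
  if (is.null(sim$detections) || nrow(sim$detections) == 0L) {
    stop("stage 'networks' cannot proceed: no survey detections ",
         "(at least one survey occasion with detections is required)",
         call. = FALSE)
  }

  ## ---- identification --------------------------------------------------
  log("identify", "consensus genotyping and individual matching")
  idres <- stage("identify", {
    identifyIndividuals(sim$calls, sim$sexing, sim$fragments)
  })
  individuals <- idres$individuals
  log("identify", nrow(individuals), " individuals from ",
      length(unique(sim$calls$sample_id)), " samples")

  ## ---- relatedness -----------------------------------------------------
  log("relatedness", "allele frequencies and pairwise relatedness")
  rel <- stage("relatedness", {
    freqs <- alleleFrequencies(idres$genotypes)
    rmat <- relatednessMatrix(idres$genotypes, freqs)
    sexVec <- setNames(individuals$sex, individuals$individual_id)
    groups <- pairGroupSummary(rmat, sexVec)
    list(freqs = freqs, rmat = rmat, groups = groups)
  })

  ## ---- networks --------------------------------------------------------
  log("networks", "building social and genetic networks")
  nets <- stage("networks", {
    analysisIds <- individuals$individual_id[individuals$sex %in% c("M", "F")]
    if (length(analysisIds) < 2L) {
      stop("fewer than 2 individuals with known sex")
    }
    ind <- individuals[individuals$individual_id %in% analysisIds, ]
    det <- merge(sim$detections[, c("survey_id", "sample_id")],
                 idres$membership, by = "sample_id")
    det <- det[det$individual_id %in% analysisIds, ]
    social <- buildSocialNetwork(det[, c("survey_id", "individual_id")], ind)
    genetic <- buildGeneticNetwork(.subsetRelatedness(rel$rmat, sort(analysisIds)),
                                   ind)
    list(social = social, genetic = genetic,
         socialMetrics = networkMetrics(social),
         geneticMetrics = networkMetrics(genetic))
  })

  ## ---- inference -------------------------------------------------------
  log("inference", "permutation tests (", nPerm, " permutations)")
  inf <- stage("inference", {
    tests <- list(
      socialSex = nodePermutationTest(nets$social, "sex", "strength",
                                      nPerm = nPerm, seed = seed + 11L),
      socialAge = tryCatch(
        nodePermutationTest(nets$social, "ageClass", "strength",
                            nPerm = nPerm, seed = seed + 12L),
        error = function(e) NULL),
      geneticSex = nodePermutationTest(nets$genetic, "sex", "strength",
                                       nPerm = nPerm, seed = seed + 13L),
      geneticAge = tryCatch(
        nodePermutationTest(nets$genetic, "ageClass", "strength",
                            nPerm = nPerm, seed = seed + 14L),
        error = function(e) NULL)
    )
    A <- networkAdjacency(nets$social)
    Bm <- as.matrix(.subsetRelatedness(rel$rmat, rownames(A)))
    mantel <- mantelTest(A, Bm, nPerm = nPerm, seed = seed + 15L)

    adults <- individuals$individual_id[
      individuals$ageClass %in% c("adult", "elderly")]
    pr <- rel$groups$pairs
    pr <- pr[pr$id1 %in% adults & pr$id2 %in% adults & !is.na(pr$R), ]
    ranksum <- if (sum(pr$sexPair == "MM") > 0L && sum(pr$sexPair == "FF") > 0L) {
      wilcoxonRankSum(pr$R[pr$sexPair == "MM"], pr$R[pr$sexPair == "FF"])
    } else NULL
    list(tests = tests, mantel = mantel, ranksum = ranksum)
  })

  ## ---- report ----------------------------------------------------------
  report <- list(
    individuals = individuals,
    populationSizeEstimate = nrow(individuals),
    socialNetwork = nets$socialMetrics$graph,
    geneticNetwork = nets$geneticMetrics$graph,
    pairGroupSummary = rel$groups$summary,
    tests = c(
      lapply(Filter(Negate(is.null), inf$tests), .permAsList),
      list(mantelSocialGenetic = .mantelAsList(inf$mantel)),
      if (!is.null(inf$ranksum))
        list(ranksumMMvsFF = .ranksumAsList(inf$ranksum))
    )
  )

  manifest <- list(
    package = "pandaNet",
    version = as.character(utils::packageVersion("pandaNet")),
    seed = seed,
    nPerm = as.integer(nPerm),
    config = configAsList(config),
    timings = as.list(timings)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(individuals, file.path(outdir, "individuals.csv"),
                     row.names = FALSE)
    writeGenotypesCsv(idres$genotypes, file.path(outdir, "genotypes.csv"))
    tryCatch(writeGenepop(idres$genotypes, file.path(outdir, "genotypes.gen")),
             error = function(e) NULL)
    writeRelatednessCsv(rel$rmat, file.path(outdir, "relatedness.csv"))
    utils::write.csv(rel$groups$pairs, file.path(outdir, "pairs.csv"),
                     row.names = FALSE)
    writeEdgeList(nets$social, file.path(outdir, "social_edges.csv"))
    writeEdgeList(nets$genetic, file.path(outdir, "genetic_edges.csv"))
    writeGraphML(nets$social, file.path(outdir, "social.graphml"))
    writeGraphML(nets$genetic, file.path(outdir, "genetic.graphml"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    writeLines(.reportMarkdown(report), file.path(outdir, "report.md"))
    files <- list.files(outdir, full.names = TRUE)
    manifest$fileHashes <- as.list(tools::md5sum(files[
      !basename(files) %in% "manifest.json"]))
    names(manifest$fileHashes) <- basename(names(manifest$fileHashes))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(individuals = individuals, genotypes = idres$genotypes,
       membership = idres$membership, relatedness = rel$rmat,
       alleleFrequencies = rel$freqs, pairGroups = rel$groups,
       socialNetwork = nets$social, geneticNetwork = nets$genetic,
       inference = inf, report = report, manifest = manifest)
}

.fmtTest <- function(name, t) {
  if (!is.null(t$W)) {
    sprintf("- %s: W = %g, p = %.4g (n1 = %d, n2 = %d, %s)",
            name, t$W, t$pValue, t$n1, t$n2, t$method)
  } else if (!is.null(t$correlation)) {
    sprintf("- %s: r = %.4f, p = %.4g (%d permutations)",
            name, t$correlation, t$pValue, t$nPerm)
  } else {
    sprintf("- %s: observed = %.4f (standardized %.3f), p = %.4g (%d permutations)",
            name, t$observed, t$standardizedEffect, t$pValue, t$nPerm)
  }
}

.reportMarkdown <- function(report) {
  gsum <- function(g) {
    sprintf("%d nodes, %d edges, connectance %.3f, mean degree %.3f (SD %.3f)",
            g$nNodes, g$nEdges, g$connectance, g$meanDegree, g$sdDegree)
  }
  c("# pandaNet pipeline report",
    "",
    sprintf("Identified individuals: %d", report$populationSizeEstimate),
    "",
    "## Networks",
    paste0("- social: ", gsum(report$socialNetwork)),
    paste0("- genetic: ", gsum(report$geneticNetwork)),
    "",
    "## Pair-group relatedness summary",
    utils::capture.output(print(report$pairGroupSummary, row.names = FALSE)),
    "",
    "## Tests",
    vapply(names(report$tests), function(nm) .fmtTest(nm, report$tests[[nm]]),
           character(1)))
}
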