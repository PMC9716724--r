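Package: pandaNet
Title: Social and Genetic Network Analysis for Solitary Mammals from
    Non-Invasive Genetic Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the community social structure of
    solitary mammals from non-invasive genetic sampling. Implements
    multi-tube consensus genotyping of microsatellite replicates,
    genotype-matching individual identification, PCR-based sexing,
    fecal-fragment age classification, Queller-Goodnight pairwise
    relatedness with kin-class binning, indirect-association social
    networks and relatedness-based genetic networks, and a permutation
    inference layer (node-permutation null models, Mantel test, Wilcoxon
    rank-sum). A synthetic-data module simulates multigenerational
    pedigrees with male philopatry and female-biased dispersal, Mendelian
    gene dropping, genotyping error, and survey detection histories, so
    the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
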