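---
title: "Methods: from fecal genotypes to social and genetic networks"
author: "pandaNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fecal genotypes to social and genetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandaNet)
```

## The problem

Solitary mammals such as the giant panda rarely meet, yet they share a
home range mosaic, communicate chemically, and disperse non-randomly, so a
population can carry real community structure that direct observation
cannot see. pandaNet reconstructs that structure from two non-invasive
data streams:

* repeated **survey detections** of individuals (via genotyped fecal
  samples found on transect occasions), which define *indirect
  associations* under the gambit of the group: all individuals detected on
  the same occasion are taken to associate;
* **multilocus microsatellite genotypes** of the same individuals, from
  which pairwise genetic relatedness and kin classes are estimated.

The package chains five stages — consensus genotyping, individual/sex/age
identification, relatedness estimation, network construction, and
permutation inference — and ships a synthetic-data generator so that every
stage can be validated against ground truth.

## Consensus genotyping and identification

Fecal DNA is error-prone, so each sample is amplified in replicate (three
PCRs, topped up to at most five). The multi-tube consensus rule is
count-based over all supplied replicates: a **heterozygote** is accepted
at a locus only if *each* of its two alleles is seen in at least two
replicates; a **homozygote** only if the identical homozygous call is seen
in at least three replicates; anything else is unresolved and ultimately
missing. Because the rule depends only on counts it is invariant to
replicate order.

Samples are then clustered into individuals by single linkage on the
relation "the genotypes differ at no more than `maxMismatchLoci` (default
2) of their jointly resolved loci", followed by a reconciliation pass that
re-compares cluster consensuses at zero mismatches and merges
indistinguishable clusters. Samples with fewer than `minSharedLoci`
(default 9 of 15) resolved loci are excluded rather than force-assigned.
These two thresholds are the package's own defaults — the field protocols
this mirrors do not publish theirs — and both are exposed as arguments.

Sex comes from a dual-band sexing PCR scored per replicate: male iff at
least two replicates show both the 210-bp (Y-linked) and the 130-bp band;
female iff no replicate shows the 210-bp band and at least two show the
130-bp band; anything else is unknown. Age class comes from bamboo-leaf
fragment sizes in the feces (at least 40 fragments measured per sample):
nearest-centroid classification of the sample's mean (length, width)
against reference centroids after per-axis standardization. The shipped
calibration (`inst/extdata/age_calibration.csv`) contains published
fragment means of known-age adults plus field-classified sub-adults, since
published known-age controls include no sub-adults. Samples whose mean
fragment length exceeds the adult centroid by a configurable factor
(default 1.3) are flagged *elderly* — tooth wear leaves markedly longer
fragments. Fragment-free samples are unweaned cubs (if flagged) or
unknown. The nearest-centroid rule is the simplest classifier consistent
with the calibration idea; the original field method's exact decision rule
is not published.

## Pairwise relatedness

Relatedness is estimated with the Queller–Goodnight (1989) moment
estimator, the default of the KINGROUP software that field studies in this
system use. For a locus where individual *x* carries alleles \((a, b)\)
and *y* carries \((c, d)\), with \(I\) the allele-identity indicator and
\(p\) the population frequency,

\[
\mathrm{num}_x = \tfrac12 (I_{ac} + I_{ad} + I_{bc} + I_{bd}) - p_a - p_b,
\qquad
\mathrm{den}_x = 1 + I_{ab} - p_a - p_b .
\]

Numerators and denominators are summed over the shared resolved loci,
\(r_x = \sum \mathrm{num}_x / \sum \mathrm{den}_x\), \(r_y\) symmetrically,
and \(R = (r_x + r_y)/2\). With true allele frequencies the estimator is
unbiased: 0.5 for parent–offspring and full sibs, 0.25 for half sibs,
0.125 for first cousins, 0 for unrelated pairs.

```{r calibration}
mean(simulateDyadRelatedness("parent-offspring", 500, seed = 1))
mean(simulateDyadRelatedness("half-sib", 500, seed = 2))
```

Allele frequencies are estimated from all identified individuals (one
genotype per individual, never per sample), focal pair included; no
small-sample bias correction is applied, and this known small-sample bias
is accepted and documented rather than corrected. Estimates slightly
outside \([-1, 1]\) are possible with estimated frequencies and are
reported as-is. Pairs sharing fewer than 6 resolved loci are kept but
flagged low-confidence (`lowConfidencePairs()`).

Kin classes bin \(R\) against the canonical anchors: below 0.125 a pair is
*unrelated*; the third/second and second/first boundaries are set at the
midpoints 0.1875 and 0.375 between the anchor values 0.125, 0.25 and 0.5.
The anchors are standard; the midpoint interpolation is this package's
declared choice and both cut points are arguments.

## Networks

The **social network** joins two individuals with an edge weighted by the
number of survey occasions on which both were detected (raw co-detection
counts; a simple-ratio index is available as an option for sensitivity
analysis). The **genetic network** joins pairs with \(R \ge 0.125\),
weighted by \(R\) itself (a kin-class rank weighting 3/2/1 is selectable,
since published figures do not state their exact mapping). Individuals of
unknown sex (e.g. unweaned cubs without genotypes) are excluded from both
networks. Reported metrics: degree (the degree-centrality measure),
strength (weighted degree), edge count, connectance
\(= E / \binom{n}{2}\), and the mean and SD of the degree distribution.

## Permutation inference

All tests follow the node-permutation null-model frame with 1000
permutations by default and two-tailed p-values that include the observed
statistic in the reference set, \(p = (b + 1)/(n_{\mathrm{perm}} + 1)\),
so p is never exactly zero.

* **Attribute effects** (sex, age) on a node metric: the statistic is the
  difference in mean metric between the two levels; the null shuffles node
  labels with the network fixed. A standardized effect (the same statistic
  on z-scored metrics) is reported alongside. For a binary attribute this
  mean-difference statistic gives the same permutation p-value as a
  single-covariate regression coefficient, so the simpler statistic is the
  default.
* **Mantel test** (Spearman by default) between the social co-occurrence
  matrix and the relatedness matrix: correlation of the strict lower
  triangles, null built by one random node relabelling applied
  simultaneously to rows and columns of the second matrix per iteration
  (which matrix is permuted is immaterial for the p-value). Masked cells
  are excluded pairwise. With no masked cells the implementation
  pre-ranks once and correlates permuted rank matrices, since the
  off-diagonal multiset is invariant under relabelling.
* **Wilcoxon rank-sum** compares MM against FF pair relatedness among
  adults. \(W\) is the rank sum of the first sample under pooled
  mid-ranks; the p-value is exact by full enumeration when
  \(n_1 + n_2 \le 12\) without ties, otherwise a normal approximation with
  tie and continuity correction.

## The synthetic-data generator

`simConfig()` fixes the study conditions the generator emulates: a
population of the scale of a dense wild giant panda community sampled over
six monthly surveys. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `nFounders`, `nGenerations` | 10, 4 | yields ~30–40 residents, the observed community scale |
| `malePhilopatryProb` | 0.9 | males settle adjacent to their mothers |
| `femaleEmigrationProb` | 0.8 | females generally disperse before breeding |
| `immigrantFemalesPerGen` | 2 | the balancing inflow of dispersing females |
| `lociSpec` | 15 loci × 8 equifrequent alleles | panel size of the fecal-DNA protocol; per-locus frequencies unpublished, so uniform and overridable |
| `dropoutRate`, `falseAlleleRate` | 0.05, 0.02 | typical fecal-DNA error magnitudes |
| `nReplicates` | 3 (max 5) | the multi-tube protocol |
| `nSurveys`, `detectionProb` | 6, 0.4 | six occasions; 0.4 makes pairwise co-detection ≈ 0.65, the connectance scale observed in the field system (0.8 would saturate the graph) |
| fragment length (mm) | sub-adult 21 (SD 2), adult 28 (SD 4), elderly 38 (SD 4) | the published fragment-size scale |

Each generation, every resident mature female produces one offspring by a
uniformly chosen resident male (promiscuous mating, no active inbreeding
avoidance — dispersal is the only inbreeding-avoidance mechanism, as in
the study system); daughters emigrate and sons stay with the configured
probabilities; emigrants leave the resident pool but stay in the pedigree
so pedigree kinship (`pedigreeRelatedness()`, the oracle used in tests)
remains computable. Allelic dropout follows the per-allele model in which
an affected heterozygous replicate *appears homozygous* — with both
alleles below detection the call is scored for a uniformly chosen allele
rather than as a failed locus — so a heterozygote appears homozygous with
probability \(1-(1-p)^2\); amplification failure as a separate process is
not modelled. False alleles replace one allele with a random other allele
of the locus.

What the generator deliberately does **not** emulate: spatially explicit
home ranges (detection is spatially uniform), bamboo phenology and
seasonal movement, null alleles and stutter artifacts, uneven sampling
effort, and immigration of males. Passing tests therefore demonstrate the
correctness and calibration of the estimators and tests under a faithful
but idealized sampling process, not robustness to every field artifact.

## Numerical and design choices

* Allele labels are opaque strings; pairs are stored sorted, missing loci
  are `NA`, never zero-filled.
* Majority-consensus ties within a matched cluster resolve toward the pair
  carried by the lowest member sample id; non-transitive matches resolve
  by single linkage followed by the zero-mismatch reconciliation pass.
* Node orderings in all written files are sorted by id for byte-stable
  output; a rerun with the same configuration and master seed reproduces
  byte-identical outputs (per-stage seeds are derived from the master seed
  by fixed offsets).
* Degenerate inputs fail loudly: fewer than 3 replicates, constant
  permutation attributes, fewer than 4 Mantel nodes, zero-survey
  configurations, detections of unknown individuals.
* Problem sizes used by the test suite are deliberately desk-scale: 500
  dyads per kin class for estimator calibration, 200 replicate populations
  for the dispersal contrast, 500 replicates × 200 permutations for the
  size calibration of both permutation tests, and full enumeration up to
  \(n_1 = n_2 = 6\) for the Wilcoxon oracle.

## Known limitations

* Allele frequencies include the focal pair; with ~30 individuals the
  induced negative bias of the mean pairwise \(R\) is visible (the mean of
  all pairwise estimates is slightly below zero) but does not affect the
  MM/FF contrast materially.
* The probability of identity of the marker panel is not computed;
  genotype-matching thresholds are heuristic and exposed.
* The likelihood-based kinship hypothesis tests of KINGROUP, pedigree
  reconstruction and parentage assignment are out of scope.
* Raw co-detection counts (not rate indices) are the primary association
  weights; use the simple-ratio option when survey effort varies.
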