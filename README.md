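# pandaNet

Community social structure of solitary mammals from non-invasive genetic
sampling.

Solitary species like the giant panda almost never interact directly, yet
repeated fecal-DNA surveys reveal who shares the landscape with whom and
how kin are arranged across it. `pandaNet` turns replicate-level fecal
genotyping data and survey detection records into:

1. **identified individuals** with sex and age class — multi-tube
   consensus genotyping (heterozygote: each allele in ≥ 2 replicates;
   homozygote: the same homozygous call in ≥ 3), single-linkage genotype
   matching, dual-band sexing PCR rules, and fragment-size age
   classification;
2. **pairwise genetic relatedness** — the Queller–Goodnight (1989)
   estimator
   `R = (r_x + r_y)/2` with
   `r_x = Σ_loci [½(I_ac+I_ad+I_bc+I_bd) − p_a − p_b] / Σ_loci [1 + I_ab − p_a − p_b]`,
   binned into kin classes anchored at 0.5 (first), 0.25 (second), 0.125
   (third), with `R < 0.125` unrelated;
3. **two networks** over the same individuals — an indirect-association
   social network (edge weight = number of survey occasions a pair was
   co-detected; "gambit of the group") and a genetic network (edge iff
   `R ≥ 0.125`, weight = R);
4. **permutation inference** — node-permutation null models for sex/age
   effects on degree or strength, a Mantel test (Spearman) between the two
   networks, and a Wilcoxon rank-sum comparison of MM vs FF pair
   relatedness, all with two-tailed `p = (b+1)/(n_perm+1)`.

A synthetic-data module simulates the whole study system — a
multigenerational pedigree with male philopatry and female-biased
dispersal, Mendelian gene dropping over a 15-locus microsatellite panel,
allelic dropout and false alleles across PCR replicates, monthly survey
detections, and age-class-specific fragment sizes — so every stage is
testable against ground truth.

## Worked example

```r
library(pandaNet)

cfg <- simConfig(seed = 42L)          # default study conditions
res <- runPipeline(cfg, nPerm = 1000, quiet = TRUE)

head(res$individuals, 2)
#>   individual_id sex ageClass n_samples n_loci meanLength meanWidth
#> 1        IND001   F  elderly         5     15   38.12174  9.838017
#> 2        IND002   M  elderly         4     15   38.03699  9.995176

res$report$socialNetwork
#> $nNodes 39  $nEdges 547  $connectance 0.738  $meanDegree 28.1  $sdDegree 6.4

res$report$pairGroupSummary
#>   group   n nDefined    meanR   sdR propRelatives propFirst propSecond propThird
#> 1    MM 253      253 -0.00863 0.185        0.1660    0.0632     0.0514    0.0514
#> 2    MF 368      368 -0.03303 0.168        0.1168    0.0598     0.0245    0.0326
#> 3    FF 120      120 -0.04217 0.133        0.0667    0.0167     0.0250    0.0250

res$inference$mantel
#> Mantel test (spearman): r = -0.0790, p = 0.02498 (1000 permutations, 741 pairs)
```

Reading the output: 39 individuals were identified from the simulated
samples; the social network has connectance 0.738 (fraction of possible
pairs ever co-detected) and mean degree 28.1; male–male pairs are on
average more related than female–female pairs (meanR −0.009 vs −0.042, and
a higher proportion of relatives, 0.166 vs 0.067) — the signature of male
philopatry with female-biased dispersal that the generator plants and the
estimator recovers.

Individual building blocks are exported too:

```r
mean(simulateDyadRelatedness("parent-offspring", 500, seed = 1))
#> [1] 0.5017836   # estimator calibration: expected 0.5

connectanceFromCounts(33, 336)
#> [1] 0.6363636   # field-scale check: 33 individuals, 336 associated dyads

wilcoxonRankSum(c(1, 2, 3), c(4, 5))
#> Wilcoxon rank-sum: W = 6, p = 0.2 (n1 = 3, n2 = 2, exact)
```

A thin command-line wrapper lives in `inst/scripts/pandanet`
(`pandanet simulate|run --config cfg.yaml --outdir DIR [--seed N]`).

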