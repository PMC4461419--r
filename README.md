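# cryptolin

Detection and characterisation of sympatric cryptic plant lineages from
codominant nuclear markers, organellar haplotype sequences, flowering
phenology and quantitative traits.

Morphologically indistinguishable ("cryptic") lineages that coexist at
one site pose a chain of analytical questions: *are* there genetically
distinct groups, how strongly are they differentiated, do they hybridize
and in which direction, do their organellar haplotypes sort by lineage,
is reproduction separated in time (allochronic isolation), and is
quantitative-trait divergence larger than neutral expectation?
`cryptolin` implements that chain as one tested R package, together
with a synthetic-data generator that emulates a three-lineage, highly
selfing rush (*Juncus*-like) study system so every stage can be
exercised against ground truth.

## What it computes

* **Diversity and differentiation** — Nei's unbiased gene diversity
  *H*<sub>E</sub> = 2n/(2n−1)·(1 − Σp²), hypergeometric rarefied
  allelic richness *A*<sub>R</sub>, and the Weir–Cockerham (1984)
  variance-component estimators θ (*F*<sub>ST</sub>) and *f*
  (*F*<sub>IS</sub>), multilocus and pairwise; codominant squared
  genotypic distances (Smouse–Peakall scheme) with principal coordinate
  analysis.
* **Genetic clustering** — a collapsed no-admixture Gibbs sampler
  (uniform cluster prior, Dirichlet(1) allele frequencies) with
  label-invariant co-assignment output, plus the Evanno
  ΔK = |L″(K)|/sd L(K) heuristic for choosing K.
* **Hybrid classification** — posterior probabilities over the six
  genotype frequency classes reachable in two generations of crossing
  (pure × 2, F1, F2, two backcrosses), via a Gibbs sampler over class,
  gene-copy pool origin and pool frequencies; calls at a 0.95 posterior
  threshold.
* **Haplotype networks** — collapsing of aligned sequences into
  haplotypes and a fixed-limit statistical parsimony network (default
  connection limit 7 steps) with inferred intermediate nodes.
* **Phenology** — among-individual flowering synchrony (mean pairwise
  Pearson *r*, within/between/overall), the lineage-specific
  probability of hybrid formation
  *P*<sub>i</sub> = Σ<sub>n</sub> [x̄<sub>i</sub>(n)/Σ<sub>m</sub>x̄<sub>i</sub>(m)] ·
  x̄<sub>j</sub>(n)N<sub>j</sub>/(x̄<sub>i</sub>(n)N<sub>i</sub> + x̄<sub>j</sub>(n)N<sub>j</sub>),
  and stratified percentile bootstrap intervals.
* **Quantitative traits** — one-way ANOVA with method-of-moments
  variance components and Tukey letters, correlation-matrix PCA, LDA
  with trait–posterior diagnostics, quasibinomial GLMs for herbivory /
  germination counts, and
  *P*<sub>ST</sub> = (c/h²)σ²<sub>B</sub> / [(c/h²)σ²<sub>B</sub> + 2σ²<sub>W</sub>]
  for comparison against neutral *F*<sub>ST</sub>.
* **Pipeline** — `runPipeline()` chains simulate/load → cluster →
  hybrid calls → diversity/FST/PCoA → network → phenology → traits into
  a reproducible report bundle; a thin CLI lives at
  `inst/scripts/cryptolin`.

## Worked example

```r
library(cryptolin)

cfg <- simulationConfig(nIndividuals = c(cong = 60, eff1 = 60, eff2 = 60))
sys <- generateStudySystem(cfg, seed = 1)
sys$genotypes
#> GenotypeMatrix with 194 individuals x 11 loci
#>   missing genotypes: 0.0%

pure <- sys$truth$type == "pure"
g    <- sys$genotypes[which(pure), ]
lin  <- sys$truth$lineage[pure]

round(wcFst(g, lin)$pairwise, 2)
#>      cong eff1 eff2
#> cong 0.00 0.59 0.59
#> eff1 0.59 0.00 0.74
#> eff2 0.59 0.74 0.00

diversitySummary(g, lin)
#>   group   HE  AR  FIS
#> 1  cong 0.51 3.6 0.89
#> 2  eff1 0.20 2.6 0.90
#> 3  eff2 0.17 2.3 0.89
```

The three lineages come back at close to their configured pairwise
differentiation (targets 0.57/0.57/0.72) with the strong homozygote
excess (F ≈ 0.9) expected under predominant selfing.  The flowering
census shows high synchrony within each lineage and quantifies the
chance that a mating event crosses lineages:

```r
slin <- lineageLabels(sys$schedule)
keep <- slin %in% c("eff1", "eff2")
s2 <- floweringSchedule(scheduleValues(sys$schedule)[keep, ],
                        censusDates(sys$schedule), slin[keep])
floweringSynchrony(s2, "within")$meanR
#> eff1 eff2
#> 0.80 0.76
hybridFormationProbability(s2, "eff1", "eff2", 60, 60)$P
#>  eff1  eff2
#> 0.212 0.247

pstFromTrait(sys$traits[pure, ], "first_flowering")$pst
#> 0.83        # vs multilocus theta 0.63 on the same individuals
```

A first-flowering *P*<sub>ST</sub> of the same order as (here above)
the neutral θ is what a purely stochastic divergence of flowering time
would produce — no selection needs to be invoked.

## Vignette

`vignettes/cryptic-lineages.Rmd` describes the models, the generator's
calibration and what it does and does not emulate, numerical choices,
and known limitations.
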