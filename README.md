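# genegravity

Somatic mutations do not accumulate uniformly across a tumor genome: the
perturbation of one gene can reshape the mutational landscape of many others.
`genegravity` quantifies this with a *gene gravity model* for cancer genome
evolution. It is aimed at computational cancer biologists who have a protein
interaction network (PIN), a tumor cohort's expression matrix, and a somatic
mutation table, and who want per-gene and per-pair scores of how strongly
mutation burden and co-expression concentrate on interacting genes — for
driver-gene prioritization, gene-set contrasts, and chromosome-level
analyses.

## The model

Per-gene nonsynonymous mutation counts, cumulated over the cohort, form an
initial mass vector **M**₀ that is smoothed over the PIN by a random walk
with restart:

```
M(t+1) = α Pᵀ M(t) + (1 − α) M₀ ,      P_ij = 1/k_i  (i ~ j)
```

where `k_i` is the connectivity of gene *i* and `α` (default 0.7) tunes how
far mutation mass diffuses; iteration stops when ‖M(t+1) − M(t)‖₂ < 10⁻⁶,
and the closed form `M = (1 − α)(I − α Pᵀ)⁻¹ M₀` is available as a direct
sparse solve. At `α = 0` the counts are returned untouched; at `α = 1` the
mass becomes purely structural (`k_i / 2N_L` of the total).

Each PIN edge is annotated with the Pearson correlation (PCC) of its
endpoints' expression across the cohort — the co-expressed PIN (CePIN) —
and the "biological distance" between interacting genes is `r_ij = 1/PCC_ij`.
Gravitation between interacting genes then follows Newton's law:

```
G_ij = k · M_i · M_j / r_ij²  =  M_i · M_j · PCC_ij²     (k = 1)
```

with the sign of the correlation kept as a class: attractive (PCC > 0) or
repulsive (PCC < 0) gravitation. Gene-level summaries are the average
gravitation `aveG_i = Σ_j G_ij / n` over gene *i*'s scored partners and the
average absolute correlation `avePCC`. On top of these the package provides
the accompanying statistics: Wilcoxon rank-sum tests (exact tie-aware
enumeration for small samples) with Benjamini–Hochberg control, Fisher
enrichment of gene sets, top-N aveG enrichment, X-versus-autosome contrasts,
per-sample mutation-density comparisons, aveG–covariate correlations, and a
mutation-enrichment benchmark of interacting pairs against random pairs.

Because real tumor cohorts are large and access-controlled, the package
ships seeded synthetic-study generators (`synth_study()`) with planted
structure — hot mutated genes, co-expressed edges with exact target
correlations, X-linked inflation, mutator-carrier samples — so the whole
pipeline is testable end to end offline.

## Worked example

```r
library(genegravity)

study <- synth_study("small", seed = 7)           # 200 genes, 50 samples
filt  <- filter_expression(study$expression)      # two-stage 20%/20% filter
cepin <- build_cepin(study$network, filt$matrix)  # PCC per surviving edge
m0    <- build_m0(study$mutations, study$network) # nonsynonymous counts
prop  <- propagate(study$network, m0, alpha = 0.7)
prop
#> Propagated mutation vector: 200 genes, alpha = 0.7, iterative (25 iterations, residual 9.5e-07)

grav   <- pairwise_gravity(cepin, prop)
scores <- aveg_scores(grav, metadata = study$metadata, network = study$network)
head(scores[order(-aveg)], 3)
#>      gene     aveg n_partners    avepcc degree chromosome cdna_length
#> 1: g00018 975.1301          4 0.8388635      4          X        4756
#> 2: g00006 467.1922         17 0.3841961     17          X        1486
#> 3: g00152 306.7372          3 0.7971175      3         17        1532
```

The top-scoring genes are exactly the planted hot, co-expressed drivers, and
the contrast against background is decisive:

```r
hot <- study$ground_truth$hot_genes
wilcoxon_rank_sum(scores$aveg[scores$gene %in% hot],
                  scores$aveg[!scores$gene %in% hot], "greater")
#> Wilcoxon rank-sum (normal approximation) (greater): statistic = 2378, p = 5.32e-09
#>   a: n = 14, mean = 235.1 +/- 63.8 (SEM)
#>   b: n = 169, mean = 17.71 +/- 3.65 (SEM)

topn_enrichment(scores, hot, n = 50)
#> Fisher's exact test (greater): statistic = Inf, p = 2.88e-09
```

The planted set's mean aveG (235.1) is more than ten times the background's
(17.71); all 14 scored planted genes land in the top 50, giving an infinite
odds-ratio estimate. `run_study(run_config(...))` executes the same stages
from TSV inputs and writes a result bundle with a manifest; the
`inst/exec/genegravity` script exposes each stage as a shell subcommand
(`synth`, `build-cepin`, `propagate`, `gravity`, `compare-sets`,
`enrich-top`, `x-chrom`, `density`, `run`).

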