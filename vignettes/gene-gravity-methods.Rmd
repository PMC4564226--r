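---
title: "The gene gravity model: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gene gravity model: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genegravity)
```

# The problem and the model

A recurrent observation in tumor genomics is that somatic mutations
concentrate on genes whose protein products interact and whose transcripts
are co-expressed. The gene gravity model turns that observation into a
score. Two ingredients are combined per interacting gene pair:

* **Mutation mass.** The cohort-cumulative count of nonsynonymous somatic
  mutations per gene, `M0`, smoothed over the protein interaction network
  (PIN) by a random walk with restart (RWR),
  `M(t+1) = α Pᵀ M(t) + (1 − α) M0`, with the row-stochastic transition
  matrix `P_ij = 1/k_i` on edges. Smoothing shares the mutation signal of a
  gene with its network neighborhood, so a sparsely mutated gene embedded in
  a heavily mutated module still acquires mass.
* **Co-expression distance.** Each PIN edge is annotated with the Pearson
  correlation (PCC) of its endpoints' expression across all cohort samples
  (the CePIN), and distance is defined as `r = 1/PCC`: strongly co-expressed
  pairs are "close".

Gravitation follows Newton's law with the gravitation constant fixed at 1:

$$G_{ij} = \frac{k\, M_i M_j}{r_{ij}^2} = M_i\, M_j\, \mathrm{PCC}_{ij}^2 .$$

`G` is non-negative; the sign of the correlation is kept as an orthogonal
class — *attractive* gravitation (AG, PCC > 0) versus *repulsive* (RG,
PCC < 0) — because the cumulative-distribution analyses use the magnitude
while the AG/RG analyses use the sign. A pair with PCC exactly 0 is retained
with class `"null"` and `G = 0`. The gene-level summary is the average
gravitation over a gene's scored partners,
$\mathrm{aveG}_i = \sum_j G_{ij}/n$, alongside the mean absolute
correlation (avePCC), the PIN degree, chromosome, and cDNA length.

The model's assumptions are worth stating plainly: mutation counts are
treated as an additive, propagatable mass (no distinction between clonal
and subclonal events); co-expression is a static cohort-level property; and
the PIN is an unweighted, undirected scaffold whose edges are all equally
trustworthy. Violations of any of these blur, rather than bias, the score.

# Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `alpha` | 0.7 | dimensionless, [0, 1] | Propagation strength: mass moves to a random neighbor with probability α, restarts at its origin with 1 − α. 0.7 balances local retention against network sharing; rankings are insensitive for α above ≈ 0.7, and `alpha_sweep()` quantifies this per data set. |
| `tol` | 1e-6 | L2 norm of the update | Convergence threshold of the power iteration; the geometric contraction factor is α, so iterations ≈ log(tol)/log(α). |
| `sample_quantile` | 0.20 | fraction | A gene counts as expressed in a sample iff its value reaches that sample's 20th percentile. |
| `sample_fraction` | 0.20 | fraction | Genes expressed in fewer than 20% of samples are removed before any correlation. |
| `n` (top-N) | 100 | genes | Size of the head of the aveG ranking tested for gene-set enrichment. |
| universe | 20,462 | genes | Protein-coding gene count used for set-versus-universe enrichment. |

Length-normalized mass (`normalize_by_length = TRUE`) divides each gene's
count by its cDNA length in bp (the M/L variant), which removes the
advantage of very long genes; the aveG–length correlation utilities help
decide whether that matters for a given cohort.

# Numerical choices

* **Sparse operator.** The transition matrix is applied as a sparse
  `Matrix` product; a dense n × n array is never materialized, so networks
  of 10⁴–10⁵ nodes propagate comfortably.
* **Isolated nodes.** `P_ij = 1/k_i` is undefined at `k_i = 0`. Isolated
  nodes are given a lazy self-loop (`P_ii = 1`), so mass placed on them
  stays put (`M_i = M0_i` is the fixed point) and total mass is conserved on
  every graph — the alternative (an all-zero row) silently destroys
  `(1 − α) M0_i` of mass per isolated node.
* **The α = 1 limit.** With no restart term the walk's stationary state is
  degree-proportional, `k_i/2N_L` of the total mass on a connected graph,
  but plain power iteration oscillates forever on bipartite graphs (a
  2-periodic parity artifact), so the update-norm test can never fire.
  `propagate()` therefore returns the analytic stationary state at α = 1,
  computed per connected component (each component redistributes its own
  mass; disconnected pieces never exchange mass under the walk).
* **Iteration start.** `M(0) = M0`; with contraction factor α the result is
  independent of the start, but this choice makes the α → 0 limit exact in
  one step.
* **Exact Wilcoxon mode.** For combined sample size ≤ 20 the rank-sum
  p-value is computed by exact enumeration over midranks (a shift-algorithm
  dynamic program on doubled ranks, which are integers even under ties);
  two-sided p is `min(1, 2·min(P≤, P≥))`. Larger samples use the normal
  approximation with tie-corrected variance and continuity correction.
  Standard R engines stand behind the other tests (`fisher.test`,
  `p.adjust(method = "BH")`, `cor.test`).
* **Fisher enrichment table.** Set-versus-universe enrichment compares the
  within-set proportion against the marginal universe proportion
  (`[[o, a−o], [b, U−b]]`); this is the construction that reproduces the
  published worked examples bundled in the acceptance checks. The
  disjoint-background table is available via `background = "exclusive"`.
  Set-versus-set comparisons (2×2) are two-sided by default; enrichment
  tests are one-sided.
* **Ties in the aveG ranking.** Top-N selection breaks aveG ties by gene
  identifier, so rankings (and file outputs) are stable across runs.
* **Serialization.** Floating-point outputs are written with 10 significant
  digits, making file-interface round trips reproduce in-process results to
  better than 1e-9 relative.

# Design decisions that were genuinely open

* **"Below the 20%" filter.** Ties at the per-sample threshold count as
  expressed (the rule is `value ≥ quantile`): "below" excludes, the boundary
  stays in. The second criterion chains on the first — the expressed flags,
  not raw nonzero counts, decide the 20%-of-samples rule.
* **PCC over all samples.** After gene-level filtering, correlations use
  every cohort sample rather than only samples where both genes pass the
  per-sample criterion; the simpler reading, and it keeps every edge's
  correlation on a common sample basis. Expression is used untransformed by
  default with an optional `log2(x + 1)` switch, since RNA-Seq pipelines
  differ on this and the choice rescales, but rarely reorders, PCC.
* **aveG denominator.** The divisor is the number of *scored* partners
  (CePIN partners with a defined G), not the raw PIN degree: G is undefined
  on edges dropped for missing expression. A `denominator = "degree"` flag
  provides the other reading.
* **M0 counts events.** Each mutation record counts once; a
  `count = "samples"` flag counts distinct mutated samples per gene instead.
  Event counting preserves the information that one sample hit a gene
  repeatedly.
* **Identifiers.** Gene identity is exact, case-sensitive string match; no
  alias resolution is attempted (symbol normalization belongs upstream).
* **BH families are explicit.** Gene-set contrasts, top-N enrichments, and
  chromosome contrasts are adjusted within explicit families (one per
  comparison batch) rather than globally or per-test; `run_study()` records
  the family of every reported q-value.

# The synthetic-study generators

`synth_study()` builds a full seeded study so every stage of the pipeline is
testable without access-controlled tumor data. What it emulates:

* a sparse scale-free-like PIN (preferential attachment, largest component
  kept; a configuration-model alternative exists);
* expression with *planted co-expression*: genes of a planted edge share a
  latent factor, `x = s·√|ρ|·z_shared + √(1−|ρ|)·z_private`, which has
  population correlation exactly ρ (sign `s` assigned consistently over each
  planted component by BFS; conflicting targets are an error);
* mutations as per-(gene, sample) Poisson counts at `base_rate/n_samples`,
  multiplied for planted hot genes (×10), mutator-carrier samples (×5), and
  X-linked planted genes (×3 extra), emitted as MAF-like rows with a
  fraction of silent records to exercise the classification filter;
* metadata with chromosomes (X given 5% of genes, Y 1%) and log-normal cDNA
  lengths (median 2 kb), so length normalization and X-versus-autosome
  paths always have support.

Presets fix the study conditions: `small` (≈200 genes × 50 samples) for
unit-scale work, `paper_shaped` (≈5,000 genes × 300 samples) for
integration-scale work, and `null` (small geometry, nothing planted) as the
negative control. The planted "driver" set is simultaneously highly mutated
and co-expressed with its partners — the conjunction the gravity score is
designed to detect; roughly a fifth of it is forced onto the X chromosome
with extra mass so the chromosome contrast has a true positive.

What the generator does **not** emulate: over-dispersed mutation counts
(real cohorts are super-Poissonian), mutational signatures and their sample
heterogeneity, copy-number alterations, subclonal structure, and the
modular correlation structure of real transcriptomes (non-planted genes are
independent). Passing the planted-recovery tests therefore shows the
machinery is correct and sensitive at realistic effect sizes — not that the
score is robust to every pathology of real tumor data.

```{r example}
study <- synth_study("small", seed = 7)
filt <- filter_expression(study$expression)
cepin <- build_cepin(study$network, filt$matrix)
prop <- propagate(study$network, build_m0(study$mutations, study$network))
scores <- aveg_scores(pairwise_gravity(cepin, prop),
                      metadata = study$metadata, network = study$network)
head(scores[order(-aveg)], 5)
```

# Validation strategy and problem sizes

The test suite validates every operation against an independent oracle:
dense linear solves for the propagation recurrence (including the worked
3-node path instance with its closed-form answer (7/12, 1/3, 1/12) at
α = 0.5), full `combn()` enumeration for the exact Wilcoxon mode,
from-definition recomputation for BH, hypergeometric enumeration for
Fisher, and group-by/sort-and-count oracles for the scoring reductions.
Cross-solver agreement is checked on 50 random graphs of up to ~200 nodes
at α ∈ {0.2, 0.5, 0.7, 0.9}; type-I calibration of the rank-sum path uses
1,000 null replicates at 30-versus-30; end-to-end planted recovery runs on
the `paper_shaped` preset and the null control on 20 seeded `null` runs.
These sizes keep the full suite under a minute on one CPU while leaving
each check statistically decisive.

Two published, self-contained worked examples are reproduced exactly by
`scripts/acceptance.R` (the driver–chromatin-regulator and driver–DNA-repair
enrichments with their 2×2 comparison). The published interactome-cleaning
check (113,473 edges over 13,579 genes) requires the original supplementary
network file, which is not redistributable with the package; the
corresponding acceptance test documents the expected counts and runs
whenever that file is placed at `inst/extdata/supplementary_network.tsv`.

# Known limitations

* aveG correlates with PIN degree and with cDNA length by construction
  (hubs have more chances to accumulate propagated mass; long genes more
  raw mutations). The covariate-correlation utilities quantify this; the
  M/L variant mitigates the length effect but not the degree effect.
* The PCC → distance map is scale-free in PCC but treats PCC = ±ε as a very
  long distance; near-zero correlations contribute almost nothing to G
  regardless of mass, which is intended but means gravity cannot rank pairs
  whose co-expression is genuinely absent.
* Propagation at α close to 1 mixes slowly (iterations grow like
  1/(1 − α) · log(1/tol)); the closed-form solver is the better choice
  there.
* Stratified analyses (by sex, smoking status, or any sample subset) are
  supported by running the pipeline on subset inputs; the package does not
  manage stratification metadata itself.
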