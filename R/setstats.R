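# Statistical comparison machinery: rank-sum tests with BH control, Fisher
# enrichment, top-N enrichment, chromosome contrasts, density contrasts,
# covariate correlations, and the PPI-pair mutation-enrichment benchmark.

new_gg_test <- function(method, statistic, p, alternative,
                        groups = NULL, details = list()) {
  structure(list(method = method, statistic = statistic, p_value = p,
                 q_value = NA_real_, alternative = alternative,
                 groups = groups, details = details),
            class = "gg_test")
}

#' @export
print.gg_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.3g", x$method, x$alternative,
              x$statistic, x$p_value))
  if (!is.na(x$q_value)) cat(sprintf(", q = %.3g", x$q_value))
  cat("\n")
  if (!is.null(x$groups)) {
    with(x$groups, cat(sprintf("  %s: n = %d, mean = %.4g +/- %.3g (SEM)\n",
                               group, n, mean, sem), sep = ""))
  }
  invisible(x)
}

group_summary <- function(labels, values_list) {
  data.table::data.table(
    group = labels,
    n = vapply(values_list, length, integer(1)),
    mean = vapply(values_list, mean, numeric(1)),
    sem = vapply(values_list, sem, numeric(1)))
}

# Exact distribution of the rank-sum of the first group over all
# choose(n, m) group assignments, on midranks (shift algorithm over doubled
# ranks, which are integers even under ties).
rank_sum_exact_p <- function(a, b, alternative) {
  m <- length(a); n_all <- m + length(b)
  r2 <- as.integer(round(2 * rank(c(a, b))))
  S <- sum(r2)
  # dp[k + 1, s + 1] = number of size-k subsets of the processed ranks with
  # doubled-rank sum s
  dp <- matrix(0, nrow = m + 1L, ncol = S + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- min(m, n_all)
    for (k in seq.int(kmax, 1L)) {
      shifted <- c(rep(0, v), dp[k, seq_len(S + 1L - v)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  counts <- dp[m + 1L, ]
  total <- choose(n_all, m)
  w2_obs <- sum(r2[seq_len(m)])
  p_ge <- sum(counts[(w2_obs + 1L):(S + 1L)]) / total
  p_le <- sum(counts[seq_len(w2_obs + 1L)]) / total
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midranks throughout. For combined sample
#' size at most 20 (the default `exact` rule) the p-value is computed by
#' exact enumeration of the tie-aware rank-sum distribution; otherwise the
#' normal approximation with the standard tie-corrected variance and
#' continuity correction is used.
#'
#' @param a,b Numeric value vectors, each of length >= 2.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger),
#'   or `"less"`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact enumeration;
#'   default `NULL` selects exact iff `length(a) + length(b) <= 20`.
#' @return A `gg_test` with the rank-sum statistic of `a`, the p-value, and
#'   per-group size / mean / standard error.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater", "less"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (is.null(exact)) exact <- (length(a) + length(b)) <= 20L
  w <- sum(rank(c(a, b))[seq_along(a)])
  p <- if (exact) {
    rank_sum_exact_p(a, b, alternative)
  } else {
    stats::wilcox.test(a, b, alternative = alternative, exact = FALSE,
                       correct = TRUE)$p.value
  }
  new_gg_test(
    method = if (exact) "Wilcoxon rank-sum (exact)"
             else "Wilcoxon rank-sum (normal approximation)",
    statistic = w, p = p, alternative = alternative,
    groups = group_summary(c("a", "b"), list(a, b)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `q_(i) = min_(j >= i) p_(j) * m / j`,
#' capped at 1, returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Attach BH q-values across a named list of gg_test objects (one family).
adjust_family <- function(tests) {
  q <- bh_adjust(vapply(tests, function(t) t$p_value, numeric(1)))
  for (i in seq_along(tests)) tests[[i]]$q_value <- q[i]
  tests
}

#' Fisher enrichment of one gene set in another
#'
#' Tests whether membership of set B is over-represented inside set A,
#' relative to the gene universe, by Fisher's exact test. The default 2x2
#' construction compares the within-set proportion `overlap / set_a_size`
#' against the marginal universe proportion `set_b_size / universe`
#' (`background = "marginal"`); `background = "exclusive"` subtracts the
#' overlap from the background column so the two columns are disjoint.
#'
#' @param overlap Number of genes in both sets.
#' @param set_a_size,set_b_size Set sizes.
#' @param universe Total gene count (e.g. 20462 protein-coding genes).
#' @param alternative Fisher alternative; `"greater"` for enrichment
#'   (default).
#' @param background 2x2 background convention; see Details.
#' @return A `gg_test` with the odds ratio as statistic.
#' @examples
#' # 38 of 176 chromatin regulators are cancer drivers, against 614 drivers
#' # among 20,462 protein-coding genes:
#' fisher_enrichment(38, 176, 614, 20462)
#' @export
fisher_enrichment <- function(overlap, set_a_size, set_b_size, universe,
                              alternative = c("greater", "two.sided", "less"),
                              background = c("marginal", "exclusive")) {
  alternative <- match.arg(alternative)
  background <- match.arg(background)
  counts <- c(overlap, set_a_size, set_b_size, universe)
  if (any(counts < 0) || overlap > min(set_a_size, set_b_size) ||
      set_a_size > universe || set_b_size > universe) {
    stop("inconsistent enrichment counts", call. = FALSE)
  }
  if (set_a_size == 0L || set_b_size == 0L) {
    return(new_gg_test("Fisher's exact test", NA_real_, 1, alternative,
                       details = list(table = NULL)))
  }
  tab <- if (background == "marginal") {
    rbind(c(overlap, set_a_size - overlap),
          c(set_b_size, universe - set_b_size))
  } else {
    rbind(c(overlap, set_a_size - overlap),
          c(set_b_size - overlap, universe - set_a_size - set_b_size + overlap))
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  new_gg_test("Fisher's exact test", unname(ft$estimate), ft$p.value,
              alternative, details = list(table = tab))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test; the two-sided p-value sums the probabilities of
#' all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return A `gg_test` with the odds ratio as statistic.
#' @export
fisher_2x2 <- function(table,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(!is.finite(tab))) {
    stop("table must be a 2x2 matrix of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all-zero margin in 2x2 table", call. = FALSE)
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  new_gg_test("Fisher's exact test", unname(ft$estimate), ft$p.value,
              alternative, details = list(table = tab))
}

#' Enrichment of a gene set among the top-N aveG genes
#'
#' Ranks genes by aveG (ties broken by gene identifier for stability), takes
#' the top `n`, and tests enrichment of `geneset` membership among them
#' against the remaining scored genes (one-sided Fisher).
#'
#' @param scores Gene score table from [aveg_scores()].
#' @param geneset Character vector of gene identifiers.
#' @param n Number of top-ranked genes (default 100).
#' @return A `gg_test`; `details$top_genes` carries the selected genes and
#'   `details$overlap` the hit count.
#' @export
topn_enrichment <- function(scores, geneset, n = 100L) {
  sc <- data.table::as.data.table(scores)
  if (n > nrow(sc)) stop("n exceeds the number of scored genes", call. = FALSE)
  ord <- order(-sc$aveg, sc$gene)
  top <- sc$gene[ord[seq_len(n)]]
  rest <- sc$gene[ord[-seq_len(n)]]
  hits_top <- sum(top %in% geneset)
  hits_rest <- sum(rest %in% geneset)
  if (hits_top == 0L && hits_rest == 0L) {
    res <- new_gg_test("Fisher's exact test", NA_real_, 1, "greater")
  } else {
    res <- fisher_2x2(rbind(c(hits_top, n - hits_top),
                            c(hits_rest, length(rest) - hits_rest)),
                      alternative = "greater")
  }
  res$details$top_genes <- top
  res$details$overlap <- hits_top
  res
}

#' X chromosome versus autosomes aveG contrast
#'
#' Compares aveG of `geneset` genes on the X chromosome against those on the
#' 22 autosomes (Wilcoxon rank-sum, two-sided); Y-linked genes are excluded.
#'
#' @param scores Gene score table from [aveg_scores()] with chromosome labels.
#' @param geneset Optional gene set restricting the contrast; default all
#'   scored genes.
#' @return A `gg_test` with groups `X` and `autosomes`.
#' @export
x_vs_autosomes <- function(scores, geneset = NULL) {
  sc <- data.table::as.data.table(scores)
  if (!is.null(geneset)) sc <- sc[sc$gene %in% geneset, ]
  if (any(is.na(sc$chromosome))) {
    stop("chromosome labels are required for every scored gene", call. = FALSE)
  }
  x_vals <- sc$aveg[sc$chromosome == "X"]
  auto_vals <- sc$aveg[sc$chromosome %in% as.character(1:22)]
  if (length(x_vals) < 2L) {
    stop(sprintf("only %d X-linked gene(s) in the set; need at least 2",
                 length(x_vals)), call. = FALSE)
  }
  if (length(auto_vals) < 2L) {
    stop(sprintf("only %d autosomal gene(s) in the set; need at least 2",
                 length(auto_vals)), call. = FALSE)
  }
  res <- wilcoxon_rank_sum(x_vals, auto_vals, alternative = "two.sided")
  res$groups <- group_summary(c("X", "autosomes"), list(x_vals, auto_vals))
  res
}

#' Compare genome-wide mutation density between carriers and wild type
#'
#' Wilcoxon rank-sum test of per-sample mutation density (mutations per Mb)
#' between samples carrying a mutation in the gene of interest and wild-type
#' samples, with per-group mean and standard error.
#'
#' @param per_sample_density Named numeric vector: sample -> mutations/Mb.
#' @param mutated_samples Character vector of carrier sample identifiers
#'   (a subset of `names(per_sample_density)`).
#' @return A `gg_test` with groups `mutated` and `wild_type`.
#' @export
mutation_density_compare <- function(per_sample_density, mutated_samples) {
  d <- per_sample_density
  if (is.null(names(d))) stop("per_sample_density must be named by sample", call. = FALSE)
  if (!all(mutated_samples %in% names(d))) {
    stop("mutated_samples must be a subset of the density samples", call. = FALSE)
  }
  mut <- d[names(d) %in% mutated_samples]
  wt <- d[!names(d) %in% mutated_samples]
  if (length(mut) == 0L || length(wt) == 0L) {
    stop("both the mutated and wild-type groups must be non-empty", call. = FALSE)
  }
  res <- wilcoxon_rank_sum(as.numeric(mut), as.numeric(wt),
                           alternative = "two.sided")
  res$groups <- group_summary(c("mutated", "wild_type"),
                              list(as.numeric(mut), as.numeric(wt)))
  res
}

#' Correlation of aveG with a gene covariate
#'
#' Pearson correlation of aveG against cDNA length, PIN degree
#' (connectivity), or avePCC, with the usual t-test p-value. Exclusions are
#' applied first (e.g. the extreme-length genes TTN and MUC16 when
#' correlating against cDNA length).
#'
#' @param scores Gene score table from [aveg_scores()].
#' @param covariate One of `"cdna_length"`, `"degree"`, `"avepcc"`.
#' @param exclusions Genes removed before correlating.
#' @return List with `r`, `p`, and `n` (genes used).
#' @export
score_covariate_correlation <- function(scores,
                                        covariate = c("cdna_length", "degree",
                                                      "avepcc"),
                                        exclusions = character()) {
  covariate <- match.arg(covariate)
  sc <- data.table::as.data.table(scores)
  sc <- sc[!sc$gene %in% exclusions, ]
  sc <- sc[is.finite(sc[[covariate]]) & is.finite(sc$aveg), ]
  if (nrow(sc) < 10L) stop("need at least 10 genes after exclusions", call. = FALSE)
  v <- as.numeric(sc[[covariate]])
  if (stats::sd(v) == 0) stop("constant covariate", call. = FALSE)
  ct <- stats::cor.test(sc$aveg, v, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(sc))
}

#' Mutation enrichment on interacting pairs versus random pairs
#'
#' Compares the summed initial mutation mass `M0_i + M0_j` over true network
#' edges against the same statistic on uniformly sampled non-adjacent node
#' pairs (with replacement across draws), by a one-sided Wilcoxon rank-sum
#' test. Fully seeded.
#'
#' @param network An `interaction_network`.
#' @param m0 Named mutation vector over `network$nodes`.
#' @param n_draws Number of random pairs; defaults to the edge count.
#' @param seed Integer seed for the pair sampling.
#' @return A `gg_test` with groups `edges` and `random_pairs`.
#' @export
ppi_pair_mutation_enrichment <- function(network, m0, n_draws = NULL, seed) {
  stopifnot(inherits(network, "interaction_network"))
  m0 <- check_m0(m0, network)
  n <- length(network$nodes)
  if (network$n_edges >= n * (n - 1) / 2) {
    stop("complete graph: no non-adjacent pairs to sample", call. = FALSE)
  }
  if (is.null(n_draws)) n_draws <- network$n_edges
  edge_stat <- as.numeric(m0[network$edges$gene_a] + m0[network$edges$gene_b])
  existing <- edge_key(network$edges$gene_a, network$edges$gene_b)
  rand_stat <- with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n_draws) {
      k <- max(2L * (n_draws - length(out)), 100L)
      i <- sample.int(n, k, replace = TRUE)
      j <- sample.int(n, k, replace = TRUE)
      ok <- i != j
      i <- i[ok]; j <- j[ok]
      ga <- network$nodes[i]; gb <- network$nodes[j]
      keep <- !(edge_key(ga, gb) %in% existing)
      out <- c(out, (m0[ga] + m0[gb])[keep])
    }
    as.numeric(out[seq_len(n_draws)])
  })
  res <- wilcoxon_rank_sum(edge_stat, rand_stat, alternative = "greater")
  res$groups <- group_summary(c("edges", "random_pairs"),
                              list(edge_stat, rand_stat))
  res
}

#' Remove listed samples from a mutation table
#'
#' Drops every record of the listed samples (e.g. ultra-mutated tumors) and
#' reports the removed row count as an attribute.
#'
#' @param mutations Mutation table with a `sample` column.
#' @param exclusion_list Character vector of sample identifiers.
#' @return Filtered mutation `data.table` with attribute `removed_rows`.
#' @export
exclude_samples <- function(mutations, exclusion_list) {
  mut <- data.table::as.data.table(mutations)
  keep <- !(mut$sample %in% exclusion_list)
  out <- mut[keep, ]
  attr(out, "removed_rows") <- sum(!keep)
  out
}

#' Build a gene-set catalog
#'
#' @param sets Named list of character gene sets (e.g. `driver`, `cgc`,
#'   `crf`, `dna_repair`, `essential`, `oncogene`, `tsg`).
#' @param universe Total protein-coding gene count used for enrichment
#'   (default 20462).
#' @return A `gene_set_catalog`.
#' @export
gene_set_catalog <- function(sets, universe = 20462L) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(vapply(sets, length, integer(1)) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  if (any(vapply(sets, length, integer(1)) > universe)) {
    stop("a gene set exceeds the declared universe size", call. = FALSE)
  }
  structure(list(sets = sets, universe = as.integer(universe)),
            class = "gene_set_catalog")
}
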