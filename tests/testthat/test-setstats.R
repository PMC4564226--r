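test_that("exact rank-sum p-values match known closed forms", {
  a <- c(3, 1, 4, 1, 5)
  expect_equal(wilcoxon_rank_sum(a, a)$p_value, 1)   # identical multisets
  sep <- wilcoxon_rank_sum(11:20, 1:10)              # complete separation
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(1, c(2, 3)), "at least 2")
})

test_that("exact mode equals the full-enumeration oracle (with and without ties)", {
  set.seed(51)
  cases <- list(
    list(a = rnorm(3), b = rnorm(4)),
    list(a = rnorm(5), b = rnorm(5)),
    list(a = rnorm(6), b = rnorm(6)),
    list(a = sample(1:4, 5, TRUE), b = sample(1:4, 6, TRUE)),   # heavy ties
    list(a = c(1, 1, 2, 2), b = c(2, 2, 3, 3)),
    list(a = rpois(4, 2), b = rpois(6, 2)))
  for (cs in cases) {
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_rank_sum(cs$a, cs$b, alt)$p_value,
                   wilcoxon_enumeration_oracle(cs$a, cs$b, alt),
                   tolerance = 1e-10,
                   info = paste(alt, paste(cs$a, collapse = ","), "vs",
                                paste(cs$b, collapse = ",")))
    }
  }
})

test_that("two-sided rank-sum p is invariant to swapping the groups", {
  set.seed(52)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(8)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcoxon_rank_sum(b, a)$p_value, tolerance = 1e-12)
  }
  a <- rnorm(25); b <- rnorm(30)   # normal-approximation path
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # from-definition oracle on random vectors
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    sorted <- p[o] * m / seq_len(m)
    q[o] <- rev(cummin(rev(pmin(sorted, 1))))
    q
  }
  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("fisher_enrichment handles degenerate input and is monotone in overlap", {
  expect_equal(fisher_enrichment(0, 0, 10, 100)$p_value, 1)
  p_prev <- 1.01
  for (o in c(2, 5, 8, 10)) {
    p <- fisher_enrichment(o, 20, 50, 500)$p_value
    expect_lt(p, p_prev)
    p_prev <- p
  }
  expect_error(fisher_enrichment(30, 20, 50, 500), "inconsistent")
})

test_that("fisher_2x2 equals a hypergeometric enumeration oracle", {
  expect_equal(fisher_2x2(matrix(5, 2, 2))$p_value, 1)
  expect_error(fisher_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "all-zero margin")
  fisher_oracle <- function(tab, alternative) {
    # enumerate all tables with the observed margins
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    xs <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(xs, c1, n - c1, r1)
    obs <- tab[1, 1]
    switch(alternative,
           greater = sum(probs[xs >= obs]),
           less = sum(probs[xs <= obs]),
           two.sided = sum(probs[probs <= dhyper(obs, c1, n - c1, r1) * (1 + 1e-7)]))
  }
  set.seed(54)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_2x2(tab, alt)$p_value, fisher_oracle(tab, alt),
                   tolerance = 1e-9,
                   info = paste(alt, paste(tab, collapse = ",")))
    }
  }
})

test_that("top-N enrichment detects a planted top set and ignores a disjoint one", {
  sc <- data.table::data.table(
    gene = sprintf("g%03d", 1:200),
    aveg = c(rep(10, 20), runif(180)),
    n_partners = 5L, avepcc = 0.5, degree = 5L,
    chromosome = "1", cdna_length = 2000)
  top_set <- sprintf("g%03d", 1:20)
  res <- topn_enrichment(sc, top_set, n = 20)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$details$overlap, 20L)
  disjoint <- topn_enrichment(sc, c("zz1", "zz2"), n = 20)
  expect_equal(disjoint$p_value, 1)
  expect_error(topn_enrichment(sc, top_set, n = 500), "exceeds")
})

test_that("X-versus-autosome contrast needs X support and honors ties", {
  sc <- data.table::data.table(
    gene = sprintf("g%03d", 1:12), aveg = 1,
    n_partners = 3L, avepcc = 0.4, degree = 3L,
    chromosome = rep(c("1", "2", "3"), 4), cdna_length = 1500)
  expect_error(x_vs_autosomes(sc), "X-linked")
  sc$chromosome[1:4] <- "X"
  res <- x_vs_autosomes(sc)
  expect_equal(res$p_value, 1)   # identical aveG everywhere, exact mode
  expect_equal(res$groups$group, c("X", "autosomes"))
})

test_that("X contrast flags a planted X inflation and spares background genes", {
  st <- synth_study("small", seed = 91)
  filt <- filter_expression(st$expression)
  cep <- build_cepin(st$network, filt$matrix)
  m <- propagate(st$network, build_m0(st$mutations, st$network))
  sc <- aveg_scores(pairwise_gravity(cep, m), metadata = st$metadata,
                    network = st$network)
  planted <- x_vs_autosomes(sc, st$ground_truth$hot_genes)
  background <- x_vs_autosomes(sc, setdiff(sc$gene, st$ground_truth$hot_genes))
  q <- bh_adjust(c(planted$p_value, background$p_value))
  expect_lt(q[1], 0.1)
  expect_gt(q[2], 0.1)
})

test_that("mutation density comparison reports group summaries and exact p", {
  d <- setNames(c(10, 10, 10, 1, 1, 1), paste0("s", 1:6))
  res <- mutation_density_compare(d, paste0("s", 1:3))
  expect_equal(res$p_value, 2 / choose(6, 3), tolerance = 1e-12)  # 0.1
  expect_equal(res$groups$mean, c(10, 1))
  expect_error(mutation_density_compare(d, paste0("s", 1:6)), "non-empty")
})

test_that("aveG-covariate correlation behaves at the extremes", {
  set.seed(55)
  sc <- data.table::data.table(
    gene = sprintf("g%04d", 1:1000), aveg = runif(1000),
    n_partners = 4L, avepcc = runif(1000), degree = 4L,
    chromosome = "2", cdna_length = rlnorm(1000, log(2000), 0.5))
  sc2 <- data.table::copy(sc); sc2$cdna_length <- sc2$aveg
  expect_equal(score_covariate_correlation(sc2, "cdna_length")$r, 1)
  # independent covariate: near-zero correlation at n = 1000
  null_r <- score_covariate_correlation(sc, "cdna_length")$r
  expect_lt(abs(null_r), 0.15)
  # planted dependence: mass (hence aveG) proportional to length
  sc3 <- data.table::copy(sc)
  sc3$aveg <- sc3$cdna_length * (1 + 0.2 * runif(1000))
  dep <- score_covariate_correlation(sc3, "cdna_length")
  expect_gt(dep$r, 0)
  expect_lt(dep$p, 0.01)
  sc4 <- data.table::copy(sc); sc4$degree <- 7L
  expect_error(score_covariate_correlation(sc4, "degree"), "constant")
  # exclusions are applied before correlating
  few <- sc[1:12]
  expect_error(score_covariate_correlation(few, "cdna_length",
                                           exclusions = few$gene[1:5]),
               "at least 10")
})

test_that("PPI-pair mutation enrichment is seeded and detects planted structure", {
  net <- synth_network(100, 4, seed = 61)
  n <- length(net$nodes)
  m0_null <- withr::with_seed(62, setNames(runif(n), net$nodes))
  r1 <- ppi_pair_mutation_enrichment(net, m0_null, n_draws = 300, seed = 7)
  r2 <- ppi_pair_mutation_enrichment(net, m0_null, n_draws = 300, seed = 7)
  expect_identical(r1$p_value, r2$p_value)   # bit-identical under a fixed seed
  # mass concentrated on one edge-dense neighborhood -> enrichment
  hub <- names(sort(net$degree, decreasing = TRUE))[1]
  nbrs <- unique(c(net$edges$gene_b[net$edges$gene_a == hub],
                   net$edges$gene_a[net$edges$gene_b == hub]))
  m0_hot <- setNames(rep(0.01, n), net$nodes)
  m0_hot[c(hub, nbrs)] <- 50
  enr <- ppi_pair_mutation_enrichment(net, m0_hot, n_draws = 500, seed = 8)
  expect_lt(enr$p_value, 0.01)
})

test_that("null PPI-pair enrichment is calibrated across seeds", {
  net <- synth_network(60, 4, seed = 63)
  n <- length(net$nodes)
  ps <- vapply(1:40, function(s) {
    m0 <- withr::with_seed(1000 + s, setNames(runif(n), net$nodes))
    ppi_pair_mutation_enrichment(net, m0, n_draws = 150, seed = s)$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.3)
})

test_that("sample exclusion filters records and can zero a gene out", {
  mut <- data.frame(gene = c("A", "A", "B"), sample = c("s1", "s2", "s1"),
                    classification = "Missense_Mutation")
  expect_equal(nrow(exclude_samples(mut, character())), 3L)
  out <- exclude_samples(mut, c("s1", "s2"))
  expect_equal(attr(out, "removed_rows"), 3L)
  net <- path_network()
  m0 <- build_m0(out, net)
  expect_equal(m0[["A"]], 0)
  # random exclusions match a filter oracle
  set.seed(64)
  big <- data.frame(gene = sample(LETTERS, 100, TRUE),
                    sample = sample(paste0("s", 1:10), 100, TRUE),
                    classification = "Missense_Mutation")
  excl <- paste0("s", c(2, 5, 9))
  expect_equal(nrow(exclude_samples(big, excl)), sum(!big$sample %in% excl))
})

test_that("gene_set_catalog validates sets against the universe", {
  cat1 <- gene_set_catalog(list(driver = c("A", "B")), universe = 100)
  expect_equal(cat1$universe, 100L)
  expect_error(gene_set_catalog(list(bad = character())), "non-empty")
  expect_error(gene_set_catalog(list(big = as.character(1:50)), universe = 10),
               "exceeds")
})
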