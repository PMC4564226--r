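test_that("build_m0 counts nonsynonymous events per network gene", {
  net <- path_network()
  empty <- build_m0(data.frame(gene = character(), sample = character(),
                               classification = character()), net)
  expect_equal(as.numeric(empty), c(0, 0, 0))
  mut <- data.frame(
    gene = c("A", "A", "A", "A", "B"),
    sample = c("s1", "s1", "s2", "s3", "s1"),
    classification = c("Missense_Mutation", "Missense_Mutation",
                       "Missense_Mutation", "Silent", "Missense_Mutation"))
  m0 <- build_m0(mut, net)
  expect_equal(m0[["A"]], 3)
  expect_equal(m0[["B"]], 1)
  expect_equal(m0[["C"]], 0)
  # distinct-samples mode collapses the two s1 events on A
  m0s <- build_m0(mut, net, count = "samples")
  expect_equal(m0s[["A"]], 2)
})

test_that("length normalization divides counts by cDNA length", {
  net <- path_network()
  mut <- data.frame(gene = rep("A", 10), sample = paste0("s", 1:10),
                    classification = "Missense_Mutation")
  md <- load_gene_metadata(data.frame(gene = c("A", "B", "C"),
                                      chromosome = c("1", "2", "X"),
                                      cdna_length = c(1000, 500, 200)))
  m0 <- build_m0(mut, net, normalize_by_length = TRUE, metadata = md)
  expect_equal(m0[["A"]], 0.01)
  md_missing <- load_gene_metadata(data.frame(gene = "B", chromosome = "2",
                                              cdna_length = 500))
  expect_error(build_m0(mut, net, normalize_by_length = TRUE,
                        metadata = md_missing), "A")
})

test_that("alpha = 0 returns M0 exactly", {
  net <- random_network(20, 60, 1)
  m0 <- setNames(rpois(length(net$nodes), 3) + 0.0, net$nodes)
  p <- propagate(net, m0, alpha = 0)
  expect_identical(unname(p$m), unname(m0))
})

test_that("alpha = 1 converges to degree-proportional mass on connected graphs", {
  net <- synth_network(80, 4, seed = 5)   # largest component: connected
  m0 <- withr::with_seed(6, setNames(runif(length(net$nodes), 0, 10), net$nodes))
  p <- propagate(net, m0, alpha = 1)
  expected <- net$degree / (2 * net$n_edges) * sum(m0)
  expect_lt(max(abs(p$m - expected)), 1e-6)
})

test_that("path-graph propagation matches the dense-solve oracle exactly", {
  net <- path_network()
  m0 <- setNames(c(1, 0, 0), c("A", "B", "C"))
  p <- propagate(net, m0, alpha = 0.5, tol = 1e-12)
  expect_equal(unname(p$m), c(7 / 12, 1 / 3, 1 / 12), tolerance = 1e-9)
  # independent dense-solve oracle
  P <- matrix(c(0, 1, 0, 0.5, 0, 0.5, 0, 1, 0), 3, 3, byrow = TRUE)
  oracle <- solve(diag(3) - 0.5 * t(P), 0.5 * c(1, 0, 0))
  expect_equal(unname(p$m), oracle, tolerance = 1e-9)
  cf <- propagate_closed_form(net, m0, alpha = 0.5)
  expect_equal(unname(cf$m), oracle, tolerance = 1e-10)
})

test_that("iterative and closed-form solvers agree on random graphs", {
  tol <- 1e-8
  for (seed in 1:6) {
    net <- random_network(40, 120, seed)
    m0 <- withr::with_seed(seed, setNames(rpois(length(net$nodes), 5) + 0.0,
                                          net$nodes))
    for (alpha in c(0.2, 0.5, 0.7, 0.9)) {
      it <- propagate(net, m0, alpha = alpha, tol = tol, max_iter = 1e5)
      cf <- propagate_closed_form(net, m0, alpha = alpha)
      expect_lt(sqrt(sum((it$m - cf$m)^2)), 10 * tol)
    }
  }
})

test_that("total mass is conserved through propagation", {
  for (seed in 1:4) {
    net <- random_network(30, 70, seed)
    m0 <- withr::with_seed(seed, setNames(runif(length(net$nodes), 0, 20),
                                          net$nodes))
    for (alpha in c(0.3, 0.7, 1)) {
      p <- propagate(net, m0, alpha = alpha)
      expect_lt(abs(sum(p$m) - sum(m0)) / sum(m0), 1e-9)
    }
  }
})

test_that("propagation is linear in the initial vector", {
  net <- random_network(25, 60, 9)
  n <- length(net$nodes)
  m1 <- withr::with_seed(1, setNames(runif(n), net$nodes))
  m2 <- withr::with_seed(2, setNames(runif(n), net$nodes))
  tol <- 1e-12
  p12 <- propagate(net, 2 * m1 + 3 * m2, alpha = 0.7, tol = tol)
  p1 <- propagate(net, m1, alpha = 0.7, tol = tol)
  p2 <- propagate(net, m2, alpha = 0.7, tol = tol)
  expect_equal(unname(p12$m), unname(2 * p1$m + 3 * p2$m), tolerance = 1e-8)
})

test_that("influence decays monotonically with distance on a path graph", {
  n <- 8
  net <- load_interactions(data.frame(a = sprintf("p%02d", 1:(n - 1)),
                                      b = sprintf("p%02d", 2:n)))
  m0 <- setNames(c(1, rep(0, n - 1)), sprintf("p%02d", 1:n))
  p <- propagate(net, m0, alpha = 0.7, tol = 1e-12)
  expect_true(all(diff(p$m[sprintf("p%02d", 1:n)]) <= 1e-12))
})

test_that("mass on isolated nodes stays put", {
  net <- load_interactions(data.frame(a = c("A", "C"), b = c("B", "D")))
  sub <- restrict_to_genes(net, c("A", "B", "C"))  # C becomes isolated
  m0 <- setNames(c(1, 2, 5), c("A", "B", "C"))
  p <- propagate(sub, m0, alpha = 0.7, tol = 1e-12)
  expect_equal(p$m[["C"]], 5, tolerance = 1e-9)
  expect_equal(sum(p$m), sum(m0), tolerance = 1e-9)
})

test_that("closed form rejects alpha = 1", {
  net <- path_network()
  m0 <- setNames(c(1, 0, 0), net$nodes)
  expect_error(propagate_closed_form(net, m0, alpha = 1),
               "closed form undefined")
})

test_that("alpha_sweep composes propagations and tracks rank stability", {
  net <- synth_network(80, 4, seed = 13)
  m0 <- withr::with_seed(14, setNames(rpois(length(net$nodes), 4) + 0.0,
                                      net$nodes))
  sw <- alpha_sweep(net, m0, c(0.2, 0.7))
  expect_equal(ncol(sw$masses), 2L)
  expect_true(all(abs(colSums(sw$masses) - sum(m0)) / sum(m0) < 1e-6))
  single <- alpha_sweep(net, m0, 0.0)
  expect_equal(unname(single$masses[, 1]), unname(m0))
  # resolvent smoothness: neighboring alphas agree in rank more than distant ones
  sw2 <- alpha_sweep(net, m0, c(0.1, 0.6, 0.7))
  r_near <- cor(sw2$masses[, 2], sw2$masses[, 3], method = "spearman")
  r_far <- cor(sw2$masses[, 1], sw2$masses[, 3], method = "spearman")
  expect_gt(r_near, r_far)
})

test_that("propagated vectors round-trip through the TSV interface", {
  net <- random_network(15, 40, 17)
  m0 <- withr::with_seed(18, setNames(runif(length(net$nodes), 0, 5), net$nodes))
  p <- propagate(net, m0, alpha = 0.7, tol = 1e-10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_propagated(p, f)
  back <- read_propagated(f)
  expect_equal(unname(back[names(p$m)]), unname(p$m), tolerance = 1e-9)
})
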