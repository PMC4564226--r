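# Mutation vector construction and random-walk-with-restart propagation.

#' Default nonsynonymous variant classifications
#'
#' The classification vocabulary counted into the initial mutation vector.
#' Configurable in [build_m0()].
#' @export
NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Splice_Site", "Translation_Start_Site",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins")

#' Build the initial mutation vector M0
#'
#' Counts nonsynonymous mutation records per network gene, cumulated over all
#' samples of the cohort. Records on genes absent from the network are dropped
#' and counted. In length-normalized mode each count is divided by the gene's
#' cDNA length in base pairs (mutations per bp, the M/L variant).
#'
#' @param mutations Data frame with columns `gene`, `sample`,
#'   `classification`, e.g. from [read_mutations()].
#' @param network An `interaction_network`; M0 is indexed by its nodes.
#' @param nonsyn_classes Classifications counted as nonsynonymous.
#' @param count Count `"events"` (every record; default) or `"samples"`
#'   (distinct mutated samples per gene).
#' @param normalize_by_length Divide each gene's count by its cDNA length.
#' @param metadata Gene metadata from [load_gene_metadata()]; required iff
#'   `normalize_by_length`.
#' @return Named numeric vector M0 over `network$nodes`, with attributes
#'   `n_samples` (cohort size seen in the table) and `dropped_records`.
#' @export
build_m0 <- function(mutations, network,
                     nonsyn_classes = NONSYNONYMOUS_CLASSES,
                     count = c("events", "samples"),
                     normalize_by_length = FALSE, metadata = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  count <- match.arg(count)
  mut <- data.table::as.data.table(mutations)
  need <- c("gene", "sample", "classification")
  if (!all(need %in% names(mut))) {
    stop("mutations must have columns gene, sample, classification", call. = FALSE)
  }
  m0 <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  keep <- mut[mut$classification %in% nonsyn_classes, ]
  in_net <- keep$gene %in% network$nodes
  dropped <- sum(!in_net)
  keep <- keep[in_net, ]
  if (nrow(keep)) {
    tallied <- if (count == "events") {
      keep[, list(n = .N), by = "gene"]
    } else {
      keep[, list(n = data.table::uniqueN(sample)), by = "gene"]
    }
    m0[tallied$gene] <- as.numeric(tallied$n)
  }
  if (normalize_by_length) {
    if (is.null(metadata)) {
      stop("metadata is required for length normalization", call. = FALSE)
    }
    md <- data.table::as.data.table(metadata)
    len <- md$cdna_length[match(names(m0), md$gene)]
    missing_len <- names(m0)[m0 > 0 & !is.finite(len)]
    if (length(missing_len)) {
      stop("missing cDNA length for mutated gene(s): ",
           paste(missing_len, collapse = ", "), call. = FALSE)
    }
    m0 <- ifelse(m0 > 0, m0 / len, 0)
    names(m0) <- network$nodes
  }
  attr(m0, "n_samples") <- data.table::uniqueN(mut$sample)
  attr(m0, "dropped_records") <- dropped
  m0
}

# Sparse row-stochastic transition matrix P with P_ij = 1/k_i on edges.
# Isolated nodes get a lazy self-loop (P_ii = 1) so that mass placed on them
# stays put and the walk conserves total mass on every graph.
transition_matrix <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  nodes <- network$nodes
  n <- length(nodes)
  ia <- match(network$edges$gene_a, nodes)
  ib <- match(network$edges$gene_b, nodes)
  i <- c(ia, ib)
  j <- c(ib, ia)
  x <- 1 / network$degree[i]
  iso <- which(network$degree == 0L)
  if (length(iso)) {
    i <- c(i, iso); j <- c(j, iso); x <- c(x, rep(1, length(iso)))
  }
  Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x), dims = c(n, n),
                       dimnames = list(nodes, nodes))
}

check_m0 <- function(m0, network) {
  if (is.null(names(m0)) || !setequal(names(m0), network$nodes) ||
      length(m0) != length(network$nodes)) {
    stop("m0 must be a named vector indexed exactly by the network nodes",
         call. = FALSE)
  }
  if (any(!is.finite(m0)) || any(m0 < 0)) {
    stop("m0 entries must be finite and non-negative", call. = FALSE)
  }
  m0[network$nodes]
}

new_propagated <- function(m, m0, alpha, iterations, residual, method) {
  structure(list(m = m, m0 = m0, alpha = alpha, iterations = iterations,
                 residual = residual, method = method),
            class = "propagated_vector")
}

#' @export
print.propagated_vector <- function(x, ...) {
  cat(sprintf(
    "Propagated mutation vector: %d genes, alpha = %g, %s (%d iterations, residual %.3g)\n",
    length(x$m), x$alpha, x$method, x$iterations, x$residual))
  invisible(x)
}

#' Propagate mutation mass by random walk with restart
#'
#' Iterates `M(t+1) = alpha * t(P) %*% M(t) + (1 - alpha) * M0` from
#' `M(0) = M0` until the L2 update norm falls below `tol`, where `P` is the
#' row-normalized adjacency (`P_ij = 1/k_i` on edges). `alpha = 0` returns M0
#' unchanged; for `alpha = 1` the recurrence has no restart term and its
#' stationary state is degree-proportional (`k_i / 2 N_L` of the total mass on
#' a connected graph), which is returned analytically per connected component
#' since power iteration need not settle on bipartite components. Total mass
#' is conserved at every iteration.
#'
#' @param network An `interaction_network`.
#' @param m0 Named initial mutation vector over `network$nodes`
#'   (see [build_m0()]).
#' @param alpha Propagation strength in \[0, 1\]: mass moves to a random
#'   neighbor with probability `alpha` and restarts at its origin with
#'   probability `1 - alpha`. Default 0.7.
#' @param tol L2 convergence threshold on the update (default `1e-6`).
#' @param max_iter Iteration cap (default 10000).
#' @return A `propagated_vector`: list with `m` (named propagated masses),
#'   `m0`, `alpha`, `iterations`, final `residual`, and solver `method`.
#' @seealso [propagate_closed_form()] for the direct linear solve.
#' @export
propagate <- function(network, m0, alpha = 0.7, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(network, "interaction_network"))
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(tol, "tol", 0)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  m0 <- check_m0(m0, network)
  if (alpha == 0) {
    return(new_propagated(m0, m0, alpha, 1L, 0, "iterative"))
  }
  if (alpha == 1) {
    return(propagate_stationary(network, m0))
  }
  W <- alpha * Matrix::t(transition_matrix(network))
  restart <- (1 - alpha) * m0
  m <- m0
  for (it in seq_len(max_iter)) {
    m_new <- as.numeric(W %*% m) + restart
    resid <- sqrt(sum((m_new - m)^2))
    m <- m_new
    if (resid < tol) {
      names(m) <- network$nodes
      return(new_propagated(m, m0, alpha, it, resid, "iterative"))
    }
  }
  stop(sprintf("propagation did not converge in %d iterations (residual %.3g)",
               max_iter, resid), call. = FALSE)
}

# alpha = 1: per-component degree-proportional stationary state. Each
# connected component redistributes its own initial mass in proportion to
# node degree; isolated nodes keep their mass.
propagate_stationary <- function(network, m0) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  comp <- igraph::components(g)$membership[network$nodes]
  deg <- network$degree
  m <- numeric(length(m0))
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    total_deg <- sum(deg[idx])
    mass <- sum(m0[idx])
    m[idx] <- if (total_deg > 0) mass * deg[idx] / total_deg else m0[idx]
  }
  names(m) <- network$nodes
  new_propagated(m, m0, 1, 0L, 0, "stationary")
}

#' Closed-form propagation solution
#'
#' Solves `M = (1 - alpha) * (I - alpha * t(P))^{-1} %*% M0` by a sparse
#' direct linear solve; the fixed point of the random-walk-with-restart
#' recurrence for `alpha` in \[0, 1).
#'
#' @inheritParams propagate
#' @return A `propagated_vector` with `method = "closed_form"`.
#' @export
propagate_closed_form <- function(network, m0, alpha = 0.7) {
  stopifnot(inherits(network, "interaction_network"))
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (alpha == 1) {
    stop("closed form undefined; use power iteration", call. = FALSE)
  }
  m0 <- check_m0(m0, network)
  n <- length(m0)
  A <- Matrix::Diagonal(n) - alpha * Matrix::t(transition_matrix(network))
  m <- as.numeric(Matrix::solve(A, (1 - alpha) * m0))
  names(m) <- network$nodes
  new_propagated(m, m0, alpha, 0L, 0, "closed_form")
}

#' Sweep the propagation strength alpha
#'
#' Propagates the same initial vector at each `alpha` and reports Spearman
#' rank correlations between consecutive alphas, quantifying how strongly the
#' gene ranking depends on the propagation strength.
#'
#' @param network An `interaction_network`.
#' @param m0 Named initial mutation vector.
#' @param alphas Numeric vector of alphas in \[0, 1).
#' @param tol,max_iter Passed to [propagate()].
#' @return List with `masses` (gene-by-alpha matrix) and `rank_cor`
#'   (`data.table` of consecutive-alpha Spearman correlations).
#' @export
alpha_sweep <- function(network, m0, alphas, tol = 1e-6, max_iter = 10000L) {
  stopifnot(is.numeric(alphas), length(alphas) >= 1L,
            all(alphas >= 0 & alphas < 1))
  res <- lapply(alphas, function(a) {
    propagate(network, m0, alpha = a, tol = tol, max_iter = max_iter)$m
  })
  masses <- do.call(cbind, res)
  colnames(masses) <- format(alphas)
  rank_cor <- if (length(alphas) >= 2L) {
    data.table::data.table(
      alpha_a = alphas[-length(alphas)],
      alpha_b = alphas[-1L],
      spearman = vapply(seq_len(length(alphas) - 1L), function(i) {
        stats::cor(masses[, i], masses[, i + 1L], method = "spearman")
      }, numeric(1)))
  } else {
    data.table::data.table(alpha_a = numeric(), alpha_b = numeric(),
                           spearman = numeric())
  }
  list(masses = masses, rank_cor = rank_cor)
}

#' Write a propagated vector
#'
#' Columns: `gene`, `m0`, `m_propagated`.
#'
#' @param propagated A `propagated_vector`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_propagated <- function(propagated, path) {
  stopifnot(inherits(propagated, "propagated_vector"))
  write_tsv10(data.table::data.table(gene = names(propagated$m),
                                     m0 = as.numeric(propagated$m0),
                                     m_propagated = as.numeric(propagated$m)),
              path)
}

#' Read a propagated vector written by [write_propagated()]
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of propagated masses, with `m0` attribute.
#' @export
read_propagated <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- stats::setNames(as.numeric(dt$m_propagated), as.character(dt$gene))
  attr(m, "m0") <- stats::setNames(as.numeric(dt$m0), as.character(dt$gene))
  m
}
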