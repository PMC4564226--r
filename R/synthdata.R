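# Seeded synthetic studies with planted structure: network, expression,
# mutations, metadata, gene sets. Stands in for a real tumor cohort so every
# pipeline stage is testable offline.

#' Generate a synthetic interaction network
#'
#' Draws a sparse network from a preferential-attachment (scale-free-like) or
#' configuration model, keeps the largest connected component, and cleans it
#' through [load_interactions()]. Fully deterministic under `seed`.
#'
#' @param n_genes Number of genes before component trimming (>= 10).
#' @param mean_degree Target mean degree (approximate).
#' @param model `"preferential_attachment"` (default) or `"configuration"`.
#' @param seed Integer seed.
#' @return An `interaction_network`; the count of nodes dropped outside the
#'   largest component is reported in `$dropped$outside_component`.
#' @export
synth_network <- function(n_genes, mean_degree = 6,
                          model = c("preferential_attachment", "configuration"),
                          seed) {
  model <- match.arg(model)
  if (n_genes < 10L) stop("n_genes must be at least 10", call. = FALSE)
  if (mean_degree < 2 || mean_degree >= n_genes) {
    stop("infeasible mean degree", call. = FALSE)
  }
  g <- with_seed(seed, {
    if (model == "preferential_attachment") {
      igraph::sample_pa(n_genes, m = max(1L, round(mean_degree / 2)),
                        directed = FALSE)
    } else {
      deg <- pmax(1L, stats::rpois(n_genes, mean_degree))
      if (sum(deg) %% 2L == 1L) deg[1L] <- deg[1L] + 1L
      igraph::simplify(igraph::sample_degseq(deg, method = "configuration"))
    }
  })
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  el <- igraph::as_edgelist(g, names = FALSE)
  names_all <- sprintf("g%05d", keep)
  net <- load_interactions(data.frame(a = names_all[el[, 1L]],
                                      b = names_all[el[, 2L]]))
  net$dropped$outside_component <- n_genes - length(keep)
  net
}

#' Generate synthetic gene metadata
#'
#' Chromosomes are assigned at random with the X chromosome given 5% of genes
#' and Y 1%, the rest uniform over the 22 autosomes; cDNA lengths are
#' log-normal with median 2 kb.
#'
#' @param genes Character vector of gene identifiers.
#' @param seed Integer seed.
#' @return A validated metadata `data.table` (see [load_gene_metadata()]).
#' @export
synth_metadata <- function(genes, seed) {
  with_seed(seed, {
    chrom <- sample(c(as.character(1:22), "X", "Y"), length(genes),
                    replace = TRUE,
                    prob = c(rep(0.94 / 22, 22), 0.05, 0.01))
    len <- pmax(200, round(stats::rlnorm(length(genes),
                                         meanlog = log(2000), sdlog = 0.6)))
    load_gene_metadata(data.frame(gene = genes, chromosome = chrom,
                                  cdna_length = len))
  })
}

# Consistent latent-factor layout for the planted co-expression structure:
# connected components of the planted edge set share one latent factor;
# per-gene signs are assigned by BFS so that sign_i * sign_j matches the sign
# of each planted edge's target correlation. Errors on conflicting |target|
# or an unbalanced sign pattern.
plan_coexpression <- function(edges, target_pcc) {
  ne <- nrow(edges)
  if (length(target_pcc) == 1L) target_pcc <- rep(target_pcc, ne)
  if (length(target_pcc) != ne) {
    stop("target_pcc must be scalar or one per planted edge", call. = FALSE)
  }
  if (any(abs(target_pcc) >= 1) || any(target_pcc == 0)) {
    stop("planted target correlations must be non-zero with |rho| < 1",
         call. = FALSE)
  }
  genes <- unique(c(edges$gene_a, edges$gene_b))
  # union-find over gene indices to group planted edges into components
  parent <- seq_along(genes)
  root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ia <- match(edges$gene_a, genes); ib <- match(edges$gene_b, genes)
  for (k in seq_len(ne)) {
    ra <- root(ia[k]); rb <- root(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp_id <- vapply(seq_along(genes), root, integer(1))
  rho <- abs(target_pcc)
  for (cid in unique(comp_id)) {
    members <- which(comp_id == cid)
    eidx <- which(ia %in% members | ib %in% members)
    if (length(unique(round(rho[eidx], 12))) > 1L) {
      stop("gene planted in edges with conflicting target correlations",
           call. = FALSE)
    }
  }
  # sign assignment by BFS over planted edges
  sign_of <- rep(NA_real_, length(genes))
  nbr <- vector("list", length(genes))
  for (k in seq_len(ne)) {
    nbr[[ia[k]]] <- c(nbr[[ia[k]]], k)
    nbr[[ib[k]]] <- c(nbr[[ib[k]]], k)
  }
  for (start in seq_along(genes)) {
    if (!is.na(sign_of[start])) next
    sign_of[start] <- 1
    queue <- start
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      for (k in nbr[[i]]) {
        jj <- if (ia[k] == i) ib[k] else ia[k]
        want <- sign_of[i] * sign(target_pcc[k])
        if (is.na(sign_of[jj])) {
          sign_of[jj] <- want
          queue <- c(queue, jj)
        } else if (sign_of[jj] != want) {
          stop("gene planted in edges with conflicting target correlations",
               call. = FALSE)
        }
      }
    }
  }
  gene_rho <- rep(NA_real_, length(genes))
  for (k in seq_len(ne)) {
    gene_rho[ia[k]] <- rho[k]
    gene_rho[ib[k]] <- rho[k]
  }
  list(genes = genes, component = comp_id, sign = sign_of,
       rho = stats::setNames(gene_rho, genes))
}

#' Generate a synthetic expression matrix with planted co-expression
#'
#' Every gene of a planted edge is built from a latent factor shared within
#' its planted component: `x = sign * sqrt(|rho|) * z_shared +
#' sqrt(1 - |rho|) * z_private`, giving population correlation exactly
#' `target_pcc` on each planted edge. Non-planted genes are independent.
#' Values are scaled by `noise_sd`, offset by a per-gene baseline, and
#' globally shifted non-negative.
#'
#' @param network An `interaction_network` (planted edges must be edges of
#'   it).
#' @param n_samples Number of samples (columns).
#' @param coexpressed_edges Data frame with `gene_a`, `gene_b` rows to plant;
#'   may be empty.
#' @param target_pcc Target correlation(s) for planted edges, |rho| < 1.
#' @param noise_sd Scale of expression variation around the baseline.
#' @param seed Integer seed.
#' @return Numeric gene-by-sample matrix.
#' @export
synth_expression <- function(network, n_samples, coexpressed_edges = NULL,
                             target_pcc = 0.8, noise_sd = 1, seed) {
  stopifnot(inherits(network, "interaction_network"))
  genes <- network$nodes
  planted <- if (is.null(coexpressed_edges) || nrow(coexpressed_edges) == 0L) {
    NULL
  } else {
    pe <- data.table::as.data.table(coexpressed_edges)
    if (!all(edge_key(pe$gene_a, pe$gene_b) %in%
             edge_key(network$edges$gene_a, network$edges$gene_b))) {
      stop("coexpressed_edges must be edges of the network", call. = FALSE)
    }
    plan_coexpression(pe, target_pcc)
  }
  with_seed(seed, {
    x <- matrix(stats::rnorm(length(genes) * n_samples), nrow = length(genes),
                dimnames = list(genes, sprintf("s%04d", seq_len(n_samples))))
    if (!is.null(planted)) {
      for (cid in unique(planted$component)) {
        members <- planted$genes[planted$component == cid]
        rho <- planted$rho[members[1L]]
        z_shared <- stats::rnorm(n_samples)
        for (gname in members) {
          s <- planted$sign[match(gname, planted$genes)]
          x[gname, ] <- s * sqrt(rho) * z_shared +
            sqrt(1 - rho) * stats::rnorm(n_samples)
        }
      }
    }
    baseline <- stats::runif(length(genes), 2, 10)
    x <- baseline + noise_sd * x
    if (min(x) < 0) x <- x - min(x)
    x
  })
}

#' Generate a synthetic somatic mutation table
#'
#' Per-(gene, sample) mutation counts are Poisson with rate
#' `base_rate / n_samples`, multiplied by `hot_multiplier` for hot genes,
#' `mutator_multiplier` for mutator-carrier samples, and any extra per-gene
#' multiplier. Events are emitted as MAF-like rows with nonsynonymous
#' classifications; an additional `silent_rate` fraction of silent rows
#' exercises the classification filter downstream.
#'
#' @param network An `interaction_network` (genes = its nodes).
#' @param n_samples Cohort size.
#' @param base_rate Expected mutations per gene over the whole cohort.
#' @param hot_genes Planted highly mutated genes.
#' @param hot_multiplier Rate multiplier for hot genes (>= 1).
#' @param mutator_carriers Sample identifiers with an elevated genome-wide
#'   rate.
#' @param mutator_multiplier Rate multiplier for carrier samples (>= 1).
#' @param gene_multipliers Optional named numeric vector of extra per-gene
#'   rate multipliers (e.g. X-linked inflation).
#' @param silent_rate Fraction of additional silent records (default 0.1).
#' @param seed Integer seed.
#' @return `data.table` with columns `gene`, `sample`, `classification`.
#' @export
synth_mutations <- function(network, n_samples, base_rate = 3,
                            hot_genes = character(), hot_multiplier = 1,
                            mutator_carriers = character(),
                            mutator_multiplier = 1,
                            gene_multipliers = NULL, silent_rate = 0.1, seed) {
  stopifnot(inherits(network, "interaction_network"))
  if (hot_multiplier < 1 || mutator_multiplier < 1) {
    stop("multipliers must be at least 1", call. = FALSE)
  }
  genes <- network$nodes
  samples <- sprintf("s%04d", seq_len(n_samples))
  gene_rate <- rep(base_rate / n_samples, length(genes))
  gene_rate[genes %in% hot_genes] <- gene_rate[genes %in% hot_genes] * hot_multiplier
  if (!is.null(gene_multipliers)) {
    idx <- match(names(gene_multipliers), genes)
    ok <- !is.na(idx)
    gene_rate[idx[ok]] <- gene_rate[idx[ok]] * as.numeric(gene_multipliers)[ok]
  }
  sample_factor <- ifelse(samples %in% mutator_carriers, mutator_multiplier, 1)
  with_seed(seed, {
    lambda <- outer(gene_rate, sample_factor)
    counts <- stats::rpois(length(lambda), as.numeric(lambda))
    nz <- which(counts > 0L)
    gi <- ((nz - 1L) %% length(genes)) + 1L
    si <- ((nz - 1L) %/% length(genes)) + 1L
    reps <- counts[nz]
    dt <- data.table::data.table(
      gene = rep(genes[gi], reps),
      sample = rep(samples[si], reps),
      classification = sample(NONSYNONYMOUS_CLASSES,
                              sum(reps), replace = TRUE,
                              prob = c(0.6, 0.1, 0.01, 0.08, 0.01,
                                       0.07, 0.05, 0.04, 0.04)))
    if (silent_rate > 0) {
      n_sil <- stats::rpois(1L, silent_rate * sum(reps))
      if (n_sil > 0L) {
        dt <- data.table::rbindlist(list(dt, data.table::data.table(
          gene = sample(genes, n_sil, replace = TRUE),
          sample = sample(samples, n_sil, replace = TRUE),
          classification = "Silent")))
      }
    }
    data.table::setorder(dt, gene, sample, classification)
    dt[]
  })
}

#' Generate a complete synthetic study
#'
#' Bundles a network, metadata, expression with planted co-expression,
#' mutations with planted hot genes and mutator-carrier samples, and a
#' gene-set catalog, with the planted ground truth recorded. The planted
#' "driver" set is both highly mutated and co-expressed with its interaction
#' partners (the high-gravitation signature); a subset of it is forced onto
#' the X chromosome with additionally inflated mutation mass so
#' X-versus-autosome contrasts always have support.
#'
#' @param preset `"small"` (~200 genes / 50 samples; unit-test scale),
#'   `"paper_shaped"` (~5000 genes / 300 samples; integration scale), or
#'   `"null"` (small geometry, nothing planted — the negative control).
#' @param seed Integer seed; the study is bit-reproducible given
#'   (preset, seed).
#' @return A `synthetic_study`: list with `network`, `expression`,
#'   `mutations`, `metadata`, `catalog`, `ground_truth`, `seed`, `preset`.
#' @export
synth_study <- function(preset = c("small", "paper_shaped", "null"), seed) {
  preset <- match.arg(preset)
  par <- switch(preset,
    small = list(n_genes = 200L, n_samples = 50L, mean_degree = 6,
                 n_hot = 15L, hot_multiplier = 10, base_rate = 3,
                 target_pcc = 0.8, n_carriers = 5L, mutator_multiplier = 5,
                 planted = TRUE),
    paper_shaped = list(n_genes = 5000L, n_samples = 300L, mean_degree = 6,
                        n_hot = 50L, hot_multiplier = 10, base_rate = 3,
                        target_pcc = 0.8, n_carriers = 30L,
                        mutator_multiplier = 5, planted = TRUE),
    null = list(n_genes = 200L, n_samples = 50L, mean_degree = 6,
                n_hot = 15L, hot_multiplier = 1, base_rate = 3,
                target_pcc = 0, n_carriers = 0L, mutator_multiplier = 1,
                planted = FALSE))
  seed <- as.integer(seed)
  network <- synth_network(par$n_genes, par$mean_degree, seed = seed)
  metadata <- synth_metadata(network$nodes, seed = seed + 1L)
  picks <- with_seed(seed + 2L, {
    deg_ok <- network$nodes[network$degree >= 2L]
    hot <- sort(sample(deg_ok, par$n_hot))
    random_set <- sort(sample(setdiff(network$nodes, hot),
                              min(30L, length(network$nodes) - par$n_hot)))
    list(hot = hot, random_set = random_set)
  })
  hot <- picks$hot
  # force ~20% of the planted set onto the X chromosome
  x_hot <- hot[seq_len(max(2L, ceiling(0.2 * length(hot))))]
  metadata[match(x_hot, metadata$gene), chromosome := "X"]
  coexpressed_edges <- NULL
  if (par$planted) {
    e <- network$edges
    incident <- e[e$gene_a %in% hot | e$gene_b %in% hot, ]
    # up to 3 planted partners per hot gene
    incident[, hub := ifelse(gene_a %in% hot, gene_a, gene_b)]
    incident[, idx := seq_len(.N), by = "hub"]
    coexpressed_edges <- incident[idx <= 3L, list(gene_a, gene_b)]
  }
  expression <- synth_expression(network, par$n_samples,
                                 coexpressed_edges = coexpressed_edges,
                                 target_pcc = par$target_pcc,
                                 seed = seed + 3L)
  gene_mult <- if (par$planted) {
    stats::setNames(rep(3, length(x_hot)), x_hot)
  } else NULL
  carriers <- if (par$n_carriers > 0L) {
    sprintf("s%04d", seq_len(par$n_carriers))
  } else character()
  mutations <- synth_mutations(network, par$n_samples,
                               base_rate = par$base_rate,
                               hot_genes = if (par$planted) hot else character(),
                               hot_multiplier = par$hot_multiplier,
                               mutator_carriers = carriers,
                               mutator_multiplier = par$mutator_multiplier,
                               gene_multipliers = gene_mult,
                               seed = seed + 4L)
  catalog <- gene_set_catalog(
    list(planted_driver = hot, random_set = picks$random_set),
    universe = length(network$nodes))
  structure(list(
    network = network,
    expression = expression,
    mutations = mutations,
    metadata = metadata,
    catalog = catalog,
    ground_truth = list(
      hot_genes = hot, hot_multiplier = if (par$planted) par$hot_multiplier else 1,
      coexpressed_edges = coexpressed_edges, target_pcc = par$target_pcc,
      mutator_carriers = carriers, mutator_multiplier = par$mutator_multiplier,
      x_linked_hot = if (par$planted) x_hot else character(),
      x_multiplier = if (par$planted) 3 else 1),
    seed = seed, preset = preset), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study (preset '%s', seed %d): %d genes, %d samples, %d mutation records\n",
    x$preset, x$seed, length(x$network$nodes), ncol(x$expression),
    nrow(x$mutations)))
  invisible(x)
}

#' Write a synthetic study to disk in the package's file dialects
#'
#' Emits `network.tsv`, `expression.tsv`, `mutations.tsv`, `metadata.tsv`,
#' and one `geneset_<name>.txt` per catalog set, exactly as consumed by the
#' file-reading entry points, so synthetic studies round-trip through the
#' public file interfaces.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    metadata = file.path(dir, "metadata.tsv"))
  data.table::fwrite(study$network$edges, paths$network, sep = "\t",
                     col.names = FALSE)
  write_expression(study$expression, paths$expression)
  maf <- data.table::data.table(Hugo_Symbol = study$mutations$gene,
                                Tumor_Sample_Barcode = study$mutations$sample,
                                Variant_Classification = study$mutations$classification)
  data.table::fwrite(maf, paths$mutations, sep = "\t")
  md <- data.table::copy(study$metadata)
  data.table::setnames(md, "cdna_length", "cdna_length_bp")
  data.table::fwrite(md, paths$metadata, sep = "\t")
  for (nm in names(study$catalog$sets)) {
    p <- file.path(dir, sprintf("geneset_%s.txt", nm))
    writeLines(study$catalog$sets[[nm]], p)
    paths[[paste0("geneset_", nm)]] <- p
  }
  invisible(paths)
}
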