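# End-to-end orchestration: validated run configuration, staged execution,
# output bundle with manifest.

#' Build and validate a run configuration
#'
#' @param network_path Edge-list TSV (see [read_edge_list()]).
#' @param expression_path Expression TSV (see [read_expression()]).
#' @param mutations_path MAF-like TSV (see [read_mutations()]).
#' @param metadata_path Optional gene metadata TSV.
#' @param geneset_paths Named character vector of gene-set file paths.
#' @param exclusions_path Optional sample-exclusion list (one barcode per
#'   line).
#' @param output_dir Directory for the result bundle.
#' @param alpha Propagation strength in \[0, 1\] (default 0.7).
#' @param tol Propagation convergence threshold (default 1e-6).
#' @param sample_quantile,sample_fraction Expression-filter parameters.
#' @param normalize_by_length Use the length-normalized M/L mutation vector.
#' @param log2_expression Apply log2(x + 1) before correlation.
#' @param network_header Does the edge list carry a header row?
#' @param universe Gene universe size for enrichment tests.
#' @param top_n Top-N cut for aveG enrichment (default 100).
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated `run_config` list.
#' @export
run_config <- function(network_path, expression_path, mutations_path,
                       metadata_path = NULL, geneset_paths = character(),
                       exclusions_path = NULL, output_dir = "gravity_run",
                       alpha = 0.7, tol = 1e-6, sample_quantile = 0.20,
                       sample_fraction = 0.20, normalize_by_length = FALSE,
                       log2_expression = FALSE, network_header = FALSE,
                       universe = 20462L, top_n = 100L, seed = 1L) {
  cfg <- list(network_path = network_path, expression_path = expression_path,
              mutations_path = mutations_path, metadata_path = metadata_path,
              geneset_paths = geneset_paths, exclusions_path = exclusions_path,
              output_dir = output_dir, alpha = alpha, tol = tol,
              sample_quantile = sample_quantile,
              sample_fraction = sample_fraction,
              normalize_by_length = normalize_by_length,
              log2_expression = log2_expression,
              network_header = network_header, universe = universe,
              top_n = top_n, seed = as.integer(seed))
  assert_scalar_number(cfg$alpha, "alpha", 0, 1)
  assert_scalar_number(cfg$tol, "tol", 0)
  assert_scalar_number(cfg$sample_quantile, "sample_quantile", 0, 1)
  assert_scalar_number(cfg$sample_fraction, "sample_fraction", 0, 1)
  req <- c(cfg$network_path, cfg$expression_path, cfg$mutations_path,
           cfg$metadata_path, cfg$exclusions_path, unname(cfg$geneset_paths))
  missing_paths <- req[!file.exists(req)]
  if (length(missing_paths)) {
    stop("input path(s) do not exist: ", paste(missing_paths, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$normalize_by_length && is.null(cfg$metadata_path)) {
    stop("normalize_by_length requires metadata_path", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML fields mirror the [run_config()] arguments; `geneset_paths` is a
#' name-to-path mapping.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  if (!is.null(y$geneset_paths)) y$geneset_paths <- unlist(y$geneset_paths)
  do.call(run_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full gene gravity pipeline
#'
#' Executes network loading, expression filtering and CePIN construction,
#' mutation propagation, gravitation and aveG scoring, and the set-level
#' statistics, writing a result bundle (`cepin.tsv`, `propagated.tsv`,
#' `gravity.tsv`, `gene_scores.tsv`, `set_tests.tsv`, `manifest.json`) to
#' `config$output_dir`. Each statistics batch (set-versus-non-set aveG
#' contrasts; top-N enrichments; X-versus-autosome contrasts) forms one
#' explicit Benjamini-Hochberg family.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory stage results (`network`,
#'   `cepin`, `propagated`, `gravity`, `scores`, `tests`, `manifest`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(...)))
  }

  network <- run_stage("netio", {
    net <- load_interactions(read_edge_list(config$network_path,
                                            header = config$network_header))
    log_stage("netio", "%d nodes, %d edges (%d self-loops, %d duplicates dropped)",
              length(net$nodes), net$n_edges, net$dropped$self_loops,
              net$dropped$duplicates)
    net
  })
  metadata <- if (!is.null(config$metadata_path)) {
    run_stage("netio", load_gene_metadata(read_gene_metadata(config$metadata_path)))
  } else NULL

  cepin <- run_stage("coexpr", {
    expr_mat <- read_expression(config$expression_path)
    filt <- filter_expression(expr_mat, config$sample_quantile,
                              config$sample_fraction,
                              log2_transform = config$log2_expression)
    cep <- build_cepin(network, filt$matrix)
    log_stage("coexpr", "%d/%d genes expressed; CePIN %d nodes, %d edges (%d undefined-PCC edges dropped)",
              length(filt$genes), nrow(expr_mat), length(cep$nodes),
              cep$n_edges, cep$dropped$undefined_pcc)
    cep
  })

  propagated <- run_stage("propagate", {
    mutations <- read_mutations(config$mutations_path)
    if (!is.null(config$exclusions_path)) {
      excl <- read_gene_set(config$exclusions_path)
      mutations <- exclude_samples(mutations, excl)
      log_stage("propagate", "excluded %d mutation records from %d listed samples",
                attr(mutations, "removed_rows"), length(excl))
    }
    m0 <- build_m0(mutations, network,
                   normalize_by_length = config$normalize_by_length,
                   metadata = metadata)
    p <- propagate(network, m0, alpha = config$alpha, tol = config$tol)
    log_stage("propagate", "alpha = %g, %d iterations, residual %.3g, %d off-network records dropped",
              config$alpha, p$iterations, p$residual,
              attr(m0, "dropped_records"))
    p
  })

  gravity <- run_stage("gravity", pairwise_gravity(cepin, propagated))
  scores <- run_stage("gravity", aveg_scores(gravity, metadata = metadata,
                                             network = network))
  log_stage("gravity", "%d scored edges, %d scored genes", nrow(gravity),
            nrow(scores))

  tests <- run_stage("setstats", {
    sets <- lapply(config$geneset_paths, read_gene_set)
    out <- list()
    if (length(sets)) {
      contrast <- lapply(sets, function(s) {
        inset <- scores$aveg[scores$gene %in% s]
        outset <- scores$aveg[!scores$gene %in% s]
        if (length(inset) >= 2L && length(outset) >= 2L) {
          wilcoxon_rank_sum(inset, outset, alternative = "two.sided")
        } else NULL
      })
      contrast <- Filter(Negate(is.null), contrast)
      if (length(contrast)) {
        out <- c(out, stats::setNames(adjust_family(contrast),
                 paste0("aveg_contrast.", names(contrast))))
      }
      topn <- lapply(sets, function(s) {
        topn_enrichment(scores, s, n = min(config$top_n, nrow(scores)))
      })
      out <- c(out, stats::setNames(adjust_family(topn),
               paste0("topn_enrichment.", names(topn))))
      if (!is.null(metadata)) {
        xa <- lapply(sets, function(s) {
          tryCatch(x_vs_autosomes(scores, s), error = function(e) NULL)
        })
        xa <- Filter(Negate(is.null), xa)
        if (length(xa)) {
          out <- c(out, stats::setNames(adjust_family(xa),
                   paste0("x_vs_autosomes.", names(xa))))
        }
      }
    }
    log_stage("setstats", "%d tests across %d gene sets", length(out),
              length(sets))
    out
  })

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(cepin = file.path(config$output_dir, "cepin.tsv"),
                propagated = file.path(config$output_dir, "propagated.tsv"),
                gravity = file.path(config$output_dir, "gravity.tsv"),
                gene_scores = file.path(config$output_dir, "gene_scores.tsv"),
                set_tests = file.path(config$output_dir, "set_tests.tsv"),
                manifest = file.path(config$output_dir, "manifest.json"))
  write_cepin(cepin, paths$cepin)
  write_propagated(propagated, paths$propagated)
  write_gravity(gravity, paths$gravity)
  write_gene_scores(scores, paths$gene_scores)
  write_test_results(tests, paths$set_tests)

  inputs <- c(network = config$network_path, expression = config$expression_path,
              mutations = config$mutations_path)
  if (!is.null(config$metadata_path)) inputs["metadata"] <- config$metadata_path
  manifest <- list(
    parameters = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs)),
    counts = list(network_nodes = length(network$nodes),
                  network_edges = network$n_edges,
                  cepin_nodes = length(cepin$nodes),
                  cepin_edges = cepin$n_edges,
                  scored_genes = nrow(scores)),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(network = network, cepin = cepin, propagated = propagated,
                 gravity = gravity, scores = scores, tests = tests,
                 manifest = manifest, paths = paths))
}

#' Write a table of test results
#'
#' One row per test: name, family, group sizes/means/SEMs, statistic, p, q.
#'
#' @param tests Named list of `gg_test` objects; names of the form
#'   `family.test` set the family column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_test_results <- function(tests, path) {
  rows <- lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    fam <- sub("\\..*$", "", nm)
    g <- t$groups
    data.table::data.table(
      test = nm, family = fam, method = t$method,
      n_a = if (!is.null(g)) g$n[1L] else NA_integer_,
      n_b = if (!is.null(g)) g$n[2L] else NA_integer_,
      mean_a = if (!is.null(g)) g$mean[1L] else NA_real_,
      mean_b = if (!is.null(g)) g$mean[2L] else NA_real_,
      sem_a = if (!is.null(g)) g$sem[1L] else NA_real_,
      sem_b = if (!is.null(g)) g$sem[2L] else NA_real_,
      statistic = t$statistic, p = t$p_value, q = t$q_value)
  })
  dt <- if (length(rows)) data.table::rbindlist(rows) else {
    data.table::data.table(test = character(), family = character(),
                           method = character(), n_a = integer(),
                           n_b = integer(), mean_a = numeric(),
                           mean_b = numeric(), sem_a = numeric(),
                           sem_b = numeric(), statistic = numeric(),
                           p = numeric(), q = numeric())
  }
  write_tsv10(dt, path)
}
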