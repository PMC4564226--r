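# Expression filtering, Pearson correlation, and CePIN assembly.

validate_expression <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(matrix))) stop("duplicate sample identifiers", call. = FALSE)
  invisible(matrix)
}

#' Two-stage expression filter
#'
#' A gene counts as expressed in a sample iff its value is at or above the
#' `sample_quantile` empirical quantile of that sample's values (per-sample
#' threshold; ties at the threshold count as expressed). Genes expressed in
#' fewer than `sample_fraction` of samples are removed. With the defaults this
#' drops, per sample, genes in the bottom 20% of that sample's expression
#' ranking, then removes genes expressed in less than 20% of samples.
#'
#' @param matrix Numeric gene-by-sample expression matrix (non-negative).
#' @param sample_quantile Per-sample expression quantile below which a gene is
#'   not expressed in that sample; in (0, 1).
#' @param sample_fraction Minimum fraction of samples a gene must be expressed
#'   in; in (0, 1].
#' @param log2_transform Apply `log2(x + 1)` before filtering and any
#'   downstream correlation. Off by default; raw values are used as-is.
#' @return List with `matrix` (surviving genes, all samples) and `genes`
#'   (the expressed-gene set).
#' @export
filter_expression <- function(matrix, sample_quantile = 0.20,
                              sample_fraction = 0.20, log2_transform = FALSE) {
  validate_expression(matrix)
  if (ncol(matrix) < 3L) stop("too few samples", call. = FALSE)
  assert_scalar_number(sample_quantile, "sample_quantile", 0, 1)
  assert_scalar_number(sample_fraction, "sample_fraction", 0, 1)
  if (sample_quantile <= 0 || sample_quantile >= 1 || sample_fraction <= 0) {
    stop("sample_quantile in (0,1) and sample_fraction in (0,1] required",
         call. = FALSE)
  }
  if (log2_transform) matrix <- log2(matrix + 1)
  thr <- apply(matrix, 2L, stats::quantile, probs = sample_quantile,
               names = FALSE, type = 7)
  expressed <- sweep(matrix, 2L, thr, ">=")
  keep <- rowMeans(expressed) >= sample_fraction
  if (!any(keep)) stop("no genes survive the expression filter", call. = FALSE)
  list(matrix = matrix[keep, , drop = FALSE], genes = rownames(matrix)[keep])
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation; errors on constant input so callers
#' can drop the affected edge explicitly.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

sign_class_of <- function(pcc) {
  ifelse(pcc > 0, "attractive", ifelse(pcc < 0, "repulsive", "null"))
}

#' Build the co-expressed protein interaction network (CePIN)
#'
#' Restricts the PIN to expressed genes present in the filtered matrix and
#' annotates each surviving edge with the Pearson correlation of its
#' endpoints' expression across all samples of the cohort. Edges whose
#' correlation is undefined (a constant endpoint) are dropped and counted.
#'
#' @param network An `interaction_network` (the PIN).
#' @param filtered Filtered gene-by-sample expression matrix, as the `matrix`
#'   element returned by [filter_expression()].
#' @return A `cepin` object: an `interaction_network` whose `edges` carry
#'   `pcc` and `sign_class` (`attractive` for positive, `repulsive` for
#'   negative, `null` for exactly zero) columns, plus drop accounting.
#' @export
build_cepin <- function(network, filtered) {
  stopifnot(inherits(network, "interaction_network"))
  validate_expression(filtered)
  common <- intersect(network$nodes, rownames(filtered))
  if (length(common) == 0L) stop("no network genes are expressed", call. = FALSE)
  sub <- restrict_to_genes(network, common)
  e <- data.table::copy(sub$edges)
  if (nrow(e) == 0L) stop("no surviving edges in CePIN", call. = FALSE)
  x <- filtered[sub$nodes, , drop = FALSE]
  n <- ncol(x)
  sds <- apply(x, 1L, stats::sd)
  z <- x - rowMeans(x)
  z <- z / ifelse(sds > 0, sds, NA_real_)
  ia <- match(e$gene_a, sub$nodes)
  ib <- match(e$gene_b, sub$nodes)
  pcc <- rowSums(z[ia, , drop = FALSE] * z[ib, , drop = FALSE]) / (n - 1)
  defined <- is.finite(pcc)
  n_undef <- sum(!defined)
  e <- e[defined, ]
  e[, pcc := pmin(1, pmax(-1, pcc[defined]))]
  e[, sign_class := sign_class_of(pcc)]
  if (nrow(e) == 0L) stop("no surviving edges in CePIN", call. = FALSE)
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  net <- new_interaction_network(e, nodes)
  net$n_samples <- n
  net$dropped <- list(undefined_pcc = n_undef,
                      unexpressed_nodes = length(network$nodes) - length(common))
  class(net) <- c("cepin", class(net))
  net
}

#' Write a CePIN edge table
#'
#' Columns: `gene_a`, `gene_b`, `pcc`, `sign_class`.
#'
#' @param cepin A `cepin` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cepin <- function(cepin, path) {
  stopifnot(inherits(cepin, "cepin"))
  write_tsv10(cepin$edges, path)
}

#' Read a CePIN edge table written by [write_cepin()]
#'
#' @param path Path to the TSV.
#' @return A `cepin` object.
#' @export
read_cepin <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("gene_a", "gene_b", "pcc")
  if (!all(need %in% names(dt))) {
    stop("CePIN file must have columns gene_a, gene_b, pcc", call. = FALSE)
  }
  dt[, `:=`(gene_a = as.character(gene_a), gene_b = as.character(gene_b),
            pcc = as.numeric(pcc))]
  if (!"sign_class" %in% names(dt)) dt[, sign_class := sign_class_of(pcc)]
  nodes <- sort(unique(c(dt$gene_a, dt$gene_b)))
  net <- new_interaction_network(dt[], nodes)
  class(net) <- c("cepin", class(net))
  net
}
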