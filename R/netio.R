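# Protein interaction network construction and gene metadata.

new_interaction_network <- function(edges, nodes) {
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes))
  structure(list(
    edges = edges,
    nodes = nodes,
    degree = stats::setNames(as.integer(deg), nodes),
    n_edges = nrow(edges)
  ), class = "interaction_network")
}

#' Build a cleaned undirected interaction network
#'
#' Constructs the protein interaction network (PIN) from raw edge records.
#' Edge direction is ignored; self-loops are dropped and duplicate pairs
#' (including reversed order) are collapsed, with the dropped counts reported
#' on the returned object.
#'
#' @param edge_records A two-column data frame (or matrix) of gene identifier
#'   pairs, e.g. from [read_edge_list()]. Identifiers are matched
#'   case-sensitively; no symbol aliasing is performed.
#' @return An `interaction_network`: list with `edges` (canonical-order
#'   `data.table`), `nodes`, per-node `degree`, `n_edges`, and a `dropped`
#'   element counting removed self-loops and duplicates.
#' @examples
#' net <- load_interactions(data.frame(a = c("A", "B", "A", "A"),
#'                                     b = c("B", "A", "A", "B")))
#' net$n_edges   # 1
#' @export
load_interactions <- function(edge_records) {
  er <- as.data.frame(edge_records, stringsAsFactors = FALSE)
  if (nrow(er) == 0L) stop("empty network", call. = FALSE)
  if (ncol(er) < 2L) stop("edge records must have two columns", call. = FALSE)
  a <- as.character(er[[1L]]); b <- as.character(er[[2L]])
  bad <- which(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b))
  if (length(bad)) {
    stop(sprintf("malformed edge record at line %d", bad[1L]), call. = FALSE)
  }
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  cp <- canonical_pairs(a, b)
  key <- paste(cp$gene_a, cp$gene_b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- data.table::data.table(gene_a = cp$gene_a[!dup],
                                  gene_b = cp$gene_b[!dup])
  data.table::setorder(edges, gene_a, gene_b)
  if (nrow(edges) == 0L) stop("empty network", call. = FALSE)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  net <- new_interaction_network(edges, nodes)
  net$dropped <- list(self_loops = n_self, duplicates = n_dup)
  net
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges (mean degree %.2f)\n",
              length(x$nodes), x$n_edges,
              if (length(x$nodes)) 2 * x$n_edges / length(x$nodes) else 0))
  invisible(x)
}

#' Induced subgraph on a gene set
#'
#' Restricts a network to the genes in `keep`; degrees and the edge count are
#' recomputed. Nodes of `keep` present in the network but left without edges
#' are retained with degree zero (downstream propagation treats them as
#' isolated).
#'
#' @param network An `interaction_network`.
#' @param keep Character vector of gene identifiers to retain.
#' @return The induced `interaction_network`.
#' @export
restrict_to_genes <- function(network, keep) {
  stopifnot(inherits(network, "interaction_network"))
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("no genes retained", call. = FALSE)
  nodes <- intersect(network$nodes, keep)
  if (length(nodes) == 0L) stop("no genes retained", call. = FALSE)
  e <- network$edges[network$edges$gene_a %in% nodes &
                     network$edges$gene_b %in% nodes, ]
  net <- new_interaction_network(e, sort(nodes))
  net$dropped <- list(nodes = length(network$nodes) - length(nodes),
                      edges = network$n_edges - nrow(e))
  net
}

#' Validate a gene metadata table
#'
#' Checks chromosome labels (1-22, X, Y), positive cDNA lengths, and gene
#' uniqueness.
#'
#' @param records Data frame with columns `gene`, `chromosome`, `cdna_length`
#'   (cDNA length in base pairs), e.g. from [read_gene_metadata()].
#' @return A validated `data.table` keyed by `gene`.
#' @export
load_gene_metadata <- function(records) {
  dt <- data.table::as.data.table(records)
  need <- c("gene", "chromosome", "cdna_length")
  if (!all(need %in% names(dt))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dt <- dt[, need, with = FALSE]
  dt[, `:=`(gene = as.character(gene), chromosome = as.character(chromosome),
            cdna_length = as.numeric(cdna_length))]
  if (anyDuplicated(dt$gene)) {
    stop("duplicate gene in metadata: ",
         dt$gene[anyDuplicated(dt$gene)], call. = FALSE)
  }
  allowed <- c(as.character(1:22), "X", "Y")
  bad_chr <- setdiff(unique(dt$chromosome), allowed)
  if (length(bad_chr)) {
    stop("unknown chromosome label(s): ", paste(bad_chr, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(dt$cdna_length) | dt$cdna_length <= 0)) {
    stop("cdna_length must be positive for every gene", call. = FALSE)
  }
  data.table::setkey(dt, gene)
  dt[]
}

#' Write a network edge list
#'
#' @param network An `interaction_network` (or a `cepin`, whose `pcc` and
#'   `sign_class` columns are then included).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  write_tsv10(network$edges, path)
}
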