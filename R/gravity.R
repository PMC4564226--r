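# Pairwise gravitation scores, per-gene aveG/avePCC, and cumulative curves.

#' Gravitation score of a gene pair
#'
#' `G = k * M_i * M_j / r^2` with gravitation constant `k = 1` and biological
#' distance `r = 1 / PCC`, i.e. `G = M_i * M_j * PCC^2`. G is stored as a
#' non-negative magnitude together with a sign class taken from the sign of
#' the co-expression correlation: `attractive` (PCC > 0), `repulsive`
#' (PCC < 0), or `null` (PCC = 0, G = 0).
#'
#' @param m_i,m_j Propagated mutation masses (non-negative; vectorized).
#' @param pcc Pearson correlation(s) in \[-1, 1\].
#' @return `data.table` with columns `g_score` and `sign_class`.
#' @examples
#' gravity_score(2, 3, -0.5)   # G = 1.5, repulsive
#' @export
gravity_score <- function(m_i, m_j, pcc) {
  if (any(m_i < 0) || any(m_j < 0)) stop("masses must be non-negative", call. = FALSE)
  if (any(abs(pcc) > 1)) stop("|pcc| must be at most 1", call. = FALSE)
  data.table::data.table(g_score = m_i * m_j * pcc^2,
                         sign_class = sign_class_of(pcc))
}

#' Gravitation scores for every CePIN edge
#'
#' @param cepin A `cepin` object.
#' @param m Propagated masses: a `propagated_vector` or a named numeric
#'   vector covering every CePIN gene.
#' @return `data.table` with columns `gene_a`, `gene_b`, `pcc`, `g_score`,
#'   `sign_class` — one row per CePIN edge.
#' @export
pairwise_gravity <- function(cepin, m) {
  stopifnot(inherits(cepin, "cepin"))
  if (inherits(m, "propagated_vector")) m <- m$m
  missing_genes <- setdiff(cepin$nodes, names(m))
  if (length(missing_genes)) {
    stop("missing propagated mass for gene(s): ",
         paste(utils::head(missing_genes, 10L), collapse = ", "), call. = FALSE)
  }
  e <- data.table::copy(cepin$edges)
  gs <- gravity_score(as.numeric(m[e$gene_a]), as.numeric(m[e$gene_b]), e$pcc)
  e[, g_score := gs$g_score]
  e[, sign_class := gs$sign_class]
  e[]
}

#' Per-gene average gravitation (aveG) scores
#'
#' For each gene, `aveG = sum(G_ij) / n` over its scored partners, together
#' with the partner count, the mean absolute co-expression correlation
#' (avePCC), the gene's PIN degree, and chromosome / cDNA-length metadata
#' where available.
#'
#' @param gravity Edge table from [pairwise_gravity()].
#' @param metadata Optional gene metadata ([load_gene_metadata()]) supplying
#'   `chromosome` and `cdna_length`.
#' @param network Optional PIN `interaction_network`; when given, `degree` is
#'   the PIN degree, otherwise the scored-partner count.
#' @param denominator Divisor for aveG: `"partners"` (scored CePIN partners;
#'   default) or `"degree"` (raw PIN degree; requires `network`).
#' @return `data.table` with columns `gene`, `aveg`, `n_partners`, `avepcc`,
#'   `degree`, `chromosome`, `cdna_length`.
#' @export
aveg_scores <- function(gravity, metadata = NULL, network = NULL,
                        denominator = c("partners", "degree")) {
  denominator <- match.arg(denominator)
  gr <- data.table::as.data.table(gravity)
  if (nrow(gr) == 0L) stop("empty gravity table", call. = FALSE)
  long <- data.table::rbindlist(list(
    gr[, list(gene = gene_a, g_score, pcc)],
    gr[, list(gene = gene_b, g_score, pcc)]))
  scores <- long[, list(g_sum = sum(g_score), n_partners = .N,
                        avepcc = mean(abs(pcc))), by = "gene"]
  if (denominator == "degree") {
    if (is.null(network)) {
      stop("denominator = \"degree\" requires the PIN network", call. = FALSE)
    }
    scores[, aveg := g_sum / as.numeric(network$degree[gene])]
  } else {
    scores[, aveg := g_sum / n_partners]
  }
  scores[, degree := if (is.null(network)) n_partners
         else as.integer(network$degree[gene])]
  if (!is.null(metadata)) {
    md <- data.table::as.data.table(metadata)
    scores[, chromosome := md$chromosome[match(gene, md$gene)]]
    scores[, cdna_length := md$cdna_length[match(gene, md$gene)]]
  } else {
    scores[, chromosome := NA_character_]
    scores[, cdna_length := NA_real_]
  }
  data.table::setorder(scores, gene)
  scores[, list(gene, aveg, n_partners, avepcc, degree, chromosome, cdna_length)]
}

#' Split gravitation edges into attractive and repulsive tables
#'
#' Attractive gravitation (AG): positively co-expressed pairs. Repulsive
#' gravitation (RG): negatively co-expressed pairs. Null edges (PCC = 0) fall
#' in neither.
#'
#' @param gravity Edge table from [pairwise_gravity()].
#' @return List with elements `attractive` and `repulsive`.
#' @export
split_ag_rg <- function(gravity) {
  gr <- data.table::as.data.table(gravity)
  list(attractive = gr[gr$sign_class == "attractive", ],
       repulsive = gr[gr$sign_class == "repulsive", ])
}

#' Classify edges into set-pairs and non-set-pairs
#'
#' A set-pair has at least one endpoint in `geneset`; a non-set-pair has
#' neither.
#'
#' @param gravity Edge table from [pairwise_gravity()].
#' @param geneset Character vector of gene identifiers.
#' @return List with elements `set_pairs` and `non_set_pairs`.
#' @export
classify_pairs <- function(gravity, geneset) {
  gr <- data.table::as.data.table(gravity)
  hit <- gr$gene_a %in% geneset | gr$gene_b %in% geneset
  list(set_pairs = gr[hit, ], non_set_pairs = gr[!hit, ])
}

#' Complementary cumulative distribution of scores
#'
#' `C(g)` is the fraction of scores at or above each threshold `g`: a valid
#' survival curve (non-increasing, 1 at or below the minimum score, 0 beyond
#' the maximum).
#'
#' @param scores Non-empty numeric vector (e.g. G scores of set-pairs).
#' @param grid Thresholds; default is 200 logarithmically spaced points from
#'   the smallest positive score to the maximum, plus 0.
#' @return `data.table` with columns `threshold` and `fraction`.
#' @export
complementary_cumulative <- function(scores, grid = NULL) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L || any(!is.finite(scores))) {
    stop("scores must be a non-empty finite vector", call. = FALSE)
  }
  if (is.null(grid)) {
    pos <- scores[scores > 0]
    grid <- if (length(pos)) {
      c(0, exp(seq(log(min(pos)), log(max(scores)), length.out = 200L)))
    } else {
      c(0, 1)
    }
  }
  grid <- sort(unique(as.numeric(grid)))
  sorted <- sort(scores)
  # fraction >= g via binary search on the sorted scores
  frac <- 1 - (findInterval(grid, sorted, left.open = TRUE) / length(sorted))
  data.table::data.table(threshold = grid, fraction = frac)
}

#' Write a gravity edge table
#'
#' Columns: `gene_a`, `gene_b`, `pcc`, `g_score`, `sign_class`.
#' @param gravity Edge table from [pairwise_gravity()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gravity <- function(gravity, path) write_tsv10(gravity, path)

#' Write a per-gene score table
#'
#' Columns as produced by [aveg_scores()], with `cdna_length` serialized as
#' `cdna_length_bp`.
#' @param scores `data.table` from [aveg_scores()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path) {
  out <- data.table::copy(data.table::as.data.table(scores))
  data.table::setnames(out, "cdna_length", "cdna_length_bp")
  write_tsv10(out, path)
}
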