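# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic entry points route through this so that a given seed
# is bit-reproducible regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical unordered edge key: endpoints sorted within the pair.
canonical_pairs <- function(a, b) {
  list(gene_a = pmin(a, b), gene_b = pmax(a, b))
}

edge_key <- function(a, b) {
  cp <- canonical_pairs(a, b)
  paste(cp$gene_a, cp$gene_b, sep = "\r")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Read a two-column interaction edge list
#'
#' Reads a TSV with columns `gene_a`, `gene_b` (header optional). Extra
#' columns are ignored.
#'
#' @param path Path to a tab-separated edge-list file.
#' @param header Logical; does the file carry a header row?
#' @return A two-column `data.table` with columns `gene_a`, `gene_b`.
#' @export
read_edge_list <- function(path, header = FALSE) {
  dt <- data.table::fread(path, header = header, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("edge list must have at least two columns", call. = FALSE)
  dt <- dt[, 1:2]
  data.table::setnames(dt, c("gene_a", "gene_b"))
  dt[]
}

#' Read a gene metadata table
#'
#' Expects columns `gene`, `chromosome`, `cdna_length_bp` (header required).
#'
#' @param path Path to a tab-separated metadata file.
#' @return A `data.table` ready for [load_gene_metadata()].
#' @export
read_gene_metadata <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("gene", "chromosome", "cdna_length_bp")
  if (!all(need %in% names(dt))) {
    stop("metadata file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data.table::data.table(gene = as.character(dt$gene),
                         chromosome = as.character(dt$chromosome),
                         cdna_length = as.numeric(dt$cdna_length_bp))
}

#' Read an expression matrix
#'
#' First column is the gene identifier; every remaining column is one sample.
#'
#' @param path Path to a tab-separated expression file with header.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  genes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_expression(m)
  m
}

#' Write an expression matrix
#'
#' @param matrix Numeric gene-by-sample matrix with dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path) {
  dt <- data.table::data.table(gene = rownames(matrix))
  dt <- cbind(dt, data.table::as.data.table(matrix))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a MAF-like somatic mutation table
#'
#' Maps the MAF column names (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`) onto the internal `gene` / `sample` /
#' `classification` columns; already-internal names pass through.
#'
#' @param path Path to a tab-separated mutation file with header.
#' @param gene_col,sample_col,classification_col Column names to use.
#' @return A `data.table` with columns `gene`, `sample`, `classification`.
#' @export
read_mutations <- function(path, gene_col = "Hugo_Symbol",
                           sample_col = "Tumor_Sample_Barcode",
                           classification_col = "Variant_Classification") {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  pick <- function(primary, fallback) {
    if (primary %in% names(dt)) primary
    else if (fallback %in% names(dt)) fallback
    else stop(sprintf("mutation table lacks column '%s'", primary), call. = FALSE)
  }
  data.table::data.table(
    gene = dt[[pick(gene_col, "gene")]],
    sample = dt[[pick(sample_col, "sample")]],
    classification = dt[[pick(classification_col, "classification")]])
}

#' Read a gene-set file (one gene per line)
#'
#' @param path Path to a plain-text file, one gene identifier per line.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

# Serialize floating-point columns at 10 significant digits so file-interface
# round trips reproduce in-process results to well below 1e-9 relative.
write_tsv10 <- function(dt, path) {
  dt <- data.table::copy(data.table::as.data.table(dt))
  for (nm in names(dt)) {
    if (is.double(dt[[nm]])) {
      data.table::set(dt, j = nm, value = formatC(dt[[nm]], digits = 10,
                                                  format = "g"))
    }
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
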