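# Shared fixtures, built in code.

# Path graph A - B - C
path_network <- function() {
  load_interactions(data.frame(a = c("A", "B"), b = c("B", "C")))
}

# Erdos-Renyi-ish random edge list on `n` nodes (may contain planted
# duplicates/self-loops when asked), as raw records for load_interactions().
random_edge_records <- function(n_nodes, n_records, seed,
                                plant_duplicates = FALSE) {
  withr::with_seed(seed, {
    a <- sample(sprintf("n%02d", seq_len(n_nodes)), n_records, replace = TRUE)
    b <- sample(sprintf("n%02d", seq_len(n_nodes)), n_records, replace = TRUE)
    df <- data.frame(a = a, b = b)
    if (plant_duplicates) {
      extra <- df[sample(nrow(df), ceiling(n_records / 4)), ]
      df <- rbind(df, extra[, c(1, 2)], setNames(extra[, c(2, 1)], c("a", "b")))
    }
    df
  })
}

random_network <- function(n_nodes, n_records, seed) {
  recs <- random_edge_records(n_nodes, n_records, seed)
  recs <- recs[recs$a != recs$b, ]
  load_interactions(recs)
}

# Toy CePIN with stated pcc values, bypassing expression, for hand arithmetic.
toy_cepin <- function(edges_df) {
  f <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(edges_df, f, sep = "\t")
  read_cepin(f)
}

# Independent full-enumeration oracle for the two-sample rank-sum test
# (midranks), used against the package's shift-algorithm exact mode.
wilcoxon_enumeration_oracle <- function(a, b, alternative = "two.sided") {
  m <- length(a)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(m)])
  sums <- combn(length(r), m, FUN = function(idx) sum(r[idx]))
  eps <- 1e-9
  p_ge <- mean(sums >= obs - eps)
  p_le <- mean(sums <= obs + eps)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
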