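# Shared fixture builders; all fixtures are generated in code.

# A record_table of categorical columns from a data.frame.
make_discrete_table <- function(df, ids = NULL) {
  schema <- table_schema(lapply(names(df), function(nm) column_schema(nm, "categorical")))
  record_table(df, schema, ids = ids)
}

# Random categorical table for property tests.
random_discrete_table <- function(nrows, cardinalities, seed) {
  set.seed(seed)
  df <- as.data.frame(lapply(cardinalities, function(K) {
    paste0("v", sample.int(K, nrows, replace = TRUE))
  }))
  names(df) <- paste0("c", seq_along(cardinalities))
  make_discrete_table(df)
}

# Population whose attribute patterns are all unique by construction:
# N distinct rows of a 5-column product space.
unique_pattern_population <- function(N, seed = 1) {
  grid <- expand.grid(a = paste0("a", 1:5), b = paste0("b", 1:5),
                      c = paste0("c", 1:5), d = paste0("d", 1:5),
                      e = paste0("e", 1:5), stringsAsFactors = FALSE)
  stopifnot(N <= nrow(grid))
  set.seed(seed)
  rows <- grid[sample.int(nrow(grid), N), , drop = FALSE]
  make_discrete_table(rows, ids = as.character(seq_len(N)))
}

# Brute-force double-loop minimum Hamming distance oracle (no NAs).
brute_force_min_distances <- function(A, B) {
  a <- as.matrix(as.data.frame(lapply(A$data, as.character)))
  b <- as.matrix(as.data.frame(lapply(B$data, as.character)))
  vapply(seq_len(nrow(a)), function(i) {
    min(vapply(seq_len(nrow(b)), function(j) sum(a[i, ] != b[j, ]), numeric(1)))
  }, numeric(1))
}
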