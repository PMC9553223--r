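#' Matching configuration
#'
#' @param h Non-negative integer Hamming distance threshold; an attack record
#'   is declared a match when its minimum distance to the synthetic table is
#'   at most `h`. Default 5, a value in the range commonly used for
#'   membership attacks on discretized health records.
#' @return A `match_config`.
#' @export
match_config <- function(h = 5L) {
  h <- as.integer(h)
  if (is.na(h) || h < 0L) stop("`h` must be a non-negative integer", call. = FALSE)
  structure(list(h = h), class = "match_config")
}

#' Hamming distance between two records
#'
#' Counts the attribute positions at which two records differ. Records must
#' be discretized (no raw numeric/date columns) so that equality is
#' meaningful. Missing values are a category of their own: two missing
#' values agree, a missing value differs from any observed one.
#'
#' @param y,y_prime Records: named character vectors or single-row
#'   data.frames over the same columns.
#' @param schema Optional `table_schema`; when given, both records must
#'   cover exactly its columns.
#' @return Integer distance.
#' @export
hamming_distance <- function(y, y_prime, schema = NULL) {
  y <- unlist_record(y); y_prime <- unlist_record(y_prime)
  if (!is.null(schema)) {
    nms <- schema_names(schema)
    if (!setequal(names(y), nms) || !setequal(names(y_prime), nms)) {
      stop("records do not conform to the schema", call. = FALSE)
    }
    y <- y[nms]; y_prime <- y_prime[nms]
  } else if (length(y) != length(y_prime)) {
    stop("records have different numbers of attributes", call. = FALSE)
  }
  agree <- (!is.na(y) & !is.na(y_prime) & y == y_prime) | (is.na(y) & is.na(y_prime))
  sum(!agree)
}

unlist_record <- function(y) {
  if (is.data.frame(y)) {
    stopifnot(nrow(y) == 1L)
    y <- vapply(y, function(v) as.character(v[1L]), character(1L))
  }
  out <- as.character(y)
  names(out) <- names(y)
  out
}

# Integer-code a pair of discretized tables over shared columns.
# NA becomes its own code so missing matches only missing.
code_tables <- function(a, b) {
  stopifnot(identical(schema_names(a$schema), schema_names(b$schema)))
  d <- length(a$schema)
  A <- matrix(0L, nrow(a$data), d); B <- matrix(0L, nrow(b$data), d)
  for (j in seq_len(d)) {
    xa <- as.character(a$data[[j]]); xb <- as.character(b$data[[j]])
    lev <- unique(c(xa, xb))
    A[, j] <- match(xa, lev)
    B[, j] <- match(xb, lev)
  }
  list(A = A, B = B)
}

# Minimum Hamming distance of every row of A to the rows of B
# (integer-coded matrices), blockwise; exactly equivalent to the
# double loop over record pairs.
min_hamming_codes <- function(A, B, block = 256L) {
  nA <- nrow(A); d <- ncol(A)
  out <- integer(nA)
  for (start in seq(1L, nA, by = block)) {
    idx <- start:min(start + block - 1L, nA)
    D <- matrix(0L, length(idx), nrow(B))
    for (j in seq_len(d)) {
      D <- D + outer(A[idx, j], B[, j], "!=")
    }
    out[idx] <- D[cbind(seq_along(idx), max.col(-D, ties.method = "first"))]
  }
  out
}

check_discretized_pair <- function(x, synthetic) {
  if (has_continuous_columns(x) || has_continuous_columns(synthetic)) {
    stop("tables contain raw numeric/date columns; discretize() them first ",
         "(with shared cut-points) before matching", call. = FALSE)
  }
  if (!identical(schema_names(x$schema), schema_names(synthetic$schema))) {
    stop("attack and synthetic tables must share the same schema columns, in order",
         call. = FALSE)
  }
}

#' Minimum Hamming distance from a record to a synthetic table
#'
#' @param y A record (named character vector or one-row data.frame).
#' @param synthetic A non-empty, discretized `record_table`.
#' @return The minimum distance over all synthetic rows.
#' @export
min_distance_to_synthetic <- function(y, synthetic) {
  stopifnot(inherits(synthetic, "record_table"))
  if (nrow(synthetic$data) == 0L) stop("synthetic table is empty", call. = FALSE)
  if (has_continuous_columns(synthetic)) {
    stop("synthetic table must be discretized before matching", call. = FALSE)
  }
  y <- unlist_record(y)
  nms <- schema_names(synthetic$schema)
  if (!setequal(names(y), nms)) stop("record does not conform to the synthetic schema", call. = FALSE)
  y <- y[nms]
  agree <- matrix(FALSE, nrow(synthetic$data), length(nms))
  for (j in seq_along(nms)) {
    xb <- as.character(synthetic$data[[j]])
    agree[, j] <- (!is.na(xb) & !is.na(y[j]) & xb == y[j]) | (is.na(xb) & is.na(y[j]))
  }
  min(length(nms) - rowSums(agree))
}

#' Match an attack set against a synthetic table
#'
#' Computes, for every attack record, the minimum Hamming distance to the
#' synthetic table and flags a match when that distance is at most the
#' threshold `h`. Membership labels on the attack set are bookkeeping for
#' later scoring; the matcher never sees them.
#'
#' @param attack An [attack_set()] or a `record_table`.
#' @param synthetic A non-empty, discretized `record_table` with the same
#'   schema columns.
#' @param config A [match_config()].
#' @return A `match_outcome` data.frame with one row per attack record, in
#'   attack order: `min_distance` (integer) and `matched` (logical).
#' @export
match_attack_set <- function(attack, synthetic, config = match_config()) {
  records <- if (inherits(attack, "attack_set")) attack$records else attack
  stopifnot(inherits(records, "record_table"), inherits(synthetic, "record_table"))
  if (nrow(synthetic$data) == 0L) stop("synthetic table is empty", call. = FALSE)
  check_discretized_pair(records, synthetic)
  d <- length(records$schema)
  if (config$h > d) {
    stop(sprintf("threshold h = %d exceeds the number of attribute columns (%d)",
                 config$h, d), call. = FALSE)
  }
  cd <- code_tables(records, synthetic)
  md <- min_hamming_codes(cd$A, cd$B)
  structure(data.frame(min_distance = md, matched = md <= config$h),
            class = c("match_outcome", "data.frame"))
}
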