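#' Column schema for a record table
#'
#' Declares the name, kind and (for continuous kinds) the discretization bin
#' count of a single attribute column. `kind` determines how values are parsed
#' from CSV and whether the column is quantile-binned before Hamming matching.
#'
#' @param name Column name (unique within a table schema).
#' @param kind One of `"categorical"`, `"ordinal"`, `"numeric"`, `"date"`.
#' @param bins Positive integer number of quantile bins; used only when
#'   `kind` is `"numeric"` or `"date"` (default 20), ignored otherwise.
#' @return A `column_schema` object (named list).
#' @seealso [table_schema()], [record_table()]
#' @export
column_schema <- function(name, kind = c("categorical", "ordinal", "numeric", "date"),
                          bins = 20L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind %in% c("numeric", "date")) {
    bins <- as.integer(bins)
    if (is.na(bins) || bins < 2L) {
      stop("`bins` must be an integer >= 2 for numeric/date columns", call. = FALSE)
    }
  } else {
    bins <- NA_integer_
  }
  structure(list(name = name, kind = kind, bins = bins), class = "column_schema")
}

#' Assemble a table schema from column declarations
#'
#' @param ... `column_schema` objects (or lists coercible to them).
#' @return A `table_schema`: a list of `column_schema` with unique names.
#' @export
table_schema <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1L]]) && !inherits(cols[[1L]], "column_schema")) {
    cols <- cols[[1L]]
  }
  cols <- lapply(cols, function(x) {
    if (inherits(x, "column_schema")) x else do.call(column_schema, x)
  })
  nms <- vapply(cols, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate column names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  structure(cols, class = "table_schema")
}

schema_names <- function(schema) vapply(schema, `[[`, character(1L), "name")
schema_kinds <- function(schema) vapply(schema, `[[`, character(1L), "kind")
schema_bins  <- function(schema) vapply(schema, `[[`, integer(1L), "bins")

#' Typed tabular microdata
#'
#' The container used for all table roles in a disclosure assessment: the
#' population P, the real dataset R, the synthetic dataset S and the attack
#' dataset D. Values are stored per declared kind (character for
#' categorical/ordinal, numeric for numeric, `Date` for date). Optional row
#' identifiers track individual identity through sampling; they are
#' bookkeeping only and never take part in distance computations.
#'
#' @param data A data.frame with one column per schema entry.
#' @param schema A `table_schema` (or list of column declarations).
#' @param ids Optional vector of unique per-row identifiers.
#' @return A `record_table`.
#' @export
record_table <- function(data, schema, ids = NULL) {
  if (!inherits(schema, "table_schema")) schema <- table_schema(schema)
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols)) {
    stop("columns declared in schema but absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)[, nms, drop = FALSE]
  for (i in seq_along(schema)) {
    data[[i]] <- coerce_column(data[[i]], schema[[i]])
  }
  if (!is.null(ids)) {
    if (length(ids) != nrow(data)) stop("`ids` length must equal the row count", call. = FALSE)
    if (anyDuplicated(ids)) stop("row identifiers must be unique", call. = FALSE)
    ids <- as.character(ids)
  }
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, ids = ids), class = "record_table")
}

coerce_column <- function(x, col) {
  switch(col$kind,
    categorical = ,
    ordinal = {
      x <- as.character(x)
      x[!is.na(x) & x == ""] <- NA_character_
      x
    },
    numeric = {
      if (is.numeric(x)) return(as.numeric(x))
      xc <- trimws(as.character(x))
      xc[xc == ""] <- NA
      out <- suppressWarnings(as.numeric(xc))
      bad <- which(!is.na(xc) & is.na(out))
      if (length(bad)) {
        stop(sprintf("cannot parse value '%s' in column '%s' (row %d) as numeric",
                     xc[bad[1L]], col$name, bad[1L]), call. = FALSE)
      }
      out
    },
    date = {
      if (inherits(x, "Date")) return(x)
      xc <- trimws(as.character(x))
      xc[xc == ""] <- NA
      out <- as.Date(xc, format = "%Y-%m-%d")
      bad <- which(!is.na(xc) & is.na(out))
      if (length(bad)) {
        stop(sprintf("cannot parse value '%s' in column '%s' (row %d) as a date (expected YYYY-MM-DD)",
                     xc[bad[1L]], col$name, bad[1L]), call. = FALSE)
      }
      out
    }
  )
}

#' @export
dim.record_table <- function(x) dim(x$data)

#' Number of records in a table
#' @param table A `record_table`.
#' @return Integer row count.
#' @export
n_records <- function(table) nrow(table$data)

#' @export
print.record_table <- function(x, ...) {
  cat(sprintf("<record_table> %d records x %d columns%s\n",
              nrow(x$data), ncol(x$data),
              if (is.null(x$ids)) "" else " (with ids)"))
  kinds <- schema_kinds(x$schema)
  cat("  columns: ",
      paste(sprintf("%s[%s]", schema_names(x$schema), substr(kinds, 1, 3)), collapse = " "),
      "\n", sep = "")
  print(utils::head(x$data, 5L))
  if (nrow(x$data) > 5L) cat(sprintf("  ... %d more rows\n", nrow(x$data) - 5L))
  invisible(x)
}

#' Subset the rows of a record table
#'
#' Keeps schema, discretization state and (subset) ids.
#' @param table A `record_table`.
#' @param i Row index vector.
#' @return A `record_table` with the selected rows, in the given order.
#' @export
subset_rows <- function(table, i) {
  out <- table
  out$data <- table$data[i, , drop = FALSE]
  rownames(out$data) <- NULL
  if (!is.null(table$ids)) out$ids <- table$ids[i]
  out
}

#' Drop row identifiers from a table
#'
#' Used before handing a table to a synthesizer: generated data must never
#' carry training identifiers.
#' @param table A `record_table`.
#' @return The table with `ids = NULL`.
#' @export
drop_ids <- function(table) { table$ids <- NULL; table }

#' Read a CSV file into a record table
#'
#' Expects an RFC-4180 style CSV (comma separated, header row, UTF-8, quoted
#' fields allowed). Values are parsed according to the declared schema; an
#' optional identifier column is split off into `ids` and removed from the
#' attribute columns.
#'
#' @param path Path to the CSV file.
#' @param schema A `table_schema` describing the attribute columns.
#' @param id_column Optional name of the identifier column in the file.
#' @return A `record_table`.
#' @export
read_table <- function(path, schema, id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!inherits(schema, "table_schema")) schema <- table_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  needed <- schema_names(schema)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("CSV is missing declared column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(raw)) {
      stop("CSV is missing the id column '", id_column, "'", call. = FALSE)
    }
    ids <- raw[[id_column]]
  }
  record_table(raw[, needed, drop = FALSE], schema, ids = ids)
}

#' Write a record table to CSV
#'
#' Inverse of [read_table()]: row order, ids and column order survive a
#' round trip.
#'
#' @param table A `record_table`.
#' @param path Output CSV path.
#' @param id_column Name for the identifier column when the table has ids.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, id_column = "id") {
  out <- table$data
  for (j in seq_along(out)) {
    if (inherits(out[[j]], "Date")) out[[j]] <- format(out[[j]], "%Y-%m-%d")
  }
  if (!is.null(table$ids)) {
    out <- cbind(stats::setNames(data.frame(table$ids, stringsAsFactors = FALSE), id_column), out)
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a schema declaration from a JSON sidecar
#'
#' The sidecar is an array of objects with fields `name`, `kind` and
#' optionally `bins`.
#' @param path Path to the JSON file.
#' @return A `table_schema`.
#' @export
read_schema <- function(path) {
  decl <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  table_schema(lapply(decl, function(d) {
    column_schema(d$name, d$kind, bins = if (is.null(d$bins)) 20L else d$bins)
  }))
}

#' Write a schema declaration to JSON
#' @param schema A `table_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  decl <- lapply(schema, function(col) {
    d <- list(name = col$name, kind = col$kind)
    if (!is.na(col$bins)) d$bins <- col$bins
    d
  })
  jsonlite::write_json(decl, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
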