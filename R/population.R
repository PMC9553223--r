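#' Specification of a synthetic validation population
#'
#' Describes a health-record-like population table used to validate the
#' disclosure estimator with no external data: a list of categorical and
#' numeric columns generated along a Markov chain in column order. With
#' probability `dependency_strength` a column's value is drawn from a
#' conditional distribution given the previous column (a coupling that gives
#' sequential trees structure to learn); otherwise from its marginal.
#'
#' @param N Population size (rows), `N >= 1`.
#' @param columns List of column descriptions: for categoricals
#'   `list(name=, kind="categorical", cardinality=)` with cardinality >= 2;
#'   for numerics `list(name=, kind="numeric", family=)` with family one of
#'   `"normal"`, `"lognormal"`, `"uniform"`, and optional `bins` (default 20).
#' @param dependency_strength Mixing weight in `[0, 1]` for the Markov
#'   coupling between adjacent columns; 0 gives fully independent columns.
#' @param seed Integer seed; identical specs generate identical tables.
#' @return A `population_spec`.
#' @export
population_spec <- function(N, columns, dependency_strength = 0.5, seed = 1L) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("`N` must be a positive integer", call. = FALSE)
  if (dependency_strength < 0 || dependency_strength > 1) {
    stop("`dependency_strength` must lie in [0, 1]", call. = FALSE)
  }
  if (!length(columns)) stop("at least one column is required", call. = FALSE)
  for (col in columns) {
    if (is.null(col$name) || is.null(col$kind)) {
      stop("every column needs `name` and `kind`", call. = FALSE)
    }
    if (col$kind == "categorical" && (is.null(col$cardinality) || col$cardinality < 2)) {
      stop("categorical columns need `cardinality` >= 2", call. = FALSE)
    }
    if (col$kind == "numeric" &&
        (is.null(col$family) || !col$family %in% c("normal", "lognormal", "uniform"))) {
      stop("numeric columns need `family` in {normal, lognormal, uniform}", call. = FALSE)
    }
  }
  structure(list(N = N, columns = columns,
                 dependency_strength = dependency_strength, seed = as.integer(seed)),
            class = "population_spec")
}

#' Default validation population
#'
#' An 8-column mixed-cardinality health-record-like population at the scale
#' of the smallest validated study condition: N = 20,000 with a real-dataset
#' size of 2,000 giving a sampling fraction n/N = 0.1, inside the 0.039-0.5
#' range spanned by realistic population/sample configurations. Seven
#' categorical columns (cardinalities 2-10) plus one lognormal length-of-stay
#' column discretized to 20 bins.
#'
#' @param N Population size (default 20000).
#' @param dependency_strength Markov coupling weight (default 0.5).
#' @param seed Integer seed.
#' @return A `population_spec`.
#' @export
default_population_spec <- function(N = 20000L, dependency_strength = 0.5, seed = 1L) {
  population_spec(
    N = N,
    columns = list(
      list(name = "sex",          kind = "categorical", cardinality = 2L),
      list(name = "age_group",    kind = "categorical", cardinality = 8L),
      list(name = "region",       kind = "categorical", cardinality = 10L),
      list(name = "exposure",     kind = "categorical", cardinality = 4L),
      list(name = "case_status",  kind = "categorical", cardinality = 3L),
      list(name = "comorbidity",  kind = "categorical", cardinality = 5L),
      list(name = "income_band",  kind = "categorical", cardinality = 6L),
      list(name = "length_of_stay", kind = "numeric", family = "lognormal", bins = 20L)
    ),
    dependency_strength = dependency_strength, seed = seed)
}

# integer code (1..10) of a generated column, for the Markov coupling
column_code <- function(x) {
  if (is.numeric(x)) {
    q <- stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1), type = 7)
    findInterval(x, unique(q)) + 1L
  } else {
    as.integer(sub("^v", "", x))
  }
}

#' Generate a synthetic population table
#'
#' Produces exactly `spec$N` rows with unique sequential ids. Categorical
#' column j is sampled, per record, from a conditional distribution given
#' column j-1 with probability `dependency_strength` (a preferred level
#' determined by the previous value, drawn with probability 0.7, otherwise
#' the marginal) and from its marginal otherwise. Numeric columns receive a
#' location shift driven by the previous column's code when the coupling
#' fires.
#'
#' @param spec A [population_spec()].
#' @return A `record_table` with ids `"1" ... "N"`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  N <- spec$N; ds <- spec$dependency_strength
  cols <- spec$columns
  data <- vector("list", length(cols))
  schema_cols <- vector("list", length(cols))
  with_seed(spec$seed, {
    prev_code <- NULL
    for (j in seq_along(cols)) {
      col <- cols[[j]]
      if (col$kind == "categorical") {
        K <- as.integer(col$cardinality)
        marg <- stats::runif(K, 0.5, 1.5); marg <- marg / sum(marg)
        base <- sample.int(K, N, replace = TRUE, prob = marg)
        if (!is.null(prev_code) && ds > 0) {
          pref <- ((prev_code - 1L) %% K) + 1L
          alt <- sample.int(K, N, replace = TRUE, prob = marg)
          dep <- ifelse(stats::runif(N) < 0.7, pref, alt)
          x <- ifelse(stats::runif(N) < ds, dep, base)
        } else {
          x <- base
        }
        data[[j]] <- paste0("v", x)
        schema_cols[[j]] <- column_schema(col$name, "categorical")
      } else {
        base <- switch(col$family,
          normal = stats::rnorm(N, mean = 50, sd = 10),
          lognormal = stats::rlnorm(N, meanlog = 1.2, sdlog = 0.6),
          uniform = stats::runif(N, 0, 100))
        if (!is.null(prev_code) && ds > 0) {
          shift <- (prev_code - mean(prev_code)) * stats::sd(base) / 2
          x <- ifelse(stats::runif(N) < ds, base + shift, base)
        } else {
          x <- base
        }
        data[[j]] <- x
        bins <- if (is.null(col$bins)) 20L else as.integer(col$bins)
        schema_cols[[j]] <- column_schema(col$name, "numeric", bins = bins)
      }
      prev_code <- column_code(data[[j]])
    }
  })
  names(data) <- vapply(cols, `[[`, character(1L), "name")
  record_table(as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE),
               table_schema(schema_cols), ids = as.character(seq_len(N)))
}

#' Fraction of records with a unique attribute pattern
#'
#' The share of rows whose full attribute pattern occurs exactly once in the
#' table. Pattern uniqueness controls attack difficulty: with h = 0 a copied
#' record discloses membership only if its pattern is unique in the
#' population.
#'
#' @param table A non-empty `record_table`.
#' @return Fraction in `[0, 1]`.
#' @export
pattern_uniqueness <- function(table) {
  stopifnot(inherits(table, "record_table"))
  if (nrow(table$data) == 0L) stop("table is empty", call. = FALSE)
  key <- do.call(paste, c(lapply(table$data, as.character), sep = "\r"))
  mean(!(duplicated(key) | duplicated(key, fromLast = TRUE)))
}

#' Write a population fixture to disk
#'
#' Generates the population and writes the CSV plus its JSON schema sidecar.
#'
#' @param spec A [population_spec()].
#' @param csv_path Output CSV path.
#' @param schema_path Output JSON schema path (default: CSV path with a
#'   `.schema.json` suffix).
#' @return Invisibly, the generated `record_table`.
#' @export
write_population_fixture <- function(spec, csv_path,
                                     schema_path = sub("\\.csv$", ".schema.json", csv_path)) {
  pop <- generate_population(spec)
  write_table(pop, csv_path, id_column = "id")
  write_schema(pop$schema, schema_path)
  invisible(pop)
}
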