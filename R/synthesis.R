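#' Synthesizer specification
#'
#' Configuration for the generative models available to the harness:
#' * `sequential_trees` — the sequential CART synthesizer: the first visited
#'   column is drawn from its empirical marginal, every later column from a
#'   classification tree conditioned on the previously generated columns,
#'   sampling from the empirical distribution of training values in the
#'   reached leaf. This is the synthpop-style synthesizer whose memorization
#'   behaviour a membership-disclosure metric must be able to detect.
#' * `independent_marginals` — per-column empirical marginals sampled
#'   independently; a no-dependency baseline.
#' * `copy` — returns training rows verbatim (test-only perfect-leakage
#'   bound).
#' * `sentinel` — emits a constant out-of-vocabulary row (test-only
#'   zero-leakage bound: nothing can match at h = 0).
#'
#' @param method One of `"sequential_trees"`, `"independent_marginals"`,
#'   `"copy"`, `"sentinel"`.
#' @param min_leaf Minimum records per tree leaf (default 5; small leaves
#'   reproduce the memorization behaviour of practical CART synthesis).
#' @param max_depth Maximum tree depth (default 30, rpart's ceiling).
#' @param visit_order Character vector of column names giving the synthesis
#'   order; default the schema order. Must be a permutation of the schema
#'   columns when supplied.
#' @param seed Integer seed used when fitting.
#' @return A `synthesizer_spec`.
#' @export
synthesizer_spec <- function(method = c("sequential_trees", "independent_marginals",
                                        "copy", "sentinel"),
                             min_leaf = 5L, max_depth = 30L,
                             visit_order = NULL, seed = 1L) {
  method <- match.arg(method)
  min_leaf <- as.integer(min_leaf)
  if (is.na(min_leaf) || min_leaf < 1L) stop("`min_leaf` must be a positive integer", call. = FALSE)
  max_depth <- as.integer(max_depth)
  if (is.na(max_depth) || max_depth < 1L) stop("`max_depth` must be a positive integer", call. = FALSE)
  structure(list(method = method, min_leaf = min_leaf,
                 max_depth = min(max_depth, 30L),
                 visit_order = visit_order, seed = as.integer(seed)),
            class = "synthesizer_spec")
}

NA_LEVEL <- "(missing)"

# Training data as a data.frame of factors over modeling names V1..Vd,
# in visit order; missing values become an explicit level.
model_frame <- function(table, order_idx) {
  df <- table$data[, order_idx, drop = FALSE]
  names(df) <- paste0("V", seq_along(df))
  for (j in seq_along(df)) {
    x <- as.character(df[[j]])
    x[is.na(x)] <- NA_LEVEL
    df[[j]] <- factor(x)
  }
  df
}

resolve_visit_order <- function(spec, schema) {
  nms <- schema_names(schema)
  if (is.null(spec$visit_order)) return(seq_along(nms))
  if (!setequal(spec$visit_order, nms) || length(spec$visit_order) != length(nms)) {
    stop("`visit_order` must be a permutation of the schema columns", call. = FALSE)
  }
  match(spec$visit_order, nms)
}

prepare_training <- function(training, spec) {
  stopifnot(inherits(training, "record_table"))
  if (nrow(training$data) == 0L) stop("training table is empty", call. = FALSE)
  discretize(training)
}

#' Fit the sequential tree-based synthesizer
#'
#' Column 1 (in visit order) is modeled by its empirical marginal; each
#' subsequent column by an rpart classification tree predicting it from all
#' previously visited columns, with the empirical class distribution stored
#' at every leaf. Continuous columns are quantile-binned first and the
#' cut-points kept with the model. Refitting with the same data and seed
#' yields an identical model.
#'
#' @param training A `record_table` (ids, if any, are ignored and never
#'   reproduced in generated data).
#' @param spec A [synthesizer_spec()]; its `method` field is ignored here.
#' @return A fitted `synth_model`.
#' @export
fit_sequential_trees <- function(training, spec = synthesizer_spec()) {
  training <- prepare_training(training, spec)
  order_idx <- resolve_visit_order(spec, training$schema)
  df <- model_frame(training, order_idx)
  d <- ncol(df)
  ctrl <- rpart::rpart.control(minbucket = spec$min_leaf,
                               minsplit = max(2L * spec$min_leaf, 4L),
                               cp = 1e-4, maxdepth = spec$max_depth,
                               xval = 0L, maxcompete = 0L, maxsurrogate = 0L,
                               usesurrogate = 0L)
  parts <- vector("list", d)
  with_seed(spec$seed, {
    for (j in seq_len(d)) {
      y <- droplevels(df[[j]])
      if (j == 1L || nlevels(y) < 2L) {
        tab <- table(y)
        parts[[j]] <- list(type = "marginal", levels = names(tab),
                           probs = as.numeric(tab) / sum(tab))
      } else {
        dat <- df[, seq_len(j - 1L), drop = FALSE]
        dat$.y <- y
        fit <- rpart::rpart(.y ~ ., data = dat, method = "class", control = ctrl)
        parts[[j]] <- list(type = "tree", fit = fit, levels = levels(y))
      }
    }
  })
  structure(list(method = "sequential_trees", parts = parts,
                 schema = training$schema, order_idx = order_idx,
                 cutpoints = training$cutpoints, n_training = nrow(df),
                 spec = spec),
            class = "synth_model")
}

#' Fit the independent-marginals baseline synthesizer
#'
#' Each column is modeled by its empirical marginal and sampled
#' independently of all others; inter-column dependence in the training data
#' is destroyed by construction.
#'
#' @inheritParams fit_sequential_trees
#' @return A fitted `synth_model`.
#' @export
fit_independent_marginals <- function(training, spec = synthesizer_spec("independent_marginals")) {
  training <- prepare_training(training, spec)
  order_idx <- resolve_visit_order(spec, training$schema)
  df <- model_frame(training, order_idx)
  parts <- lapply(df, function(x) {
    tab <- table(droplevels(x))
    list(type = "marginal", levels = names(tab), probs = as.numeric(tab) / sum(tab))
  })
  structure(list(method = "independent_marginals", parts = parts,
                 schema = training$schema, order_idx = order_idx,
                 cutpoints = training$cutpoints, n_training = nrow(df),
                 spec = spec),
            class = "synth_model")
}

#' Fit a synthesizer according to its spec
#'
#' Dispatches on `spec$method`; the `copy` and `sentinel` test-only methods
#' simply retain the (discretized) training table.
#'
#' @inheritParams fit_sequential_trees
#' @return A fitted `synth_model`.
#' @export
fit_synthesizer <- function(training, spec = synthesizer_spec()) {
  switch(spec$method,
    sequential_trees = fit_sequential_trees(training, spec),
    independent_marginals = fit_independent_marginals(training, spec),
    copy = ,
    sentinel = {
      training <- prepare_training(training, spec)
      structure(list(method = spec$method, table = drop_ids(training),
                     schema = training$schema,
                     order_idx = resolve_visit_order(spec, training$schema),
                     cutpoints = training$cutpoints,
                     n_training = nrow(training$data), spec = spec),
                class = "synth_model")
    })
}

#' @export
print.synth_model <- function(x, ...) {
  cat(sprintf("<synth_model> method=%s, %d columns, fitted on %d rows\n",
              x$method, length(x$schema), x$n_training))
  invisible(x)
}

# Draw one class index per row from a row-stochastic probability matrix.
sample_from_rows <- function(P) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  cs <- P
  for (k in seq_len(ncol(P))[-1L]) cs[, k] <- cs[, k - 1L] + cs[, k]
  cs[, ncol(cs)] <- 1
  u <- stats::runif(nrow(P))
  max.col(cs >= u, ties.method = "first")
}

#' Generate synthetic records from a fitted model
#'
#' Rows are produced column-by-column in the model's visit order: the first
#' column sampled from its stored marginal, each later column from the leaf
#' distribution its tree reaches given the partially generated row.
#' Generated tables carry the training schema (discretized), the training
#' cut-points, and no row identifiers.
#'
#' @param model A fitted `synth_model`.
#' @param rows Number of records to generate (positive).
#' @param seed Integer seed; identical seed and model give identical output.
#' @return A `record_table` of `rows` synthetic records.
#' @export
generate <- function(model, rows, seed = 1L) {
  stopifnot(inherits(model, "synth_model"))
  rows <- as.integer(rows)
  if (is.na(rows) || rows < 1L) stop("`rows` must be a positive integer", call. = FALSE)

  if (model$method == "copy") {
    idx <- rep_len(seq_len(nrow(model$table$data)), rows)
    return(subset_rows(model$table, idx))
  }
  if (model$method == "sentinel") {
    out <- model$table
    sent <- as.data.frame(stats::setNames(as.list(rep("##sentinel##", length(model$schema))),
                                   schema_names(model$schema)),
                          check.names = FALSE, stringsAsFactors = FALSE)
    out$data <- sent[rep(1L, rows), , drop = FALSE]
    rownames(out$data) <- NULL
    out$ids <- NULL
    return(out)
  }

  d <- length(model$parts)
  gen <- vector("list", d) # factors over modeling names V1..Vd, visit order
  with_seed(seed, {
    for (j in seq_len(d)) {
      part <- model$parts[[j]]
      if (part$type == "marginal") {
        if (length(part$levels) == 1L) {
          val <- rep(part$levels, rows)
        } else {
          val <- part$levels[sample.int(length(part$levels), rows, replace = TRUE,
                                        prob = part$probs)]
        }
        gen[[j]] <- factor(val, levels = part$levels)
      } else {
        newdata <- stats::setNames(gen[seq_len(j - 1L)], paste0("V", seq_len(j - 1L)))
        newdata <- as.data.frame(newdata)
        P <- stats::predict(part$fit, newdata = newdata, type = "prob")
        if (is.null(dim(P))) P <- matrix(P, nrow = rows, byrow = TRUE,
                                         dimnames = list(NULL, part$levels))
        idx <- sample_from_rows(P)
        gen[[j]] <- factor(colnames(P)[idx], levels = part$levels)
      }
    }
  })
  data <- vector("list", d)
  for (j in seq_len(d)) {
    x <- as.character(gen[[j]])
    x[x == NA_LEVEL] <- NA_character_
    data[[model$order_idx[j]]] <- x
  }
  names(data) <- schema_names(model$schema)
  out <- record_table(as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE),
                      model$schema)
  out$cutpoints <- model$cutpoints
  out
}
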