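#' Assess the membership disclosure risk of a real/synthetic pair
#'
#' The data-custodian workflow, run before a synthetic dataset is released:
#' the real dataset is split into training and holdout halves, an attack set
#' of `m` records is composed with a fraction `t` from the training half
#' (default `t = n/N`, the composition an adversary sampling from the
#' population would actually obtain), the attack set is matched against the
#' supplied synthetic table at Hamming threshold `h`, and the resulting F1
#' is corrected by the naive baseline `Fmax(n, N)` into the M score with its
#' acceptability verdict (`M <= 0.2` by default).
#'
#' Continuous columns are quantile-binned with cut-points learned from the
#' synthetic table (the reference frame of the assessment) and applied to
#' the real data, so both sides land in identical bins.
#'
#' A population size `N` is required: the real dataset is a sample from some
#' population, and `Fmax` and `t` both depend on the sampling fraction. If N
#' is underestimated the risk is overestimated, so when in doubt a smaller
#' (more conservative) N is preferable.
#'
#' Two ways to supply the synthetic side:
#' * `synthetic` — a synthetic table produced elsewhere. The partitioning
#'   estimator assumes the synthetic data was generated from the training
#'   half of the split; a synthetic table trained on the *full* real dataset
#'   is matched by holdout records too, which drives the estimate toward the
#'   naive ceiling (M near 0) rather than above it.
#' * `synthesizer` — a [synthesizer_spec()]; the full estimation procedure
#'   is then run internally: the training half is synthesized and the attack
#'   is matched against that output. This is the recommended path when the
#'   generative method is available to the custodian.
#'
#' @param real The real dataset: a `record_table`, or a CSV path (then
#'   `schema` is required).
#' @param synthetic The synthetic dataset: a `record_table` or CSV path,
#'   same schema columns as `real`. Exactly one of `synthetic` and
#'   `synthesizer` must be given.
#' @param synthesizer Optional [synthesizer_spec()] fit on the training half.
#' @param N Population size, `N >=` number of real records.
#' @param schema A `table_schema` (or JSON sidecar path) used when `real` /
#'   `synthetic` are CSV paths.
#' @param t Attack-set training fraction; default `n/N`.
#' @param h Hamming distance threshold (default 5).
#' @param m Requested attack-set size (default 1000); shrunk with a message
#'   if the training/holdout halves cannot supply it at the given t.
#' @param holdout_fraction Fraction of the real data held out (default 0.5).
#' @param seed Integer seed for the split and the attack draw.
#' @param threshold M acceptability threshold (default [M_THRESHOLD]).
#' @param id_column Optional id column name when reading CSVs.
#' @return An `assessment_report`.
#' @export
assess <- function(real, synthetic = NULL, N, schema = NULL, t = NULL, h = 5L,
                   m = 1000L, holdout_fraction = 0.5, seed = 1L,
                   threshold = M_THRESHOLD, id_column = NULL, synthesizer = NULL) {
  if (is.null(synthetic) == is.null(synthesizer)) {
    stop("supply exactly one of `synthetic` (a table) or `synthesizer` (a spec)",
         call. = FALSE)
  }
  if (missing(N) || is.null(N) || is.na(N)) {
    stop("a population size `N` must be supplied: the real dataset is a sample ",
         "from a population and both Fmax and t = n/N depend on N. ",
         "If N is uncertain, choose a smaller value (underestimating N ",
         "overestimates the risk, which is the conservative direction).",
         call. = FALSE)
  }
  if (is.character(schema)) schema <- read_schema(schema)
  load_tab <- function(x, what) {
    if (inherits(x, "record_table")) return(x)
    if (is.character(x)) {
      if (is.null(schema)) stop("a `schema` is required to read the ", what, " CSV", call. = FALSE)
      return(read_table(x, schema, id_column = id_column))
    }
    stop("`", what, "` must be a record_table or a CSV path", call. = FALSE)
  }
  real <- load_tab(real, "real")
  if (!is.null(synthetic)) {
    synthetic <- load_tab(synthetic, "synthetic")
    if (!identical(schema_names(real$schema), schema_names(synthetic$schema))) {
      stop("real and synthetic tables must share the same schema columns, in order",
           call. = FALSE)
    }
  }
  n <- nrow(real$data)
  N <- as.integer(N)
  if (N < n) stop(sprintf("N (%d) must be at least the real dataset size (%d)", N, n),
                  call. = FALSE)
  if (is.null(t)) t <- n / N
  if (t < 0 || t > 1) stop("`t` must lie in [0, 1]", call. = FALSE)

  if (!is.null(synthetic)) {
    # the provided synthetic table is the reference frame for binning
    syn_d <- discretize(drop_ids(synthetic))
    real_d <- discretize(real, cutpoints = syn_d$cutpoints)
  } else {
    real_d <- discretize(real)
  }
  if (is.null(real_d$ids)) real_d$ids <- as.character(seq_len(n))

  parts <- split_real(real_d, holdout_fraction, seed = derive_seed(seed, 1L))
  if (is.null(synthetic)) {
    spec <- synthesizer
    spec$seed <- derive_seed(seed, 3L)
    model <- fit_synthesizer(drop_ids(parts$training), spec)
    syn_d <- generate(model, nrow(parts$training$data), seed = derive_seed(seed, 4L))
  }
  n_train <- nrow(parts$training$data); n_hold <- nrow(parts$holdout$data)
  m_feasible <- min(
    if (t > 0) floor(n_train / t) else Inf,
    if (t < 1) floor(n_hold / (1 - t)) else Inf,
    n)
  m_used <- as.integer(min(m, m_feasible))
  if (m_used < m) {
    message(sprintf("attack-set size reduced from %d to %d to fit the training/holdout sizes at t = %.4f",
                    as.integer(m), m_used, t))
  }
  design <- sampling_design(n, N, m = m_used, t = t,
                            holdout_fraction = holdout_fraction,
                            seed = derive_seed(seed, 2L))
  attack <- build_partition_attack(parts$training, parts$holdout, design)
  outcome <- match_attack_set(attack, syn_d, match_config(h))
  score <- suppressWarnings(score_attack(outcome, attack, design, threshold = threshold))

  structure(list(
    n = n, N = N, m = m_used, t = t, h = as.integer(h),
    holdout_fraction = holdout_fraction, seed = as.integer(seed),
    threshold = threshold,
    precision = score$precision, recall = score$recall, f1 = score$f1,
    f_max = score$f_max, m_score = score$m_score, acceptable = score$acceptable,
    match_rate = mean(outcome$matched),
    tool_version = as.character(utils::packageVersion("memdisc"))),
    class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Membership disclosure assessment (partitioning method)\n")
  cat(sprintf("  inputs: n = %d, N = %d (n/N = %.4f), m = %d, t = %.4f, h = %d, seed = %d\n",
              x$n, x$N, x$n / x$N, x$m, x$t, x$h, x$seed))
  cat(sprintf("  matched %.1f%% of attack records\n", 100 * x$match_rate))
  cat(sprintf("  precision = %.4f, recall = %.4f, F1 = %.4f, Fmax = %.4f\n",
              x$precision, x$recall, x$f1, x$f_max))
  if (is.na(x$m_score)) {
    cat("  M undefined (Fmax = 1: the real dataset is the whole population)\n")
  } else {
    cat(sprintf("  M = %.4f -> %s (threshold %.2f)\n", x$m_score,
                if (isTRUE(x$acceptable)) "acceptable risk" else "risk ABOVE threshold",
                x$threshold))
  }
  cat("  note: if N was underestimated the risk is overestimated (conservative).\n")
  invisible(x)
}

#' Write an assessment report to JSON
#'
#' @param report An `assessment_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "assessment_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run a validation simulation from a configuration
#'
#' Drives [run_partition_sweep()] and [compare_to_ground_truth()] from a
#' configuration list or JSON file and writes the tidy per-iteration CSV and
#' the JSON summary. The configuration must name its population: either
#' `population` (`csv`, `schema`, optional `id_column`) or `fixture`
#' (arguments for [default_population_spec()] / [population_spec()]).
#'
#' Recognized fields: `iterations`, `n`, `m`, `h`, `t_policy`, `t_grid`,
#' `holdout_fraction`, `master_seed`, `synthesizer` (list of
#' [synthesizer_spec()] arguments), `population`, `fixture`.
#'
#' @param config A list or path to a JSON file.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `experiment_result` and the summary.
#' @export
simulate_run <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  known <- c("iterations", "n", "m", "h", "t_policy", "t_grid", "holdout_fraction",
             "master_seed", "synthesizer", "population", "fixture")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         "; recognized fields are: ", paste(known, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$population) && is.null(config$fixture)) {
    stop("configuration must provide either `population` (csv + schema) or `fixture`",
         call. = FALSE)
  }
  if (!is.null(config$population)) {
    p <- config$population
    if (is.null(p$csv) || is.null(p$schema)) {
      stop("`population` needs fields `csv` and `schema`", call. = FALSE)
    }
    pop <- read_table(p$csv, read_schema(p$schema),
                      id_column = if (is.null(p$id_column)) NULL else p$id_column)
    if (is.null(pop$ids)) pop$ids <- as.character(seq_len(nrow(pop$data)))
  } else {
    pop <- generate_population(do.call(
      if (is.null(config$fixture$columns)) default_population_spec else population_spec,
      config$fixture))
  }
  syn_args <- if (is.null(config$synthesizer)) list() else config$synthesizer
  cfg <- experiment_config(
    iterations = config$iterations %||% 50L,
    n_values = config$n %||% 2000L,
    m = config$m %||% 1000L,
    h = config$h %||% 5L,
    t_policy = config$t_policy %||% "n_over_N",
    t_grid = config$t_grid %||% seq(0, 1, by = 0.05),
    synthesizer = do.call(synthesizer_spec, syn_args),
    holdout_fraction = config$holdout_fraction %||% 0.5,
    master_seed = config$master_seed %||% 1L)
  if (!quiet) {
    message(sprintf("simulate: N = %d, n = %s, iterations = %d, t_policy = %s, master_seed = %d (memdisc %s)",
                    nrow(pop$data), paste(cfg$n_values, collapse = "/"),
                    cfg$iterations, cfg$t_policy, cfg$master_seed,
                    as.character(utils::packageVersion("memdisc"))))
  }
  result <- run_partition_sweep(pop, cfg)
  paths <- write_experiment_result(result, out_dir)
  if (!quiet) message("wrote ", paste(paths, collapse = " and "))
  invisible(list(result = result, summary = compare_to_ground_truth(result)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
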