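#' Configuration for the estimator-validation experiment
#'
#' Describes a simulation sweep in which, per iteration, a real dataset is
#' drawn from a population, synthesized, and attacked twice: once by the
#' ground-truth adversary (attack records sampled from the population,
#' membership decided by identity) and once by the partitioning estimator
#' (real data split into training/holdout, attack set composed with training
#' fraction t). Comparing the two F1 scores across t values validates the
#' `t = n/N` parameterization.
#'
#' @param iterations Iterations per condition (default 50).
#' @param n_values Real-dataset sizes to sweep (one or more).
#' @param m Attack-set size (default 1000).
#' @param h Hamming distance threshold (default 5).
#' @param t_policy How t is chosen per iteration: `"n_over_N"` (the
#'   validated default), `"random_uniform"` (one uniform draw per
#'   iteration), or `"fixed_grid"` (every value of `t_grid` per iteration).
#' @param t_grid Grid of t values for `"fixed_grid"` (default steps of 0.05).
#' @param synthesizer A [synthesizer_spec()].
#' @param holdout_fraction Holdout fraction for the partitioning split.
#' @param master_seed Master seed; per-iteration seeds are derived from it
#'   by a fixed counter scheme, so reruns are bit-for-bit reproducible.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(iterations = 50L, n_values = 2000L, m = 1000L, h = 5L,
                              t_policy = c("n_over_N", "random_uniform", "fixed_grid"),
                              t_grid = seq(0, 1, by = 0.05),
                              synthesizer = synthesizer_spec(),
                              holdout_fraction = 0.5, master_seed = 1L) {
  t_policy <- match.arg(t_policy)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  structure(list(iterations = iterations, n_values = as.integer(n_values),
                 m = as.integer(m), h = as.integer(h),
                 t_policy = t_policy, t_grid = t_grid,
                 synthesizer = synthesizer,
                 holdout_fraction = holdout_fraction,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

stage_seed <- function(seed_i, stage) derive_seed(seed_i, stage)

# One iteration's shared state: the real draw and the ground-truth score.
run_gt_iteration <- function(pop_d, n, config, seed_i) {
  N <- nrow(pop_d$data)
  real <- draw_real_sample(pop_d, n, stage_seed(seed_i, 1L))
  spec <- config$synthesizer
  spec$seed <- stage_seed(seed_i, 2L)
  model <- fit_synthesizer(drop_ids(real), spec)
  synth <- generate(model, nrow(real$data), seed = stage_seed(seed_i, 3L))
  attack <- build_ground_truth_attack(pop_d, real$ids, config$m, stage_seed(seed_i, 4L))
  outcome <- match_attack_set(attack, synth, match_config(config$h))
  design <- sampling_design(n, N, m = config$m, t = n / N,
                            holdout_fraction = config$holdout_fraction)
  list(real = real, score = score_attack(outcome, attack, design))
}

#' Run the ground-truth membership disclosure attack
#'
#' Per iteration: draw a real dataset R of size n from the population, fit
#' the synthesizer on all of R (no split — in the ground-truth procedure the
#' full real dataset is the training data), generate |R| synthetic rows,
#' sample m attack records from the population, match at threshold h, and
#' score with membership decided by row identity.
#'
#' @param population A `record_table` with ids (discretized internally).
#' @param config An [experiment_config()].
#' @return Data frame with one row per iteration and condition:
#'   `n`, `N`, `iteration`, `seed`, `f1`, `precision`, `recall`, `m_score`.
#' @export
run_ground_truth <- function(population, config = experiment_config()) {
  pop_d <- discretize(population)
  N <- nrow(pop_d$data)
  rows <- list(); counter <- 0L
  for (n in config$n_values) {
    for (i in seq_len(config$iterations)) {
      counter <- counter + 1L
      seed_i <- derive_seed(config$master_seed, counter)
      it <- run_gt_iteration(pop_d, n, config, seed_i)
      s <- it$score
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, N = N, iteration = i, seed = seed_i,
        f1 = s$f1, precision = s$precision, recall = s$recall, m_score = s$m_score)
    }
  }
  do.call(rbind, rows)
}

iteration_ts <- function(config, n, N, seed_i) {
  switch(config$t_policy,
    n_over_N = n / N,
    random_uniform = with_seed(stage_seed(seed_i, 9L), stats::runif(1)),
    fixed_grid = config$t_grid)
}

#' Run the partitioning estimator sweep with a paired ground-truth run
#'
#' Per iteration the same real-dataset draw feeds both procedures so that
#' their difference isolates the estimator's error:
#' * ground truth — synthesizer fit on all of R, attack from the population;
#' * partitioning — R split into training and holdout, synthesizer fit on
#'   the training sample, attack sets composed at each t of the iteration's
#'   policy and matched against the training-sample synthesis.
#'
#' For efficiency the minimum Hamming distance to the synthetic table is
#' computed once per iteration for every real record and reused across t
#' values; this is exactly equivalent to matching each attack set directly,
#' because the distance depends only on the record.
#'
#' @inheritParams run_ground_truth
#' @return An `experiment_result` data.frame: one row per iteration for the
#'   ground truth (`method = "ground_truth"`, `t = NA`) and one row per
#'   iteration x t for the estimator (`method = "partition"`).
#' @export
run_partition_sweep <- function(population, config = experiment_config()) {
  pop_d <- discretize(population)
  N <- nrow(pop_d$data)
  rows <- list(); counter <- 0L
  for (n in config$n_values) {
    for (i in seq_len(config$iterations)) {
      counter <- counter + 1L
      seed_i <- derive_seed(config$master_seed, counter)
      it <- run_gt_iteration(pop_d, n, config, seed_i)
      gt <- it$score
      rows[[length(rows) + 1L]] <- data.frame(
        method = "ground_truth", n = n, N = N, iteration = i, t = NA_real_,
        n_over_N = n / N, seed = seed_i, f1 = gt$f1,
        precision = gt$precision, recall = gt$recall, m_score = gt$m_score)

      parts <- split_real(it$real, config$holdout_fraction, stage_seed(seed_i, 5L))
      spec <- config$synthesizer
      spec$seed <- stage_seed(seed_i, 6L)
      model <- fit_synthesizer(drop_ids(parts$training), spec)
      synth <- generate(model, nrow(parts$training$data), seed = stage_seed(seed_i, 7L))
      check_discretized_pair(it$real, synth)
      cd <- code_tables(it$real, synth)
      md_real <- min_hamming_codes(cd$A, cd$B)
      names(md_real) <- it$real$ids

      ts <- iteration_ts(config, n, N, seed_i)
      for (k in seq_along(ts)) {
        design <- sampling_design(n, N, m = config$m, t = ts[k],
                                  holdout_fraction = config$holdout_fraction,
                                  seed = stage_seed(seed_i, 10L + k))
        attack <- build_partition_attack(parts$training, parts$holdout, design)
        md <- unname(md_real[attack$records$ids])
        outcome <- structure(data.frame(min_distance = md, matched = md <= config$h),
                             class = c("match_outcome", "data.frame"))
        s <- suppressWarnings(score_attack(outcome, attack, design))
        rows[[length(rows) + 1L]] <- data.frame(
          method = "partition", n = n, N = N, iteration = i, t = ts[k],
          n_over_N = n / N, seed = seed_i, f1 = s$f1,
          precision = s$precision, recall = s$recall, m_score = s$m_score)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_result", "data.frame")
  out
}

#' Compare the partitioning estimator with the ground truth
#'
#' Summarizes an [run_partition_sweep()] result: mean ground-truth F1, mean
#' estimator F1 at the t closest to `n/N` and at the t closest to 0.5 (the
#' older literature default), and the absolute estimator error at `t = n/N`.
#'
#' @param result An `experiment_result`.
#' @return A list with elements `n`, `N`, `n_over_N`,
#'   `mean_ground_truth_f1`, `t_at_n_over_N`, `mean_partition_f1_at_n_over_N`,
#'   `abs_difference_at_n_over_N`, `t_at_half`, `mean_partition_f1_at_half`,
#'   `abs_difference_at_half`, and `by_t` (mean estimator F1 per t value).
#'   With several `n` conditions a list of such summaries is returned.
#' @export
compare_to_ground_truth <- function(result) {
  stopifnot(is.data.frame(result))
  if (!any(result$method == "ground_truth")) {
    stop("result contains no ground-truth rows; run run_partition_sweep()", call. = FALSE)
  }
  summaries <- lapply(split(result, result$n), function(res) {
    gt <- res[res$method == "ground_truth", ]
    pt <- res[res$method == "partition", ]
    if (!nrow(pt)) stop("result contains no partition rows", call. = FALSE)
    n <- gt$n[1L]; N <- gt$N[1L]
    by_t <- stats::aggregate(f1 ~ t, data = pt, FUN = mean)
    pick <- function(target) by_t$t[which.min(abs(by_t$t - target))]
    t_ref <- pick(n / N); t_half <- pick(0.5)
    gt_mean <- mean(gt$f1)
    ref_mean <- by_t$f1[by_t$t == t_ref][1L]
    half_mean <- by_t$f1[by_t$t == t_half][1L]
    list(n = n, N = N, n_over_N = n / N,
         mean_ground_truth_f1 = gt_mean,
         t_at_n_over_N = t_ref,
         mean_partition_f1_at_n_over_N = ref_mean,
         abs_difference_at_n_over_N = abs(ref_mean - gt_mean),
         t_at_half = t_half,
         mean_partition_f1_at_half = half_mean,
         abs_difference_at_half = abs(half_mean - gt_mean),
         by_t = by_t)
  })
  if (length(summaries) == 1L) summaries[[1L]] else summaries
}

#' Locate where the estimator's mean-F1 curve crosses the ground truth
#'
#' On a fixed-grid sweep, linearly interpolates the per-t mean estimator F1
#' curve and returns the t at which it first crosses the mean ground-truth
#' F1. The validated parameterization predicts this crossing at `t = n/N`.
#'
#' @param result An `experiment_result` for a single `n` condition.
#' @return The interpolated crossing t, or `NA` if the curve never crosses.
#' @export
crossing_t <- function(result) {
  gt <- result[result$method == "ground_truth", ]
  pt <- result[result$method == "partition", ]
  if (!nrow(gt) || !nrow(pt)) stop("need both ground-truth and partition rows", call. = FALSE)
  if (length(unique(pt$n)) != 1L) stop("crossing_t expects a single n condition", call. = FALSE)
  target <- mean(gt$f1)
  by_t <- stats::aggregate(f1 ~ t, data = pt, FUN = mean)
  by_t <- by_t[order(by_t$t), ]
  diffs <- by_t$f1 - target
  if (any(diffs == 0)) return(by_t$t[which(diffs == 0)[1L]])
  sgn <- sign(diffs)
  flip <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (!length(flip)) return(NA_real_)
  k <- flip[1L]
  t0 <- by_t$t[k]; t1 <- by_t$t[k + 1L]
  d0 <- diffs[k]; d1 <- diffs[k + 1L]
  t0 + (t1 - t0) * (0 - d0) / (d1 - d0)
}

#' Write experiment results to disk
#'
#' Writes the tidy per-iteration table as CSV and the
#' [compare_to_ground_truth()] summary as JSON.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_experiment_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "experiment_result.csv")
  utils::write.csv(result, csv, row.names = FALSE)
  summ <- compare_to_ground_truth(result)
  json <- file.path(dir, "experiment_summary.json")
  jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(c(csv = csv, json = json))
}
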