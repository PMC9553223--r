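#' Sampling design for a membership disclosure assessment
#'
#' Captures the sizes that govern the attack: population size `N`, real
#' dataset size `n`, attack dataset size `m`, and the composition parameter
#' `t` — the proportion of attack records drawn from the synthesis-training
#' sample in the partitioning estimator. The validated choice is
#' `t = n/N` (the default here): an adversary sampling targets from the
#' population can expect exactly that fraction of them to be in the real
#' dataset. `t = 0.5`, the older literature default, is available for
#' comparison runs.
#'
#' @param n Real-dataset size.
#' @param N Population size (`n <= N`).
#' @param m Attack-set size (default 1000). Overridden by `s` when given.
#' @param t Training fraction of the attack set in `[0, 1]`; default `n/N`.
#' @param s Optional sampling fraction; when supplied, `m = round(s * n)`.
#' @param holdout_fraction Fraction of the real dataset held out of
#'   synthesis training in the partitioning estimator, in `(0, 1)`;
#'   default 0.5.
#' @param seed Integer seed for the attack-set draw.
#' @return A `sampling_design`.
#' @export
sampling_design <- function(n, N, m = 1000L, t = n / N, s = NULL,
                            holdout_fraction = 0.5, seed = 1L) {
  n <- as.integer(n); N <- as.integer(N)
  if (is.na(n) || is.na(N) || n < 1L || n > N) stop("need 1 <= n <= N", call. = FALSE)
  if (!is.null(s)) {
    if (s <= 0) stop("`s` must be positive", call. = FALSE)
    m <- round_half_away(s * n)
  }
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer", call. = FALSE)
  if (is.na(t) || t < 0 || t > 1) stop("`t` must lie in [0, 1]", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("`holdout_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n = n, N = N, m = m, t = t, s = s,
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "sampling_design")
}

#' Attack dataset with ground-truth membership labels
#'
#' Pairs attack records with the boolean bookkeeping label "is this record
#' in the dataset used to train the generative model". Labels exist so the
#' attack can be *scored*; the matcher never reads them.
#'
#' @param records A `record_table` of attack records.
#' @param member Logical vector, one label per record.
#' @return An `attack_set`.
#' @export
attack_set <- function(records, member) {
  stopifnot(inherits(records, "record_table"))
  member <- as.logical(member)
  if (length(member) != nrow(records$data)) {
    stop("one membership label per attack record is required", call. = FALSE)
  }
  structure(list(records = records, member = member), class = "attack_set")
}

#' @export
print.attack_set <- function(x, ...) {
  cat(sprintf("<attack_set> %d records, %d members (%.1f%%)\n",
              length(x$member), sum(x$member), 100 * mean(x$member)))
  invisible(x)
}

#' Write an attack set to CSV for audit
#'
#' Emits the attack records plus a `member` column with the ground-truth
#' labels.
#' @param attack An `attack_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attack_set <- function(attack, path) {
  out <- attack$records$data
  out$member <- attack$member
  if (!is.null(attack$records$ids)) out <- cbind(id = attack$records$ids, out)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Draw a real dataset from the population
#'
#' Simple random sample of `n` rows without replacement; identifiers are
#' retained so membership can later be decided by identity, never by
#' attribute equality (two distinct individuals may share a pattern).
#'
#' @param population A `record_table` with ids.
#' @param n Sample size, `1 <= n <= N`.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A `record_table` of `n` rows.
#' @export
draw_real_sample <- function(population, n, seed) {
  stopifnot(inherits(population, "record_table"))
  if (is.null(population$ids)) stop("population must carry row ids", call. = FALSE)
  N <- nrow(population$data)
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > N) stop("need 1 <= n <= N", call. = FALSE)
  idx <- with_seed(seed, sample.int(N, n))
  subset_rows(population, idx)
}

#' Split the real dataset into training and holdout samples
#'
#' Random, disjoint, exhaustive partition. The training sample is what the
#' generative model is fit on; the holdout supplies known non-member records
#' for the partitioning attack set. The training size is
#' `round((1 - holdout_fraction) * n)`, rounding halves away from zero.
#'
#' @param real A `record_table` with at least 2 rows.
#' @param holdout_fraction Fraction in `(0, 1)` (default 0.5).
#' @param seed Integer seed.
#' @return List with `record_table`s `training` and `holdout`.
#' @export
split_real <- function(real, holdout_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(real, "record_table"))
  n <- nrow(real$data)
  if (n < 2L) stop("real dataset must have at least 2 rows to split", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("`holdout_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_train <- as.integer(round_half_away((1 - holdout_fraction) * n))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  list(training = subset_rows(real, perm[seq_len(n_train)]),
       holdout  = subset_rows(real, perm[(n_train + 1L):n]))
}

#' Build the partitioning attack set
#'
#' Composes an attack set of exactly `m` records: `round(m * t)` sampled
#' without replacement from the training sample (labelled members) and the
#' remainder from the holdout sample (labelled non-members), then shuffled.
#'
#' @param training,holdout `record_table`s from [split_real()].
#' @param design A [sampling_design()] supplying `m`, `t` and the seed.
#' @return An [attack_set()] with exactly `round(m*t)` member labels.
#' @export
build_partition_attack <- function(training, holdout, design) {
  stopifnot(inherits(design, "sampling_design"))
  m <- design$m
  k_train <- as.integer(round_half_away(m * design$t))
  k_hold <- m - k_train
  if (k_train > nrow(training$data)) {
    stop(sprintf("training sample too small: need %d attack records from %d training rows",
                 k_train, nrow(training$data)), call. = FALSE)
  }
  if (k_hold > nrow(holdout$data)) {
    stop(sprintf("holdout sample too small: need %d attack records from %d holdout rows",
                 k_hold, nrow(holdout$data)), call. = FALSE)
  }
  with_seed(design$seed, {
    i_train <- if (k_train > 0L) sample.int(nrow(training$data), k_train) else integer(0)
    i_hold <- if (k_hold > 0L) sample.int(nrow(holdout$data), k_hold) else integer(0)
    parts_member <- c(rep(TRUE, k_train), rep(FALSE, k_hold))
    shuffle <- sample.int(m)
    rec <- bind_record_tables(subset_rows(training, i_train), subset_rows(holdout, i_hold))
    attack_set(subset_rows(rec, shuffle), parts_member[shuffle])
  })
}

bind_record_tables <- function(a, b) {
  stopifnot(identical(schema_names(a$schema), schema_names(b$schema)))
  ids <- if (!is.null(a$ids) && !is.null(b$ids)) c(a$ids, b$ids) else NULL
  out <- a
  out$data <- rbind(a$data, b$data)
  rownames(out$data) <- NULL
  out$ids <- ids
  out
}

#' Build the ground-truth attack set
#'
#' The adversary's view: `m` records sampled without replacement from the
#' population, labelled member when their identifier belongs to the real
#' dataset. In this ground-truth procedure the full real dataset is the
#' synthesis-training data (there is no split), so the member count is
#' hypergeometric with mean `m*n/N`.
#'
#' @param population A `record_table` with ids.
#' @param real_ids Identifiers of the real-dataset rows (subset of the
#'   population ids).
#' @param m Attack-set size, `m <= N`.
#' @param seed Integer seed.
#' @return An [attack_set()].
#' @export
build_ground_truth_attack <- function(population, real_ids, m, seed) {
  stopifnot(inherits(population, "record_table"))
  if (is.null(population$ids)) stop("population must carry row ids", call. = FALSE)
  N <- nrow(population$data)
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > N) stop("need 1 <= m <= N", call. = FALSE)
  real_ids <- as.character(real_ids)
  if (!all(real_ids %in% population$ids)) {
    stop("`real_ids` must be a subset of the population ids", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(N, m))
  rec <- subset_rows(population, idx)
  attack_set(rec, rec$ids %in% real_ids)
}

#' Score a matched attack set
#'
#' Counts true positives (matched AND member), computes precision over the
#' matched records and recall over the members, combines them into F1, and
#' corrects by the naive baseline `Fmax(n, N)` from the design to obtain M
#' and the acceptability verdict. Precision is 0 when nothing matched;
#' recall is 0 (with a warning) when the attack set contains no members.
#'
#' @param outcome A `match_outcome` from [match_attack_set()], aligned to
#'   the attack records.
#' @param attack The [attack_set()] that was matched.
#' @param design The [sampling_design()] supplying `n` and `N`.
#' @param threshold M acceptability threshold (default [M_THRESHOLD]).
#' @return A `disclosure_score`.
#' @export
score_attack <- function(outcome, attack, design, threshold = M_THRESHOLD) {
  stopifnot(inherits(attack, "attack_set"), inherits(design, "sampling_design"))
  if (nrow(outcome) != length(attack$member)) {
    stop("match outcome is not aligned to the attack set", call. = FALSE)
  }
  matched <- outcome$matched
  member <- attack$member
  tp <- sum(matched & member)
  precision <- if (any(matched)) tp / sum(matched) else 0
  if (!any(member)) {
    warning("attack set contains no training members; recall defined as 0", call. = FALSE)
    recall <- 0
  } else {
    recall <- tp / sum(member)
  }
  disclosure_score(precision, recall, design$n, design$N, threshold = threshold)
}
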