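#' Harmonic-mean F1 score
#'
#' Combines an attack's precision and recall into the single score used for
#' membership disclosure decisions: `2*p*r/(p + r)`. When both precision and
#' recall are 0 the score is defined as 0 (no matches means no disclosure
#' signal).
#'
#' @param precision Fraction in `[0, 1]`.
#' @param recall Fraction in `[0, 1]`.
#' @return The F1 score in `[0, 1]`. Vectorized.
#' @export
f1_score <- function(precision, recall) {
  check_fraction(precision, "precision")
  check_fraction(recall, "recall")
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / ifelse(s == 0, 1, s))
}

check_fraction <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("`", what, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Sampling-overlap model for real and attack datasets
#'
#' When the real dataset (size `n`) and the attack dataset (size `m`) are
#' independent random samples without replacement from the same population of
#' size `N`, the number of individuals in both is hypergeometric with mean
#' `m*n/N`. This is what justifies composing the partitioning attack set with
#' a training fraction of t = n/N.
#'
#' @param N Population size.
#' @param n Real-dataset size, `1 <= n <= N`.
#' @param m Attack-dataset size, `1 <= m <= N`.
#' @return An `overlap_model` object.
#' @export
overlap_model <- function(N, n, m) {
  N <- as.numeric(N); n <- as.numeric(n); m <- as.numeric(m)
  if (any(is.na(c(N, n, m))) || n < 1 || m < 1 || n > N || m > N) {
    stop("overlap model requires 1 <= n <= N and 1 <= m <= N", call. = FALSE)
  }
  structure(list(N = N, n = n, m = m), class = "overlap_model")
}

#' Probability mass of the real/attack overlap size
#'
#' `P(|R intersect D| = x)` under the hypergeometric overlap model;
#' 0 outside the support `[max(0, n + m - N), min(n, m)]`.
#'
#' @param model An [overlap_model()].
#' @param x Overlap count (vectorized).
#' @return Probabilities.
#' @export
overlap_pmf <- function(model, x) {
  stopifnot(inherits(model, "overlap_model"))
  # draws of size m from N with n "marked": dhyper(x; n, N - n, m)
  stats::dhyper(x, m = model$n, n = model$N - model$n, k = model$m)
}

#' Expected overlap between real and attack datasets
#'
#' @param model An [overlap_model()].
#' @return `m * n / N`.
#' @export
expected_overlap <- function(model) {
  stopifnot(inherits(model, "overlap_model"))
  model$m * model$n / model$N
}

#' Naive-attack maximum F1 score
#'
#' The best F1 an adversary achieves with no synthetic data at all, by
#' claiming every attack record is in the real dataset: recall is 1,
#' precision is the sampling fraction n/N, so
#' `Fmax = 2*(n/N) / (1 + n/N)`. Any observed attack F1 is interpreted
#' relative to this ceiling-free baseline; `Fmax = 1` exactly when `n = N`.
#'
#' @param n Real-dataset size.
#' @param N Population size, `N >= n >= 1`.
#' @return `Fmax` in `(0, 1]`. Vectorized.
#' @export
f_max <- function(n, N) {
  n <- as.numeric(n); N <- as.numeric(N)
  if (any(is.na(n)) || any(is.na(N)) || any(n < 1) || any(n > N)) {
    stop("f_max requires 1 <= n <= N", call. = FALSE)
  }
  p <- n / N
  2 * p / (1 + p)
}

#' Chance-corrected membership disclosure score M
#'
#' Rescales an attack F1 against the naive baseline, in the manner of
#' Cohen's kappa: `M = (F1 - Fmax) / (1 - Fmax)`. `M = 0` means the
#' synthetic-data attack does no better than naively claiming everyone;
#' negative M means it does worse; `M = 1` is a perfect attack. M is
#' undefined when `Fmax = 1` (the real dataset is the whole population, no
#' improvement is possible).
#'
#' @param f1 Attack F1 score in `[0, 1]`.
#' @param f_max_value Naive maximum F1, in `(0, 1)`.
#' @return The M score (at most 1, possibly negative). Vectorized.
#' @export
m_score <- function(f1, f_max_value) {
  check_fraction(f1, "f1")
  if (any(is.na(f_max_value)) || any(f_max_value <= 0) || any(f_max_value > 1)) {
    stop("`f_max_value` must lie in (0, 1]", call. = FALSE)
  }
  if (any(f_max_value == 1)) {
    stop("M is undefined when Fmax = 1 (n = N): no improvement over the naive attack is possible",
         call. = FALSE)
  }
  (f1 - f_max_value) / (1 - f_max_value)
}

#' Default acceptability threshold for the M score
#'
#' A 20% improvement over the naive baseline is the conventional upper bound
#' for acceptable membership disclosure risk; risk is acceptable when
#' `M <= m_threshold`.
#' @export
M_THRESHOLD <- 0.2

#' Risk-utility loss for generative-model tuning
#'
#' A loss that can drive hyperparameter selection: while the membership
#' disclosure risk M is acceptable (`M <= 0.2`) the loss is minus the data
#' utility `U`; once M exceeds the threshold the utility is discounted by a
#' sigmoid factor `0.31 + 1/(1 + exp(M - 1))` that is nearly 1 just above
#' the threshold (the loss is continuous there to about 3e-5) and decreases
#' monotonically as M grows, reaching `-0.81 * U` at the perfect-attack
#' extreme M = 1. Implemented with Iverson brackets, literally:
#' `-max([M > 0.2] * (0.31 + 1/(1 + exp(M - 1))), [M <= 0.2]) * U`.
#'
#' @param m_value The M score (any real at most 1, negatives allowed).
#' @param utility Validated utility metric `U` in `[0, 1]`.
#' @param threshold Acceptability threshold (default [M_THRESHOLD]).
#' @return The (negative) loss. Vectorized over `m_value`.
#' @export
risk_utility_loss <- function(m_value, utility, threshold = M_THRESHOLD) {
  check_fraction(utility, "utility")
  above <- as.numeric(m_value > threshold)
  below <- as.numeric(m_value <= threshold)
  -pmax(above * (0.31 + 1 / (1 + exp(m_value - 1))), below) * utility
}

#' Bundle attack counts into a disclosure score
#'
#' Internal constructor shared by [score_attack()] and [assess()].
#'
#' @param precision,recall Attack precision and recall.
#' @param n,N Real-dataset and population sizes for the naive baseline.
#' @param threshold M acceptability threshold.
#' @return A `disclosure_score`: precision, recall, f1, f_max, m_score,
#'   acceptable.
#' @keywords internal
disclosure_score <- function(precision, recall, n, N, threshold = M_THRESHOLD) {
  f1 <- f1_score(precision, recall)
  fm <- f_max(n, N)
  if (fm < 1) {
    m <- m_score(f1, fm)
    acc <- m <= threshold
  } else {
    warning("Fmax = 1 (n = N): M is undefined", call. = FALSE)
    m <- NA_real_
    acc <- NA
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 f_max = fm, m_score = m, acceptable = acc,
                 threshold = threshold),
            class = "disclosure_score")
}

#' @export
print.disclosure_score <- function(x, ...) {
  cat("<disclosure_score>\n")
  cat(sprintf("  precision: %.4f   recall: %.4f   F1: %.4f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  Fmax (naive baseline): %.4f\n", x$f_max))
  if (is.na(x$m_score)) {
    cat("  M: undefined (Fmax = 1)\n")
  } else {
    cat(sprintf("  M: %.4f  -> %s (threshold %.2f)\n", x$m_score,
                if (isTRUE(x$acceptable)) "acceptable" else "NOT acceptable",
                x$threshold))
  }
  invisible(x)
}
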