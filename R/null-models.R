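# Markov-chain Monte-Carlo null model for turn-direction bias and the
# one-sample permutation test of the Match Index.
#
# The null simulator reproduces the structure of the observed data -- same
# number of larvae, same per-trial turn counts -- but draws each trial's
# first turn direction with a fair coin and each subsequent direction as a
# repeat of the previous one with probability p_same. Sequential turns are
# not independent (they "lock" onto a direction), which is why a binomial
# null would be wrong and the chain is simulated instead.

#' Convert a lock index to a same-direction probability
#'
#' The lock index L measures sequential turn persistence on a -100..100
#' scale; it maps linearly to the probability that consecutive routine
#' turns share a direction: `p_same = (100 + L) / 200`. The reference
#' values are 62.8 -> 0.814 (light-off) and 13.2 -> 0.566 (baseline
#' illumination).
#'
#' @param lock_index Numeric in `[-100, 100]`.
#' @return Probability in `[0, 1]`.
#' @seealso [prob_to_lock()] for the exact inverse.
#' @export
lock_to_prob <- function(lock_index) {
  if (any(is.na(lock_index)) || any(lock_index < -100 | lock_index > 100)) {
    stop("`lock_index` must lie in [-100, 100]", call. = FALSE)
  }
  (100 + lock_index) / 200
}

#' @rdname lock_to_prob
#' @param p_same Probability in `[0, 1]`.
#' @export
prob_to_lock <- function(p_same) {
  if (any(is.na(p_same)) || any(p_same < 0 | p_same > 1)) {
    stop("`p_same` must lie in [0, 1]", call. = FALSE)
  }
  200 * p_same - 100
}

#' Empirical Monte-Carlo p-value
#'
#' The convention used throughout: `p = k / n_sims` where `k` simulations
#' meet or exceed the observed statistic; when `k = 0` the p-value is
#' reported as a bound below `1 / n_sims` (e.g. "p < 0.0001" at 10,000
#' simulations) with `is_bound` set. The `"plus_one"` alternative
#' `(k + 1) / (n_sims + 1)` is available but not the default.
#'
#' @param n_exceed Number of simulations at least as extreme as observed.
#' @param n_sims Number of simulations.
#' @param convention `"count"` (default) or `"plus_one"`.
#' @return List `p_value, is_bound`.
#' @export
empirical_p_value <- function(n_exceed, n_sims,
                              convention = c("count", "plus_one")) {
  convention <- match.arg(convention)
  n_sims <- assert_count(n_sims, "n_sims")
  stopifnot(n_exceed >= 0, n_exceed <= n_sims)
  if (convention == "plus_one") {
    list(p_value = (n_exceed + 1) / (n_sims + 1), is_bound = FALSE)
  } else if (n_exceed == 0) {
    list(p_value = 1 / n_sims, is_bound = TRUE)
  } else {
    list(p_value = n_exceed / n_sims, is_bound = FALSE)
  }
}

# Vectorized chain core: per-trial percent rightward for a vector of trial
# lengths. Iterates over event position, drawing reversals only for trials
# still active, so cost scales with total turns.
sim_trial_pct <- function(n_turns, p_same) {
  N <- length(n_turns)
  dir <- ifelse(runif(N) < 0.5, 1L, -1L)
  n_right <- as.integer(dir == 1L)
  kmax <- max(n_turns)
  t <- 2L
  while (t <= kmax) {
    act <- which(n_turns >= t)
    flip <- runif(length(act)) >= p_same
    dir[act[flip]] <- -dir[act[flip]]
    n_right[act] <- n_right[act] + (dir[act] == 1L)
    t <- t + 1L
  }
  100 * n_right / n_turns
}

#' Simulate the null distribution of per-larva percent rightward turns
#'
#' Runs `n_sims` unbiased cohorts that mirror the observed cohort: the same
#' larvae with the same per-trial turn counts, first turn of each trial a
#' fair coin, subsequent turns repeating with probability `p_same`. Each
#' larva is summarized by the mean over its trials of the per-trial percent
#' rightward.
#'
#' @param counts Data frame `larva_id, trial, n_turns` (all counts >= 1).
#' @param p_same Sequential same-direction probability (see
#'   [lock_to_prob()]).
#' @param n_sims Number of simulated cohorts.
#' @param seed Optional seed.
#' @return Matrix of per-larva mean percent rightward, `n_larvae` rows x
#'   `n_sims` columns; row order follows sorted `larva_id`.
#' @export
simulate_null_pct <- function(counts, p_same, n_sims = 1L, seed = NULL) {
  stopifnot(all(c("larva_id", "trial", "n_turns") %in% names(counts)))
  if (nrow(counts) == 0L) stop("empty turn-count table", call. = FALSE)
  if (any(counts$n_turns < 1L)) stop("all turn counts must be >= 1", call. = FALSE)
  assert_prob(p_same, "p_same")
  n_sims <- assert_count(n_sims, "n_sims")
  counts <- counts[order(counts$larva_id, counts$trial), , drop = FALSE]
  ids <- unique(counts$larva_id)
  L <- length(ids)
  larva_idx <- match(counts$larva_id, ids)
  trials_per <- tabulate(larva_idx, nbins = L)
  with_seed(seed, {
    n_rep <- rep(counts$n_turns, times = n_sims)
    pct <- sim_trial_pct(n_rep, p_same)
    grp <- rep(larva_idx, times = n_sims) +
      rep((seq_len(n_sims) - 1L) * L, each = nrow(counts))
    sums <- rowsum(pct, grp, reorder = TRUE)
    means <- as.vector(sums) / rep(trials_per, times = n_sims)
    matrix(means, nrow = L, dimnames = list(ids, NULL))
  })
}

#' Simulate one unbiased cohort
#'
#' Convenience wrapper around [simulate_null_pct()] returning a tidy
#' per-larva summary for a single simulated cohort.
#'
#' @inheritParams simulate_null_pct
#' @return Tibble `larva_id, mean_pct_right`.
#' @export
simulate_null_cohort <- function(counts, p_same, seed = NULL) {
  m <- simulate_null_pct(counts, p_same, n_sims = 1L, seed = seed)
  tibble::tibble(larva_id = sort(unique(counts$larva_id)),
                 mean_pct_right = m[, 1])
}

#' Monte-Carlo test for excess strongly biased larvae
#'
#' Tests whether more larvae show extreme direction preferences than
#' expected if turn direction were unbiased (but sequentially persistent).
#' Tail thresholds are the `tail/2` and `1 - tail/2` quantiles of the
#' pooled simulated per-larva distribution (so by construction ~`tail` of
#' simulated larvae fall outside them); a larva counts as biased when its
#' value is strictly below the low or strictly above the high threshold.
#' The p-value is the fraction of simulated cohorts whose biased-larva
#' count reaches the observed count.
#'
#' @param observed_pct Observed per-larva mean percent rightward, aligned
#'   with the larvae in `counts` (sorted by `larva_id`).
#' @inheritParams simulate_null_pct
#' @param n_sims Number of simulated cohorts (default 10,000).
#' @param tail Total two-sided tail mass defining the thresholds (default
#'   0.10).
#' @param convention Passed to [empirical_p_value()].
#' @param keep_null Keep the pooled simulated values (needed by
#'   [null_histogram()]); disable to save memory in calibration loops.
#' @param seed Optional seed.
#' @return An object of class `mc_bias_test`: thresholds, observed and
#'   simulated exceedance counts, p-value (with `p_is_bound`), and
#'   metadata. Thresholds are always derived from the simulation, never
#'   fixed constants.
#' @export
mc_bias_test <- function(observed_pct, counts, p_same, n_sims = 10000L,
                         tail = 0.10, convention = c("count", "plus_one"),
                         keep_null = TRUE, seed = NULL) {
  convention <- match.arg(convention)
  if (!is.numeric(tail) || tail <= 0 || tail >= 1) {
    stop("`tail` must be in (0, 1)", call. = FALSE)
  }
  ids <- sort(unique(counts$larva_id))
  if (length(observed_pct) != length(ids)) {
    stop("`observed_pct` must have one value per larva in `counts`", call. = FALSE)
  }
  m <- simulate_null_pct(counts, p_same, n_sims = n_sims, seed = seed)
  pooled <- as.vector(m)
  thr <- quantile(pooled, c(tail / 2, 1 - tail / 2), names = FALSE)
  exceed_sim <- colSums(m < thr[1] | m > thr[2])
  obs_exceed <- sum(observed_pct < thr[1] | observed_pct > thr[2], na.rm = TRUE)
  k <- sum(exceed_sim >= obs_exceed)
  p <- empirical_p_value(k, n_sims, convention)
  structure(list(
    n_larvae = length(ids), n_sims = n_sims, tail = tail, p_same = p_same,
    thresholds = c(low = thr[1], high = thr[2]),
    observed_exceedance = obs_exceed,
    exceedance_counts = exceed_sim,
    n_sims_exceeding = k,
    p_value = p$p_value, p_is_bound = p$is_bound,
    convention = convention,
    threshold_rule = "quantiles of pooled simulated distribution",
    null_pct = if (keep_null) pooled else NULL,
    seed = seed
  ), class = "mc_bias_test")
}

#' @export
print.mc_bias_test <- function(x, ...) {
  cat("Monte-Carlo turn-bias test (Markov-chain null)\n")
  cat(sprintf("  %d larvae, %d simulated cohorts, p_same = %.3f\n",
              x$n_larvae, x$n_sims, x$p_same))
  cat(sprintf("  tail thresholds (%g%%/%g%%): %.1f%% / %.1f%% rightward\n",
              100 * x$tail / 2, 100 * (1 - x$tail / 2),
              x$thresholds[1], x$thresholds[2]))
  cat(sprintf("  observed larvae outside thresholds: %d\n", x$observed_exceedance))
  cat(if (x$p_is_bound) sprintf("  p < %.4g\n", 1 / x$n_sims)
      else sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' One-sample permutation test of the Match Index against 0.5
#'
#' Under the null of no individual bias each follow-up trial matches the
#' trial-1 direction with probability 1/2, so each larva's null Match Index
#' is Binomial(k_i, 1/2) / k_i with its own number of informative follow-up
#' trials k_i. The observed cohort mean is ranked against `n_sims` null
#' cohort means; by default the test is two-sided on the deviation from
#' 0.5.
#'
#' @param mi Observed per-larva Match Index values in `[0, 1]` (missing
#'   values are dropped together with their `n_followups` entry).
#' @param n_followups Integer vector of informative follow-up trial counts
#'   per larva (all >= 1).
#' @param n_sims Number of null simulations (default 100,000).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @param convention Passed to [empirical_p_value()].
#' @param seed Optional seed.
#' @return An object of class `permutation_match_test` with the observed
#'   mean, p-value (and `p_is_bound`), and metadata.
#' @export
permutation_match_test <- function(mi, n_followups, n_sims = 100000L,
                                   alternative = c("two.sided", "greater", "less"),
                                   convention = c("count", "plus_one"),
                                   seed = NULL) {
  alternative <- match.arg(alternative)
  convention <- match.arg(convention)
  stopifnot(length(mi) == length(n_followups))
  keep <- !is.na(mi)
  mi <- mi[keep]
  n_followups <- n_followups[keep]
  if (length(mi) == 0L) stop("no non-missing Match Index values", call. = FALSE)
  if (any(mi < 0 | mi > 1)) stop("Match Index values must lie in [0, 1]", call. = FALSE)
  if (any(n_followups < 1L)) {
    stop("every larva needs at least one informative follow-up trial", call. = FALSE)
  }
  n_sims <- assert_count(n_sims, "n_sims")
  L <- length(mi)
  obs <- mean(mi)
  null_means <- with_seed(seed, {
    draws <- rbinom(L * n_sims, size = n_followups, prob = 0.5) / n_followups
    colMeans(matrix(draws, nrow = L))
  })
  eps <- 1e-12
  k <- switch(alternative,
    two.sided = sum(abs(null_means - 0.5) >= abs(obs - 0.5) - eps),
    greater = sum(null_means - 0.5 >= obs - 0.5 - eps),
    less = sum(0.5 - null_means >= 0.5 - obs - eps))
  p <- empirical_p_value(k, n_sims, convention)
  structure(list(
    n_larvae = L, n_sims = n_sims, observed_mean = obs,
    alternative = alternative, n_sims_exceeding = k,
    p_value = p$p_value, p_is_bound = p$is_bound,
    convention = convention, seed = seed
  ), class = "permutation_match_test")
}

#' @export
print.permutation_match_test <- function(x, ...) {
  cat("One-sample permutation test of Match Index against 0.5\n")
  cat(sprintf("  %d larvae, %d null simulations, %s\n",
              x$n_larvae, x$n_sims, x$alternative))
  cat(sprintf("  observed mean Match Index = %.2f\n", x$observed_mean))
  cat(if (x$p_is_bound) sprintf("  p < %.4g\n", 1 / x$n_sims)
      else sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Expected histogram of per-larva percent rightward under the null
#'
#' Bins the pooled simulated per-larva distribution of an [mc_bias_test()]
#' (run with `keep_null = TRUE`) into fractions summing to 1 -- the
#' "expected distribution" overlay for observed bias histograms.
#'
#' @param x An `mc_bias_test` object or a numeric vector of simulated
#'   per-larva percent-rightward values.
#' @param bin_width Bin width in percent (must divide evenly into
#'   `[0, 100]`; the last bin is closed).
#' @return Tibble `bin_low, bin_high, fraction`.
#' @export
null_histogram <- function(x, bin_width = 4) {
  if (inherits(x, "mc_bias_test")) {
    if (is.null(x$null_pct)) {
      stop("test was run with `keep_null = FALSE`; no simulated values retained",
           call. = FALSE)
    }
    x <- x$null_pct
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  breaks <- seq(0, 100, by = bin_width)
  if (tail(breaks, 1) < 100) breaks <- c(breaks, 100)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  tibble::tibble(bin_low = head(breaks, -1), bin_high = breaks[-1],
                 fraction = h$counts / sum(h$counts))
}
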