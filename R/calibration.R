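# Calibration loops: operating characteristics of the two tests under
# matched null generators.

#' Type-I error calibration of the Monte-Carlo bias test
#'
#' Repeatedly draws an unbiased cohort (fair first turns, persistence
#' `p_same`), runs [mc_bias_test()] against a freshly simulated null at
#' reduced `n_sims`, and records the p-value. Under the null the rejection
#' rate at level alpha should approximate alpha.
#'
#' @param n_cohorts Number of null cohorts to test (default 500).
#' @param n_larvae,trials_per_larva Cohort shape (defaults 89 larvae, 4
#'   trials -- the light-off assay size).
#' @param turn_counts A [turn_count_model()] for per-trial counts.
#' @param p_same Sequential same-direction probability.
#' @param n_sims Simulations per test (reduced default 1,000).
#' @param tail Tail level passed to [mc_bias_test()].
#' @param seed Optional master seed (per-cohort substreams).
#' @return Tibble `cohort, p_value, p_is_bound, observed_exceedance`.
#' @export
calibrate_mc_bias <- function(n_cohorts = 500L, n_larvae = 89L,
                              trials_per_larva = 4L,
                              turn_counts = turn_count_model(),
                              p_same = 0.814, n_sims = 1000L, tail = 0.10,
                              seed = NULL) {
  n_cohorts <- assert_count(n_cohorts, "n_cohorts")
  p <- numeric(n_cohorts)
  bound <- logical(n_cohorts)
  exceed <- integer(n_cohorts)
  for (b in seq_len(n_cohorts)) {
    if (!is.null(seed)) set.seed(substream_seed(seed, b, stream = 7L))
    counts <- tibble::tibble(
      larva_id = rep(seq_len(n_larvae), each = trials_per_larva),
      trial = rep(seq_len(trials_per_larva), n_larvae),
      n_turns = draw_turn_counts(n_larvae * trials_per_larva, turn_counts)
    )
    obs <- simulate_null_cohort(counts, p_same)$mean_pct_right
    r <- mc_bias_test(obs, counts, p_same, n_sims = n_sims, tail = tail,
                      keep_null = FALSE)
    p[b] <- r$p_value
    bound[b] <- r$p_is_bound
    exceed[b] <- r$observed_exceedance
  }
  tibble::tibble(cohort = seq_len(n_cohorts), p_value = p, p_is_bound = bound,
                 observed_exceedance = exceed)
}

#' Null-distribution calibration of the Match-Index permutation test
#'
#' Generates unbiased cohorts with the synthetic turn generator
#' (`bias_strength = 0.5`), computes Match Indices through the full metric
#' path, and runs [permutation_match_test()] on each. The returned
#' p-values should be approximately uniform on (0, 1].
#'
#' @param n_runs Number of null cohorts (default 500).
#' @param n_larvae Larvae per cohort (default 30).
#' @param trials_per_larva Trials per larva (default 4).
#' @param lock_prob Within-trial persistence of the generator.
#' @param n_sims Permutations per test (reduced default 2,000).
#' @param seed Optional master seed.
#' @return Tibble `run, p_value, observed_mean, n_larvae_used`.
#' @export
calibrate_match_permutation <- function(n_runs = 500L, n_larvae = 30L,
                                        trials_per_larva = 4L,
                                        lock_prob = 0.814, n_sims = 2000L,
                                        seed = NULL) {
  n_runs <- assert_count(n_runs, "n_runs")
  p <- numeric(n_runs)
  om <- numeric(n_runs)
  nl <- integer(n_runs)
  for (b in seq_len(n_runs)) {
    cfg <- cohort_config(n_larvae = n_larvae,
                         trials_per_larva = trials_per_larva,
                         bias_strength = 0.5, lock_prob = lock_prob,
                         seed = if (is.null(seed)) NULL
                                else substream_seed(seed, b, stream = 11L))
    cohort <- generate_turn_cohort(cfg)
    bias <- cohort_bias_table(cohort$turns,
                              n_trials_required = trials_per_larva)
    keep <- !is.na(bias$match_index)
    r <- permutation_match_test(bias$match_index[keep],
                                bias$n_valid_followups[keep],
                                n_sims = n_sims)
    p[b] <- r$p_value
    om[b] <- r$observed_mean
    nl[b] <- sum(keep)
  }
  tibble::tibble(run = seq_len(n_runs), p_value = p, observed_mean = om,
                 n_larvae_used = nl)
}
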