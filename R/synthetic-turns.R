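# Synthetic turn-sequence and heading-series generators.
#
# The generators emulate the dark-induced circling assay: cohorts of larvae
# probed with repeated light-off trials, each trial yielding an ordered
# sequence of signed routine-turn directions with sequential persistence
# (consecutive turns tend to repeat). Ground truth is returned alongside so
# every downstream metric can be checked against what was planted.

#' Turn-count model specification
#'
#' Describes how many routine turns a larva executes on each trial. The
#' default is a Poisson model truncated from below, mirroring the analysis
#' filter that only keeps trials with a minimum number of turns.
#'
#' @param type `"poisson"` (mean `lambda`, truncated at `min_turns`) or
#'   `"fixed"` (exactly `k` turns per trial).
#' @param lambda Poisson mean (ignored for `"fixed"`).
#' @param k Fixed per-trial count (ignored for `"poisson"`).
#' @param min_turns Lower truncation bound; no generated trial has fewer
#'   turns than this.
#' @return A `turn_count_model` list.
#' @export
turn_count_model <- function(type = c("poisson", "fixed"), lambda = 8, k = 8,
                             min_turns = 3L) {
  type <- match.arg(type)
  min_turns <- assert_count(min_turns, "min_turns", min = 1L)
  if (type == "poisson") {
    assert_pos(lambda, "lambda")
  } else {
    k <- assert_count(k, "k", min = min_turns)
  }
  structure(list(type = type, lambda = lambda, k = k, min_turns = min_turns),
            class = "turn_count_model")
}

#' Draw per-trial turn counts from a count model
#'
#' Truncation uses the inverse-CDF so the number of RNG draws per call is
#' fixed regardless of the truncation bound (substream stability).
#'
#' @param n Number of counts to draw.
#' @param model A [turn_count_model()].
#' @return Integer vector of length `n`, each at least `model$min_turns`.
#' @export
draw_turn_counts <- function(n, model) {
  stopifnot(inherits(model, "turn_count_model"))
  if (model$type == "fixed") return(rep(model$k, n))
  p_lo <- ppois(model$min_turns - 1L, model$lambda)
  u <- runif(n, min = p_lo, max = 1)
  pmax(qpois(u, model$lambda), model$min_turns)
}

#' Configuration for a synthetic turn-sequence cohort
#'
#' Defaults are the study conditions of the dark-induced circling assay:
#' four 10-s light-off trials per larva, sequential same-direction
#' probability 0.814 (the light-off lock index), and a 70% chance that each
#' trial's first turn is in the larva's preferred direction -- the strength
#' of individual bias the assay reports. Setting `bias_strength = 0.5`
#' ignores preferred directions and reduces the generator exactly to the
#' unbiased Markov null model used for Monte-Carlo testing.
#'
#' @param n_larvae Number of larvae.
#' @param trials_per_larva Trials per larva (default 4).
#' @param turn_counts A [turn_count_model()].
#' @param bias_strength Probability pi in `[0.5, 1]` that the first turn of
#'   each trial is in the larva's preferred direction.
#' @param preferred_dir_prob Probability that a larva is right-preferring.
#' @param lock_prob Probability p_same that each subsequent turn repeats the
#'   previous direction (see [lock_to_prob()]).
#' @param trial_duration_s Trial recording window in seconds; event
#'   timestamps are drawn within it.
#' @param seed Optional master seed; per-larva substreams are derived from
#'   it (see [substream_seed()]).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_larvae, trials_per_larva = 4L,
                          turn_counts = turn_count_model(),
                          bias_strength = 0.7, preferred_dir_prob = 0.5,
                          lock_prob = 0.814, trial_duration_s = 10,
                          seed = NULL) {
  n_larvae <- assert_count(n_larvae, "n_larvae")
  trials_per_larva <- assert_count(trials_per_larva, "trials_per_larva")
  stopifnot(inherits(turn_counts, "turn_count_model"))
  assert_prob(bias_strength, "bias_strength")
  if (bias_strength < 0.5) {
    stop("`bias_strength` below 0.5 would bias larvae away from their preferred direction",
         call. = FALSE)
  }
  assert_prob(preferred_dir_prob, "preferred_dir_prob")
  assert_prob(lock_prob, "lock_prob")
  assert_pos(trial_duration_s, "trial_duration_s")
  structure(list(n_larvae = n_larvae, trials_per_larva = trials_per_larva,
                 turn_counts = turn_counts, bias_strength = bias_strength,
                 preferred_dir_prob = preferred_dir_prob, lock_prob = lock_prob,
                 trial_duration_s = trial_duration_s, seed = seed),
            class = "cohort_config")
}

# One within-trial direction sequence: the chain repeats the previous
# direction with probability p_same, so the running sign is the first
# direction times the parity of accumulated reversals.
markov_turn_seq <- function(first_dir, n, p_same) {
  if (n == 1L) return(first_dir)
  reversed <- runif(n - 1L) >= p_same
  first_dir * cumprod(c(1, ifelse(reversed, -1, 1)))
}

#' Generate a synthetic turn-event cohort
#'
#' For each larva and trial, emits an ordered sequence of signed turn
#' directions (+1 rightward, -1 leftward). The first event of each trial is
#' in the larva's preferred direction with probability `bias_strength`;
#' every subsequent event repeats the previous direction with probability
#' `lock_prob`. Deterministic given the config seed, and stable per larva
#' under changes of `n_larvae`.
#'
#' @param config A [cohort_config()].
#' @return A `turn_cohort` list with elements:
#'   \describe{
#'     \item{turns}{tibble `larva_id, trial, event_index, direction, time_s`.}
#'     \item{larvae}{ground truth: `larva_id, preferred_dir, pct_rightward`
#'       (realized, recomputable from `turns`).}
#'     \item{trials}{per-trial ground truth: `larva_id, trial, n_turns,
#'       pct_rightward`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
generate_turn_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_larvae
  n_trials <- config$trials_per_larva
  pref <- integer(n)
  dir_col <- vector("list", n)
  time_col <- vector("list", n)
  counts_col <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(config$seed)) set.seed(substream_seed(config$seed, i))
    pref[i] <- if (runif(1) < config$preferred_dir_prob) 1L else -1L
    counts <- draw_turn_counts(n_trials, config$turn_counts)
    dirs <- vector("list", n_trials)
    times <- vector("list", n_trials)
    for (j in seq_len(n_trials)) {
      first <- if (runif(1) < config$bias_strength) pref[i] else -pref[i]
      dirs[[j]] <- markov_turn_seq(first, counts[j], config$lock_prob)
      times[[j]] <- sort(runif(counts[j], 0, config$trial_duration_s))
    }
    dir_col[[i]] <- unlist(dirs)
    time_col[[i]] <- unlist(times)
    counts_col[[i]] <- counts
  }
  counts_all <- unlist(counts_col)
  turns <- tibble::tibble(
    larva_id = rep(seq_len(n), times = vapply(counts_col, sum, numeric(1))),
    trial = rep(rep(seq_len(n_trials), n), times = counts_all),
    event_index = sequence(counts_all),
    direction = as.integer(unlist(dir_col)),
    time_s = unlist(time_col)
  )
  trial_pct <- 100 * tapply(turns$direction == 1L,
                            list(turns$larva_id, turns$trial), mean)
  trials <- tibble::tibble(
    larva_id = rep(seq_len(n), each = n_trials),
    trial = rep(seq_len(n_trials), n),
    n_turns = counts_all,
    pct_rightward = as.vector(t(trial_pct))
  )
  larvae <- tibble::tibble(
    larva_id = seq_len(n),
    preferred_dir = pref,
    pct_rightward = unname(rowMeans(trial_pct))
  )
  structure(list(turns = turns, larvae = larvae, trials = trials,
                 config = config),
            class = "turn_cohort")
}

#' Generate a synthetic heading-change time series
#'
#' Emits time-stamped signed angular path changes (degrees; rightward
#' positive) for one trial window, optionally with dropout intervals during
#' which the tracker loses the larva and no samples are produced. Feeds
#' [compute_nta()], whose data-span exclusion rule the dropouts exercise.
#'
#' @param duration_s Window length in seconds (default 30, the trajectory
#'   recording interval).
#' @param rate_hz Sampling rate.
#' @param step_mean,step_sd Mean and sd of the per-sample signed change
#'   (degrees); a nonzero mean plants a net directional drift.
#' @param step_fn Optional custom sampler `function(n)` overriding the
#'   normal model.
#' @param dropouts Optional list of `c(start, end)` intervals (seconds,
#'   within `[0, duration_s]`) that emit no samples.
#' @param seed Optional seed.
#' @return A tibble `time_s, dtheta_deg` with strictly increasing times.
#' @export
generate_heading_series <- function(duration_s = 30, rate_hz = 5,
                                    step_mean = 0, step_sd = 15,
                                    step_fn = NULL, dropouts = NULL,
                                    seed = NULL) {
  assert_pos(duration_s, "duration_s")
  assert_pos(rate_hz, "rate_hz")
  if (!is.null(dropouts)) {
    for (iv in dropouts) {
      if (length(iv) != 2L || iv[1] >= iv[2] || iv[1] < 0 || iv[2] > duration_s) {
        stop("each dropout must be an ordered interval within [0, duration_s]",
             call. = FALSE)
      }
    }
  }
  t <- seq(0, by = 1 / rate_hz, length.out = floor(duration_s * rate_hz))
  keep <- rep(TRUE, length(t))
  for (iv in dropouts %||% list()) {
    keep <- keep & !(t >= iv[1] & t < iv[2])
  }
  t <- t[keep]
  steps <- with_seed(seed, {
    if (is.null(step_fn)) rnorm(length(t), step_mean, step_sd) else step_fn(length(t))
  })
  tibble::tibble(time_s = t, dtheta_deg = steps)
}
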