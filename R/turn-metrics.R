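# Per-larva bias metrics: net turn angle (NTA), Match Index, percent
# rightward turns, left/right classification, and the exclusion rules that
# accompany them.

#' Net turn angle for one heading series
#'
#' NTA is the signed sum of all path direction changes over the recording
#' window (rightward positive, leftward negative); the absolute NTA sums the
#' unsigned changes and measures total turning regardless of direction.
#' Trials with less than `min_span_s` seconds of data are flagged invalid
#' and excluded downstream. The span of an irregularly covered window is
#' estimated as sample count times the median inter-sample interval, so a
#' tracker dropout shrinks it even when the first and last samples are far
#' apart.
#'
#' @param series Data frame with columns `time_s`, `dtheta_deg` for one
#'   larva-trial, times strictly increasing.
#' @param window Recording window `c(start, end)` in seconds (default 30-s
#'   interval).
#' @param min_span_s Minimum seconds of data for a valid trial (default 10).
#' @return One-row tibble `nta_deg, abs_nta_deg, n_samples, data_span_s,
#'   valid`. An empty series yields `valid = FALSE` with missing NTA rather
#'   than an error.
#' @export
compute_nta <- function(series, window = c(0, 30), min_span_s = 10) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (nrow(series) == 0L) {
    return(tibble::tibble(nta_deg = NA_real_, abs_nta_deg = NA_real_,
                          n_samples = 0L, data_span_s = 0, valid = FALSE))
  }
  stopifnot(all(c("time_s", "dtheta_deg") %in% names(series)))
  t <- series$time_s
  if (is.unsorted(t, strictly = TRUE)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (any(t < window[1] | t > window[2])) {
    stop("series times fall outside the recording window", call. = FALSE)
  }
  n <- length(t)
  dt <- if (n > 1L) stats::median(diff(t)) else NA_real_
  span <- if (n > 1L) n * dt else 0
  tibble::tibble(nta_deg = sum(series$dtheta_deg),
                 abs_nta_deg = sum(abs(series$dtheta_deg)),
                 n_samples = n,
                 data_span_s = span,
                 valid = span >= min_span_s)
}

#' Per-trial NTA table for a cohort of heading series
#'
#' @param heading Long data frame `larva_id, trial, time_s, dtheta_deg`.
#' @inheritParams compute_nta
#' @return Tibble with one row per larva-trial (columns of [compute_nta()]
#'   plus `larva_id`, `trial`), ordered by larva then trial.
#' @export
nta_table <- function(heading, window = c(0, 30), min_span_s = 10) {
  stopifnot(all(c("larva_id", "trial", "time_s", "dtheta_deg") %in% names(heading)))
  heading |>
    dplyr::group_by(.data$larva_id, .data$trial) |>
    dplyr::group_modify(~ compute_nta(.x, window = window, min_span_s = min_span_s)) |>
    dplyr::ungroup()
}

#' Classify a larva as left- or right-biased from its first trial
#'
#' Positive NTA on trial 1 classifies the larva as right-biased (`"R"`),
#' negative as left-biased (`"L"`). A zero or invalid first trial leaves the
#' larva `"unclassified"` (and excluded from the Match Index).
#'
#' @param nta Numeric vector of trial-1 NTA values (or any signed per-trial
#'   statistic).
#' @param valid Logical vector of trial validity flags (recycled).
#' @return Character vector in `{"L", "R", "unclassified"}`.
#' @export
classify_lr <- function(nta, valid = TRUE) {
  valid <- rep_len(valid, length(nta))
  out <- rep("unclassified", length(nta))
  ok <- valid & !is.na(nta)
  out[ok & nta > 0] <- "R"
  out[ok & nta < 0] <- "L"
  out
}

#' Match Index: persistence of trial-1 turn direction
#'
#' The fraction of follow-up trials (2 onward) whose NTA sign matches the
#' first trial. Invalid follow-up trials are dropped from both numerator and
#' denominator, as are follow-ups with an exactly zero statistic (a tie
#' carries no directional information). The index is undefined (`NA`) when
#' trial 1 is invalid or zero, or when fewer than `min_valid_followups`
#' follow-ups remain. Under no individual bias the expected value is 0.5; a
#' value of 1 means every follow-up matched trial 1.
#'
#' @param nta Numeric vector of per-trial signed statistics, ordered by
#'   trial (trial 1 first).
#' @param valid Logical validity flags per trial (default: non-missing).
#' @param min_valid_followups Minimum informative follow-ups (default 2).
#' @return List with `match_index` and `n_valid_followups`.
#' @export
match_index <- function(nta, valid = !is.na(nta), min_valid_followups = 2L) {
  stopifnot(length(valid) == length(nta))
  if (length(nta) < 2L) stop("need at least two trials", call. = FALSE)
  informative <- valid & !is.na(nta) & nta != 0
  if (!informative[1]) {
    return(list(match_index = NA_real_, n_valid_followups = 0L))
  }
  fu <- informative[-1]
  n_valid <- sum(fu)
  if (n_valid < min_valid_followups) {
    return(list(match_index = NA_real_, n_valid_followups = n_valid))
  }
  matches <- sign(nta[-1][fu]) == sign(nta[1])
  list(match_index = sum(matches) / n_valid, n_valid_followups = n_valid)
}

#' Percent rightward turns per trial and per larva
#'
#' The per-trial statistic is the percentage of routine turns executed
#' rightward; each larva is summarized by the unweighted mean over its
#' trials. Larvae are only `included` if they executed at least `min_turns`
#' routine turns on each of the `n_trials_required` trials.
#'
#' @param turns Turn-event data frame `larva_id, trial, direction` with
#'   directions in `{-1, +1}`.
#' @param min_turns Minimum turns per trial (default 3).
#' @param n_trials_required Number of trials the assay requires (default 4).
#' @return List of tibbles: `trials` (`larva_id, trial, n_turns, pct_right`)
#'   and `larvae` (`larva_id, mean_pct_right, included`).
#' @export
percent_rightward <- function(turns, min_turns = 3L, n_trials_required = 4L) {
  stopifnot(all(c("larva_id", "trial", "direction") %in% names(turns)))
  if (nrow(turns) == 0L) stop("no turn events supplied", call. = FALSE)
  if (!all(turns$direction %in% c(-1L, 1L))) {
    bad <- which(!(turns$direction %in% c(-1L, 1L)))
    stop(sprintf("`direction` must be -1 or +1 (offending rows: %s)",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  trials <- turns |>
    dplyr::group_by(.data$larva_id, .data$trial) |>
    dplyr::summarise(n_turns = dplyr::n(),
                     pct_right = 100 * mean(.data$direction == 1L),
                     .groups = "drop")
  larvae <- trials |>
    dplyr::filter(.data$trial <= n_trials_required) |>
    dplyr::group_by(.data$larva_id) |>
    dplyr::summarise(
      mean_pct_right = mean(.data$pct_right),
      included = dplyr::n() == n_trials_required && all(.data$n_turns >= min_turns),
      .groups = "drop")
  list(trials = trials, larvae = larvae)
}

#' Classify bias from mean percent rightward turns
#'
#' Larvae below the `low` threshold are left-biased, above `high`
#' right-biased, otherwise unclassified. Defaults are the 33/66% cutoffs
#' used for multiday persistence grouping.
#'
#' @param pct Numeric vector of mean percent-rightward values in `[0, 100]`.
#' @param low,high Classification thresholds, `low < high`.
#' @return Character vector in `{"L", "R", "unclassified"}`.
#' @export
classify_by_percent <- function(pct, low = 33, high = 66) {
  if (!(low < high)) stop("`low` must be below `high`", call. = FALSE)
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("`pct` must lie in [0, 100]", call. = FALSE)
  }
  out <- rep("unclassified", length(pct))
  out[!is.na(pct) & pct < low] <- "L"
  out[!is.na(pct) & pct > high] <- "R"
  out
}

#' Decompose turn bias into magnitude and direction
#'
#' Magnitude is the distance of the mean percent-rightward value from the
#' unbiased 50%; direction is its side (+1 rightward, -1 leftward, 0 none).
#'
#' @param pct Numeric vector of mean percent-rightward values in `[0, 100]`.
#' @return Tibble `magnitude, direction`.
#' @export
decompose_bias <- function(pct) {
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("`pct` must lie in [0, 100]", call. = FALSE)
  }
  d <- pct - 50
  d[!is.na(d) & abs(d) < 1e-9] <- 0 # snap float dust from trial averaging
  tibble::tibble(magnitude = abs(d), direction = sign(d))
}

#' Cohort bias table from a turn-event table
#'
#' One row per larva combining every per-larva metric: per-trial turn
#' counts, mean percent rightward, inclusion flag, left/right class from
#' the first trial's net direction, Match Index over follow-up trials, and
#' the magnitude/direction decomposition. The per-trial signed statistic
#' used for classification and matching is the net turn count (sum of
#' signed directions), the turn-table analogue of the NTA. Trials with
#' fewer than `min_turns` turns are invalid for matching.
#'
#' @inheritParams percent_rightward
#' @inheritParams match_index
#' @return Tibble with one row per larva; columns `larva_id, mean_pct_right,
#'   included, class, match_index, n_valid_followups, bias_magnitude,
#'   bias_direction` and a list-column `trial_sign` of per-trial net
#'   direction signs. Attribute `mi_denominator` records the Match-Index
#'   denominator convention.
#' @export
cohort_bias_table <- function(turns, min_turns = 3L, n_trials_required = 4L,
                              min_valid_followups = 2L) {
  pr <- percent_rightward(turns, min_turns = min_turns,
                          n_trials_required = n_trials_required)
  net <- turns |>
    dplyr::group_by(.data$larva_id, .data$trial) |>
    dplyr::summarise(net = sum(.data$direction), n_turns = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$larva_id, .data$trial)
  per_larva <- split(net, net$larva_id)
  ids <- as.integer(names(per_larva))
  mi <- lapply(per_larva, function(d) {
    full <- merge(data.frame(trial = seq_len(n_trials_required)), d,
                  by = "trial", all.x = TRUE)
    match_index(full$net,
                valid = !is.na(full$n_turns) & full$n_turns >= min_turns,
                min_valid_followups = min_valid_followups)
  })
  cls <- vapply(per_larva, function(d) {
    t1 <- d[d$trial == 1L, , drop = FALSE]
    if (nrow(t1) == 0L || t1$n_turns < min_turns) "unclassified"
    else classify_lr(t1$net)
  }, character(1))
  signs <- lapply(per_larva, function(d) as.integer(sign(d$net)))
  out <- tibble::tibble(
    larva_id = ids,
    class = unname(cls),
    match_index = vapply(mi, `[[`, numeric(1), "match_index"),
    n_valid_followups = vapply(mi, `[[`, integer(1), "n_valid_followups"),
    trial_sign = unname(signs)
  )
  out <- dplyr::left_join(pr$larvae, out, by = "larva_id")
  out <- dplyr::bind_cols(out, decompose_bias(out$mean_pct_right) |>
                            stats::setNames(c("bias_magnitude", "bias_direction")))
  attr(out, "mi_denominator") <- "valid_nonzero_followups_only"
  out
}

#' Select larvae with strong, consistent bias
#'
#' Retains larvae whose mean percent-rightward value lies in the top or
#' bottom quartile of the cohort (inclusive, linear-interpolation
#' quantiles) and whose per-trial net directions are identical and nonzero
#' on every trial -- the selection filter used when breeding for motor
#' asymmetry.
#'
#' @param bias_tbl A [cohort_bias_table()] result (needs `mean_pct_right`
#'   and the `trial_sign` list-column).
#' @return The retained subset of `bias_tbl`.
#' @export
select_consistent_larvae <- function(bias_tbl) {
  stopifnot(all(c("mean_pct_right", "trial_sign") %in% names(bias_tbl)))
  ok <- !is.na(bias_tbl$mean_pct_right)
  if (sum(ok) < 4L) stop("need at least 4 larvae to define quartiles", call. = FALSE)
  q <- quantile(bias_tbl$mean_pct_right[ok], c(0.25, 0.75), names = FALSE)
  outer_quartile <- ok & (bias_tbl$mean_pct_right <= q[1] |
                            bias_tbl$mean_pct_right >= q[2])
  consistent <- vapply(bias_tbl$trial_sign, function(s) {
    length(s) > 0L && all(s != 0L) && length(unique(s)) == 1L
  }, logical(1))
  bias_tbl[outer_quartile & consistent, , drop = FALSE]
}
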