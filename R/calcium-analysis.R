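# dF/F normalization and baseline-noise-scaled responder classification.

#' Compute dF/F traces and baseline noise
#'
#' Normalizes raw fluorescence as `(F_t - F0) / F0`, where `F0` is the mean
#' intensity during the first baseline period -- the opening light epoch of
#' the (by default trial-averaged) trace. `S`, the standard deviation of
#' dF/F over that baseline, scales the responder threshold. dF/F is
#' invariant under positive rescaling of the raw intensities.
#'
#' @param traces Long data frame `neuron_id, trial, frame, intensity`.
#' @param epochs Data frame `trial, frame, label` (labels `"light"`/
#'   `"dark"`, identical across trials).
#' @param frame_rate_hz Acquisition rate, used to timestamp frames.
#' @param average_trials Average intensities across trials before
#'   normalizing (the default, matching analysis of mean-of-trials traces);
#'   set `FALSE` to normalize each trial separately.
#' @return A `dff_set` list: `dff` (tibble `neuron_id[, trial], frame,
#'   time_s, epoch, label, dff`), `neurons` (tibble `neuron_id[, trial],
#'   f0, s`), plus `frame_rate_hz` and `average_trials`.
#' @export
compute_dff <- function(traces, epochs, frame_rate_hz = 0.96,
                        average_trials = TRUE) {
  stopifnot(all(c("neuron_id", "trial", "frame", "intensity") %in% names(traces)),
            all(c("trial", "frame", "label") %in% names(epochs)))
  assert_pos(frame_rate_hz, "frame_rate_hz")
  lab <- epochs[epochs$trial == epochs$trial[1], c("frame", "label")]
  lab <- lab[order(lab$frame), ]
  chk <- tapply(epochs$label, epochs$frame, function(x) length(unique(x)) == 1L)
  if (!all(chk)) stop("epoch labels differ across trials", call. = FALSE)
  if (!setequal(unique(traces$frame), lab$frame)) {
    stop("trace frames and epoch frames are misaligned", call. = FALSE)
  }
  lab$epoch <- cumsum(c(TRUE, lab$label[-1] != head(lab$label, -1)))
  if (lab$label[1] != "light") {
    stop("the first epoch must be the baseline light period", call. = FALSE)
  }
  lab$time_s <- (lab$frame - 1) / frame_rate_hz

  grp_cols <- if (average_trials) "neuron_id" else c("neuron_id", "trial")
  d <- traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_cols, "frame")))) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::inner_join(lab, by = "frame") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp_cols, "frame"))))
  base <- d |>
    dplyr::filter(.data$epoch == 1L) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(f0 = mean(.data$intensity), .groups = "drop")
  if (any(base$f0 <= 0)) {
    stop("baseline mean fluorescence must be positive for dF/F", call. = FALSE)
  }
  d <- d |>
    dplyr::inner_join(base, by = grp_cols) |>
    dplyr::mutate(dff = (.data$intensity - .data$f0) / .data$f0)
  s_tbl <- d |>
    dplyr::filter(.data$epoch == 1L) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(s = sd(.data$dff), .groups = "drop")
  neurons <- dplyr::inner_join(base, s_tbl, by = grp_cols)
  dff <- d[, c(grp_cols, "frame", "time_s", "epoch", "label", "dff")]
  structure(list(dff = tibble::as_tibble(dff),
                 neurons = tibble::as_tibble(neurons),
                 frame_rate_hz = frame_rate_hz,
                 average_trials = average_trials,
                 epoch_labels = lab),
            class = "dff_set")
}

# First frame index (within an ordered dff vector) starting a run of at
# least `len` TRUE values; NA when no such run exists.
first_run_start <- function(above, len) {
  r <- rle(above)
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(cumsum(c(1L, r$lengths))[hit[1]])
}

#' Classify neurons as light-OFF / light-ON responders
#'
#' A neuron is a responder when its dF/F exceeds `n_sd` baseline standard
#' deviations on at least `n_consecutive` successive frames. The onset is
#' the first frame of the earliest qualifying run; onsets in a dark epoch
#' yield class `"OFF"`, onsets in a light epoch that follows a dark epoch
#' yield `"ON"`, anything else (including excursions confined to the
#' baseline) stays `"none"`. Neurons whose baseline sd is exactly zero are
#' still classified (any positive excursion qualifies) and flagged via
#' `zero_baseline_sd`.
#'
#' @param x A [compute_dff()] result.
#' @param n_sd Threshold multiple of the baseline sd (default 3).
#' @param n_consecutive Required run length in frames (default 3).
#' @return Tibble `neuron_id[, trial], class, onset_frame, onset_time_s,
#'   zero_baseline_sd`.
#' @export
classify_responders <- function(x, n_sd = 3, n_consecutive = 3L) {
  stopifnot(inherits(x, "dff_set"))
  n_consecutive <- assert_count(n_consecutive, "n_consecutive")
  grp_cols <- if (x$average_trials) "neuron_id" else c("neuron_id", "trial")
  lab <- x$epoch_labels
  epoch_first_label <- tapply(lab$label, lab$epoch, `[`, 1L)
  prev_dark <- c(FALSE, head(epoch_first_label, -1) == "dark")
  calls <- x$dff |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$frame), ]
      s <- x$neurons$s[match_rows(x$neurons, key, grp_cols)]
      idx <- first_run_start(d$dff > n_sd * s, n_consecutive)
      if (is.na(idx)) {
        return(tibble::tibble(class = "none", onset_frame = NA_integer_,
                              onset_time_s = NA_real_, zero_baseline_sd = s == 0))
      }
      ep <- d$epoch[idx]
      cls <- if (d$label[idx] == "dark") "OFF"
             else if (d$label[idx] == "light" && prev_dark[ep]) "ON"
             else "none"
      tibble::tibble(class = cls, onset_frame = d$frame[idx],
                     onset_time_s = d$time_s[idx], zero_baseline_sd = s == 0)
    }) |>
    dplyr::ungroup()
  calls
}

# Row index in `tbl` matching the one-row key on `cols`.
match_rows <- function(tbl, key, cols) {
  hit <- rep(TRUE, nrow(tbl))
  for (cl in cols) hit <- hit & tbl[[cl]] == key[[cl]]
  which(hit)[1]
}

#' Response-timing metrics for classified responders
#'
#' For each responder, locates the stimulus that initiates its response
#' epoch (light offset for OFF, light restoration for ON), the peak dF/F
#' within that epoch, the latency from stimulus to onset, and the time from
#' stimulus to the first post-peak half-maximal crossing (linear
#' interpolation between frames). Traces that never fall back to half-max
#' are flagged unreturned with a missing time.
#'
#' @param x A [compute_dff()] result.
#' @param calls A [classify_responders()] result.
#' @param return_window_s Window (seconds from stimulus) defining the
#'   `returned_within` flag (default 30).
#' @return `calls` augmented with `stim_frame, peak_dff, latency_s,
#'   time_to_half_max_s, half_max_reached, returned_within_30s`.
#' @export
response_timing <- function(x, calls, return_window_s = 30) {
  stopifnot(inherits(x, "dff_set"))
  grp_cols <- if (x$average_trials) "neuron_id" else c("neuron_id", "trial")
  lab <- x$epoch_labels
  out <- calls
  out$stim_frame <- NA_integer_
  out$peak_dff <- NA_real_
  out$latency_s <- NA_real_
  out$time_to_half_max_s <- NA_real_
  out$half_max_reached <- NA
  out$returned_within_30s <- NA
  for (i in seq_len(nrow(out))) {
    if (!(out$class[i] %in% c("OFF", "ON"))) next
    d <- x$dff
    for (cl in grp_cols) d <- d[d[[cl]] == out[[cl]][i], ]
    d <- d[order(d$frame), ]
    onset_idx <- match(out$onset_frame[i], d$frame)
    ep <- d$epoch[onset_idx]
    ep_idx <- which(d$epoch == ep)
    stim_idx <- ep_idx[1]
    peak_rel <- which.max(d$dff[ep_idx])
    peak_idx <- ep_idx[peak_rel]
    peak <- d$dff[peak_idx]
    t_stim <- d$time_s[stim_idx]
    out$stim_frame[i] <- d$frame[stim_idx]
    out$peak_dff[i] <- peak
    out$latency_s[i] <- d$time_s[onset_idx] - t_stim
    post <- which(seq_len(nrow(d)) > peak_idx & d$dff <= peak / 2)
    if (length(post) == 0L) {
      out$half_max_reached[i] <- FALSE
      out$returned_within_30s[i] <- FALSE
    } else {
      j <- post[1]
      half <- peak / 2
      t_cross <- if (d$dff[j - 1] == d$dff[j]) d$time_s[j] else {
        d$time_s[j - 1] + (d$dff[j - 1] - half) / (d$dff[j - 1] - d$dff[j]) *
          (d$time_s[j] - d$time_s[j - 1])
      }
      out$time_to_half_max_s[i] <- t_cross - t_stim
      out$half_max_reached[i] <- TRUE
      out$returned_within_30s[i] <- (t_cross - t_stim) <= return_window_s
    }
  }
  out
}

#' Cohort-level responder summary
#'
#' Fractions of OFF-, ON-, and non-responsive neurons over all classified
#' neurons, and -- when timing metrics are present -- the fraction of OFF
#' responders returning to half-maximal activity within 30 s plus the mean
#' and sd of their time to half-max. Percentages are reported unrounded;
#' raw counts are included so any rounding convention can be recomputed.
#'
#' @param calls A [classify_responders()] (optionally
#'   [response_timing()]-augmented) tibble.
#' @return One-row tibble of counts, percentages, and timing summaries.
#' @export
cohort_response_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("no responder calls supplied", call. = FALSE)
  n <- nrow(calls)
  n_off <- sum(calls$class == "OFF")
  n_on <- sum(calls$class == "ON")
  out <- tibble::tibble(
    n_neurons = n, n_off = n_off, n_on = n_on, n_none = n - n_off - n_on,
    pct_off = 100 * n_off / n, pct_on = 100 * n_on / n,
    pct_none = 100 * (n - n_off - n_on) / n
  )
  if ("returned_within_30s" %in% names(calls) && n_off > 0) {
    off <- calls[calls$class == "OFF", ]
    out$n_off_returned_30s <- sum(off$returned_within_30s, na.rm = TRUE)
    out$frac_off_returned_30s <- out$n_off_returned_30s / n_off
    out$mean_time_to_half_max_s <- mean(off$time_to_half_max_s, na.rm = TRUE)
    out$sd_time_to_half_max_s <- sd(off$time_to_half_max_s, na.rm = TRUE)
  }
  out
}
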