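# End-to-end orchestration: generate or load data, compute metrics, run the
# null-model tests, classify responders, and serialize reproducible reports.

#' Pipeline run configuration
#'
#' Bundles everything one run needs. Exactly one data source per mode:
#' behavior takes either a generator config (`cohort`) or a turn-event CSV
#' (`turn_csv`); calcium takes either a `traces` generator config or a pair
#' of trace/epoch CSVs. The seed is recorded in every output.
#'
#' @param mode `"behavior"`, `"calcium"`, or `"both"`.
#' @param cohort Optional [cohort_config()] for synthetic behavior data.
#' @param turn_csv Optional path to a turn-event CSV.
#' @param traces Optional [trace_config()] for synthetic calcium data.
#' @param trace_csv,epoch_csv Optional paths to trace/epoch CSVs.
#' @param p_same Same-direction probability for the behavioral null model;
#'   defaults to the cohort generator's `lock_prob` (or 0.814).
#' @param n_sims_mc Simulations for [mc_bias_test()] (default 10,000).
#' @param n_sims_perm Simulations for [permutation_match_test()] (default
#'   100,000).
#' @param tail Tail level for the bias test (default 0.10).
#' @param hist_bin_width Bin width for the expected histogram.
#' @param min_turns,n_trials_required Analysis filters (see
#'   [percent_rightward()]).
#' @param seed Master seed; pipeline stages use derived substreams.
#' @param out_dir Optional output directory; when set, reports and tables
#'   are written there.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("behavior", "calcium", "both"),
                       cohort = NULL, turn_csv = NULL,
                       traces = NULL, trace_csv = NULL, epoch_csv = NULL,
                       p_same = NULL, n_sims_mc = 10000L,
                       n_sims_perm = 100000L, tail = 0.10,
                       hist_bin_width = 4, min_turns = 3L,
                       n_trials_required = 4L, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("behavior", "both")) {
    if (is.null(cohort) == is.null(turn_csv)) {
      stop("behavior mode needs exactly one of `cohort` or `turn_csv`",
           call. = FALSE)
    }
    if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_config"))
  }
  if (mode %in% c("calcium", "both")) {
    has_gen <- !is.null(traces)
    has_csv <- !is.null(trace_csv) && !is.null(epoch_csv)
    if (has_gen == has_csv) {
      stop("calcium mode needs exactly one of `traces` or `trace_csv` + `epoch_csv`",
           call. = FALSE)
    }
    if (has_gen) stopifnot(inherits(traces, "trace_config"))
  }
  structure(list(mode = mode, cohort = cohort, turn_csv = turn_csv,
                 traces = traces, trace_csv = trace_csv, epoch_csv = epoch_csv,
                 p_same = p_same, n_sims_mc = n_sims_mc,
                 n_sims_perm = n_sims_perm, tail = tail,
                 hist_bin_width = hist_bin_width, min_turns = min_turns,
                 n_trials_required = n_trials_required, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the behavioral bias pipeline
#'
#' Generates (or loads) a turn-event cohort, builds the cohort bias table,
#' runs the Match-Index permutation test and the Monte-Carlo bias test on
#' the included larvae, derives the expected percent-rightward histogram,
#' and computes effect sizes for the left- versus right-classified groups.
#' Reruns with the same configuration and seed produce byte-identical
#' serialized reports.
#'
#' @param config A [run_config()] with behavior inputs.
#' @return A `behavior_report` list: `cohort_bias` table, test results,
#'   `expected_histogram`, `effect_sizes`, `exclusions` log, and run
#'   metadata. Written to `config$out_dir` when set (see
#'   [write_behavior_report()]).
#' @export
run_behavior_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$turn_csv)) {
    turns <- read_turn_events(config$turn_csv)
    truth <- NULL
    p_same <- config$p_same %||% 0.814
  } else {
    cohort_cfg <- config$cohort
    if (is.null(cohort_cfg$seed)) {
      cohort_cfg$seed <- substream_seed(config$seed, 1L, stream = 101L)
    }
    gen <- generate_turn_cohort(cohort_cfg)
    turns <- gen$turns
    truth <- gen$larvae
    p_same <- config$p_same %||% cohort_cfg$lock_prob
  }
  bias <- cohort_bias_table(turns, min_turns = config$min_turns,
                            n_trials_required = config$n_trials_required)

  n_total <- nrow(bias)
  included <- bias$included
  mi_ok <- !is.na(bias$match_index)
  exclusions <- list(
    n_larvae = n_total,
    excluded_by_min_turns = sum(!included),
    excluded_from_match_index = sum(!mi_ok),
    min_turns = config$min_turns,
    n_trials_required = config$n_trials_required
  )

  counts <- turns |>
    dplyr::filter(.data$larva_id %in% bias$larva_id[included],
                  .data$trial <= config$n_trials_required) |>
    dplyr::count(.data$larva_id, .data$trial, name = "n_turns")
  if (nrow(counts) == 0L) {
    return(structure(list(empty = TRUE, exclusions = exclusions,
                          meta = report_meta(config)),
                     class = "behavior_report"))
  }
  observed <- bias$mean_pct_right[included][order(bias$larva_id[included])]
  mc <- mc_bias_test(observed, counts, p_same = p_same,
                     n_sims = config$n_sims_mc, tail = config$tail,
                     seed = substream_seed(config$seed, 2L, stream = 102L))
  mi_test <- permutation_match_test(bias$match_index[mi_ok],
                                    bias$n_valid_followups[mi_ok],
                                    n_sims = config$n_sims_perm,
                                    seed = substream_seed(config$seed, 3L,
                                                          stream = 103L))
  hist <- null_histogram(mc, bin_width = config$hist_bin_width)

  eff <- NULL
  l_vals <- bias$mean_pct_right[bias$class == "L" & included]
  r_vals <- bias$mean_pct_right[bias$class == "R" & included]
  if (length(l_vals) >= 2L && length(r_vals) >= 2L) {
    eff <- list(contrast = "right vs left classified, mean % rightward",
                cohens_d = cohens_d(r_vals, l_vals),
                rank_biserial_r = rank_biserial_r(r_vals, l_vals))
  }

  report <- structure(list(
    empty = FALSE,
    cohort_bias = bias,
    ground_truth = truth,
    mc_bias_test = mc,
    match_test = mi_test,
    expected_histogram = hist,
    effect_sizes = eff,
    exclusions = exclusions,
    p_same = p_same,
    meta = report_meta(config)
  ), class = "behavior_report")
  if (!is.null(config$out_dir)) write_behavior_report(report, config$out_dir)
  report
}

#' Run the calcium responder pipeline
#'
#' Generates (or loads) fluorescence traces with epoch labels, computes
#' trial-averaged dF/F, classifies light-OFF/ON responders, measures
#' response timing, and summarizes the cohort. When synthetic ground truth
#' is available, the report carries a self-check block with recovery
#' sensitivity and specificity.
#'
#' @param config A [run_config()] with calcium inputs.
#' @return A `calcium_report` list: per-neuron `calls`, `summary`,
#'   optional `self_check`, and run metadata.
#' @export
run_calcium_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$trace_csv)) {
    traces <- read_calcium_traces(config$trace_csv)
    epochs <- read_epoch_labels(config$epoch_csv)
    truth <- NULL
    rate <- config$traces$frame_rate_hz %||% 0.96
  } else {
    trace_cfg <- config$traces
    if (is.null(trace_cfg$seed)) {
      trace_cfg$seed <- substream_seed(config$seed, 1L, stream = 201L)
    }
    gen <- generate_calcium_cohort(trace_cfg)
    traces <- gen$traces
    epochs <- gen$epochs
    truth <- gen$truth
    rate <- trace_cfg$frame_rate_hz
  }
  dff <- compute_dff(traces, epochs, frame_rate_hz = rate)
  calls <- classify_responders(dff)
  calls <- response_timing(dff, calls)
  summary <- cohort_response_summary(calls)

  self_check <- NULL
  if (!is.null(truth)) {
    merged <- dplyr::inner_join(calls, truth, by = "neuron_id",
                                suffix = c("", "_truth"))
    planted <- merged$class_truth %in% c("OFF", "ON")
    self_check <- list(
      sensitivity = if (any(planted)) {
        mean(merged$class[planted] == merged$class_truth[planted])
      } else NA_real_,
      specificity = if (any(!planted)) {
        mean(merged$class[!planted] == "none")
      } else NA_real_
    )
  }
  report <- structure(list(
    calls = calls, summary = summary, self_check = self_check,
    ground_truth = truth, meta = report_meta(config)
  ), class = "calcium_report")
  if (!is.null(config$out_dir)) write_calcium_report(report, config$out_dir)
  report
}

report_meta <- function(config) {
  list(package = "turnbias",
       version = as.character(utils::packageVersion("turnbias")),
       seed = config$seed,
       mode = config$mode,
       n_sims_mc = config$n_sims_mc,
       n_sims_perm = config$n_sims_perm,
       tail = config$tail,
       mi_denominator = "valid_nonzero_followups_only",
       threshold_rule = "quantiles of pooled simulated distribution")
}

#' Serialize pipeline reports
#'
#' Writes the machine-readable report: `behavior_report.json` (tests,
#' exclusion log, effect sizes, metadata -- bulky simulation vectors are
#' dropped), `cohort_bias.csv`, and `expected_histogram.csv`; respectively
#' `calcium_report.json` and `responder_calls.csv`. Output carries no
#' timestamps, so identical runs produce identical bytes.
#'
#' @param report A pipeline report.
#' @param dir Output directory (created if needed).
#' @return The report, invisibly.
#' @export
write_behavior_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!report$empty) {
    bias_out <- report$cohort_bias
    bias_out$trial_sign <- vapply(bias_out$trial_sign, paste, character(1),
                                  collapse = ";")
    utils::write.csv(bias_out, file.path(dir, "cohort_bias.csv"),
                     row.names = FALSE)
    utils::write.csv(report$expected_histogram,
                     file.path(dir, "expected_histogram.csv"),
                     row.names = FALSE)
  }
  json <- list(
    meta = report$meta,
    exclusions = report$exclusions,
    empty = report$empty
  )
  if (!report$empty) {
    mc <- report$mc_bias_test
    json$mc_bias_test <- list(
      n_larvae = mc$n_larvae, n_sims = mc$n_sims, tail = mc$tail,
      p_same = mc$p_same, thresholds = as.list(mc$thresholds),
      observed_exceedance = mc$observed_exceedance,
      p_value = mc$p_value, p_is_bound = mc$p_is_bound,
      threshold_rule = mc$threshold_rule)
    mt <- report$match_test
    json$match_test <- list(
      n_larvae = mt$n_larvae, n_sims = mt$n_sims,
      observed_mean = mt$observed_mean, alternative = mt$alternative,
      p_value = mt$p_value, p_is_bound = mt$p_is_bound)
    json$effect_sizes <- report$effect_sizes
    json$p_same <- report$p_same
  }
  jsonlite::write_json(json, file.path(dir, "behavior_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @rdname write_behavior_report
#' @export
write_calcium_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$calls, file.path(dir, "responder_calls.csv"),
                   row.names = FALSE)
  json <- list(meta = report$meta,
               summary = as.list(report$summary),
               self_check = report$self_check)
  jsonlite::write_json(json, file.path(dir, "calcium_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
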