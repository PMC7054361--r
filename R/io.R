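# Flat-file interfaces: plain CSV schemas for turn events, heading series,
# calcium traces, and epoch labels.

read_checked_csv <- function(path, required, validators = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("%s: missing required columns: %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in names(validators)) {
    bad <- which(!validators[[col]](d[[col]]))
    if (length(bad)) {
      stop(sprintf("%s: invalid values in column `%s` at rows: %s",
                   basename(path), col,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  tibble::as_tibble(d)
}

#' Read and write turn-event tables
#'
#' Turn-event CSVs have columns `larva_id, trial, event_index, direction,
#' time_s`, with directions restricted to -1 (leftward) and +1 (rightward).
#' Malformed files fail with the offending rows named.
#'
#' @param path File path.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @export
read_turn_events <- function(path) {
  read_checked_csv(path,
    required = c("larva_id", "trial", "event_index", "direction", "time_s"),
    validators = list(direction = function(x) x %in% c(-1, 1),
                      trial = function(x) !is.na(x) & x >= 1))
}

#' @rdname read_turn_events
#' @param turns Turn-event data frame.
#' @export
write_turn_events <- function(turns, path) {
  utils::write.csv(turns, path, row.names = FALSE)
  invisible(turns)
}

#' Read and write heading-change series
#'
#' Heading CSVs have columns `larva_id, trial, time_s, dtheta_deg` (signed
#' angular path changes in degrees, rightward positive).
#'
#' @param path File path.
#' @export
read_heading_series <- function(path) {
  read_checked_csv(path,
    required = c("larva_id", "trial", "time_s", "dtheta_deg"),
    validators = list(time_s = function(x) !is.na(x)))
}

#' @rdname read_heading_series
#' @param heading Heading data frame.
#' @export
write_heading_series <- function(heading, path) {
  utils::write.csv(heading, path, row.names = FALSE)
  invisible(heading)
}

#' Read and write calcium traces and epoch labels
#'
#' Trace CSVs have columns `neuron_id, trial, frame, intensity`; epoch CSVs
#' have `trial, frame, label` with labels `"light"` or `"dark"`.
#'
#' @param path File path.
#' @export
read_calcium_traces <- function(path) {
  read_checked_csv(path,
    required = c("neuron_id", "trial", "frame", "intensity"),
    validators = list(intensity = function(x) !is.na(x) & x >= 0))
}

#' @rdname read_calcium_traces
#' @export
read_epoch_labels <- function(path) {
  read_checked_csv(path,
    required = c("trial", "frame", "label"),
    validators = list(label = function(x) x %in% c("light", "dark")))
}

#' @rdname read_calcium_traces
#' @param traces Trace data frame.
#' @export
write_calcium_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(traces)
}

#' @rdname read_calcium_traces
#' @param epochs Epoch data frame.
#' @export
write_epoch_labels <- function(epochs, path) {
  utils::write.csv(epochs, path, row.names = FALSE)
  invisible(epochs)
}
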