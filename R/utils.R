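# Shared validation and RNG plumbing.

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible substream seed
#'
#' One master seed governs a whole run; per-unit (larva, neuron, pipeline
#' stage) seeds are derived deterministically from it with a fixed integer
#' mix, so enlarging a cohort never reshuffles the units that were already
#' there. All results stay below 2^31 so they are valid R integer seeds.
#'
#' @param master Master integer seed.
#' @param index Unit index (1-based).
#' @param stream Optional stream offset separating independent generator
#'   families that share a master seed.
#' @return An integer seed.
#' @export
substream_seed <- function(master, index, stream = 0L) {
  m <- 2147483647 # 2^31 - 1
  x <- (abs(as.numeric(master)) %% m)
  x <- (x * 48271 + as.numeric(index) * 16807 + as.numeric(stream) * 69621) %% (m - 1)
  as.integer(x + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
# A NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
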