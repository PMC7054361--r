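test_that("NTA sums signed and unsigned path changes", {
  s <- tibble::tibble(time_s = c(1, 2, 3), dtheta_deg = c(10, 20, -5))
  nta <- compute_nta(s, window = c(0, 30), min_span_s = 0)
  expect_equal(nta$nta_deg, 25)
  expect_equal(nta$abs_nta_deg, 35)
  # mirrored series: NTA negates, absolute NTA unchanged
  m <- compute_nta(tibble::tibble(time_s = s$time_s, dtheta_deg = -s$dtheta_deg),
                   min_span_s = 0)
  expect_equal(m$nta_deg, -25)
  expect_equal(m$abs_nta_deg, 35)
})

test_that("trials with under 10 s of data are invalid; empty series report missing", {
  s <- tibble::tibble(time_s = seq(0, 8, by = 0.2), dtheta_deg = 1)
  nta <- compute_nta(s)
  expect_false(nta$valid)
  e <- compute_nta(tibble::tibble(time_s = numeric(0), dtheta_deg = numeric(0)))
  expect_false(e$valid)
  expect_true(is.na(e$nta_deg))
  full <- compute_nta(tibble::tibble(time_s = seq(0, 29.9, by = 0.1),
                                     dtheta_deg = 0))
  expect_true(full$valid)
})

test_that("left/right classification follows the trial-1 sign with ties unclassified", {
  expect_equal(classify_lr(c(120, -0.5, 0)), c("R", "L", "unclassified"))
  expect_equal(classify_lr(5, valid = FALSE), "unclassified")
})

test_that("Match Index counts matching follow-up signs over valid follow-ups", {
  expect_equal(match_index(c(1, 2, 3, 4))$match_index, 1.0)
  expect_equal(match_index(c(1, -2, -3, 4))$match_index, 1 / 3)
  # an excluded follow-up drops from numerator and denominator
  mi <- match_index(c(1, 99, -2, 3), valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(mi$match_index, 1 / 2)
  expect_equal(mi$n_valid_followups, 2L)
  # trial-1 tie or invalid trial 1: undefined
  expect_true(is.na(match_index(c(0, 1, 1, 1))$match_index))
  expect_true(is.na(match_index(c(1, 1, 1, 1),
                                valid = c(FALSE, TRUE, TRUE, TRUE))$match_index))
  # too few informative follow-ups: undefined
  expect_true(is.na(match_index(c(1, 1, 0, 0))$match_index))
})

test_that("Match Index over four fully valid trials is confined to {0, 1/3, 2/3, 1}", {
  for (signs in asplit(as.matrix(expand.grid(rep(list(c(-1, 1)), 4))), 1)) {
    mi <- match_index(as.numeric(signs))$match_index
    expect_true(mi %in% c(0, 1 / 3, 2 / 3, 1))
  }
})

test_that("percent rightward applies the three-turns-per-trial filter", {
  turns <- tibble::tibble(
    larva_id = c(rep(1L, 12), rep(2L, 11)),
    trial = c(rep(1:4, each = 3), rep(1:4, c(3, 3, 3, 2))),
    direction = c(rep(c(1L, 1L, -1L), 4), rep(1L, 11)))
  pr <- percent_rightward(turns)
  expect_equal(pr$trials$pct_right[1], 100 * 2 / 3, tolerance = 1e-12)
  expect_true(pr$larvae$included[pr$larvae$larva_id == 1])
  expect_false(pr$larvae$included[pr$larvae$larva_id == 2]) # a 2-turn trial
  expect_error(percent_rightward(turns[0, ]), "no turn events")
  bad <- turns; bad$direction[3] <- 0L
  expect_error(percent_rightward(bad), "offending rows")
})

test_that("per-larva mean is the unweighted mean of per-trial percentages", {
  turns <- tibble::tibble(
    larva_id = 1L,
    trial = rep(1:4, c(10, 4, 3, 3)),
    direction = c(rep(1L, 10), rep(1L, 4), rep(-1L, 3), rep(-1L, 3)))
  pr <- percent_rightward(turns)
  expect_equal(pr$larvae$mean_pct_right, 50)
})

test_that("percent-based classification uses the 33/66 thresholds", {
  expect_equal(classify_by_percent(c(20, 70, 50)), c("L", "R", "unclassified"))
  expect_error(classify_by_percent(50, low = 70, high = 30), "below")
  expect_error(classify_by_percent(120), "0, 100")
})

test_that("bias decomposes into magnitude and direction", {
  d <- decompose_bias(c(70, 30, 50))
  expect_equal(d$magnitude, c(20, 20, 0))
  expect_equal(d$direction, c(1, -1, 0))
})

test_that("consistent-larva selection needs outer-quartile strength and uniform direction", {
  set.seed(5)
  cfg <- cohort_config(n_larvae = 20, seed = 31)
  bias <- cohort_bias_table(generate_turn_cohort(cfg)$turns)
  sel <- select_consistent_larvae(bias)
  q <- quantile(bias$mean_pct_right, c(0.25, 0.75), names = FALSE)
  expect_true(all(sel$mean_pct_right <= q[1] | sel$mean_pct_right >= q[2]))
  expect_true(all(vapply(sel$trial_sign,
                         function(s) all(s != 0) && length(unique(s)) == 1,
                         logical(1))))
  # a larva in the outer quartile but with one opposite trial is dropped
  mixed <- bias[vapply(bias$trial_sign, function(s) length(unique(s)) > 1,
                       logical(1)) &
                  (bias$mean_pct_right <= q[1] | bias$mean_pct_right >= q[2]), ]
  if (nrow(mixed) > 0) {
    expect_false(any(mixed$larva_id %in% sel$larva_id))
  }
  expect_error(select_consistent_larvae(bias[1:3, ]), "at least 4")
})

test_that("mirroring every turn flips classes and directions but preserves the rest", {
  for (seed in c(101, 202, 303)) {
    cfg <- cohort_config(n_larvae = 15, seed = seed)
    turns <- generate_turn_cohort(cfg)$turns
    flipped <- turns
    flipped$direction <- -flipped$direction
    a <- cohort_bias_table(turns)
    b <- cohort_bias_table(flipped)
    expect_equal(b$mean_pct_right, 100 - a$mean_pct_right)
    expect_identical(b$included, a$included)
    expect_equal(b$match_index, a$match_index)
    expect_identical(b$n_valid_followups, a$n_valid_followups)
    expect_equal(b$bias_magnitude, a$bias_magnitude)
    expect_equal(b$bias_direction, -a$bias_direction)
    swap <- c(L = "R", R = "L", unclassified = "unclassified")
    expect_identical(b$class, unname(swap[a$class]))
  }
})

test_that("mirroring a heading series flips NTA-based classes symmetrically", {
  h <- generate_heading_series(step_mean = 3, seed = 17)
  nta <- compute_nta(h)
  m <- compute_nta(tibble::tibble(time_s = h$time_s, dtheta_deg = -h$dtheta_deg))
  expect_equal(m$nta_deg, -nta$nta_deg)
  expect_identical(classify_lr(m$nta_deg),
                   c(R = "L", L = "R")[[classify_lr(nta$nta_deg)]])
})

test_that("null cohorts center on 50% rightward and Match Index 0.5", {
  cfg <- cohort_config(n_larvae = 400, bias_strength = 0.5, seed = 23)
  bias <- cohort_bias_table(generate_turn_cohort(cfg)$turns)
  expect_equal(mean(bias$mean_pct_right), 50, tolerance = 0.06)
  expect_equal(mean(bias$match_index, na.rm = TRUE), 0.5, tolerance = 0.1)
})
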