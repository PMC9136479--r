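a <- anatomy_params()
fb <- golgi_feedback_params()

test_that("feedback parameter invariants are enforced", {
  expect_error(golgi_feedback_params(veto_max = 1.5), "veto_max")
  expect_error(golgi_feedback_params(damping = 0), "damping")
  expect_error(golgi_feedback_params(tol = -1), "tol")
  expect_error(golgi_feedback_params(local_weight = 0.5), "local_weight")
  expect_error(golgi_feedback_params(neighbor_weight = 2), "neighbor_weight")
})

test_that("Golgi input count is the linear contact fraction", {
  expect_equal(golgi_active_inputs(0, a), 0)
  expect_equal(golgi_active_inputs(1200, a), 1600 * 1200 / 350000)
  expect_equal(golgi_active_inputs(350000, a), 1600)
  expect_error(golgi_active_inputs(-5, a), "beam_pf_total")
})

test_that("veto sigmoid has exact floor, saturation and midpoint", {
  expect_equal(veto_from_inputs(3.9, fb, a), 0)
  expect_equal(veto_from_inputs(0, fb, a), 0)
  expect_equal(veto_from_inputs(16, fb, a), fb$veto_max)
  expect_equal(veto_from_inputs(25, fb, a), fb$veto_max)
  expect_equal(veto_from_inputs(fb$sigmoid_midpoint, fb, a),
    fb$veto_max / 2,
    tolerance = 1e-9
  )
  grid <- seq(0, 20, by = 0.05)
  expect_true(all(diff(veto_from_inputs(grid, fb, a)) >= 0))
  v <- veto_from_inputs(grid, fb, a)
  expect_true(all(v >= 0 & v <= fb$veto_max))
})

test_that("field drive reduces to the plain beam total at degenerate weights", {
  xg <- matrix(sample(3:30, 100, replace = TRUE), 5, 20)
  counts <- matrix(expected_firing_count(as.vector(xg), 0, a), 5, 20)
  plain <- golgi_feedback_params(
    local_weight = 1, neighbor_weight = 0, basal_boost = 0
  )
  for (b in c(1, 3, 5)) {
    expect_equal(field_drive(counts, xg, b, 7, plain, a), sum(counts[b, ]))
  }
  zero <- matrix(0L, 5, 20)
  expect_equal(field_drive(zero, zero, 3, 1, fb, a), 0)
  expect_error(field_drive(counts, xg, 6, 1, fb, a), "out of range")
})

test_that("basal term equals the brute-force hypergeometric tail", {
  # x = 30 active of 100, 12 basal contacts, at least 4 hits
  counts <- matrix(0, 5, 20)
  xg <- matrix(30L, 5, 20)
  plain <- golgi_feedback_params(
    local_weight = 1, neighbor_weight = 0, basal_boost = 1
  )
  expect_equal(
    field_drive(counts, xg, 3, 1, plain, a),
    enum_hyper_tail(30, 12, 4),
    tolerance = 1e-12
  )
  # probability rises with x
  p_lo <- field_drive(counts, matrix(10L, 5, 20), 3, 1, plain, a)
  p_hi <- field_drive(counts, matrix(28L, 5, 20), 3, 1, plain, a)
  expect_lt(p_lo, p_hi)
})

test_that("disabling feedback leaves the threshold population untouched", {
  xg <- matrix(sample(3:30, 100, replace = TRUE), 5, 20)
  off <- golgi_feedback_params(veto_max = 0)
  res <- run_beam_regulation(xg, off, a)
  expect_equal(res$beam_totals, res$unregulated_totals)
  expect_true(res$converged)
})

test_that("regulation only removes cells and reports sane diagnostics", {
  set.seed(3)
  for (i in 1:5) {
    xg <- matrix(sample(3:30, 100, replace = TRUE), 5, 20)
    res <- run_beam_regulation(xg, fb, a)
    expect_lte(res$middle_beam_total, res$middle_beam_unregulated)
    expect_true(all(res$beam_totals <= res$unregulated_totals + 1e-9))
    expect_true(all(res$fields$count_firing <= res$fields$count_threshold + 1e-9))
    expect_true(all(res$fields$p_veto >= 0 & res$fields$p_veto <= fb$veto_max))
    expect_lte(res$iterations, fb$max_iter)
    expect_true(res$converged)
  }
})

test_that("expectation mode is bit-identical across repeated runs", {
  xg <- matrix(15L, 5, 20)
  r1 <- run_beam_regulation(xg, fb, a)
  r2 <- run_beam_regulation(xg, fb, a)
  expect_identical(r1$fields, r2$fields)
  expect_identical(r1$middle_beam_total, r2$middle_beam_total)
})

test_that("realization mode stays below the threshold count too", {
  set.seed(5)
  xg <- matrix(sample(3:30, 100, replace = TRUE), 5, 20)
  res <- run_beam_regulation(xg, golgi_feedback_params(mode = "realization"), a)
  expect_true(all(res$fields$count_firing <= a$n_grc_per_field))
  expect_lte(res$middle_beam_total, res$middle_beam_unregulated)
})

test_that("multi-trial runs are reproducible and tidy", {
  t1 <- run_trials(n_trials = 4, seed = 9)
  t2 <- run_trials(n_trials = 4, seed = 9)
  expect_identical(t1$trials, t2$trials)
  expect_identical(t1$fields, t2$fields)
  expect_equal(nrow(t1$fields), 4 * 5 * 20)
  expect_named(
    tidy(t1),
    c("trial", "middle_beam_total", "middle_beam_unregulated",
      "middle_beam_all_inputs", "iterations", "converged")
  )
  expect_equal(nrow(glance(t1)), 1)
  expect_true(all(t1$trials$middle_beam_total <=
    t1$trials$middle_beam_unregulated))
})

test_that("a degenerate zero input range yields all-zero totals", {
  t0 <- run_trials(n_trials = 1, x_range = c(0, 0), seed = 1)
  expect_equal(t0$trials$middle_beam_total, 0)
  expect_equal(t0$trials$middle_beam_unregulated, 0)
})

test_that("calibration returns a single candidate unchanged", {
  cal <- calibrate_gain(fb, a,
    input_ranges = list(c(10, 25), c(15, 30)),
    seed = 2, veto_max_grid = fb$veto_max,
    steepness_grid = fb$sigmoid_steepness,
    n_trials = 3, high_range = NULL
  )
  expect_equal(cal$veto_max, fb$veto_max)
  expect_equal(cal$sigmoid_steepness, fb$sigmoid_steepness)
  expect_true(is.finite(attr(cal, "spread")))
})

test_that("calibration beats weak feedback on plateau spread", {
  cal <- calibrate_gain(fb, a,
    input_ranges = list(c(5, 25), c(15, 30)),
    seed = 4, veto_max_grid = c(0.1, fb$veto_max),
    steepness_grid = fb$sigmoid_steepness,
    n_trials = 5, high_range = NULL
  )
  search <- attr(cal, "search")
  weak <- search$spread[search$veto_max == 0.1]
  expect_gt(cal$veto_max, 0.1)
  expect_lt(attr(cal, "spread"), weak)
  expect_error(
    calibrate_gain(fb, a, input_ranges = list(c(5, 25)), seed = 1),
    "at least two"
  )
})
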