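a <- anatomy_params()

test_that("anatomy invariants are enforced with informative errors", {
  expect_error(anatomy_params(input_threshold = 5), "input_threshold")
  expect_error(anatomy_params(n_grc_per_field = 0), "n_grc_per_field")
  expect_error(anatomy_params(golgi_pf_floor = 16, golgi_pf_sat = 16),
    "golgi_pf_floor")
  expect_error(anatomy_params(x_range = c(3, 200)), "x_range")
  expect_error(anatomy_params(x_range = c(20, 10)), "x_range")
})

test_that("expected firing count matches hand-checked and degenerate values", {
  expect_equal(expected_firing_count(0, 0.3, a), 0)
  expect_equal(expected_firing_count(17, 1, a), 0)
  # 8750 * (4 * 0.3^3 * 0.7 + 0.3^4), checked by hand
  expect_equal(expected_firing_count(30, 0, a), 732.375)
  expect_equal(
    expected_firing_count(30, 0.5, a),
    enum_expected_firing(30, 0.5),
    tolerance = 1e-12
  )
})

test_that("expected firing count equals the dendrite-enumeration oracle", {
  for (x in c(3, 10, 17, 25, 30)) {
    for (pv in c(0, 0.25, 0.5, 0.9)) {
      expect_equal(
        expected_firing_count(x, pv, a),
        enum_expected_firing(x, pv),
        tolerance = 1e-12
      )
    }
  }
  # other thresholds too
  for (m in c(2, 4)) {
    am <- anatomy_params(input_threshold = m)
    expect_equal(
      expected_firing_count(22, 0.4, am),
      enum_expected_firing(22, 0.4, m = m),
      tolerance = 1e-12
    )
  }
})

test_that("expected firing count is monotone in x and in p_veto", {
  xs <- 0:100
  for (pv in c(0, 0.3, 0.8)) {
    expect_true(all(diff(expected_firing_count(xs, pv, a)) >= 0))
  }
  pvs <- seq(0, 1, by = 0.01)
  for (x in c(5, 15, 30)) {
    expect_true(all(diff(expected_firing_count(x, pvs, a)) <= 0))
  }
})

test_that("at m = n with no veto the closed form N (x/y)^n holds", {
  a4 <- anatomy_params(input_threshold = 4)
  xs <- 0:30
  expect_equal(
    expected_firing_count(xs, 0, a4),
    8750 * (xs / 100)^4,
    tolerance = 1e-12
  )
})

test_that("out-of-range inputs raise errors naming the offending parameter", {
  expect_error(expected_firing_count(-1, 0, a), "`x`")
  expect_error(expected_firing_count(101, 0, a), "`x`")
  expect_error(expected_firing_count(10, 1.2, a), "`p_veto`")
  expect_error(realize_threshold_counts(200, 0, a), "`x`")
  expect_error(realize_threshold_counts(10, -0.1, a), "`p_veto`")
})

test_that("realized counts honour their degenerate cases", {
  set.seed(42)
  expect_equal(
    realize_threshold_counts(0, 0.2, a),
    c(count_threshold = 0L, count_firing = 0L)
  )
  r <- realize_threshold_counts(25, 0, a)
  expect_equal(r[["count_firing"]], r[["count_threshold"]])
})

test_that("firing never exceeds threshold count in any single draw", {
  set.seed(7)
  for (i in 1:200) {
    x <- sample(0:30, 1)
    pv <- runif(1)
    r <- realize_threshold_counts(x, pv, a)
    expect_lte(r[["count_firing"]], r[["count_threshold"]])
    expect_lte(r[["count_threshold"]], a$n_grc_per_field)
  }
})

test_that("Monte-Carlo mean converges to the analytic expectation", {
  set.seed(11)
  reps <- 4000
  draws <- replicate(reps, realize_threshold_counts(30, 0.5, a)[["count_firing"]])
  analytic <- expected_firing_count(30, 0.5, a)
  se <- sd(draws) / sqrt(reps)
  expect_lt(abs(mean(draws) - analytic), 3 * se)
})
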