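test_that("rate population shapes honour their definitions", {
  expect_equal(
    generate_mf_rates(rate_spec("uniform_grid", n_active_mf = 3)),
    c(50, 175, 300)
  )
  set.seed(1)
  r <- generate_mf_rates(rate_spec("uniform_random"))
  expect_length(r, 300)
  expect_true(all(r >= 50 & r <= 300))

  disc <- rate_spec("discontinuous")
  set.seed(2)
  d <- generate_mf_rates(disc)
  expect_length(d, 300)
  for (band in disc$gap_bands) {
    expect_false(any(d > band[1] & d < band[2]))
  }
})

test_that("top-weighted draws match the analytic power-density mean", {
  # density prop. to u^2 on [0,1]: E[u] = 3/4, so E[rate] = 50 + 0.75 * 250
  spec <- rate_spec("top_weighted", n_active_mf = 1e5, skew_power = 2)
  set.seed(3)
  r <- generate_mf_rates(spec)
  analytic_mean <- 50 + 0.75 * 250
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - analytic_mean), 3 * se)
})

test_that("invalid rate specifications are rejected", {
  expect_error(rate_spec(rate_min = 300, rate_max = 50), "rate_min")
  expect_error(
    rate_spec("discontinuous", gap_bands = list(c(50, 300))),
    "whole rate range"
  )
  expect_error(rate_spec(gap_bands = list(c(10, 40))), "gap band")
})

test_that("sample means are unbiased with the finite-population variance", {
  set.seed(4)
  rates <- runif(300, 50, 300)
  expect_error(sample_granule_means(rates, sample_size = 301), "sample_size")

  expect_equal(
    sample_granule_means(rep(120, 50), 3, 10),
    rep(120, 10)
  )

  n_samples <- 20000
  sm <- sample_granule_means(rates, 3, n_samples)
  expect_true(all(sm >= min(rates) & sm <= max(rates)))
  se <- sd(sm) / sqrt(n_samples)
  expect_lt(abs(mean(sm) - mean(rates)), 3 * se)

  # without-replacement triples of 300: var = sigma^2 / 3 * (1 - 2/299)
  sigma2 <- mean((rates - mean(rates))^2)
  expected_var <- sigma2 / 3 * (1 - 2 / 299)
  expect_equal(var(sm), expected_var, tolerance = 0.06)
})

test_that("top-slice selection is an exact order statistic", {
  set.seed(5)
  sm <- runif(4500, 50, 300)
  expect_equal(select_top_slice(sm, 4500), sort(sm, decreasing = TRUE))
  expect_equal(select_top_slice(sm, 1), max(sm))
  top <- select_top_slice(sm, 1200)
  sorted <- sort(sm, decreasing = TRUE)
  expect_equal(min(top), sorted[1200])
  expect_true(min(top) >= max(sm[!sm %in% top]))
  expect_error(select_top_slice(sm, 0), "`k`")
  expect_error(select_top_slice(sm, 4501), "`k`")
})

test_that("the full pipeline narrows and symmetrizes every shape", {
  rs <- recoding_summary(seed = 6)
  tab <- tidy(rs)
  base <- dplyr::filter(tab, shift == 0)
  # top slice is always narrower than the parent population range
  expect_true(all(base$top_slice_width < base$population_range))
  # CLT symmetrization: a strongly skewed parent loses skew in the means;
  # the near-symmetric gapped parent loses its (large) excess kurtosis
  tw <- dplyr::filter(base, shape == "top_weighted")
  expect_lt(abs(tw$sample_means_skewness), abs(tw$population_skewness))
  disc <- dplyr::filter(base, shape == "discontinuous")
  expect_lt(abs(disc$sample_means_kurtosis), 1)
})

test_that("sample means approach normality for non-normal parents", {
  set.seed(7)
  r_tw <- recode_rates(rate_spec("top_weighted"))
  s <- r_tw$stats
  parent <- s[s$stage == "rates", ]
  sm <- s[s$stage == "sample_means", ]
  expect_lt(abs(sm$skewness), abs(parent$skewness))
  expect_lt(abs(sm$kurtosis), abs(parent$kurtosis))
  # the gapped uniform parent is platykurtic (excess kurtosis near -1.2);
  # means of three recover most of the way toward mesokurtic
  r_disc <- recode_rates(rate_spec("discontinuous"))
  s <- r_disc$stats
  expect_lt(s$kurtosis[s$stage == "rates"], -0.8)
  expect_lt(
    abs(s$kurtosis[s$stage == "sample_means"]),
    abs(s$kurtosis[s$stage == "rates"])
  )
})

test_that("location shifts move the top slice exactly and linearly", {
  rs <- recoding_summary(seed = 8)
  tab <- tidy(rs)
  for (sh in unique(tab$shape)) {
    d <- dplyr::filter(tab, shape == sh)
    base <- d$top_slice_mean[d$shift == 0]
    # translation equivariance is exact because the sampling draws are shared
    expect_equal(d$top_slice_mean, base + d$shift, tolerance = 1e-9)
  }
  fits <- glance(rs)
  expect_true(all(fits$r_squared > 0.99))
  expect_true(all(abs(fits$slope - 1) < 1e-6))
  expect_error(recoding_summary(shifts = c(0, 10), seed = 1), "at least 3")
})

test_that("top-slice mean always sits above the sample-mean average", {
  set.seed(9)
  for (spec in default_rate_specs()) {
    res <- recode_rates(spec)
    expect_gte(mean(res$top_slice), mean(res$sample_means))
  }
})
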