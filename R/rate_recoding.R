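#' Specification of a mossy-fiber firing-rate population
#'
#' Describes the frequency distribution of firing rates over the active mossy
#' fibers of a beam. Four shapes are supported: an even grid across the rate
#' range (`uniform_grid`), i.i.d. uniform draws (`uniform_random`), uniform
#' draws with excluded bands (`discontinuous`), and draws weighted toward the
#' top of the range (`top_weighted`, density proportional to
#' `((r - rate_min) / (rate_max - rate_min))^skew_power`).
#'
#' @param shape One of `"uniform_grid"`, `"uniform_random"`,
#'   `"discontinuous"`, `"top_weighted"`.
#' @param rate_min,rate_max Rate range in Hz (defaults 50 and 300).
#' @param n_active_mf Active mossy fibers in the beam (default 300).
#' @param gap_bands List of `c(low, high)` Hz bands excluded by the
#'   `discontinuous` shape (default bands 100--130 and 200--240 Hz).
#' @param skew_power Exponent of the `top_weighted` density (default 2).
#'
#' @return An object of class `rate_spec`.
#' @examples
#' rate_spec("top_weighted", skew_power = 3)
#' @export
rate_spec <- function(shape = c(
                        "uniform_grid", "uniform_random",
                        "discontinuous", "top_weighted"
                      ),
                      rate_min = 50, rate_max = 300,
                      n_active_mf = 300,
                      gap_bands = list(c(100, 130), c(200, 240)),
                      skew_power = 2) {
  shape <- match.arg(shape)
  if (!(rate_min < rate_max)) {
    stop("`rate_min` must be strictly less than `rate_max`", call. = FALSE)
  }
  if (n_active_mf < 1) stop("`n_active_mf` must be >= 1", call. = FALSE)
  gap_bands <- lapply(gap_bands, as.numeric)
  for (b in gap_bands) {
    if (length(b) != 2L || b[1] >= b[2] || b[1] < rate_min || b[2] > rate_max) {
      stop("each gap band must be an increasing pair within [rate_min, rate_max]",
        call. = FALSE
      )
    }
  }
  if (shape == "discontinuous" &&
    sum(vapply(gap_bands, diff, numeric(1))) >= rate_max - rate_min) {
    stop("`gap_bands` must not cover the whole rate range", call. = FALSE)
  }
  structure(
    list(
      shape = shape, rate_min = rate_min, rate_max = rate_max,
      n_active_mf = as.integer(n_active_mf),
      gap_bands = gap_bands, skew_power = skew_power
    ),
    class = "rate_spec"
  )
}

#' Generate a mossy-fiber rate population
#'
#' Draws (or lays out) `n_active_mf` firing rates according to a
#' [rate_spec()]. `uniform_grid` is deterministic; the other shapes use the
#' session RNG stream.
#'
#' @param spec A [rate_spec()] object.
#' @return Numeric vector of rates in Hz, length `spec$n_active_mf`.
#' @examples
#' generate_mf_rates(rate_spec("uniform_grid", n_active_mf = 3)) # 50 175 300
#' @export
generate_mf_rates <- function(spec = rate_spec()) {
  stopifnot(inherits(spec, "rate_spec"))
  n <- spec$n_active_mf
  switch(spec$shape,
    uniform_grid = seq(spec$rate_min, spec$rate_max, length.out = n),
    uniform_random = stats::runif(n, spec$rate_min, spec$rate_max),
    discontinuous = {
      in_gap <- function(r) {
        Reduce(`|`, lapply(spec$gap_bands, function(b) r > b[1] & r < b[2]))
      }
      out <- numeric(0)
      while (length(out) < n) {
        draw <- stats::runif(2L * (n - length(out)), spec$rate_min, spec$rate_max)
        out <- c(out, draw[!in_gap(draw)])
      }
      out[seq_len(n)]
    },
    top_weighted = {
      # density on [0,1] proportional to u^k: inverse-CDF u = U^(1/(k+1))
      u <- stats::runif(n)^(1 / (spec$skew_power + 1))
      spec$rate_min + u * (spec$rate_max - spec$rate_min)
    }
  )
}

#' Granule-cell sample means of mossy-fiber rates
#'
#' Each granule cell samples `sample_size` distinct mossy fibers (one per
#' dendrite, without replacement within a cell) and receives their mean rate;
#' cells sample independently of one another. The frequency distribution of
#' these sample means approaches a normal distribution by the central limit
#' theorem regardless of the parent shape.
#'
#' @param rates Numeric vector of mossy-fiber rates (Hz).
#' @param sample_size Mossy fibers sampled per granule cell (default 3); must
#'   not exceed `length(rates)`.
#' @param n_samples Number of granule cells (default 4500).
#' @return Numeric vector of `n_samples` mean input rates (Hz).
#' @examples
#' set.seed(1)
#' mu <- sample_granule_means(runif(300, 50, 300))
#' mean(mu)
#' @export
sample_granule_means <- function(rates, sample_size = 3, n_samples = 4500) {
  if (sample_size > length(rates)) {
    stop("`sample_size` must not exceed the number of rates", call. = FALSE)
  }
  if (sample_size < 1 || n_samples < 1) {
    stop("`sample_size` and `n_samples` must be >= 1", call. = FALSE)
  }
  idx <- sample_mean_indices(length(rates), sample_size, n_samples)
  colMeans(matrix(rates[idx], nrow = sample_size))
}

# Index matrix (sample_size x n_samples) of without-replacement draws,
# reusable across location-shifted copies of the same population.
sample_mean_indices <- function(n_rates, sample_size, n_samples) {
  vapply(
    seq_len(n_samples),
    function(i) sample.int(n_rates, sample_size),
    integer(sample_size)
  )
}

#' Select the top slice of granule-cell sample means
#'
#' The cells that actually fire after glomerular competition are those
#' receiving the highest mean input rates: the `k` largest sample means. Ties
#' are broken stably, retaining earlier-indexed samples.
#'
#' @param sample_means Numeric vector of granule-cell mean input rates.
#' @param k Top-slice size, `1 <= k <= length(sample_means)` (default 1200).
#' @return The `k` largest values, in decreasing order.
#' @examples
#' select_top_slice(c(3, 1, 4, 1, 5), 2) # 5 4
#' @export
select_top_slice <- function(sample_means, k = 1200) {
  n <- length(sample_means)
  if (k < 1 || k > n) {
    stop("`k` must lie in [1, ", n, "]", call. = FALSE)
  }
  ord <- order(sample_means, seq_len(n), decreasing = c(TRUE, FALSE),
    method = "radix")
  sample_means[ord[seq_len(k)]]
}

rate_stats <- function(v) {
  tibble::tibble(
    mean = mean(v), sd = stats::sd(v),
    min = min(v), max = max(v),
    skewness = e1071::skewness(v),
    kurtosis = e1071::kurtosis(v)
  )
}

#' Run the full rate-recoding pipeline for one population
#'
#' Generates the mossy-fiber rate population, forms granule-cell sample
#' means, selects the top slice, and summarises all three distributions.
#'
#' @param spec A [rate_spec()] object.
#' @param sample_size Mossy fibers averaged per granule cell (default 3).
#' @param n_samples Granule cells sampled (default 4500).
#' @param top_slice_size Cells that fire after regulation (default 1200).
#' @param seed Optional integer seed.
#'
#' @return An object of class `sample_means_result`: a list with `rates`,
#'   `sample_means`, `top_slice` and a `stats` tibble (one row per stage).
#' @examples
#' r <- recode_rates(rate_spec("top_weighted"), seed = 1)
#' r$stats
#' @export
recode_rates <- function(spec = rate_spec(), sample_size = 3,
                         n_samples = 4500, top_slice_size = 1200,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- generate_mf_rates(spec)
  sm <- sample_granule_means(rates, sample_size, n_samples)
  top <- select_top_slice(sm, top_slice_size)
  stats <- dplyr::bind_rows(
    dplyr::mutate(rate_stats(rates), stage = "rates", .before = 1L),
    dplyr::mutate(rate_stats(sm), stage = "sample_means", .before = 1L),
    dplyr::mutate(rate_stats(top), stage = "top_slice", .before = 1L)
  )
  structure(
    list(
      spec = spec, rates = rates, sample_means = sm, top_slice = top,
      sample_size = sample_size, n_samples = n_samples,
      top_slice_size = top_slice_size, stats = stats
    ),
    class = "sample_means_result"
  )
}

#' @export
print.sample_means_result <- function(x, ...) {
  cat("<sample_means_result> shape ", x$spec$shape, "\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Rate-recoding summary across population shapes and location shifts
#'
#' For each population shape and each location-shifted copy of its rate
#' population, runs the full sampling pipeline and records the population
#' mean, top-slice mean and width, and the skewness of rates and sample
#' means. One rate population and one set of granule-cell sampling draws are
#' generated per shape and reused across shifts, so the top slice inherits
#' the exact translation equivariance of means and order statistics. A
#' straight line of top-slice mean against population mean is fitted per
#' shape.
#'
#' @param specs Named list of [rate_spec()] objects (default: all four
#'   standard shapes).
#' @param shifts Numeric location offsets in Hz (at least 3; default
#'   `c(-40, -20, 0, 20, 40)`).
#' @param sample_size,n_samples,top_slice_size Pipeline sizes (defaults 3,
#'   4500, 1200).
#' @param seed Integer seed.
#'
#' @return An object of class `recoding_summary`: `table` (one row per
#'   shape x shift) and `fits` (per-shape slope, intercept and R-squared).
#'   [generics::tidy()] returns `table`, [generics::glance()] returns `fits`.
#' @examples
#' rs <- recoding_summary(seed = 1)
#' glance(rs)
#' @export
recoding_summary <- function(specs = default_rate_specs(),
                             shifts = c(-40, -20, 0, 20, 40),
                             sample_size = 3, n_samples = 4500,
                             top_slice_size = 1200, seed = 1) {
  if (length(shifts) < 3L) {
    stop("at least 3 `shifts` are needed for the linearity fit", call. = FALSE)
  }
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$shape, character(1))
  }
  set.seed(seed)
  rows <- purrr::imap(specs, function(spec, nm) {
    rates0 <- generate_mf_rates(spec)
    idx <- sample_mean_indices(length(rates0), sample_size, n_samples)
    purrr::map(shifts, function(dc) {
      rates <- rates0 + dc
      sm <- colMeans(matrix(rates[idx], nrow = sample_size))
      top <- select_top_slice(sm, top_slice_size)
      tibble::tibble(
        shape = nm, shift = dc,
        population_mean = mean(rates),
        population_range = diff(range(rates)),
        population_skewness = e1071::skewness(rates),
        sample_means_skewness = e1071::skewness(sm),
        sample_means_kurtosis = e1071::kurtosis(sm),
        top_slice_mean = mean(top),
        top_slice_width = diff(range(top))
      )
    }) |> purrr::list_rbind()
  })
  table <- purrr::list_rbind(rows)
  fits <- table |>
    dplyr::group_by(.data$shape) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::lm(top_slice_mean ~ population_mean, data = d)
      # R^2 computed directly: the fit is exact by construction (shared
      # sampling draws), and summary.lm() warns on perfect fits
      sst <- sum((d$top_slice_mean - mean(d$top_slice_mean))^2)
      tibble::tibble(
        slope = stats::coef(fit)[["population_mean"]],
        intercept = stats::coef(fit)[["(Intercept)"]],
        r_squared = 1 - sum(stats::resid(fit)^2) / sst
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(table = table, fits = fits, shifts = shifts, seed = seed),
    class = "recoding_summary"
  )
}

#' The four standard mossy-fiber rate population shapes
#'
#' @param ... Passed to every [rate_spec()] (e.g. `n_active_mf`).
#' @return Named list of four [rate_spec()] objects.
#' @export
default_rate_specs <- function(...) {
  list(
    uniform_grid = rate_spec("uniform_grid", ...),
    uniform_random = rate_spec("uniform_random", ...),
    discontinuous = rate_spec("discontinuous", ...),
    top_weighted = rate_spec("top_weighted", ...)
  )
}

#' @export
print.recoding_summary <- function(x, ...) {
  cat("<recoding_summary> ", dplyr::n_distinct(x$table$shape), " shapes x ",
    length(x$shifts), " shifts\n",
    sep = ""
  )
  print(x$fits)
  invisible(x)
}
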