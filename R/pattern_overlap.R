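#' Analytic overlap spectrum of stored parallel-fiber patterns
#'
#' With a fraction `p_active` of parallel fibers active in every stored
#' pattern, and membership independent across patterns, the proportion of a
#' focal pattern's synapses that also participate in exactly `k` of
#' `n_other` other stored patterns is binomial:
#' `C(n_other, k) * p^k * (1 - p)^(n_other - k)`. The spectrum is identical
#' for every stored pattern.
#'
#' @param n_other Number of other stored patterns (total stored is
#'   `n_other + 1`).
#' @param p_active Fraction of parallel fibers active per pattern, in
#'   `[0, 1]`.
#' @return An object of class `overlap_spectrum`: a tibble with columns `k`
#'   (0..`n_other`) and `proportion`, carrying `n_other` and `p_active` as
#'   attributes. Proportions sum to 1.
#' @examples
#' overlap_proportions(4, 0.01)
#' @export
overlap_proportions <- function(n_other, p_active) {
  if (length(n_other) != 1L || is.na(n_other) || n_other < 0) {
    stop("`n_other` must be a single count >= 0", call. = FALSE)
  }
  if (length(p_active) != 1L || is.na(p_active) ||
    p_active < 0 || p_active > 1) {
    stop("`p_active` must lie in [0, 1]", call. = FALSE)
  }
  n_other <- as.integer(n_other)
  k <- 0:n_other
  out <- tibble::tibble(
    k = k,
    proportion = stats::dbinom(k, n_other, p_active)
  )
  attr(out, "n_other") <- n_other
  attr(out, "p_active") <- p_active
  class(out) <- c("overlap_spectrum", class(out))
  out
}

#' Monte-Carlo pattern-storage oracle for the overlap spectrum
#'
#' Draws `n_patterns` stored patterns as independent fixed-size random
#' subsets of `n_active` fibers out of `n_pf` parallel fibers, then, for one
#' focal pattern, tabulates for each of its fibers how many of the other
#' patterns also contain it. The empirical proportions agree with
#' [overlap_proportions()] at `p = n_active / n_pf` up to multinomial
#' sampling error (fixed-size subsets versus Bernoulli membership is a
#' negligible distinction when `n_active << n_pf`).
#'
#' @param n_patterns Stored patterns, >= 1.
#' @param n_pf Total parallel fibers (default 350000).
#' @param n_active Active fibers per pattern (default 1200); must not exceed
#'   `n_pf`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `k` (0..`n_patterns - 1`), `proportion`
#'   (empirical), and `analytic` (the binomial spectrum at
#'   `p = n_active / n_pf`).
#' @examples
#' simulate_pattern_overlap(5, seed = 1)
#' @export
simulate_pattern_overlap <- function(n_patterns, n_pf = 350000,
                                     n_active = 1200, seed = NULL) {
  if (n_patterns < 1) stop("`n_patterns` must be >= 1", call. = FALSE)
  if (n_active > n_pf) {
    stop("`n_active` must not exceed `n_pf`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  focal <- sample.int(n_pf, n_active)
  shared <- integer(n_active)
  for (j in seq_len(n_patterns - 1L)) {
    other <- sample.int(n_pf, n_active)
    shared <- shared + as.integer(focal %in% other)
  }
  k <- 0:(n_patterns - 1L)
  counts <- tabulate(shared + 1L, nbins = n_patterns)
  tibble::tibble(
    k = k,
    proportion = counts / n_active,
    analytic = stats::dbinom(k, n_patterns - 1L, n_active / n_pf)
  )
}

#' Overlap spectra over a sweep of pattern counts and activity levels
#'
#' Tabulates [overlap_proportions()] for every combination of activity level
#' and number of other stored patterns — the changing relative proportions of
#' a stored pattern shared with k others as more patterns are stored.
#'
#' @param p_active Activity fractions (default the four standard levels
#'   17500, 7500, 3500 and 1200 of 350000 fibers, i.e. 5, ~2.14, 1 and
#'   ~0.343 percent).
#' @param n_other Values of the other-pattern count (default 1..10).
#' @return Tibble with columns `p_active`, `n_other`, `k`, `proportion`.
#' @examples
#' overlap_sweep(p_active = 0.01, n_other = 1:3)
#' @export
overlap_sweep <- function(p_active = c(17500, 7500, 3500, 1200) / 350000,
                          n_other = 1:10) {
  tidyr::expand_grid(p_active = p_active, n_other = as.integer(n_other)) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      p_active = .data$p_active, n_other = .data$n_other,
      overlap_proportions(.data$n_other, .data$p_active)
    )
}
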