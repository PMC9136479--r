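#' Expected number of granule cells firing in a cluster field
#'
#' The per-field population model. With `x` of the field's `y` mossy fibers
#' active and a glomerular veto probability `p_veto`, each of a granule
#' cell's `n` dendrites independently carries an effective (active and
#' un-vetoed) input with probability `(1 - p_veto) * x / y`. The number of
#' effective inputs per cell is then binomial, and the expected number of
#' firing cells among the field's `N` granule cells is
#' `N * P(Binomial(n, (1 - p_veto) * x / y) >= m)`, where `m` is the input
#' threshold.
#'
#' @param x Active mossy fibers in the field (integer-valued, vectorised);
#'   must lie in `[0, n_mf_per_field]`.
#' @param p_veto Glomerular veto probability in `[0, 1]` (vectorised,
#'   recycled against `x`).
#' @param anatomy An [anatomy_params()] object.
#'
#' @return Expected count of firing granule cells (numeric, same length as
#'   the recycled inputs). Deterministic and continuous in `p_veto`.
#' @examples
#' a <- anatomy_params()
#' expected_firing_count(30, 0, a) # 732.375
#' expected_firing_count(30, 0.5, a) # ~104.8
#' @export
expected_firing_count <- function(x, p_veto, anatomy = anatomy_params()) {
  if (any(is.na(x)) || any(x < 0) || any(x > anatomy$n_mf_per_field)) {
    stop("`x` must lie in [0, ", anatomy$n_mf_per_field, "]", call. = FALSE)
  }
  if (any(is.na(p_veto)) || any(p_veto < 0) || any(p_veto > 1)) {
    stop("`p_veto` must lie in [0, 1]", call. = FALSE)
  }
  q <- (1 - p_veto) * x / anatomy$n_mf_per_field
  anatomy$n_grc_per_field *
    stats::pbinom(anatomy$input_threshold - 1L, anatomy$n_dendrites, q,
      lower.tail = FALSE
    )
}

#' Monte-Carlo realization of per-field threshold and firing counts
#'
#' Stochastic twin of [expected_firing_count()]. For each of the field's `N`
#' granule cells, each of its `n` dendrites is active with probability
#' `x / y` and, independently, un-vetoed with probability `1 - p_veto`.
#' `count_threshold` is the number of cells with at least `m` active
#' dendrites (veto ignored); `count_firing` the number with at least `m`
#' active *and* un-vetoed dendrites. Within every draw
#' `count_firing <= count_threshold`, since an effective dendrite is in
#' particular active.
#'
#' Uses the session RNG stream; seed it (e.g. with [set.seed()]) for
#' reproducibility.
#'
#' @inheritParams expected_firing_count
#' @param x Active mossy fibers in the field (single integer).
#' @return A named integer vector `c(count_threshold =, count_firing =)`.
#' @examples
#' set.seed(1)
#' realize_threshold_counts(30, 0.5, anatomy_params())
#' @export
realize_threshold_counts <- function(x, p_veto, anatomy = anatomy_params()) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > anatomy$n_mf_per_field) {
    stop("`x` must be a single count in [0, ", anatomy$n_mf_per_field, "]",
      call. = FALSE
    )
  }
  if (length(p_veto) != 1L || is.na(p_veto) || p_veto < 0 || p_veto > 1) {
    stop("`p_veto` must be a single probability in [0, 1]", call. = FALSE)
  }
  n_cells <- anatomy$n_grc_per_field
  # active dendrites per cell, then thin each cell's active set by the veto
  active <- stats::rbinom(n_cells, anatomy$n_dendrites,
    x / anatomy$n_mf_per_field)
  effective <- stats::rbinom(n_cells, active, 1 - p_veto)
  m <- anatomy$input_threshold
  c(
    count_threshold = sum(active >= m),
    count_firing = sum(effective >= m)
  )
}
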