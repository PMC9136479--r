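#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the regulated and unregulated middle-beam totals across trials
#'
#' Scatter of per-trial middle-beam totals: granule cells meeting the input
#' threshold (unregulated), those that fire under Golgi regulation, and the
#' cells receiving input to every dendrite.
#'
#' @param object A `beam_trials` object from [run_trials()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.beam_trials <- function(object, ...) {
  d <- object$trials |>
    tidyr::pivot_longer(
      c("middle_beam_unregulated", "middle_beam_total",
        "middle_beam_all_inputs"),
      names_to = "series", values_to = "count"
    ) |>
    dplyr::mutate(series = dplyr::recode(.data$series,
      middle_beam_unregulated = "meets threshold (unregulated)",
      middle_beam_total = "fires (regulated)",
      middle_beam_all_inputs = "input to all dendrites"
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$trial, .data$count,
    colour = .data$series)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "trial", y = "granule cells per beam (middle beam)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the rate-recoding pipeline for one population
#'
#' Faceted histograms of the mossy-fiber rates, the granule-cell sample
#' means, and the top slice.
#'
#' @param object A `sample_means_result` from [recode_rates()].
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sample_means_result <- function(object, bins = 40, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(stage = "mossy-fiber rates", rate = object$rates),
    tibble::tibble(stage = "sample means", rate = object$sample_means),
    tibble::tibble(stage = "top slice", rate = object$top_slice)
  ) |>
    dplyr::mutate(stage = factor(.data$stage,
      levels = c("mossy-fiber rates", "sample means", "top slice")))
  ggplot2::ggplot(d, ggplot2::aes(.data$rate)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue") +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(x = "rate (Hz)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot an overlap spectrum
#'
#' @param object An `overlap_spectrum` from [overlap_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "other stored patterns sharing a synapse (k)",
      y = "proportion of the pattern's synapses",
      title = sprintf(
        "n_other = %d, p_active = %.4g",
        attr(object, "n_other"), attr(object, "p_active")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an overlap sweep as spectra against pattern count
#'
#' One line per overlap order k, proportion of shared synapses against the
#' number of other stored patterns, faceted by activity level.
#'
#' @param sweep A tibble from [overlap_sweep()].
#' @param max_k Largest overlap order to draw (default 6).
#' @return A ggplot object.
#' @export
plot_overlap_sweep <- function(sweep, max_k = 6) {
  d <- dplyr::filter(sweep, .data$k <= max_k)
  ggplot2::ggplot(d, ggplot2::aes(.data$n_other, .data$proportion,
    colour = factor(.data$k), group = .data$k)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~p_active, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "other stored patterns (n)", y = "proportion of synapses",
      colour = "k"
    ) +
    ggplot2::theme_minimal()
}
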