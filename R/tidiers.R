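#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the multi-trial beam experiment
#'
#' @param x A `beam_trials` object from [run_trials()].
#' @param ... Unused.
#' @return The per-trial middle-beam summary tibble (`trial`,
#'   `middle_beam_total`, `middle_beam_unregulated`,
#'   `middle_beam_all_inputs`, `iterations`, `converged`).
#' @exportS3Method generics::tidy
tidy.beam_trials <- function(x, ...) {
  x$trials
}

#' One-row summary of the multi-trial beam experiment
#'
#' @param x A `beam_trials` object from [run_trials()].
#' @param ... Unused.
#' @return A one-row tibble: trial count, mean/sd of the regulated and
#'   unregulated middle-beam totals, the regulated density as a fraction of
#'   the parallel fibers over a Purkinje territory, and convergence counts.
#' @exportS3Method generics::glance
glance.beam_trials <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$trials),
    mean_regulated = mean(x$trials$middle_beam_total),
    sd_regulated = stats::sd(x$trials$middle_beam_total),
    mean_unregulated = mean(x$trials$middle_beam_unregulated),
    sd_unregulated = stats::sd(x$trials$middle_beam_unregulated),
    regulated_density = mean(x$trials$middle_beam_total) /
      x$anatomy$pf_per_purkinje,
    mean_all_inputs = mean(x$trials$middle_beam_all_inputs),
    n_converged = sum(x$trials$converged),
    mean_iterations = mean(x$trials$iterations)
  )
}

#' Tidy a rate-recoding summary
#'
#' @param x A `recoding_summary` object.
#' @param ... Unused.
#' @return The shape-by-shift table of population and top-slice statistics.
#' @exportS3Method generics::tidy
tidy.recoding_summary <- function(x, ...) {
  x$table
}

#' Per-shape linearity fits of a rate-recoding summary
#'
#' @param x A `recoding_summary` object.
#' @param ... Unused.
#' @return Tibble with one row per shape: slope, intercept and R-squared of
#'   top-slice mean against population mean across location shifts.
#' @exportS3Method generics::glance
glance.recoding_summary <- function(x, ...) {
  x$fits
}

#' Tidy a single-grid regulation result
#'
#' @param x A `beam_regulation` object from [run_beam_regulation()].
#' @param ... Unused.
#' @return The per-field tibble (`beam`, `field`, `x`, `p_veto`,
#'   `count_threshold`, `count_firing`, `all_inputs`).
#' @exportS3Method generics::tidy
tidy.beam_regulation <- function(x, ...) {
  x$fields
}

#' One-row summary of a single-grid regulation result
#'
#' @param x A `beam_regulation` object.
#' @param ... Unused.
#' @return A one-row tibble of middle-beam totals and convergence
#'   diagnostics.
#' @exportS3Method generics::glance
glance.beam_regulation <- function(x, ...) {
  tibble::tibble(
    middle_beam_total = x$middle_beam_total,
    middle_beam_unregulated = x$middle_beam_unregulated,
    iterations = x$iterations,
    converged = x$converged
  )
}
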