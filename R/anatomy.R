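#' Anatomical constants of the granular-layer model
#'
#' Bundles the fixed anatomical quantities the simulator is built on: the
#' mossy-fiber and granule-cell census of one cluster field, granule-cell
#' dendrite count and input threshold, beam geometry, and the parallel-fiber
#' convergence numbers onto Purkinje and Golgi cells. Defaults are the model's
#' standard estimates; every one can be overridden.
#'
#' @param n_mf_per_field Mossy fibers innervating one cluster field (default
#'   100).
#' @param n_grc_per_field Granule cells per cluster field (default 8750).
#' @param n_dendrites Dendrites per granule cell, one mossy fiber each
#'   (default 4).
#' @param input_threshold Minimum co-active, un-vetoed inputs for a granule
#'   cell to fire (default 3; must not exceed `n_dendrites`).
#' @param fields_per_beam Cluster fields in one mediolateral beam (default 20).
#' @param n_beams Beams simulated side by side; the middle beam is the
#'   reported one (default 5).
#' @param beam_length_um,beam_width_um Physical beam dimensions in micrometres
#'   (defaults 3000 and 200); informational only.
#' @param pf_per_purkinje Parallel fibers traversing one Purkinje-cell
#'   territory (default 350000).
#' @param pf_per_golgi Parallel-fiber contacts on one Golgi cell (default
#'   1600).
#' @param golgi_pf_floor Active parallel-fiber inputs below which a Golgi cell
#'   shows no response (default 4).
#' @param golgi_pf_sat Active parallel-fiber inputs at which the Golgi
#'   response saturates (default 16; must exceed `golgi_pf_floor`).
#' @param basal_mf_min Minimum active direct mossy-fiber inputs to Golgi basal
#'   dendrites for an effect (default 4).
#' @param x_range Integer vector `c(lo, hi)`: inclusive range of active mossy
#'   fibers per field per trial (default `c(3, 30)`).
#'
#' @return An object of class `anatomy_params` (a validated named list).
#' @examples
#' anatomy_params()
#' anatomy_params(input_threshold = 2)
#' @export
anatomy_params <- function(n_mf_per_field = 100,
                           n_grc_per_field = 8750,
                           n_dendrites = 4,
                           input_threshold = 3,
                           fields_per_beam = 20,
                           n_beams = 5,
                           beam_length_um = 3000,
                           beam_width_um = 200,
                           pf_per_purkinje = 350000,
                           pf_per_golgi = 1600,
                           golgi_pf_floor = 4,
                           golgi_pf_sat = 16,
                           basal_mf_min = 4,
                           x_range = c(3L, 30L)) {
  p <- list(
    n_mf_per_field = as.integer(n_mf_per_field),
    n_grc_per_field = as.integer(n_grc_per_field),
    n_dendrites = as.integer(n_dendrites),
    input_threshold = as.integer(input_threshold),
    fields_per_beam = as.integer(fields_per_beam),
    n_beams = as.integer(n_beams),
    beam_length_um = as.numeric(beam_length_um),
    beam_width_um = as.numeric(beam_width_um),
    pf_per_purkinje = as.integer(pf_per_purkinje),
    pf_per_golgi = as.integer(pf_per_golgi),
    golgi_pf_floor = as.numeric(golgi_pf_floor),
    golgi_pf_sat = as.numeric(golgi_pf_sat),
    basal_mf_min = as.integer(basal_mf_min),
    x_range = as.integer(x_range)
  )
  class(p) <- "anatomy_params"
  validate_anatomy_params(p)
}

validate_anatomy_params <- function(p) {
  counts <- c(
    "n_mf_per_field", "n_grc_per_field", "n_dendrites", "input_threshold",
    "fields_per_beam", "n_beams", "pf_per_purkinje", "pf_per_golgi",
    "basal_mf_min"
  )
  for (nm in counts) {
    v <- p[[nm]]
    if (length(v) != 1L || is.na(v) || v <= 0L) {
      stop("`", nm, "` must be a single strictly positive integer", call. = FALSE)
    }
  }
  if (p$input_threshold > p$n_dendrites) {
    stop("`input_threshold` must not exceed `n_dendrites` (got ",
      p$input_threshold, " > ", p$n_dendrites, ")",
      call. = FALSE
    )
  }
  if (!(p$golgi_pf_floor < p$golgi_pf_sat)) {
    stop("`golgi_pf_floor` must be strictly less than `golgi_pf_sat`",
      call. = FALSE
    )
  }
  if (length(p$x_range) != 2L || anyNA(p$x_range) ||
    p$x_range[1] > p$x_range[2]) {
    stop("`x_range` must be an increasing integer pair c(lo, hi)", call. = FALSE)
  }
  if (p$x_range[1] < 0L || p$x_range[2] > p$n_mf_per_field) {
    stop("`x_range` must lie within [0, n_mf_per_field]", call. = FALSE)
  }
  p
}

#' @export
print.anatomy_params <- function(x, ...) {
  cat("<anatomy_params>\n")
  cat(sprintf(
    "  %d mossy fibers / field, %d granule cells / field\n",
    x$n_mf_per_field, x$n_grc_per_field
  ))
  cat(sprintf(
    "  %d dendrites, input threshold %d\n",
    x$n_dendrites, x$input_threshold
  ))
  cat(sprintf(
    "  %d beams x %d fields (%g x %g um)\n",
    x$n_beams, x$fields_per_beam, x$beam_length_um, x$beam_width_um
  ))
  cat(sprintf(
    "  %d pf / Purkinje, %d pf / Golgi (floor %g, saturation %g)\n",
    x$pf_per_purkinje, x$pf_per_golgi, x$golgi_pf_floor, x$golgi_pf_sat
  ))
  cat(sprintf(
    "  active mossy fibers per field: %d..%d\n",
    x$x_range[1], x$x_range[2]
  ))
  invisible(x)
}
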