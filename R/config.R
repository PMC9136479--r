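#' Default run configuration
#'
#' The full configuration driving every experiment, with the model's
#' standard values filled in: anatomy constants (8750 granule cells and 100
#' mossy fibers per field, 4 dendrites, input threshold 3, 5 beams of 20
#' fields), the calibrated Golgi feedback parameters, the four rate
#' population shapes, the overlap sweep settings, 100 trials and seed 1.
#'
#' @return An object of class `run_config`.
#' @examples
#' cfg <- default_config()
#' cfg$anatomy$input_threshold
#' @export
default_config <- function() {
  structure(
    list(
      anatomy = anatomy_params(),
      feedback = golgi_feedback_params(),
      rate_specs = default_rate_specs(),
      rate_pipeline = list(
        sample_size = 3L, n_samples = 4500L, top_slice_size = 1200L,
        shifts = c(-40, -20, 0, 20, 40)
      ),
      overlap = list(
        p_active = c(17500, 7500, 3500, 1200) / 350000,
        n_other = 1:10,
        n_pf = 350000L, n_active = 1200L, n_patterns = 5L
      ),
      n_trials = 100L,
      seed = 1L,
      out_dir = "."
    ),
    class = "run_config"
  )
}

config_field_names <- function() {
  list(
    top = names(default_config()),
    anatomy = names(unclass(anatomy_params())),
    feedback = names(unclass(golgi_feedback_params())),
    rate_spec = c(
      "shape", "rate_min", "rate_max", "n_active_mf", "gap_bands",
      "skew_power"
    ),
    rate_pipeline = c("sample_size", "n_samples", "top_slice_size", "shifts"),
    overlap = c("p_active", "n_other", "n_pf", "n_active", "n_patterns")
  )
}

check_known_keys <- function(given, known, where) {
  unknown <- setdiff(names(given), known)
  if (length(unknown)) {
    stop("unknown configuration key", if (length(unknown) > 1) "s", " in ",
      where, ": ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(given)
}

#' Load and validate a JSON run configuration
#'
#' Reads a JSON file, rejects unknown keys at every level, fills every
#' omitted field with its default (so the empty object `{}` yields
#' [default_config()]), and validates the invariants of all parameter blocks.
#'
#' @param path Path to a JSON file.
#' @return A validated `run_config` object.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines("{}", f)
#' load_config(f)$n_trials
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  known <- config_field_names()
  check_known_keys(raw, known$top, "top level")

  cfg <- default_config()
  if (!is.null(raw$anatomy)) {
    check_known_keys(raw$anatomy, known$anatomy, "anatomy")
    cfg$anatomy <- do.call(anatomy_params, raw$anatomy)
  }
  if (!is.null(raw$feedback)) {
    check_known_keys(raw$feedback, known$feedback, "feedback")
    cfg$feedback <- do.call(golgi_feedback_params, raw$feedback)
  }
  if (!is.null(raw$rate_specs)) {
    cfg$rate_specs <- purrr::map(raw$rate_specs, function(s) {
      check_known_keys(s, known$rate_spec, "rate_specs")
      if (!is.null(s$gap_bands)) {
        s$gap_bands <- asplit_bands(s$gap_bands)
      }
      do.call(rate_spec, s)
    })
  }
  if (!is.null(raw$rate_pipeline)) {
    check_known_keys(raw$rate_pipeline, known$rate_pipeline, "rate_pipeline")
    cfg$rate_pipeline <- utils::modifyList(cfg$rate_pipeline, raw$rate_pipeline)
  }
  if (!is.null(raw$overlap)) {
    check_known_keys(raw$overlap, known$overlap, "overlap")
    cfg$overlap <- utils::modifyList(cfg$overlap, raw$overlap)
  }
  for (nm in c("n_trials", "seed", "out_dir")) {
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  }
  validate_run_config(cfg)
}

# jsonlite may hand gap bands back as a matrix; normalise to a list of pairs
asplit_bands <- function(b) {
  if (is.matrix(b)) {
    lapply(seq_len(nrow(b)), function(i) b[i, ])
  } else if (is.numeric(b)) {
    list(b)
  } else {
    b
  }
}

validate_run_config <- function(cfg) {
  if (length(cfg$seed) != 1L || is.na(cfg$seed) || cfg$seed < 0) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  if (cfg$n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  cfg$n_trials <- as.integer(cfg$n_trials)
  cfg$seed <- as.integer(cfg$seed)
  if (any(cfg$overlap$p_active < 0) || any(cfg$overlap$p_active > 1)) {
    stop("overlap `p_active` values must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$overlap$n_active > cfg$overlap$n_pf) {
    stop("overlap `n_active` must not exceed `n_pf`", call. = FALSE)
  }
  cfg
}

#' Write a run configuration as JSON
#'
#' Round-trips with [load_config()]: writing [default_config()] and loading
#' it back yields an equal configuration.
#'
#' @param cfg A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- list(
    anatomy = unclass(cfg$anatomy),
    feedback = unclass(cfg$feedback),
    rate_specs = purrr::map(cfg$rate_specs, unclass),
    rate_pipeline = cfg$rate_pipeline,
    overlap = cfg$overlap,
    n_trials = cfg$n_trials,
    seed = cfg$seed,
    out_dir = cfg$out_dir
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed ", x$seed, ", ", x$n_trials, " trials\n", sep = "")
  print(x$anatomy)
  print(x$feedback)
  invisible(x)
}
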