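# Run configuration: every tunable threshold of the pipeline in one place.

#' Pipeline configuration
#'
#' Collects the thresholds used across scanning, classification and disorder
#' profiling. The score tiers (0.80 / 0.55 by default) play the role that
#' BLAST E-value tiers play in database surveys: `strong` hits are confident
#' domain assignments, `weak` hits are worth inspection, anything below is a
#' `candidate` retained only when it clears `min_normalized`.
#'
#' @param min_normalized Minimum normalized profile score for any hit.
#' @param tier_strong,tier_weak Normalized-score tier thresholds.
#' @param truncated_affinity Minimum normalized core-profile score for a
#'   core-only protein to be called `truncated` rather than `short_type`
#'   (applies only to metazoan records; see [classify_architecture()]).
#' @param gap_tolerance Maximum residue gap between the core and
#'   partial-core hits still treated as one contiguous long domain.
#' @param min_tail Minimum number of residues preceding the domain that
#'   count as an N-terminal tail.
#' @param disorder_window Odd window width for the disorder profiler.
#' @param disorder_threshold Score above which a residue is called
#'   disordered (convention: 0.5).
#' @param seed Optional integer seed recorded with the run.
#' @param verbosity One of "quiet", "info".
#' @return A list of class `tppp_config`.
#' @export
run_config <- function(min_normalized = 0.55,
                       tier_strong = 0.80,
                       tier_weak = 0.55,
                       truncated_affinity = 0.87,
                       gap_tolerance = 10L,
                       min_tail = 40L,
                       disorder_window = 21L,
                       disorder_threshold = 0.5,
                       seed = NULL,
                       verbosity = "info") {
  cfg <- list(
    min_normalized = min_normalized, tier_strong = tier_strong,
    tier_weak = tier_weak, truncated_affinity = truncated_affinity,
    gap_tolerance = as.integer(gap_tolerance), min_tail = as.integer(min_tail),
    disorder_window = as.integer(disorder_window),
    disorder_threshold = disorder_threshold,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    verbosity = verbosity
  )
  .validate_config(cfg)
  structure(cfg, class = "tppp_config")
}

.validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(cfg$min_normalized) || !in01(cfg$tier_strong) ||
      !in01(cfg$tier_weak) || !in01(cfg$truncated_affinity) ||
      !in01(cfg$disorder_threshold)) {
    abort("all score thresholds must lie in [0, 1]")
  }
  if (cfg$tier_weak > cfg$tier_strong) abort("tier_weak must not exceed tier_strong")
  if (cfg$gap_tolerance < 0) abort("gap_tolerance must be >= 0")
  if (cfg$min_tail < 0) abort("min_tail must be >= 0")
  if (cfg$disorder_window < 1 || cfg$disorder_window %% 2 == 0) {
    abort("disorder_window must be a positive odd integer")
  }
  if (!cfg$verbosity %in% c("quiet", "info")) {
    abort("verbosity must be 'quiet' or 'info'")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param config A `tppp_config`.
#' @param path File path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tppp_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @export
print.tppp_config <- function(x, ...) {
  cat("<tppp_config>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-20s %s\n", nm, x[[nm]]))
  }
  invisible(x)
}
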