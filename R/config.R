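#' Analysis configuration
#'
#' Bundles every tunable constant of the transport and single-molecule
#' pipelines in one place, with defaults matching the acquisition and
#' filtering rules used throughout the package:
#' vesicle imaging at 5 frames/s over 60 s, a stall threshold of
#' 0.02 um/frame (0.1 um/s), a mobility gate of 0.75 um net displacement,
#' a minimum track span of 15 frames (3 s), a tracking gap limit of
#' 2 frames (400 ms), a 50 nm immobility radius for single-molecule dwell
#' detection, and a 95% confidence level for the mitochondria classifier.
#'
#' @param fps_vesicle Vesicle acquisition rate, frames per second.
#' @param stall_threshold Per-frame displacement below which a vesicle step
#'   counts as stalled, um/frame.
#' @param mobility_displacement Net displacement a vesicle must exceed over
#'   the observation window to be called mobile, um.
#' @param observation_time Nominal observation window, seconds.
#' @param min_track_frames Minimum frame span (last - first + 1) a track
#'   must cover to enter the analysis.
#' @param max_gap_frames Maximum tracking gap bridged by the upstream
#'   linker, frames.
#' @param immobility_radius Radius within which consecutive single-molecule
#'   localizations count as one immobile event, nm.
#' @param mito_confidence Confidence level (1 - two-sided p) required to
#'   call a mitochondrion mobile or stationary.
#' @param d_free Diffusion constant of the free (unbound) protein used when
#'   fitting the reaction-diffusion model, um^2/s. No measured value ships
#'   with the package: the default of 10 um^2/s is a placeholder of the
#'   right order of magnitude for a free cytosolic protein and should be
#'   set explicitly for quantitative work.
#' @param rng_seed Optional integer seed recorded with simulation output.
#'
#' @return A list of class `nk_config`.
#' @seealso [validate_config()]
#' @export
#' @examples
#' cfg <- validate_config(nk_config())
#' cfg$stall_speed_um_s # 0.1 um/s
nk_config <- function(fps_vesicle = 5,
                      stall_threshold = 0.02,
                      mobility_displacement = 0.75,
                      observation_time = 60,
                      min_track_frames = 15,
                      max_gap_frames = 2,
                      immobility_radius = 50,
                      mito_confidence = 0.95,
                      d_free = 10,
                      rng_seed = NULL) {
  cfg <- list(
    fps_vesicle = fps_vesicle,
    stall_threshold = stall_threshold,
    mobility_displacement = mobility_displacement,
    observation_time = observation_time,
    min_track_frames = min_track_frames,
    max_gap_frames = max_gap_frames,
    immobility_radius = immobility_radius,
    mito_confidence = mito_confidence,
    d_free = d_free,
    rng_seed = rng_seed
  )
  structure(cfg, class = "nk_config")
}

#' Validate a configuration and derive audit quantities
#'
#' Checks every invariant (thresholds strictly positive, confidence level in
#' (0, 1), at least 2 frames per track) and attaches derived audit fields so
#' that unit conversions are stated once and can be checked against the
#' acquisition settings:
#' `stall_speed_um_s = stall_threshold * fps_vesicle`,
#' `max_gap_ms = max_gap_frames * 1000 / fps_vesicle`, and
#' `min_track_duration_s = min_track_frames / fps_vesicle`.
#' Validation is idempotent: re-validating a validated configuration
#' returns an identical object.
#'
#' @param cfg An `nk_config` list, as returned by [nk_config()].
#' @return The configuration with audit fields filled in.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "nk_config")) {
    abort("`cfg` must be created with `nk_config()`.")
  }
  for (fld in c("fps_vesicle", "stall_threshold", "mobility_displacement",
                "observation_time", "max_gap_frames", "immobility_radius",
                "d_free")) {
    assert_positive(cfg[[fld]], fld)
  }
  if (!is.numeric(cfg$min_track_frames) || cfg$min_track_frames < 2) {
    abort("`min_track_frames` must be at least 2.")
  }
  if (!is.numeric(cfg$mito_confidence) || cfg$mito_confidence <= 0 ||
      cfg$mito_confidence >= 1) {
    abort("`mito_confidence` must lie strictly inside (0, 1).")
  }
  cfg$stall_speed_um_s <- cfg$stall_threshold * cfg$fps_vesicle
  cfg$max_gap_ms <- cfg$max_gap_frames * 1000 / cfg$fps_vesicle
  cfg$min_track_duration_s <- cfg$min_track_frames / cfg$fps_vesicle
  cfg
}

#' @export
print.nk_config <- function(x, ...) {
  cat("<nk_config>\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flds)) cat(sprintf("  %-22s %s\n", nm, format(flds[[nm]])))
  invisible(x)
}

#' Read a configuration from a YAML or JSON file
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [nk_config()].
#' @return A validated `nk_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the 'yaml' package.")
    }
    yaml::read_yaml(path)
  }
  known <- names(formals(nk_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  validate_config(do.call(nk_config, vals))
}
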