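# vesicle transport: duration filter, orientation, mobility gate,
# per-step state segmentation and derived metrics
#
# conventions: signed arclength s in um with anterograde positive
# (increasing away from the axon-hillock reference); per-step displacement
# in um/frame, where a step spanning a 1-2 frame tracking gap is normalized
# by the number of frames elapsed; a step with |ds/frame| <= stall_threshold
# is a stalling event (equality is assigned to stall, the conservative
# call), larger positive steps are anterograde, larger negative retrograde.

#' Filter tracks by frame span
#'
#' Keeps tracks whose observed frame span (`last - first + 1`) is at least
#' `min_frames` (inclusive bound: a 15-frame track passes a 15-frame
#' minimum). Counts of kept and dropped tracks are reported via a message.
#'
#' @param tracks Track tibble.
#' @param min_frames Minimum frame span (default 15 frames = 3 s at 5
#'   frames/s).
#' @return The filtered tibble.
#' @export
filter_tracks <- function(tracks, min_frames = 15) {
  if (nrow(tracks) == 0) return(tracks)
  spans <- tracks |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::summarise(span = max(.data$frame) - min(.data$frame) + 1L,
                     .groups = "drop")
  keep <- spans[spans$span >= min_frames, c("cell_id", "track_id")]
  inform(sprintf("filter_tracks: kept %d of %d tracks (span >= %d frames).",
                 nrow(keep), nrow(spans), min_frames))
  dplyr::semi_join(tracks, keep, by = c("cell_id", "track_id"))
}

#' Orient tracks relative to an axon-hillock reference
#'
#' Re-expresses each track's arclength so that increasing values point away
#' from the reference point (anterograde positive): tracks lying at
#' arclengths above the reference keep their sign, tracks below it are
#' flipped. Moving the reference to the other side of a track therefore
#' swaps anterograde and retrograde while leaving speeds and state-change
#' counts unchanged.
#'
#' @param tracks Track tibble with an `s` column (um).
#' @param reference_s Arclength of the axon-hillock reference point, um.
#'   Required: direction is undefined without it.
#' @return The tibble with `s` replaced by the oriented arclength.
#' @export
orient_track <- function(tracks, reference_s) {
  if (missing(reference_s) || is.null(reference_s)) {
    abort("`reference_s` is required to assign transport direction.")
  }
  if (!"s" %in% names(tracks)) abort("`tracks` needs an `s` column.")
  tracks |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::mutate(s = sign(mean(.data$s) - reference_s) *
                    (.data$s - reference_s)) |>
    dplyr::ungroup()
}

#' Classify vesicle mobility
#'
#' A vesicle is mobile when its absolute net arclength displacement over
#' the observation window strictly exceeds `displacement_threshold`
#' ("more than" 0.75 um: a net displacement of exactly 0.75 um is
#' stationary). Tracks shorter than the nominal window are gated on their
#' own duration; the threshold is not rescaled.
#'
#' @param tracks Oriented track tibble with `s`.
#' @param displacement_threshold Mobility gate, um (default 0.75).
#' @return A tibble with one row per track: `cell_id`, `track_id`,
#'   `net_displacement_signed` (um), `duration` (s), `mobility`.
#' @export
classify_mobility <- function(tracks, displacement_threshold = 0.75) {
  tracks |>
    dplyr::arrange(.data$cell_id, .data$track_id, .data$frame) |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::summarise(
      net_displacement_signed = dplyr::last(.data$s) - dplyr::first(.data$s),
      duration = dplyr::last(.data$t) - dplyr::first(.data$t),
      .groups = "drop") |>
    dplyr::mutate(mobility = ifelse(
      abs(.data$net_displacement_signed) > displacement_threshold,
      "mobile", "stationary"))
}

#' Segment vesicle tracks into transport states
#'
#' For each pair of successive observations of a track, the per-frame
#' displacement is `ds_per_frame = (s_j - s_i) / (j - i)`: a step spanning
#' a 1- or 2-frame tracking gap is normalized by the frames elapsed. Steps
#' with `ds_per_frame > stall_threshold` are anterograde, steps below
#' `-stall_threshold` retrograde, everything in between (inclusive) a
#' stalling event. Gaps longer than `max_gap + 1` frames split the track
#' into separately segmented pieces (reported via a message); steps across
#' a split are not adjacent, so they contribute no state change.
#'
#' @param tracks Oriented track tibble with `s`.
#' @param stall_threshold Stall threshold, um/frame (default 0.02).
#' @param max_gap Longest bridgeable gap, frames (default 2).
#' @return A tibble of steps: `cell_id`, `track_id`, `segment`,
#'   `frame_start`, `frame_end`, `n_frames_spanned`, `ds` (um),
#'   `ds_per_frame` (um/frame), `state`, and `run_id` (index of the maximal
#'   same-state run within the track).
#' @export
segment_states <- function(tracks, stall_threshold = 0.02, max_gap = 2) {
  assert_positive(stall_threshold, "stall_threshold")
  split_count <- 0L
  steps <- tracks |>
    dplyr::arrange(.data$cell_id, .data$track_id, .data$frame) |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < 2) return(NULL)
      dfr <- diff(df$frame)
      ds <- diff(df$s)
      # segment id per step: over-long gaps start a new segment and the
      # step spanning them is dropped
      seg_id <- cumsum(c(0L, as.integer(dfr > max_gap + 1)))[seq_along(dfr)] + 1L
      keep <- dfr <= max_gap + 1
      if (any(!keep)) split_count <<- split_count + sum(!keep)
      if (!any(keep)) return(NULL)
      ds_pf <- ds / dfr
      state <- ifelse(ds_pf > stall_threshold, "anterograde",
                      ifelse(ds_pf < -stall_threshold, "retrograde",
                             "stall"))
      out <- tibble::tibble(
        segment = seg_id[keep],
        frame_start = df$frame[-nrow(df)][keep],
        frame_end = df$frame[-1][keep],
        n_frames_spanned = as.integer(dfr[keep]),
        ds = ds[keep], ds_per_frame = ds_pf[keep], state = state[keep])
      # maximal same-state runs, not crossing segment boundaries
      new_run <- c(TRUE, out$state[-1] != out$state[-nrow(out)] |
                     out$segment[-1] != out$segment[-nrow(out)])
      out$run_id <- cumsum(new_run)
      dplyr::bind_cols(key, out)
    }) |>
    dplyr::bind_rows()
  if (split_count > 0) {
    inform(sprintf(
      "segment_states: %d over-long gap(s) split tracks into segments.",
      split_count))
  }
  steps
}

count_state_changes <- function(steps_one_track) {
  st <- steps_one_track$state
  seg <- steps_one_track$segment
  if (length(st) < 2) return(0L)
  sum(st[-1] != st[-length(st)] & seg[-1] == seg[-length(seg)])
}

#' Per-track vesicle transport metrics
#'
#' From the segmented steps of mobile tracks: signed velocity (net
#' arclength change / duration, um/s), mean speed (mean |ds_per_frame| over
#' steps, converted to um/s), maximum speed on the track, processivity
#' (mean length in um of the maximal uninterrupted anterograde or
#' retrograde runs; stall-only tracks report `NA`, missing rather than
#' zero) and the number of state changes (adjacent step pairs with
#' different states).
#'
#' @param steps Step tibble from [segment_states()].
#' @param tracks The oriented track tibble the steps came from (for net
#'   displacement and duration).
#' @param fps Frames per second (converts um/frame to um/s).
#' @param mobility Optional tibble from [classify_mobility()]; when given,
#'   only mobile tracks are summarized.
#' @param processivity `"run_length"` (default: mean length of moving
#'   runs, um) or `"time_moving"` (fraction of step frames spent moving).
#' @return A tibble with one row per track: `cell_id`, `track_id`,
#'   `velocity`, `speed`, `max_speed`, `processivity`, `n_state_changes`,
#'   `n_runs_moving`.
#' @export
vesicle_metrics <- function(steps, tracks, fps = 5, mobility = NULL,
                            processivity = c("run_length", "time_moving")) {
  processivity <- match.arg(processivity)
  if (!is.null(mobility)) {
    keep <- mobility[mobility$mobility == "mobile",
                     c("cell_id", "track_id")]
    steps <- dplyr::semi_join(steps, keep, by = c("cell_id", "track_id"))
    tracks <- dplyr::semi_join(tracks, keep, by = c("cell_id", "track_id"))
  }
  if (nrow(steps) == 0) {
    abort("No steps to summarize (no mobile tracks?).")
  }
  net <- tracks |>
    dplyr::arrange(.data$cell_id, .data$track_id, .data$frame) |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::summarise(
      net_ds = dplyr::last(.data$s) - dplyr::first(.data$s),
      duration = dplyr::last(.data$t) - dplyr::first(.data$t),
      .groups = "drop")
  per_track <- steps |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::group_map(function(df, key) {
      moving <- df[df$state != "stall", ]
      runs <- if (nrow(moving) > 0) {
        moving |>
          dplyr::group_by(.data$run_id) |>
          dplyr::summarise(length_um = sum(abs(.data$ds)),
                           n_frames = sum(.data$n_frames_spanned))
      } else {
        NULL
      }
      proc <- if (is.null(runs)) {
        NA_real_
      } else if (processivity == "run_length") {
        mean(runs$length_um)
      } else {
        sum(runs$n_frames) / sum(df$n_frames_spanned)
      }
      dplyr::bind_cols(key, tibble::tibble(
        speed = mean(abs(df$ds_per_frame)) * fps,
        max_speed = max(abs(df$ds_per_frame)) * fps,
        processivity = proc,
        n_state_changes = count_state_changes(df),
        n_runs_moving = if (is.null(runs)) 0L else nrow(runs)))
    }) |>
    dplyr::bind_rows()
  dplyr::left_join(per_track, net, by = c("cell_id", "track_id")) |>
    dplyr::mutate(velocity = .data$net_ds / .data$duration) |>
    dplyr::select(dplyr::all_of(c(
      "cell_id", "track_id", "velocity", "speed", "max_speed",
      "processivity", "n_state_changes", "n_runs_moving")))
}

#' Per-cell vesicle transport summary
#'
#' Unweighted per-cell means of velocity, speed, max speed and processivity
#' over that cell's mobile tracks, the per-cell mean and total state
#' changes, and the mobile fraction. Cells without mobile tracks report
#' missing means.
#'
#' @param metrics Per-track tibble from [vesicle_metrics()] (mobile tracks).
#' @param mobility Per-track tibble from [classify_mobility()] (all
#'   tracks, for the mobile fraction).
#' @return A tibble with one row per cell.
#' @export
summarize_vesicles <- function(metrics, mobility) {
  if (nrow(mobility) == 0) abort("No tracks to summarize.")
  frac <- mobility |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_tracks = dplyr::n(),
                     frac_mobile = mean(.data$mobility == "mobile"))
  means <- metrics |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_mobile = dplyr::n(),
      mean_velocity = mean(.data$velocity),
      mean_speed = mean(.data$speed),
      mean_max_speed = mean(.data$max_speed),
      mean_processivity = mean(.data$processivity, na.rm = TRUE),
      mean_state_changes = mean(.data$n_state_changes),
      total_state_changes = sum(.data$n_state_changes))
  dplyr::left_join(frac, means, by = "cell_id") |>
    dplyr::mutate(n_mobile = dplyr::coalesce(.data$n_mobile, 0L))
}

#' Full vesicle transport pipeline
#'
#' Chains the analysis steps on a raw track table: duration filter,
#' orientation, mobility gate, state segmentation, per-track metrics and
#' the per-cell summary.
#'
#' @param tracks Track tibble with `s`.
#' @param reference_s Axon-hillock reference arclength, um.
#' @param config A validated [nk_config()].
#' @return A list: `mobility`, `steps`, `metrics`, `summary`.
#' @export
analyze_vesicles <- function(tracks, reference_s, config = validate_config(nk_config())) {
  tracks <- filter_tracks(tracks, config$min_track_frames) |>
    orient_track(reference_s)
  mobility <- classify_mobility(tracks, config$mobility_displacement)
  steps <- segment_states(tracks, config$stall_threshold,
                          config$max_gap_frames)
  metrics <- vesicle_metrics(steps, tracks, fps = config$fps_vesicle,
                             mobility = mobility)
  list(mobility = mobility, steps = steps, metrics = metrics,
       summary = summarize_vesicles(metrics, mobility))
}
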