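# mitochondria transport: mobile/stationary/undefined classification and
# kinematic summaries
#
# the classifier compares the distribution of a track's per-frame apparent
# diameters against the track's displacement with a one-sample t-test: a
# mitochondrion is mobile when it moved significantly farther than its own
# diameter (t < 0, i.e. mean diameter below the displacement), stationary
# when it moved significantly less (t >= 0), and undefined when the test is
# inconclusive. "p" in the decision rule is a confidence level,
# 1 - (two-sided p-value), so the printed threshold 0.95 applies unchanged.

track_position_cols <- function(df) {
  if (all(c("x", "y") %in% names(df)) &&
      all(is.finite(df$x)) && all(is.finite(df$y))) {
    c("x", "y")
  } else if ("s" %in% names(df)) {
    "s"
  } else {
    abort("Track needs either (x, y) or s positions.")
  }
}

track_net_displacement <- function(df, cols) {
  if (length(cols) == 2) {
    point_distance(df$x[1], df$y[1], df$x[nrow(df)], df$y[nrow(df)])
  } else {
    abs(df$s[nrow(df)] - df$s[1])
  }
}

track_max_excursion <- function(df, cols) {
  if (length(cols) == 2) {
    max(point_distance(df$x[1], df$y[1], df$x, df$y))
  } else {
    max(abs(df$s - df$s[1]))
  }
}

track_path_length <- function(df, cols) {
  if (length(cols) == 2) sum(step_lengths(df$x, df$y)) else
    sum(step_lengths(df$s))
}

#' Per-track kinematics
#'
#' For every (cell, track): net displacement (straight-line distance
#' between first and last position), path length (sum of inter-frame step
#' lengths), duration, velocity (net displacement / duration) and speed
#' (path length / duration). The triangle inequality guarantees
#' `path_length >= net_displacement`, hence `speed >= velocity`.
#'
#' @param tracks Track tibble (`cell_id`, `track_id`, `frame`, `t`, and
#'   `x`/`y` or `s`), e.g. from [read_tracks()].
#' @return A tibble with one row per track: `cell_id`, `track_id`,
#'   `n_frames`, `duration`, `net_displacement`, `path_length`, `velocity`,
#'   `speed`.
#' @export
track_kinematics <- function(tracks) {
  short <- tracks |>
    dplyr::count(.data$cell_id, .data$track_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(short) > 0) {
    abort(sprintf("Track(s) with fewer than 2 frames: %s.",
                  paste(short$track_id, collapse = ", ")))
  }
  tracks |>
    dplyr::arrange(.data$cell_id, .data$track_id, .data$frame) |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::group_map(function(df, key) {
      cols <- track_position_cols(df)
      dur <- df$t[nrow(df)] - df$t[1]
      net <- track_net_displacement(df, cols)
      path <- track_path_length(df, cols)
      dplyr::bind_cols(key, tibble::tibble(
        n_frames = nrow(df), duration = dur,
        net_displacement = net, path_length = path,
        velocity = net / dur, speed = path / dur))
    }) |>
    dplyr::bind_rows()
}

#' Classify mitochondria as mobile, stationary or undefined
#'
#' One-sample t-statistic of each track's per-frame diameter distribution
#' against the track's displacement:
#' \deqn{t = \frac{\bar{d} - \mathrm{disp}}{s_d / \sqrt{n}},}
#' with a two-sided p-value on n - 1 degrees of freedom and confidence
#' `1 - p`. Decision rule: mobile when confidence > threshold and t < 0;
#' stationary when confidence > threshold and t >= 0; undefined otherwise.
#' Tracks with fewer than 3 diameter observations are undefined (no t-test
#' possible); zero diameter variance degenerates to labeling by the sign of
#' (mean diameter - displacement) with confidence 1 (reported via a
#' message).
#'
#' @param tracks Mito track tibble with a `diameter` column (um).
#' @param confidence_threshold Confidence level required for a definite
#'   label (default 0.95).
#' @param displacement `"net"` (straight-line first-to-last distance, the
#'   default) or `"max"` (maximal excursion from the start).
#' @return A tibble with one row per track: `cell_id`, `track_id`, `label`,
#'   `t_stat`, `confidence`, `displacement`, `mean_diameter`, `n_frames`.
#' @export
classify_mito <- function(tracks, confidence_threshold = 0.95,
                          displacement = c("net", "max")) {
  displacement <- match.arg(displacement)
  if (!"diameter" %in% names(tracks)) {
    abort("`tracks` needs a `diameter` column (mito schema).")
  }
  degenerate <- 0L
  out <- tracks |>
    dplyr::arrange(.data$cell_id, .data$track_id, .data$frame) |>
    dplyr::group_by(.data$cell_id, .data$track_id) |>
    dplyr::group_map(function(df, key) {
      cols <- track_position_cols(df)
      disp <- if (displacement == "net") {
        track_net_displacement(df, cols)
      } else {
        track_max_excursion(df, cols)
      }
      d <- df$diameter[is.finite(df$diameter)]
      n <- length(d)
      if (n < 3) {
        return(dplyr::bind_cols(key, tibble::tibble(
          label = "undefined", t_stat = NA_real_, confidence = NA_real_,
          displacement = disp, mean_diameter = mean(d), n_frames = n)))
      }
      if (sd(d) == 0) {
        degenerate <<- degenerate + 1L
        tstat <- sign(mean(d) - disp) * Inf
        conf <- 1
      } else {
        tstat <- (mean(d) - disp) / (sd(d) / sqrt(n))
        conf <- 1 - 2 * pt(-abs(tstat), df = n - 1)
      }
      label <- if (conf > confidence_threshold) {
        if (tstat < 0) "mobile" else "stationary"
      } else {
        "undefined"
      }
      dplyr::bind_cols(key, tibble::tibble(
        label = label, t_stat = tstat, confidence = conf,
        displacement = disp, mean_diameter = mean(d), n_frames = n))
    }) |>
    dplyr::bind_rows()
  if (degenerate > 0) {
    inform(sprintf(
      "%d track(s) had zero diameter variance; labeled by sign of (mean diameter - displacement).",
      degenerate))
  }
  out
}

#' Per-cell mitochondria transport summary
#'
#' Fractions of mobile, stationary and undefined tracks per cell (summing
#' to 1 over all tracks), the same fractions among defined tracks only,
#' and mean velocity and speed over the mobile tracks. Cells without
#' mobile tracks report `NA` velocity/speed (missing, not zero); cells
#' where every track is undefined report `NA` defined fractions.
#'
#' @param classifications Output of [classify_mito()].
#' @param kinematics Output of [track_kinematics()] on the same tracks.
#' @return A tibble with one row per cell.
#' @export
summarize_mito <- function(classifications, kinematics) {
  if (nrow(classifications) == 0) abort("No classifications to summarize.")
  merged <- dplyr::left_join(
    classifications,
    dplyr::select(kinematics, dplyr::all_of(
      c("cell_id", "track_id", "velocity", "speed"))),
    by = c("cell_id", "track_id"))
  merged |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      frac_mobile = mean(.data$label == "mobile"),
      frac_stationary = mean(.data$label == "stationary"),
      frac_undefined = mean(.data$label == "undefined"),
      n_defined = sum(.data$label != "undefined"),
      frac_mobile_defined = ifelse(
        .data$n_defined > 0,
        sum(.data$label == "mobile") / .data$n_defined, NA_real_),
      mean_velocity_mobile = ifelse(
        any(.data$label == "mobile"),
        mean(.data$velocity[.data$label == "mobile"]), NA_real_),
      mean_speed_mobile = ifelse(
        any(.data$label == "mobile"),
        mean(.data$speed[.data$label == "mobile"]), NA_real_))
}
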