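# ggplot2 graphics for the main result types

#' Plot FDAP curves
#'
#' @param curves Tibble with `cell_id`, `t`, `F`.
#' @param alpha Line transparency.
#' @return A ggplot.
#' @export
plot_fdap_curves <- function(curves, alpha = 0.6) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$t, .data$F,
                                       group = .data$cell_id)) +
    ggplot2::geom_line(alpha = alpha, colour = "grey30") +
    ggplot2::labs(x = "time after activation (s)",
                  y = "normalized fluorescence") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_deff Plot the fitted curve over the data.
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t = seq(min(object$data$t), max(object$data$t), length.out = 200))
  grid$F <- predict(object, grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$t, .data$F)) +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "time after activation (s)",
                  y = "normalized fluorescence",
                  title = sprintf("%s model fit", object$model)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_residence_time Plot the dwell histogram with the
#'   exponential fit.
#' @param object A `residence_fit`.
#' @param ... Unused.
#' @export
autoplot.residence_fit <- function(object, ...) {
  h <- object$histogram
  dt <- object$frame_interval
  grid <- tibble::tibble(
    n = seq(min(h$duration_frames), max(h$duration_frames),
            length.out = 200))
  grid$count <- object$amplitude * exp(-grid$n * dt / object$tau_res)
  ggplot2::ggplot(h, ggplot2::aes(.data$duration_frames, .data$count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$n, .data$count),
                       colour = "firebrick") +
    ggplot2::labs(x = "immobile duration (frames)", y = "events",
                  title = sprintf("residence time %.1f ms", object$tau_res)) +
    ggplot2::theme_minimal()
}

#' Kymograph-style state plot of segmented vesicle tracks
#'
#' Arclength against time for each track, colored by the assigned
#' transport state of the step that ends at each observation.
#'
#' @param steps Step tibble from [segment_states()].
#' @param tracks The oriented track tibble.
#' @param max_tracks Plot at most this many tracks.
#' @return A ggplot.
#' @export
plot_track_states <- function(steps, tracks, max_tracks = 12) {
  ids <- utils::head(unique(steps$track_id), max_tracks)
  seg <- steps[steps$track_id %in% ids, ]
  pos <- tracks[tracks$track_id %in% ids, ]
  pos <- dplyr::left_join(
    pos,
    dplyr::select(seg, dplyr::all_of(
      c("cell_id", "track_id", "frame_end", "state"))),
    by = c("cell_id", "track_id", frame = "frame_end"))
  ggplot2::ggplot(pos, ggplot2::aes(.data$t, .data$s,
                                    group = .data$track_id)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 0.8,
                        na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(anterograde = "#2166ac", retrograde = "#b2182b",
                 stall = "grey50"), na.translate = FALSE) +
    ggplot2::facet_wrap(~track_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "arclength from hillock (um)") +
    ggplot2::theme_minimal()
}
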