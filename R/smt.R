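# single-molecule residence-time analysis
#
# an immobile event is a stretch of consecutive frames during which a
# molecule stays within `radius` of the event's first localization (the
# anchor). Anchoring to the first localization -- rather than a rolling
# centroid -- is the simplest reading of a "stays within a radius"
# criterion; gaps terminate events because the criterion counts
# *consecutive* frames. Events touching the ends of a track are kept
# (naive counting), a known source of mild censoring bias.

#' Detect immobile events in localization series
#'
#' Scans each molecule's localizations in frame order. An event opens at an
#' anchor localization and extends while each subsequent *consecutive*
#' frame lies within `radius` of the anchor; the event closes at the first
#' distance violation or frame gap. Events spanning at least 2 frames are
#' reported (a single frame cannot evidence dwelling); the closing frame
#' may anchor a new event.
#'
#' @param localizations Tibble with columns `molecule_id`, `frame`, `x`,
#'   `y` (um), e.g. from [read_localizations()] or [simulate_smt()].
#' @param radius Immobility radius, nm (default 50).
#' @return A tibble with one row per event: `molecule_id`, `start_frame`,
#'   `duration_frames`.
#' @export
#' @examples
#' locs <- tibble::tibble(molecule_id = "m1", frame = 0:4,
#'                        x = c(0, 0.01, 0.02, 0.01, 0.5), y = 0)
#' detect_immobile_events(locs, radius = 50)
detect_immobile_events <- function(localizations, radius = 50) {
  assert_positive(radius, "radius")
  if (nrow(localizations) == 0) {
    return(tibble::tibble(molecule_id = character(),
                          start_frame = integer(),
                          duration_frames = integer()))
  }
  r_um <- radius / 1000
  localizations |>
    dplyr::arrange(.data$molecule_id, .data$frame) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      events <- list()
      anchor <- 1L
      len <- 1L
      close_event <- function(events, start, len) {
        if (len >= 2L) {
          events[[length(events) + 1L]] <-
            c(start = df$frame[start], dur = len)
        }
        events
      }
      if (n >= 2) {
        for (k in 2:n) {
          consecutive <- df$frame[k] == df$frame[k - 1] + 1L
          within <- point_distance(df$x[anchor], df$y[anchor],
                                   df$x[k], df$y[k]) <= r_um
          if (consecutive && within) {
            len <- len + 1L
          } else {
            events <- close_event(events, anchor, len)
            anchor <- k
            len <- 1L
          }
        }
      }
      events <- close_event(events, anchor, len)
      if (length(events) == 0) return(NULL)
      ev <- do.call(rbind, events)
      tibble::tibble(molecule_id = key$molecule_id,
                     start_frame = as.integer(ev[, "start"]),
                     duration_frames = as.integer(ev[, "dur"]))
    }) |>
    dplyr::bind_rows()
}

#' Build a dwell-duration frequency histogram
#'
#' Integer-binned frequency table of event durations (frames), including
#' zero-count bins inside the observed range so an exponential fit sees
#' the full support.
#'
#' @param durations Integer event durations in frames (each `>= 2`), e.g.
#'   the `duration_frames` column from [detect_immobile_events()].
#' @param frame_interval Frame interval, ms (carried for time conversion).
#' @return A tibble of class `dwell_histogram` with columns
#'   `duration_frames` and `count`; attributes `frame_interval` (ms) and
#'   `n_events`.
#' @export
build_dwell_histogram <- function(durations, frame_interval) {
  assert_positive(frame_interval, "frame_interval")
  if (length(durations) == 0) {
    abort("No events: report zero events rather than building a histogram.")
  }
  if (any(durations < 2) || any(durations != round(durations))) {
    abort("Durations must be integer frame counts >= 2.")
  }
  counts <- tibble::tibble(
    duration_frames = seq(min(durations), max(durations)),
    count = as.integer(tabulate(factor(durations,
                                       levels = seq(min(durations),
                                                    max(durations))))))
  structure(counts, class = c("dwell_histogram", class(counts)),
            frame_interval = frame_interval,
            n_events = length(durations))
}

#' Fit a mono-exponential residence time to a dwell histogram
#'
#' Least squares of \eqn{counts(n) = A \exp(-n\,\Delta t / \tau)} over
#' \eqn{(A, \tau)} on the raw counts (zero-count bins inside the observed
#' range included), where \eqn{\Delta t} is the frame interval in ms. The
#' time constant \eqn{\tau} is the residence (dwell) time. Initialized from
#' a log-linear regression on the positive counts, refined by [nlminb()].
#'
#' @param h A `dwell_histogram` from [build_dwell_histogram()], with at
#'   least 3 distinct duration bins.
#' @return A list of class `residence_fit`: `tau_res` (ms), `amplitude`
#'   (counts at n = 0), `fit_r2`, `n_events`, `converged`, plus the
#'   histogram.
#' @export
fit_residence_time <- function(h) {
  if (!inherits(h, "dwell_histogram")) {
    abort("`h` must come from build_dwell_histogram().")
  }
  if (nrow(h) < 3) {
    abort("Need at least 3 duration bins; collect more events.")
  }
  dt <- attr(h, "frame_interval")
  n <- h$duration_frames
  y <- h$count
  pos <- y > 0
  if (sum(pos) < 2) abort("Need at least 2 non-empty bins.")
  init_fit <- stats::lm(log(y[pos]) ~ n[pos])
  slope <- unname(stats::coef(init_fit)[2])
  tau0 <- if (is.finite(slope) && slope < 0) -dt / slope else dt * mean(n)
  a0 <- exp(unname(stats::coef(init_fit)[1]))
  obj <- function(p) sum((y - exp(p[1]) * exp(-n * dt / exp(p[2])))^2)
  opt <- nlminb(c(log(a0), log(tau0)), obj)
  amplitude <- exp(opt$par[1])
  tau <- exp(opt$par[2])
  ss_res <- opt$objective
  ss_tot <- sum((y - mean(y))^2)
  structure(list(tau_res = tau, amplitude = amplitude,
                 fit_r2 = 1 - ss_res / ss_tot,
                 n_events = attr(h, "n_events"),
                 converged = opt$convergence == 0,
                 frame_interval = dt, histogram = h),
            class = "residence_fit")
}

#' Residence-time analysis of a localization table
#'
#' Convenience wrapper: detect immobile events, build the dwell histogram
#' and fit the mono-exponential residence time.
#'
#' @inheritParams detect_immobile_events
#' @param frame_interval Frame interval, ms.
#' @return A `residence_fit`; the event table is attached as `$events`.
#' @export
residence_time <- function(localizations, radius = 50, frame_interval) {
  ev <- detect_immobile_events(localizations, radius = radius)
  if (nrow(ev) == 0) abort("No immobile events detected.")
  fit <- fit_residence_time(
    build_dwell_histogram(ev$duration_frames, frame_interval))
  fit$events <- ev
  fit
}

#' @export
print.residence_fit <- function(x, ...) {
  cat(sprintf(
    "<residence_fit: tau = %.1f ms from %d events (R^2 = %.3f)>\n",
    x$tau_res, x$n_events, x$fit_r2))
  invisible(x)
}

#' Tidy a residence-time fit
#'
#' @param x A `residence_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (`tau_res` in ms,
#'   `amplitude` in counts).
#' @export
tidy.residence_fit <- function(x, ...) {
  tibble::tibble(term = c("tau_res", "amplitude"),
                 estimate = c(x$tau_res, x$amplitude))
}

#' One-row summary of a residence-time fit
#'
#' @param x A `residence_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `tau_res`, `amplitude`, `fit_r2`, `n_events`,
#'   `converged`.
#' @export
glance.residence_fit <- function(x, ...) {
  tibble::tibble(tau_res = x$tau_res, amplitude = x$amplitude,
                 fit_r2 = x$fit_r2, n_events = x$n_events,
                 converged = x$converged)
}
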