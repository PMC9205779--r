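# synthetic organelle transport: mobile/stationary mitochondria and
# 3-state (anterograde / retrograde / stall) vesicle dynamics along a 1-D
# neurite, with tracking gaps.

CARGO_STATES <- c("anterograde", "retrograde", "stall")

#' Default 3-state transition-rate matrix
#'
#' Continuous-time transition rates (1/s) between the anterograde,
#' retrograde and stalled states of a moving cargo. Rows are the current
#' state, columns the destination; diagonals are ignored. The default gives
#' runs of tens of seconds punctuated by stalls, with a slight anterograde
#' bias out of the stalled state -- a few state changes per minute-long
#' track, the regime seen for axonal APP vesicles.
#'
#' @param a_to_r,a_to_s Rates out of the anterograde state, 1/s.
#' @param r_to_a,r_to_s Rates out of the retrograde state, 1/s.
#' @param s_to_a,s_to_r Rates out of the stalled state, 1/s.
#' @return A 3 x 3 matrix with dimnames `anterograde`, `retrograde`,
#'   `stall`.
#' @export
cargo_state_rates <- function(a_to_r = 0.02, a_to_s = 0.05,
                              r_to_a = 0.02, r_to_s = 0.05,
                              s_to_a = 0.05, s_to_r = 0.03) {
  m <- matrix(c(0, a_to_r, a_to_s,
                r_to_a, 0, r_to_s,
                s_to_a, s_to_r, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(CARGO_STATES, CARGO_STATES))
  if (any(m < 0)) abort("Transition rates must be >= 0.")
  m
}

#' Parameters for the organelle-track simulators
#'
#' Shared by [simulate_mito_tracks()] and [simulate_vesicle_tracks()].
#' Vesicle defaults match the acquisition the analysis assumes (60 s at 5
#' frames/s, ~20% mobile, run speeds around 1 um/s); mitochondria are imaged
#' more slowly (8 min at one frame per 2 s), move at a few hundred nm/s and
#' carry a fluctuating apparent diameter (lognormal per frame).
#'
#' @param n_tracks Number of tracks.
#' @param n_cells Number of cells the tracks are spread over (uniformly at
#'   random).
#' @param p_mobile Probability that a track belongs to the mobile
#'   subpopulation.
#' @param speed_antero,speed_retro Run speeds per state, um/s.
#' @param state_rates 3 x 3 transition-rate matrix, see
#'   [cargo_state_rates()].
#' @param duration Track duration, s.
#' @param fps Frames per second.
#' @param gap_probability Per-frame probability that a localization is
#'   dropped. Gaps never exceed `max_gap_frames` consecutive frames and
#'   never remove the first or last frame, so tracks stay linkable.
#' @param max_gap_frames Longest allowed gap, frames.
#' @param diameter_mean Mean apparent diameter, um (mitochondria only).
#' @param diameter_cv Coefficient of variation of the per-frame diameter
#'   (mitochondria only).
#' @param position_noise Localization noise SD per coordinate, nm.
#' @return A list of class `cargo_sim_params`.
#' @export
cargo_sim_params <- function(n_tracks = 200, n_cells = 10, p_mobile = 0.2,
                             speed_antero = 1.0, speed_retro = 0.8,
                             state_rates = cargo_state_rates(),
                             duration = 60, fps = 5,
                             gap_probability = 0.05, max_gap_frames = 2,
                             diameter_mean = 0.5, diameter_cv = 0.1,
                             position_noise = 10) {
  assert_fraction(p_mobile, "p_mobile")
  assert_fraction(gap_probability, "gap_probability")
  if (speed_antero < 0 || speed_retro < 0) abort("Speeds must be >= 0.")
  assert_positive(duration, "duration")
  assert_positive(fps, "fps")
  assert_positive(diameter_mean, "diameter_mean")
  if (diameter_cv < 0) abort("`diameter_cv` must be >= 0.")
  if (position_noise < 0) abort("`position_noise` must be >= 0.")
  stopifnot(is.matrix(state_rates), all(dim(state_rates) == c(3, 3)),
            all(state_rates >= 0))
  structure(list(n_tracks = n_tracks, n_cells = n_cells,
                 p_mobile = p_mobile, speed_antero = speed_antero,
                 speed_retro = speed_retro, state_rates = state_rates,
                 duration = duration, fps = fps,
                 gap_probability = gap_probability,
                 max_gap_frames = max_gap_frames,
                 diameter_mean = diameter_mean, diameter_cv = diameter_cv,
                 position_noise = position_noise),
            class = "cargo_sim_params")
}

# per-frame 3-state Markov chain: leave state i within a frame with
# probability 1 - exp(-q_i / fps), destination by relative rates
simulate_state_chain <- function(n_steps, rates, fps, init = NULL) {
  leave <- rowSums(rates)
  p_leave <- 1 - exp(-leave / fps)
  # stationary-ish start: uniform over states unless given
  state <- integer(n_steps)
  state[1] <- init %||% sample.int(3, 1)
  if (n_steps > 1) {
    u <- runif(n_steps - 1)
    for (k in 2:n_steps) {
      s <- state[k - 1]
      if (u[k - 1] < p_leave[s]) {
        state[k] <- sample.int(3, 1, prob = rates[s, ] / leave[s])
      } else {
        state[k] <- s
      }
    }
  }
  state
}

# drop frames i.i.d. but never > max_gap consecutive and never the ends
inject_gaps <- function(frames, gap_probability, max_gap) {
  n <- length(frames)
  if (gap_probability <= 0 || n <= 2) return(rep(TRUE, n))
  keep <- runif(n) >= gap_probability
  keep[c(1, n)] <- TRUE
  run <- 0L
  for (k in seq_len(n)) {
    if (!keep[k]) {
      run <- run + 1L
      if (run > max_gap) {
        keep[k] <- TRUE
        run <- 0L
      }
    } else {
      run <- 0L
    }
  }
  keep
}

#' Simulate mitochondria tracks with known mobility labels
#'
#' Stationary mitochondria jitter around a fixed point with
#' `position_noise`; mobile mitochondria follow the 3-state run-and-pause
#' chain along the process axis. Every frame carries an apparent diameter
#' drawn from a lognormal with mean `diameter_mean` and coefficient of
#' variation `diameter_cv`, emulating the frame-to-frame diameter
#' fluctuation caused by z-motion, rotation and fusion/fission.
#'
#' @param params A [cargo_sim_params()] list; mitochondria-appropriate
#'   settings are `fps = 0.5`, `duration = 480` (8 min at one frame per
#'   2 s), `speed_antero = 0.3`, `speed_retro = 0.25`,
#'   `position_noise = 20`.
#' @param seed Integer seed; pure function of `(params, seed)`.
#' @return A list with `tracks` (tibble `cell_id`, `track_id`, `frame`,
#'   `t`, `x`, `y`, `diameter`) and `truth` (tibble `track_id`, `cell_id`,
#'   `label` in mobile/stationary).
#' @export
simulate_mito_tracks <- function(params = cargo_sim_params(
                                   fps = 0.5, duration = 480,
                                   speed_antero = 0.3, speed_retro = 0.25,
                                   position_noise = 20),
                                 seed = NULL) {
  stopifnot(inherits(params, "cargo_sim_params"))
  n_fr <- floor(params$duration * params$fps) + 1
  sdlog <- sqrt(log(1 + params$diameter_cv^2))
  meanlog <- log(params$diameter_mean) - sdlog^2 / 2
  noise_um <- params$position_noise / 1000
  with_seed(seed, {
    mobile <- runif(params$n_tracks) < params$p_mobile
    cells <- sample.int(params$n_cells, params$n_tracks, replace = TRUE)
    res <- purrr::map(seq_len(params$n_tracks), function(i) {
      x0 <- runif(1, 10, 100)
      y0 <- runif(1, -2, 2)
      if (mobile[i]) {
        st <- simulate_state_chain(n_fr, params$state_rates, params$fps)
        v <- c(params$speed_antero, -params$speed_retro, 0)[st] / params$fps
        x <- x0 + cumsum(c(0, v[-1])) + rnorm(n_fr, sd = noise_um)
      } else {
        x <- x0 + rnorm(n_fr, sd = noise_um)
      }
      y <- y0 + rnorm(n_fr, sd = noise_um)
      keep <- inject_gaps(seq_len(n_fr), params$gap_probability,
                          params$max_gap_frames)
      tibble::tibble(
        cell_id = sprintf("cell_%02d", cells[i]),
        track_id = sprintf("mito_%04d", i),
        frame = (seq_len(n_fr) - 1L)[keep],
        t = ((seq_len(n_fr) - 1) / params$fps)[keep],
        x = x[keep], y = y[keep],
        diameter = rlnorm(sum(keep), meanlog, sdlog))
    })
    tracks <- dplyr::bind_rows(res) |>
      dplyr::arrange(.data$cell_id, .data$track_id, .data$frame)
    truth <- tibble::tibble(
      track_id = sprintf("mito_%04d", seq_len(params$n_tracks)),
      cell_id = sprintf("cell_%02d", cells),
      label = ifelse(mobile, "mobile", "stationary"))
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate vesicle tracks with known per-frame states
#'
#' Mobile vesicles follow the 3-state Markov chain along the neurite; their
#' signed arclength `s` (anterograde positive) increments by the state
#' speed divided by `fps`, plus localization noise. Stationary vesicles
#' stay in the stalled state throughout. Frames are dropped i.i.d. with
#' `gap_probability`, never more than `max_gap_frames` in a row, mirroring
#' the gap limit of the upstream tracker.
#'
#' @param params A [cargo_sim_params()] list (vesicle defaults apply).
#' @param seed Integer seed; pure function of `(params, seed)`.
#' @return A list with `tracks` (tibble `cell_id`, `track_id`, `frame`,
#'   `t`, `s`), `truth_states` (tibble `track_id`, `frame`, `state`: the
#'   generative per-frame state), and `truth` (per-track tibble with
#'   `label` and `n_state_changes`, the number of adjacent generative
#'   frame pairs with different states).
#' @export
simulate_vesicle_tracks <- function(params = cargo_sim_params(),
                                    seed = NULL) {
  stopifnot(inherits(params, "cargo_sim_params"))
  n_fr <- floor(params$duration * params$fps) + 1
  noise_um <- params$position_noise / 1000
  with_seed(seed, {
    mobile <- runif(params$n_tracks) < params$p_mobile
    cells <- sample.int(params$n_cells, params$n_tracks, replace = TRUE)
    res <- purrr::map(seq_len(params$n_tracks), function(i) {
      s0 <- runif(1, 5, 50)
      if (mobile[i]) {
        st <- simulate_state_chain(n_fr, params$state_rates, params$fps)
      } else {
        st <- rep(3L, n_fr)
      }
      v <- c(params$speed_antero, -params$speed_retro, 0)[st] / params$fps
      s <- s0 + cumsum(c(0, v[-1])) + rnorm(n_fr, sd = noise_um)
      keep <- inject_gaps(seq_len(n_fr), params$gap_probability,
                          params$max_gap_frames)
      id <- sprintf("ves_%04d", i)
      list(
        track = tibble::tibble(
          cell_id = sprintf("cell_%02d", cells[i]),
          track_id = id,
          frame = (seq_len(n_fr) - 1L)[keep],
          t = ((seq_len(n_fr) - 1) / params$fps)[keep],
          s = s[keep]),
        states = tibble::tibble(track_id = id, frame = seq_len(n_fr) - 1L,
                                state = CARGO_STATES[st]),
        changes = sum(st[-1] != st[-n_fr]))
    })
    tracks <- purrr::map_dfr(res, "track") |>
      dplyr::arrange(.data$cell_id, .data$track_id, .data$frame)
    truth <- tibble::tibble(
      track_id = sprintf("ves_%04d", seq_len(params$n_tracks)),
      cell_id = sprintf("cell_%02d", cells),
      label = ifelse(mobile, "mobile", "stationary"),
      n_state_changes = purrr::map_int(res, ~ as.integer(.x$changes)))
    list(tracks = tracks, truth_states = purrr::map_dfr(res, "states"),
         truth = truth)
  })
}
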