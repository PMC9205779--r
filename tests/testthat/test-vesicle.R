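ves_track <- function(id, s, frames = seq_along(s) - 1L, fps = 5,
                      cell = "c1") {
  tibble::tibble(cell_id = cell, track_id = id, frame = as.integer(frames),
                 t = frames / fps, s = s)
}

test_that("the duration filter keeps 15-frame tracks and drops 14-frame ones", {
  short <- ves_track("short", s = rep(0, 14))
  exact <- ves_track("exact", s = rep(0, 15))
  both <- dplyr::bind_rows(short, exact)
  kept <- suppressMessages(filter_tracks(both, min_frames = 15))
  expect_setequal(unique(kept$track_id), "exact")
  expect_equal(nrow(suppressMessages(filter_tracks(both[0, ], 15))), 0)
  # span counts frames, not rows: gaps do not shorten a track
  gappy <- ves_track("gappy", s = rep(0, 13),
                     frames = c(0:5, 7:12, 14))
  expect_equal(
    unique(suppressMessages(filter_tracks(gappy, 15))$track_id), "gappy")
})

test_that("orientation makes motion away from the reference positive", {
  away <- ves_track("a", s = seq(10, 15, length.out = 20))
  o <- orient_track(away, reference_s = 0)
  expect_gt(dplyr::last(o$s) - dplyr::first(o$s), 0)
  # reference on the other side flips the sign
  o2 <- orient_track(away, reference_s = 100)
  expect_lt(dplyr::last(o2$s) - dplyr::first(o2$s), 0)
  expect_error(orient_track(away), "reference_s")
})

test_that("direction flip swaps antero/retro and preserves scalar metrics", {
  withr::with_seed(17, {
    s <- 20 + cumsum(sample(c(0.15, -0.12, 0), 40, replace = TRUE,
                            prob = c(.4, .3, .3)))
  })
  tr <- ves_track("flip", s = s)
  near <- orient_track(tr, reference_s = 0)
  far <- orient_track(tr, reference_s = 1000)
  st_near <- segment_states(near)
  st_far <- segment_states(far)
  expect_equal(sum(st_near$state == "anterograde"),
               sum(st_far$state == "retrograde"))
  expect_equal(sum(st_near$state == "retrograde"),
               sum(st_far$state == "anterograde"))
  expect_equal(sum(st_near$state == "stall"), sum(st_far$state == "stall"))
  m_near <- vesicle_metrics(st_near, near)
  m_far <- vesicle_metrics(st_far, far)
  expect_equal(m_near$velocity, -m_far$velocity)
  expect_equal(m_near$speed, m_far$speed)
  expect_equal(m_near$processivity, m_far$processivity)
  expect_equal(m_near$n_state_changes, m_far$n_state_changes)
})

test_that("the mobility gate is strict at 0.75 um", {
  for (net in c(0.74, 0.75, 0.76)) {
    tr <- ves_track("g", s = seq(0, net, length.out = 20))
    got <- classify_mobility(tr)$mobility
    expect_equal(got, if (net > 0.75) "mobile" else "stationary")
  }
})

test_that("uniform motion gives a single run with no state changes", {
  tr <- ves_track("u", s = cumsum(rep(0.1, 21)))
  st <- segment_states(tr)
  expect_true(all(st$state == "anterograde"))
  expect_equal(dplyr::n_distinct(st$run_id), 1)
  m <- vesicle_metrics(st, tr)
  expect_equal(m$n_state_changes, 0)
})

test_that("alternating direction yields a state change at every step", {
  tr <- ves_track("alt", s = cumsum(c(0, rep(c(0.1, -0.1), 5))))
  st <- segment_states(tr)
  expect_equal(nrow(st), 10)
  expect_equal(count_state_changes(st), 9)
})

test_that("steps across bridgeable gaps are normalized per frame", {
  # +0.03 um over a 2-frame gap (3 frames elapsed) -> 0.01 um/frame: stall
  tr <- ves_track("gap", s = c(0, 0.03, 0.06),
                  frames = c(0L, 3L, 6L))
  st <- segment_states(tr, stall_threshold = 0.02, max_gap = 2)
  expect_equal(st$ds_per_frame, c(0.01, 0.01))
  expect_true(all(st$state == "stall"))
})

test_that("a step of exactly the threshold is a stall (conservative)", {
  tr <- ves_track("b", s = cumsum(c(0, 0.02, 0.02, -0.02, 0.021)))
  st <- segment_states(tr, stall_threshold = 0.02)
  expect_equal(st$state, c("stall", "stall", "stall", "anterograde"))
})

test_that("over-long gaps split tracks and contribute no state change", {
  tr <- ves_track("split", s = c(0, 0.1, 0.2, 1.0, 0.9, 0.8),
                  frames = c(0L, 1L, 2L, 7L, 8L, 9L))
  expect_message(st <- segment_states(tr, max_gap = 2), "split")
  expect_equal(dplyr::n_distinct(st$segment), 2)
  expect_equal(nrow(st), 4)  # the spanning step is dropped
  # antero steps then retro steps, but split apart: no adjacent change
  expect_equal(count_state_changes(st), 0)
})

test_that("raising the stall threshold never decreases stall steps", {
  withr::with_seed(19, {
    tr <- ves_track("mono", s = cumsum(rnorm(60, 0.01, 0.05)))
  })
  stalls <- vapply(c(0.01, 0.02, 0.05, 0.1), function(thr) {
    sum(segment_states(tr, stall_threshold = thr)$state == "stall")
  }, numeric(1))
  expect_true(all(diff(stalls) >= 0))
})

test_that("every step of a track receives exactly one state", {
  sim <- simulate_vesicle_tracks(cargo_sim_params(n_tracks = 20), seed = 23)
  st <- suppressMessages(segment_states(sim$tracks))
  expect_true(all(st$state %in% c("anterograde", "retrograde", "stall")))
  n_steps <- sim$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(n = sum(diff(frame) <= 3)) |>
    dplyr::pull(n)
  expect_equal(nrow(st), sum(n_steps))
})

test_that("metrics arithmetic: uniform anterograde run", {
  tr <- ves_track("a", s = cumsum(rep(0.2, 21)))
  st <- segment_states(tr)
  m <- vesicle_metrics(st, tr, fps = 5)
  expect_equal(m$velocity, 1)
  expect_equal(m$speed, 1)
  expect_equal(m$max_speed, 1)
  expect_equal(m$processivity, 4)  # one 20-step run of 0.2 um each
  expect_equal(m$n_state_changes, 0)
})

test_that("metrics: two runs separated by stalls", {
  s <- cumsum(c(0, rep(0.2, 10), rep(0.001, 5), rep(-0.2, 5)))
  tr <- ves_track("two", s = s)
  st <- segment_states(tr)
  m <- vesicle_metrics(st, tr, fps = 5)
  expect_equal(m$processivity, 1.5)  # mean of 2 um and 1 um runs
  expect_gte(m$n_state_changes, 2)
  expect_equal(m$n_runs_moving, 2L)
})

test_that("stall-only tracks have missing processivity, not zero", {
  tr <- ves_track("s", s = cumsum(rep(0.001, 20)))
  st <- segment_states(tr)
  m <- vesicle_metrics(st, tr)
  expect_true(is.na(m$processivity))
  expect_equal(m$n_runs_moving, 0L)
})

test_that("per-state speeds are recovered from simulated 3-state tracks", {
  sim <- simulate_vesicle_tracks(
    cargo_sim_params(n_tracks = 60, p_mobile = 1, speed_antero = 1,
                     speed_retro = 0.8, position_noise = 0,
                     gap_probability = 0), seed = 29)
  st <- segment_states(sim$tracks)
  sp <- st |>
    dplyr::group_by(state) |>
    dplyr::summarise(v = mean(abs(ds_per_frame)) * 5)
  expect_equal(sp$v[sp$state == "anterograde"], 1, tolerance = 0.1)
  expect_equal(sp$v[sp$state == "retrograde"], 0.8, tolerance = 0.1)
})

test_that("segmentation accuracy beats 90% in the stated regime", {
  # state speeds >= 5 x threshold * fps, noise <= threshold / 2
  sim <- simulate_vesicle_tracks(
    cargo_sim_params(n_tracks = 60, p_mobile = 1, speed_antero = 1,
                     speed_retro = 0.8, position_noise = 10,
                     gap_probability = 0), seed = 37)
  st <- segment_states(sim$tracks)
  truth <- dplyr::left_join(
    st, sim$truth_states,
    by = c("track_id", frame_end = "frame"))
  expect_gte(mean(truth$state.x == truth$state.y), 0.9)
})

test_that("stall-only populations are called stationary", {
  stall_rates <- cargo_state_rates(s_to_a = 0, s_to_r = 0)
  sim <- simulate_vesicle_tracks(
    cargo_sim_params(n_tracks = 40, p_mobile = 0,
                     state_rates = stall_rates), seed = 41)
  mob <- classify_mobility(sim$tracks)
  expect_gte(mean(mob$mobility == "stationary"), 0.95)
})

test_that("pure anterograde transport is kinematically exact", {
  sim <- simulate_vesicle_tracks(
    cargo_sim_params(n_tracks = 5, p_mobile = 1, speed_antero = 1,
                     position_noise = 0, gap_probability = 0,
                     state_rates = matrix(0, 3, 3, dimnames = list(
                       c("anterograde", "retrograde", "stall"),
                       c("anterograde", "retrograde", "stall")))),
    seed = 43)
  # force all tracks to start anterograde: with zero rates the chain stays
  # in its initial state, so keep only tracks that began anterograde
  started_a <- sim$truth_states |>
    dplyr::filter(frame == 0, state == "anterograde") |>
    dplyr::pull(track_id)
  expect_gt(length(started_a), 0)
  tr <- sim$tracks |> dplyr::filter(track_id %in% started_a)
  mob <- classify_mobility(tr)
  expect_true(all(mob$mobility == "mobile"))
  expect_equal(mob$net_displacement_signed, rep(60, nrow(mob)),
               tolerance = 1e-6)
})

test_that("recovered state changes match generative truth without noise", {
  sym <- cargo_state_rates(1 / 60, 1 / 60, 1 / 60, 1 / 60, 1 / 60, 1 / 60)
  # each state leaves at 1/30 s^-1: ~2 switches over 60 s
  sim <- simulate_vesicle_tracks(
    cargo_sim_params(n_tracks = 120, p_mobile = 1, state_rates = sym,
                     position_noise = 0, gap_probability = 0),
    seed = 47)
  st <- segment_states(sim$tracks)
  m <- vesicle_metrics(st, sim$tracks)
  expect_equal(mean(m$n_state_changes), mean(sim$truth$n_state_changes),
               tolerance = 0.02)
  expect_equal(mean(sim$truth$n_state_changes), 2, tolerance = 0.25)
})

test_that("per-cell summaries aggregate mobile tracks only", {
  sim <- simulate_vesicle_tracks(cargo_sim_params(n_tracks = 100),
                                 seed = 53)
  out <- suppressMessages(
    analyze_vesicles(sim$tracks, reference_s = 0))
  expect_true(all(c("frac_mobile", "mean_velocity", "mean_processivity",
                    "mean_state_changes", "total_state_changes") %in%
                    names(out$summary)))
  overall_frac <- sum(out$summary$frac_mobile * out$summary$n_tracks) /
    sum(out$summary$n_tracks)
  truth_frac <- mean(sim$truth$label == "mobile")
  expect_lt(abs(overall_frac - truth_frac), 0.1)
  one_cell <- out$metrics |> dplyr::filter(cell_id == cell_id[1])
  sm <- out$summary |> dplyr::filter(cell_id == one_cell$cell_id[1])
  expect_equal(sm$mean_velocity, mean(one_cell$velocity))
})
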