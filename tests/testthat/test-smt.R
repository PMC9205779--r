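test_that("a stationary stretch yields one event of the full duration", {
  locs <- tibble::tibble(molecule_id = "m1", frame = 0:4,
                         x = c(0, 0.01, 0.02, 0.01, 0), y = 0)
  ev <- detect_immobile_events(locs, radius = 50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_frames, 5)
  expect_equal(ev$start_frame, 0)
})

test_that("kiss-and-hop at every frame produces no events", {
  locs <- tibble::tibble(molecule_id = "m1", frame = 0:9,
                         x = cumsum(rep(0.3, 10)), y = 0)
  ev <- detect_immobile_events(locs, radius = 50)
  expect_equal(nrow(ev), 0)
})

test_that("gaps terminate events and the closing frame anchors a new one", {
  locs <- tibble::tibble(molecule_id = "m1",
                         frame = c(0, 1, 2, 4, 5, 6),  # gap after frame 2
                         x = 0, y = 0)
  ev <- detect_immobile_events(locs, radius = 50)
  expect_equal(ev$duration_frames, c(3, 3))
  # distance violation: the violating frame starts the next event
  locs2 <- tibble::tibble(molecule_id = "m2", frame = 0:5,
                          x = c(0, 0, 0, 0.4, 0.4, 0.4), y = 0)
  ev2 <- detect_immobile_events(locs2, radius = 50)
  expect_equal(ev2$duration_frames, c(3, 3))
  expect_equal(ev2$start_frame, c(0, 3))
})

test_that("detection is invariant under translation and rotation", {
  withr::with_seed(42, {
    locs <- tibble::tibble(molecule_id = "m", frame = 0:49,
                           x = cumsum(rnorm(50, sd = 0.02)),
                           y = cumsum(rnorm(50, sd = 0.02)))
  })
  base <- detect_immobile_events(locs, radius = 50)
  shifted <- dplyr::mutate(locs, x = x + 12.3, y = y - 4.5)
  th <- 0.7
  rotated <- dplyr::mutate(locs,
                           x0 = x, x = cos(th) * x0 - sin(th) * y,
                           y = sin(th) * x0 + cos(th) * y)
  expect_equal(detect_immobile_events(shifted, radius = 50)$duration_frames,
               base$duration_frames)
  expect_equal(detect_immobile_events(rotated, radius = 50)$duration_frames,
               base$duration_frames)
})

test_that("shrinking the radius below the noise scale reduces event counts", {
  sim <- simulate_smt(smt_sim_params(n_molecules = 20,
                                     localization_sigma = 16.7), seed = 8)
  counts <- vapply(c(50, 25, 10),
                   function(r) nrow(detect_immobile_events(
                     sim$localizations, radius = r)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[3], counts[1])
})

test_that("histogram counts conserve the number of events", {
  h <- build_dwell_histogram(c(2, 2, 3), frame_interval = 20)
  expect_equal(h$count[h$duration_frames == 2], 2)
  expect_equal(h$count[h$duration_frames == 3], 1)
  expect_equal(attr(h, "n_events"), 3)
  withr::with_seed(5, {
    durs <- sample(2:12, 300, replace = TRUE)
    h2 <- build_dwell_histogram(durs, 20)
    expect_equal(sum(h2$count), length(durs))
    # zero-count bins inside the range are present
    expect_equal(h2$duration_frames, 2:12)
  })
  expect_error(build_dwell_histogram(integer(0), 20), "zero events")
  expect_error(build_dwell_histogram(c(1, 2), 20), ">= 2")
})

test_that("exact geometric counts give the closed-form residence time", {
  # counts decay by exactly 1/3 per frame: tau = frame_interval / ln 3
  n <- 2:8
  h <- build_dwell_histogram(rep(n, 3^(8 - n)), frame_interval = 20)
  fit <- fit_residence_time(h)
  expect_equal(fit$tau_res, 20 / log(3), tolerance = 1e-6)
  expect_gt(fit$fit_r2, 0.999)
})

test_that("residence time is invariant under doubling all counts", {
  withr::with_seed(11, {
    durs <- 1 + stats::rgeom(800, prob = 1 - exp(-1 / 3))
    durs <- durs[durs >= 2]
  })
  h1 <- build_dwell_histogram(durs, 20)
  fit1 <- fit_residence_time(h1)
  h2 <- build_dwell_histogram(rep(durs, 2), 20)
  fit2 <- fit_residence_time(h2)
  expect_equal(fit2$tau_res, fit1$tau_res, tolerance = 0.01)
})

test_that("simulated exponential dwells recover tau at the study scale", {
  # ~2000 immobile events, 60 ms mean dwell, 20 ms frames, low-noise regime
  sim <- simulate_smt(smt_sim_params(mean_dwell = 60, frame_interval = 20,
                                     n_molecules = 60,
                                     track_length_frames = 160,
                                     localization_sigma = 5), seed = 21)
  fit <- residence_time(sim$localizations, radius = 50,
                        frame_interval = 20)
  expect_gt(fit$n_events, 1000)
  expect_equal(fit$tau_res, 60, tolerance = 0.1)
})

test_that("recovered tau is unbiased across dwell scales", {
  for (k in c(2, 3, 5)) {
    sim <- simulate_smt(smt_sim_params(mean_dwell = 20 * k,
                                       frame_interval = 20,
                                       n_molecules = 50,
                                       track_length_frames = 150,
                                       localization_sigma = 5),
                        seed = 30 + k)
    fit <- residence_time(sim$localizations, radius = 50,
                          frame_interval = 20)
    expect_equal(fit$tau_res, 20 * k, tolerance = 0.1)
  }
})

test_that("fits demand enough histogram structure", {
  expect_error(fit_residence_time(build_dwell_histogram(c(2, 2), 20)),
               "3 duration bins")
})
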