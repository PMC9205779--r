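make_track <- function(id, x, y = rep(0, length(x)), dt = 2,
                       diameter = NULL, cell = "c1") {
  out <- tibble::tibble(cell_id = cell, track_id = id,
                        frame = seq_along(x) - 1L,
                        t = (seq_along(x) - 1) * dt, x = x, y = y)
  if (!is.null(diameter)) out$diameter <- diameter
  out
}

test_that("kinematics of a straight run: net = path, velocity = speed", {
  tr <- make_track("t1", x = seq(0, 1, by = 0.1), dt = 1)
  k <- track_kinematics(tr)
  expect_equal(k$net_displacement, 1)
  expect_equal(k$path_length, 1)
  expect_equal(k$velocity, k$speed)
  expect_equal(k$duration, 10)
})

test_that("an out-and-back path cancels net displacement but not path", {
  tr <- make_track("t1", x = c(0, 1, 2, 1, 0))
  k <- track_kinematics(tr)
  expect_equal(k$net_displacement, 0)
  expect_equal(k$path_length, 4)
  expect_equal(k$velocity, 0)
  expect_gt(k$speed, 0)
})

test_that("path length dominates net displacement on random walks", {
  withr::with_seed(13, {
    walks <- purrr::map_dfr(1:20, function(i) {
      make_track(sprintf("w%02d", i), x = cumsum(rnorm(30)),
                 y = cumsum(rnorm(30)))
    })
  })
  k <- track_kinematics(walks)
  expect_true(all(k$path_length >= k$net_displacement))
  expect_true(all(k$speed >= k$velocity))
})

test_that("single-frame tracks are rejected", {
  expect_error(track_kinematics(make_track("t1", x = 0)), "fewer than 2")
})

test_that("the t-test rule labels clear movers and parkers", {
  withr::with_seed(2, d50 <- rnorm(50, 0.5, 0.01))
  mover <- make_track("m", x = seq(0, 5, length.out = 50), diameter = d50)
  cl <- classify_mito(mover)
  expect_equal(cl$label, "mobile")
  expect_lt(cl$t_stat, 0)
  expect_gt(cl$confidence, 0.999)

  parker <- make_track("p", x = seq(0, 0.02, length.out = 50),
                       diameter = d50)
  cl2 <- classify_mito(parker)
  expect_equal(cl2$label, "stationary")
  expect_gte(cl2$t_stat, 0)

  # displacement equal to the mean diameter: inconclusive
  centred <- make_track("u", x = seq(0, mean(d50), length.out = 50),
                        diameter = d50)
  cl3 <- classify_mito(centred)
  expect_equal(cl3$label, "undefined")
  expect_lt(cl3$confidence, 0.5)
})

test_that("the classifier matches t.test's statistic and p-value", {
  withr::with_seed(3, d <- rnorm(20, 0.6, 0.05))
  tr <- make_track("t", x = seq(0, 2, length.out = 20), diameter = d)
  cl <- classify_mito(tr)
  ref <- stats::t.test(d, mu = 2)
  expect_equal(cl$t_stat, unname(ref$statistic))
  expect_equal(1 - cl$confidence, unname(ref$p.value))
})

test_that("degenerate zero-variance diameters fall back to the sign rule", {
  tr <- make_track("z", x = seq(0, 3, length.out = 10),
                   diameter = rep(0.5, 10))
  expect_message(cl <- classify_mito(tr), "zero diameter variance")
  expect_equal(cl$label, "mobile")
  expect_equal(cl$confidence, 1)
})

test_that("short tracks (< 3 diameters) are undefined", {
  tr <- make_track("s", x = c(0, 1), diameter = c(0.5, 0.5))
  expect_equal(classify_mito(tr)$label, "undefined")
})

test_that("classification is rigid-motion invariant", {
  withr::with_seed(4, {
    tr <- make_track("r", x = cumsum(rnorm(30, 0.05, 0.02)),
                     y = cumsum(rnorm(30, 0, 0.02)),
                     diameter = rnorm(30, 0.5, 0.03))
  })
  base <- classify_mito(tr)
  th <- 1.1
  rot <- dplyr::mutate(tr, x0 = x,
                       x = cos(th) * x0 - sin(th) * y + 7,
                       y = sin(th) * x0 + cos(th) * y - 3)
  moved <- classify_mito(rot[names(tr)])
  expect_equal(moved$t_stat, base$t_stat)
  expect_equal(moved$label, base$label)
})

test_that("inflating diameters flips mobile calls to stationary", {
  withr::with_seed(5, d <- rnorm(40, 0.5, 0.05))
  tr <- make_track("f", x = seq(0, 2, length.out = 40), diameter = d)
  labels <- vapply(c(0, 1, 4), function(extra) {
    tr2 <- dplyr::mutate(tr, diameter = diameter + extra)
    classify_mito(tr2)$label
  }, character(1))
  expect_equal(labels[1], "mobile")
  expect_equal(labels[3], "stationary")
})

test_that("summaries report per-cell fractions and mobile-only kinematics", {
  withr::with_seed(6, d <- rnorm(30, 0.5, 0.01))
  tracks <- dplyr::bind_rows(
    purrr::map(1:2, ~ make_track(paste0("m", .x),
                                 x = seq(0, 5, length.out = 30),
                                 diameter = d)),
    purrr::map(3:10, ~ make_track(paste0("s", .x),
                                  x = rep(0.2, 30) +
                                    seq(0, 0.01, length.out = 30),
                                  diameter = d)))
  cl <- classify_mito(tracks)
  k <- track_kinematics(tracks)
  sm <- summarize_mito(cl, k)
  expect_equal(sm$frac_mobile, 0.2)
  expect_equal(sm$frac_stationary, 0.8)
  expect_gt(sm$mean_velocity_mobile, 0)
})

test_that("cells with no mobile tracks report missing kinematics", {
  withr::with_seed(7, d <- rnorm(30, 0.5, 0.01))
  tr <- make_track("s1", x = rep(0, 30) + seq(0, 0.005, length.out = 30),
                   diameter = d)
  sm <- summarize_mito(classify_mito(tr), track_kinematics(tr))
  expect_true(is.na(sm$mean_velocity_mobile))
})

test_that("end-to-end: mobile fraction and accuracy recovered on simulations", {
  sim <- simulate_mito_tracks(
    cargo_sim_params(n_tracks = 150, p_mobile = 0.2, fps = 0.5,
                     duration = 480, speed_antero = 0.3,
                     speed_retro = 0.25, position_noise = 20),
    seed = 31)
  cl <- classify_mito(sim$tracks)
  truth <- sim$truth$label[match(cl$track_id, sim$truth$track_id)]
  sens <- mean(cl$label[truth == "mobile"] == "mobile")
  spec <- mean(cl$label[truth == "stationary"] == "stationary")
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
  p_hat <- mean(cl$label == "mobile")
  p_true <- mean(truth == "mobile")
  expect_lt(abs(p_hat - p_true), 3 * sqrt(0.2 * 0.8 / 150) + 0.02)
})
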