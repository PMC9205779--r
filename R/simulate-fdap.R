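#' Parameters for the FDAP simulator
#'
#' Defaults reproduce the photoactivation acquisition the analysis targets:
#' a 6 um activated segment imaged at 1 frame/s for 112 frames, additive
#' Gaussian measurement noise with sd 0.02 on the normalized fluorescence,
#' and binding kinetics in the physiological regime of a microtubule-bound
#' fraction around 0.8 (`k_on_star / (k_on_star + k_off) = 4/5`). The free
#' diffusion constant defaults to 10 um^2/s, a placeholder of the right
#' order for a free cytosolic protein.
#'
#' @param d_free Free-species diffusion constant, um^2/s.
#' @param k_on_star Pseudo-first-order association rate, 1/s.
#' @param k_off Dissociation rate, 1/s.
#' @param window_length Activated segment length, um.
#' @param frame_interval Seconds per frame.
#' @param n_frames Number of frames (first frame at t = 0).
#' @param noise_sigma SD of additive Gaussian noise on normalized
#'   fluorescence.
#' @param pure_diffusion If `TRUE`, both rates are set to zero and the
#'   species simply diffuses at `d_free`.
#' @return A list of class `fdap_sim_params`.
#' @export
fdap_sim_params <- function(d_free = 10, k_on_star = 4, k_off = 1,
                            window_length = 6, frame_interval = 1,
                            n_frames = 112, noise_sigma = 0.02,
                            pure_diffusion = FALSE) {
  if (pure_diffusion) {
    k_on_star <- 0
    k_off <- 0
  }
  if (k_on_star < 0 || k_off < 0) abort("Rates must be >= 0.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  assert_positive(d_free, "d_free")
  assert_positive(window_length, "window_length")
  assert_positive(frame_interval, "frame_interval")
  if (n_frames < 2) abort("`n_frames` must be at least 2.")
  structure(list(d_free = d_free, k_on_star = k_on_star, k_off = k_off,
                 window_length = window_length,
                 frame_interval = frame_interval, n_frames = n_frames,
                 noise_sigma = noise_sigma,
                 pure_diffusion = pure_diffusion),
            class = "fdap_sim_params")
}

#' Simulate FDAP curves with known kinetics
#'
#' Integrates the two-species reaction-diffusion system numerically
#' ([fdap_solve_pde()]: method of lines on a domain much longer than the
#' activation window, reflecting ends, cell-averaged top-hat initial
#' condition with the activated molecules partitioned at binding
#' equilibrium), then draws `n_curves` noisy realizations by adding i.i.d.
#' Gaussian noise per frame to the normalized solution (the first sample
#' is 1 plus noise, as in a real measurement; [read_fdap()] renormalizes
#' curves on ingestion). The noise-free solution is computed once and
#' shared by all
#' replicates. The returned truth record carries every generative
#' parameter, so downstream estimators can be scored without hidden state.
#'
#' @param params An [fdap_sim_params()] list.
#' @param n_curves Number of noisy replicate curves (cells) to emit.
#' @param seed Integer seed; the simulation is a pure function of
#'   `(params, n_curves, seed)`.
#' @return A list with `curves` (tibble `cell_id`, `t`, `F`), `truth`
#'   (one-row tibble of generative parameters plus `mass_error`, the PDE
#'   mass-conservation diagnostic), and `clean` (tibble `t`, `F` of the
#'   noise-free solution).
#' @export
#' @examples
#' sim <- simulate_fdap_curves(fdap_sim_params(n_frames = 30), seed = 1)
#' head(sim$curves)
simulate_fdap_curves <- function(params = fdap_sim_params(), n_curves = 1,
                                 seed = NULL) {
  stopifnot(inherits(params, "fdap_sim_params"))
  times <- (seq_len(params$n_frames) - 1) * params$frame_interval
  sol <- fdap_solve_pde(times, d_free = params$d_free,
                        k_on_star = params$k_on_star, k_off = params$k_off,
                        window_length = params$window_length)
  clean <- tibble::tibble(t = times, F = sol$F)
  curves <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_curves), function(i) {
      tibble::tibble(cell_id = sprintf("sim_%03d", i), t = times,
                     F = sol$F + rnorm(length(times),
                                       sd = params$noise_sigma))
    })
  })
  truth <- tibble::as_tibble(params[c("d_free", "k_on_star", "k_off",
                                      "window_length", "frame_interval",
                                      "n_frames", "noise_sigma")])
  truth$bound_fraction <- if (params$k_on_star + params$k_off > 0) {
    params$k_on_star / (params$k_on_star + params$k_off)
  } else {
    0
  }
  truth$mass_error <- sol$mass_error
  truth$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  list(curves = curves, truth = truth, clean = clean)
}
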