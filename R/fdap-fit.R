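# least-squares fitting of FDAP curves
#
# chi^2 is the unweighted sum of squared residuals: single curves carry no
# per-point variance estimate, so chi^2 is only compared relatively (between
# models on the same curve), never interpreted on an absolute scale.

new_kinetic_fit <- function(model, estimates, chi2, n_points, converged,
                            data, window_length, d_free = NA_real_,
                            note = NA_character_) {
  structure(
    list(model = model, estimates = estimates, chi2 = chi2,
         n_points = n_points, converged = converged, data = data,
         window_length = window_length, d_free = d_free, note = note),
    class = "kinetic_fit")
}

check_fdap_curve <- function(data, min_points = 10) {
  if (!all(c("t", "F") %in% names(data))) {
    abort("`data` must have columns `t` and `F` (one FDAP curve).")
  }
  if ("cell_id" %in% names(data) && dplyr::n_distinct(data$cell_id) > 1) {
    abort("`data` contains several cells; use `fit_fdap()` for batch fits.")
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) < min_points) {
    abort(sprintf("Need at least %d points to fit, got %d.",
                  min_points, nrow(data)))
  }
  if (any(diff(data$t) <= 0)) abort("`t` must be strictly increasing.")
  data
}

#' Fit the effective diffusion constant of an FDAP curve
#'
#' Nonlinear least squares of [fdap_model_diffusion()] over the single
#' parameter `d_eff`, multi-started from 7 log-spaced values of `d` in
#' 10^\[-2, 2\] um^2/s and optimized on the log scale (bounded to
#' 10^\[-4, 4\]). Ties are broken by lowest chi^2, then smallest parameter.
#' A fit that lands on a search bound or fails to converge from every start
#' is returned with `converged = FALSE` and should not be interpreted.
#'
#' @param data One FDAP curve: a data frame with columns `t` (s, strictly
#'   increasing from 0) and `F` (normalized fluorescence), at least 10 rows.
#' @param window_length Activated segment length, um.
#' @return A `kinetic_fit` object; see [tidy.kinetic_fit()],
#'   [glance.kinetic_fit()], [autoplot.kinetic_fit()].
#' @export
#' @examples
#' t <- 0:30
#' curve <- tibble::tibble(t = t, F = fdap_model_diffusion(t, d = 5))
#' glance(fit_deff(curve))
fit_deff <- function(data, window_length = 6) {
  data <- check_fdap_curve(data)
  obj <- function(log10_d) {
    sum((data$F - fdap_model_diffusion(data$t, 10^log10_d, window_length))^2)
  }
  starts <- seq(-2, 2, length.out = 7)
  fits <- lapply(starts, function(s) {
    tryCatch(nlminb(s, obj, lower = -4, upper = 4),
             error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    return(new_kinetic_fit("diffusion", c(d_eff = NA_real_), NA_real_,
                           nrow(data), FALSE, data, window_length,
                           note = "no start converged"))
  }
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  pars <- vapply(fits, function(f) f$par, numeric(1))
  best <- order(objs, abs(pars))[1]
  d_hat <- 10^fits[[best]]$par
  at_bound <- abs(fits[[best]]$par) >= 4 - 1e-6
  converged <- fits[[best]]$convergence == 0 && !at_bound
  new_kinetic_fit("diffusion", c(d_eff = d_hat), objs[best], nrow(data),
                  converged, data, window_length,
                  note = if (at_bound) "estimate at search bound" else
                    NA_character_)
}

#' Fit binding rates with the reaction-diffusion FDAP model
#'
#' Least-squares fit of [fdap_model_reaction()] over
#' \eqn{(k^*_{on}, k_{off})} with the free-protein diffusion constant
#' `d_free` held fixed (it is an acquisition-level input, not a fitted
#' parameter). Both rates are optimized on the log scale from a 5 x 5
#' multi-start grid over 10^\[-2, 2\] 1/s: the sum of squared residuals is
#' evaluated at all 25 grid points and local optimization is run from the
#' best `n_local` of them. The returned object carries the equilibrium
#' bound fraction \eqn{k^*_{on}/(k^*_{on}+k_{off})}.
#'
#' When the best reaction-model chi^2 is worse than `misfit_factor` times
#' the pure-diffusion chi^2 on the same curve, a warning records likely
#' model mis-specification.
#'
#' @inheritParams fit_deff
#' @param d_free Diffusion constant of the free species, um^2/s (fixed).
#' @param n_local Number of grid starts refined by local optimization.
#' @param misfit_factor Chi^2 ratio (reaction / diffusion) above which a
#'   mis-specification warning is raised; `Inf` disables the check.
#' @return A `kinetic_fit` object with estimates `k_on_star`, `k_off` and
#'   `bound_fraction`.
#' @export
fit_reaction_diffusion <- function(data, d_free, window_length = 6,
                                   n_local = 3, misfit_factor = 2) {
  assert_positive(d_free, "d_free")
  data <- check_fdap_curve(data)
  obj <- function(lp) {
    sum((data$F - fdap_model_reaction(data$t, 10^lp[1], 10^lp[2],
                                      d_free, window_length))^2)
  }
  grid <- as.matrix(expand.grid(lon = seq(-2, 2, length.out = 5),
                                loff = seq(-2, 2, length.out = 5)))
  ssr <- apply(grid, 1, obj)
  starts <- grid[order(ssr)[seq_len(n_local)], , drop = FALSE]
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(nlminb(starts[i, ], obj, lower = c(-4, -4), upper = c(4, 4)),
             error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    return(new_kinetic_fit("reaction", c(k_on_star = NA_real_,
                                         k_off = NA_real_), NA_real_,
                           nrow(data), FALSE, data, window_length, d_free,
                           note = "no start converged"))
  }
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  norms <- vapply(fits, function(f) sum(f$par^2), numeric(1))
  best <- order(objs, norms)[1]
  par <- fits[[best]]$par
  at_bound <- any(abs(par) >= 4 - 1e-6)
  converged <- fits[[best]]$convergence == 0 && !at_bound
  note <- if (at_bound) "estimate at search bound" else NA_character_
  if (is.finite(misfit_factor)) {
    chi2_diff <- fit_deff(data, window_length)$chi2
    if (is.finite(chi2_diff) && objs[best] > misfit_factor * chi2_diff) {
      warn(sprintf(
        "Reaction-diffusion chi^2 (%.3g) exceeds %.3g x pure-diffusion chi^2 (%.3g): possible model mis-specification.",
        objs[best], misfit_factor, chi2_diff))
      note <- "chi2 worse than pure-diffusion fit"
    }
  }
  est <- c(k_on_star = 10^par[[1]], k_off = 10^par[[2]])
  est["bound_fraction"] <- bound_fraction(est[["k_on_star"]], est[["k_off"]])
  new_kinetic_fit("reaction", est, objs[best], nrow(data), converged, data,
                  window_length, d_free, note = note)
}

#' Fit FDAP curves for every cell in a table
#'
#' Batch interface: splits a long table of curves by `cell_id`, fits each
#' with [fit_deff()] or [fit_reaction_diffusion()], and binds the tidy
#' results.
#'
#' @param data Tibble with columns `cell_id`, `t`, `F`, e.g. from
#'   [read_fdap()] or [simulate_fdap_curves()].
#' @param model `"diffusion"` or `"reaction"`.
#' @param d_free Free diffusion constant, um^2/s (required for
#'   `model = "reaction"`).
#' @inheritParams fit_deff
#' @param ... Passed to the single-curve fitter.
#' @return A tibble with one row per cell: estimates, `chi2`, `n_points`,
#'   `converged`.
#' @export
fit_fdap <- function(data, model = c("diffusion", "reaction"),
                     d_free = NULL, window_length = 6, ...) {
  model <- match.arg(model)
  if (!"cell_id" %in% names(data)) data$cell_id <- "cell_1"
  if (model == "reaction" && is.null(d_free)) {
    abort("`d_free` is required for the reaction-diffusion model.")
  }
  data |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(curve, key) {
      fit <- if (model == "diffusion") {
        fit_deff(curve, window_length = window_length, ...)
      } else {
        fit_reaction_diffusion(curve, d_free = d_free,
                               window_length = window_length, ...)
      }
      dplyr::bind_cols(key, glance(fit))
    }) |>
    dplyr::bind_rows()
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit: %s model, %d points>\n", x$model, x$n_points))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-15s %.5g\n", nm, x$estimates[[nm]]))
  }
  cat(sprintf("  %-15s %.4g\n", "chi2", x$chi2))
  cat(sprintf("  %-15s %s\n", "converged", x$converged))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates))
}

#' One-row summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the estimates, `chi2`, `n_points` and
#'   `converged`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(as.list(x$estimates)),
    tibble::tibble(chi2 = x$chi2, n_points = x$n_points,
                   converged = x$converged))
}

#' Predicted FDAP curve of a fitted model
#'
#' @param object A `kinetic_fit`.
#' @param t Times at which to evaluate; defaults to the fitted data's times.
#' @param ... Unused.
#' @return A numeric vector of model values.
#' @export
predict.kinetic_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$data$t
  if (object$model == "diffusion") {
    fdap_model_diffusion(t, object$estimates[["d_eff"]],
                         object$window_length)
  } else {
    fdap_model_reaction(t, object$estimates[["k_on_star"]],
                        object$estimates[["k_off"]], object$d_free,
                        object$window_length)
  }
}
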