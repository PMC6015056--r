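#' Integrate the lattice dynamics
#'
#' Stiff-capable time integration (via [deSolve::ode()], `lsoda`) of the
#' heterogeneous-Notch model or of the classical single-pool model. The
#' pooled variant with tension (`W = Inf`, `h > 0`) has no finite dynamic
#' law and is rejected; use a large finite `W` to study its relaxation.
#'
#' @param params An [li_params()] object (finite `W`, or `W = Inf` with
#'   `h = 0`).
#' @param init Initial [lattice_state()].
#' @param t_end Final dimensionless time (> 0).
#' @param rtol,atol Integrator tolerances (defaults 1e-8, 1e-10).
#' @param n_snapshots Number of evenly spaced snapshots (>= 200 by
#'   default).
#' @return An object of class `li_trajectory`: a long tibble with columns
#'   `time`, `cell`, `D`, `N_left`, `N_right`, plus attributes `params`,
#'   `final_residual` and `converged` (residual below 1e-9 at `t_end`).
#' @export
integrate_lattice <- function(params, init, t_end, rtol = 1e-8, atol = 1e-10,
                              n_snapshots = 200L) {
  stopifnot(inherits(params, "li_params"), t_end > 0)
  if (params$variant == "pooled" && params$h > 0) {
    abort_unsupported_variant(
      "no dynamics for W = Inf with h > 0; use a large finite W instead")
  }
  validate_li_state(init)
  check_state_size(init, params)
  y0 <- state_to_vec(init, params$variant)
  deriv <- if (params$variant == "heterogeneous") {
    function(t, y, parms) {
      dy <- rhs_het_vec(y, params)
      if (is.null(dy)) abort_degenerate_interface()
      list(dy)
    }
  } else {
    function(t, y, parms) list(rhs_classical_vec(y, params))
  }
  times <- seq(0, t_end, length.out = max(n_snapshots, 2L))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort_numerical_failure("stiff integrator failed before t_end")
  }
  new_li_trajectory(sol, params)
}

new_li_trajectory <- function(sol, params) {
  n <- params$n_cells
  times <- sol[, 1]
  ymat <- sol[, -1, drop = FALSE]
  y_end <- ymat[nrow(ymat), ]
  r_end <- full_residual_vec(
    if (params$variant == "pooled") y_end else y_end, params)
  final_residual <- if (is.null(r_end)) NA_real_ else max(abs(r_end))
  snap <- function(i) {
    y <- ymat[i, ]
    if (params$variant == "pooled") {
      tibble::tibble(time = times[i], cell = 0:(n - 1L), D = y[seq_len(n)],
                     N_left = y[n + seq_len(n)], N_right = y[n + seq_len(n)])
    } else {
      tibble::tibble(time = times[i], cell = 0:(n - 1L), D = y[seq_len(n)],
                     N_left = y[n + seq_len(n)], N_right = y[2L * n + seq_len(n)])
    }
  }
  out <- dplyr::bind_rows(lapply(seq_along(times), snap))
  structure(out,
            params = params,
            final_residual = final_residual,
            converged = isTRUE(final_residual <= 1e-9),
            class = c("li_trajectory", class(out)))
}

#' Final state of a trajectory
#'
#' @param trajectory An `li_trajectory`.
#' @return An [lattice_state()] tibble at the last time point, with Notch
#'   fractions clipped to \[0, 1\] against integrator round-off.
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "li_trajectory"))
  last <- dplyr::filter(trajectory, .data$time == max(.data$time))
  lattice_state(D = pmax(last$D, 0),
                N_left = pmin(pmax(last$N_left, 0), 1),
                N_right = pmin(pmax(last$N_right, 0), 1))
}

#' Relax a state to a steady state by integration
#'
#' Integrates in doubling time chunks until the right-hand side max-norm
#' falls below `tol` or the accumulated time exceeds `max_time`.
#' Non-convergence is reported as a flag, not an error.
#'
#' @inheritParams integrate_lattice
#' @param tol Steady-state residual tolerance (default 1e-9).
#' @param max_time Maximum accumulated dimensionless time (default 1e5).
#' @return A list with `state` (the last [lattice_state()]), `converged`,
#'   `residual` and `time` spent.
#' @export
relax_to_steady <- function(params, init, tol = 1e-9, max_time = 1e5,
                            rtol = 1e-8, atol = 1e-10) {
  state <- init
  total <- 0
  chunk <- 1
  resid <- state_residual(state, params)
  while (resid > tol && total < max_time) {
    traj <- integrate_lattice(params, state, t_end = chunk,
                              rtol = rtol, atol = atol, n_snapshots = 2L)
    state <- final_state(traj)
    total <- total + chunk
    chunk <- chunk * 2
    resid <- state_residual(state, params)
  }
  list(state = state, converged = resid <= tol, residual = resid,
       time = total)
}

state_residual <- function(state, params) {
  r <- full_residual_vec(state_to_vec(state, params$variant), params)
  if (is.null(r)) Inf else max(abs(r))
}

#' Multiplicatively perturb a lattice state
#'
#' Each variable is multiplied by `1 + magnitude * u` with
#' `u ~ U(-1, 1)` drawn from a seeded generator; Notch fractions are then
#' clipped back into \[0, 1\] and Delta to non-negative values.
#'
#' @param state An [lattice_state()] tibble.
#' @param magnitude Relative perturbation size (>= 0).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A perturbed [lattice_state()].
#' @export
perturb <- function(state, magnitude, seed = 1L) {
  validate_li_state(state)
  stopifnot(magnitude >= 0)
  n <- nrow(state)
  u <- withr::with_seed(seed, stats::runif(3L * n, -1, 1))
  lattice_state(
    D = pmax(state$D * (1 + magnitude * u[seq_len(n)]), 0),
    N_left = pmin(pmax(state$N_left * (1 + magnitude * u[n + seq_len(n)]), 0), 1),
    N_right = pmin(pmax(state$N_right * (1 + magnitude * u[2L * n + seq_len(n)]), 0), 1)
  )
}
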