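abort_incompatible_lattice <- function(spacing, n_cells) {
  rlang::abort(
    sprintf("spacing %d has period %d, which does not divide n_cells = %d",
            spacing, spacing + 1L, n_cells),
    class = "tipstalk_error_incompatible_lattice"
  )
}

abort_numerical_failure <- function(msg) {
  rlang::abort(msg, class = "tipstalk_error_numerical")
}

# ---- damped (Gauss-)Newton ----------------------------------------------
# res_fn returns the residual vector, or NULL when the point is outside the
# admissible manifold (degenerate interface). Overdetermined systems are
# handled by least-squares steps; convergence is on the max-norm.
newton_solve <- function(res_fn, x0, tol = 1e-10, max_iter = 60L,
                         max_halving = 20L) {
  x <- x0
  r <- res_fn(x)
  if (is.null(r) || anyNA(r) || any(!is.finite(r))) return(NULL)
  rn <- max(abs(r))
  for (iter in seq_len(max_iter)) {
    if (rn <= tol) return(list(x = x, residual = rn, iterations = iter - 1L))
    if (rn > 1e8) return(NULL)
    J <- matrix(0, nrow = length(r), ncol = length(x))
    for (i in seq_along(x)) {
      hstep <- 1e-8 * max(1, abs(x[i]))
      xp <- x; xp[i] <- xp[i] + hstep
      rp <- res_fn(xp)
      if (is.null(rp) || anyNA(rp)) return(NULL)
      J[, i] <- (rp - r) / hstep
    }
    dx <- tryCatch(qr.coef(qr(J), -r), error = function(e) NULL)
    if (is.null(dx) || anyNA(dx) || any(!is.finite(dx))) return(NULL)
    step <- 1
    accepted <- FALSE
    for (half in 0:max_halving) {
      xn <- x + step * dx
      rn_vec <- res_fn(xn)
      if (!is.null(rn_vec) && !anyNA(rn_vec) && all(is.finite(rn_vec)) &&
          max(abs(rn_vec)) < rn) {
        x <- xn; r <- rn_vec; rn <- max(abs(rn_vec)); accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) return(NULL)
  }
  if (rn <= tol) list(x = x, residual = rn, iterations = max_iter) else NULL
}

# ---- pattern ansatz ------------------------------------------------------

#' Periodic pattern ansatz for an n-cell spacing
#'
#' An n-cell spacing has n stalk cells between consecutive tip cells, so a
#' candidate pattern has period `spacing + 1` and is sought by solving the
#' steady-state equations on one period (the periodic lattice arithmetic
#' makes the period-reduced system identical to the full one).
#'
#' @param spacing Integer >= 0: number of stalk cells between tips.
#' @param params An [li_params()] object; `spacing + 1` must divide
#'   `params$n_cells`.
#' @return An object of class `li_ansatz`: spacing, period, `tiling` (the
#'   period position of every lattice cell, 0-based), the per-period
#'   initial guess `x0`, and the unknown count.
#' @export
build_ansatz <- function(spacing, params) {
  stopifnot(inherits(params, "li_params"))
  spacing <- as.integer(spacing)
  if (is.na(spacing) || spacing < 0L) {
    abort_invalid_parameter("spacing", "must be an integer >= 0")
  }
  period <- spacing + 1L
  if (params$n_cells %% period != 0L) {
    abort_incompatible_lattice(spacing, params$n_cells)
  }
  # initial guess on one period: the tip cell at high Delta, stalks low,
  # Notch from the quasi-steady activation balance
  D <- c(params$b0, rep(0.05 * params$b0, spacing))
  qs <- function(Dn) params$kf0 * Dn / (params$kd + params$kf0 * Dn)
  if (period == 1L) {
    pv <- nx <- 1L
  } else {
    pv <- idx_prev(period)
    nx <- idx_next(period)
  }
  if (params$variant == "heterogeneous") {
    x0 <- c(D, qs(D[pv]), qs(D[nx]))
    n_unknowns <- 3L * period
  } else {
    x0 <- c(D, (qs(D[pv]) + qs(D[nx])) / 2)
    n_unknowns <- 2L * period
  }
  structure(
    list(spacing = spacing, period = period,
         tiling = (0:(params$n_cells - 1L)) %% period,
         x0 = x0, n_unknowns = n_unknowns, variant = params$variant),
    class = "li_ansatz"
  )
}

# expand a per-period packed vector onto the full lattice
tile_vec <- function(x, period, n_cells, variant) {
  reps <- n_cells / period
  blocks <- if (variant == "pooled") 2L else 3L
  unlist(lapply(seq_len(blocks), function(b) {
    rep(x[(b - 1L) * period + seq_len(period)], reps)
  }), use.names = FALSE)
}

params_for_period <- function(params, period) {
  p <- params
  p$n_cells <- as.integer(period)
  p
}

# ---- uniform steady state -----------------------------------------------

#' Spatially uniform steady state
#'
#' Solves the fixed point at which every cell (and both Notch sides) is
#' identical, by bracketed 1-D root finding on the Delta level in
#' `[0, b0]`. At a uniform state all interfaces share one distance, so the
#' tension factor reduces to a scalar.
#'
#' @param params An [li_params()] object.
#' @return An [lattice_state()] tibble with `params$n_cells` identical rows.
#' @export
uniform_state <- function(params) {
  stopifnot(inherits(params, "li_params"))
  b0 <- params$b0
  notch_of_D <- function(D) {
    # per-side activation balance N = kf D / (kd + kf D); kf may depend on
    # N through the interface distance, so solve the inner fixed point too
    side_D <- if (params$variant == "pooled" && params$h == 0) 2 * D else D
    if (params$h == 0) {
      return(params$kf0 * side_D / (params$kd + params$kf0 * side_D))
    }
    f <- function(N) {
      x <- 1 / (2 * pmax(1 - N, D))
      kf <- params$kf0 * exp(-params$h * (x - params$lambda)^2)
      -params$kd * N + kf * side_D * (1 - N)
    }
    if (f(0) <= 0) return(0)
    stats::uniroot(f, c(0, 1), tol = 1e-14)$root
  }
  g <- function(D) -D + b0 / (1 + (notch_of_D(D) / params$K)^params$hill)
  root <- tryCatch(
    stats::uniroot(g, c(0, b0), tol = 1e-14, extendInt = "no")$root,
    error = function(e) abort_numerical_failure(
      paste0("uniform fixed point bracketing failed: ", conditionMessage(e)))
  )
  N <- notch_of_D(root)
  lattice_state(D = rep(root, params$n_cells),
                N_left = rep(N, params$n_cells))
}

# ---- Jacobian and stability ---------------------------------------------

#' Finite-difference Jacobian of the lattice dynamics
#'
#' Central finite differences of the model right-hand side at a state,
#' including the dependence of the interface binding rates on the state.
#' For the pooled variant with tension (`W = Inf`, `h > 0`) no finite
#' dynamic law exists; stability is assessed on the side-resolved system
#' with a large finite diffusion surrogate.
#'
#' @param state An [lattice_state()] tibble.
#' @param params An [li_params()] object.
#' @param step Base finite-difference step (default 1e-6; relative for
#'   variables exceeding 1 in magnitude).
#' @param W_surrogate Diffusion rate standing in for `W = Inf` when
#'   `h > 0` (default 1e4).
#' @return A square numeric matrix (3n for side-resolved states, 2n for
#'   the classical variant).
#' @export
lattice_jacobian <- function(state, params, step = 1e-6, W_surrogate = 1e4) {
  stopifnot(inherits(params, "li_params"))
  validate_li_state(state)
  check_state_size(state, params)
  if (params$variant == "heterogeneous") {
    y <- state_to_vec(state, "heterogeneous")
    f <- function(v) rhs_het_vec(v, params)
  } else if (params$h == 0) {
    y <- state_to_vec(state, "pooled")
    f <- function(v) rhs_classical_vec(v, params)
  } else {
    y <- c(state$D, state$N_left, state$N_right)
    f <- function(v) rhs_het_vec(v, params, W = W_surrogate)
  }
  m <- length(y)
  J <- matrix(0, m, m)
  for (i in seq_len(m)) {
    hstep <- step * max(1, abs(y[i]))
    yp <- y; yp[i] <- yp[i] + hstep
    ym <- y; ym[i] <- ym[i] - hstep
    fp <- f(yp); fm <- f(ym)
    if (is.null(fp) || is.null(fm)) abort_degenerate_interface()
    J[, i] <- (fp - fm) / (2 * hstep)
  }
  J
}

#' Linear stability verdict from a Jacobian spectrum
#'
#' @param x A `li_steady` result or a numeric/complex eigenvalue vector.
#' @param tol Marginality band (default 1e-8): stable if the largest real
#'   part is below `-tol`, unstable if above `+tol`, marginal otherwise.
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
assess_stability <- function(x, tol = 1e-8) {
  ev <- if (inherits(x, "li_steady")) x$eigenvalues else x
  max_re <- max(Re(ev))
  if (max_re < -tol) "stable" else if (max_re > tol) "unstable" else "marginal"
}

#' Interface-balance residual of a pooled tension steady state
#'
#' In the fast-diffusion (`W = Inf`) limit with tension-dependent binding,
#' both side equations of every cell must vanish separately at a steady
#' state, forcing the flux balance `kf_left * D_left = kf_right * D_right`
#' across each cell. Returns the largest violation over the lattice.
#'
#' @param result A found `li_steady` result from [solve_pattern()].
#' @param params Parameters (defaults to those stored in `result`).
#' @return Maximum over cells of
#'   `|kf[j-1] * D[j-1] - kf[j] * D[j+1]|`.
#' @export
check_interface_balance <- function(result, params = result$params) {
  stopifnot(inherits(result, "li_steady"))
  if (params$variant != "pooled" || params$h <= 0) {
    abort_unsupported_variant(
      "interface balance applies to the W = Inf variant with h > 0")
  }
  st <- result$state
  ir <- interface_rates(st, params)
  n <- nrow(st)
  pv <- idx_prev(n); nx <- idx_next(n)
  # interface i sits between cells i and i+1: cell j's left interface is
  # j-1 (rate ir$kf[pv]), its right interface is j (rate ir$kf[j])
  max(abs(ir$kf[pv] * st$D[pv] - ir$kf * st$D[nx]))
}

# ---- pattern solving -----------------------------------------------------

#' Solve for a periodic n-cell-spacing steady state
#'
#' Reduces the steady-state equations to one period of the candidate
#' spacing and applies damped Newton iteration (Gauss-Newton least squares
#' for the overdetermined side-resolved system of the pooled tension
#' variant) from a structured initial guess plus a fixed set of seeded
#' random restarts. A converged root is expanded to the full lattice,
#' its Jacobian spectrum computed and its realized spacing classified.
#'
#' @param params An [li_params()] object.
#' @param spacing Candidate spacing (integer >= 0); `spacing + 1` must
#'   divide `params$n_cells`.
#' @param seed Seed of the random-restart stream (default 20180622).
#' @param n_restarts Number of random restarts after the default guess
#'   (default 8).
#' @param tol Residual max-norm tolerance (default 1e-10).
#' @param stability_tol Marginality band for the verdict (default 1e-8).
#' @return An object of class `li_steady`. When no root converges the
#'   object has `found = FALSE` (a data value, not an error). Otherwise it
#'   carries the full-lattice `state`, `residual_norm`, `eigenvalues`,
#'   `verdict`, the claimed and observed spacings and a `collapsed` flag.
#' @examples
#' \donttest{
#' p <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.3, W = 0)
#' res <- solve_pattern(p, spacing = 2)
#' glance(res)
#' }
#' @export
solve_pattern <- function(params, spacing, seed = 20180622, n_restarts = 8L,
                          tol = 1e-10, stability_tol = 1e-8) {
  stopifnot(inherits(params, "li_params"))
  ansatz <- build_ansatz(spacing, params)
  period <- ansatz$period
  if (period == 1L) {
    # the uniform fixed point: scalar bracketed root, then (if needed) a
    # full-lattice Newton polish
    u <- uniform_state(params)
    y_full <- state_to_vec(u, params$variant)
    r_full <- full_residual_vec(y_full, params)
    if (!is.null(r_full) && max(abs(r_full)) > tol) {
      sol <- newton_solve(function(y) full_residual_vec(y, params), y_full,
                          tol = tol)
      if (!is.null(sol)) {
        y_full <- sol$x
        r_full <- full_residual_vec(y_full, params)
      }
    }
    if (is.null(r_full) || max(abs(r_full)) > tol) {
      return(new_li_steady(found = FALSE, params = params,
                           spacing_claimed = 0L, seed = seed))
    }
    state <- vec_to_state(y_full, params$variant)
    J <- lattice_jacobian(state, params)
    ev <- eigen(J, only.values = TRUE)$values
    cls <- classify_spacing(state)
    return(new_li_steady(
      found = TRUE, state = state, params = params, spacing_claimed = 0L,
      spacing_observed = cls$spacing, collapsed = !identical(cls$spacing, 0L),
      residual_norm = max(abs(r_full)), eigenvalues = ev,
      verdict = assess_stability(ev, stability_tol),
      restarts_used = 0L, seed = seed))
  }
  pp <- params_for_period(params, period)
  eff_period <- period
  x0 <- ansatz$x0
  starts <- list(x0)
  if (n_restarts > 0) {
    draws <- withr::with_seed(seed, {
      lapply(seq_len(n_restarts), function(r) {
        D <- stats::runif(eff_period, 0, params$b0)
        if (params$variant == "heterogeneous") {
          c(D, stats::runif(2L * eff_period))
        } else {
          c(D, stats::runif(eff_period))
        }
      })
    })
    starts <- c(starts, draws)
  }
  res_fn <- function(y) full_residual_vec(y, pp)
  # examine every start: among converged roots prefer (1) a stable root
  # realizing the claimed spacing, (2) any root realizing it, (3) any root
  # (collapsed), ties broken by start order for determinism
  best <- NULL
  best_rank <- Inf
  seen <- character()
  for (a in seq_along(starts)) {
    sol <- newton_solve(res_fn, starts[[a]], tol = tol)
    if (is.null(sol)) next
    y <- sol$x
    # admissibility: tiny numerical excursions are clamped, real ones reject
    nD <- eff_period
    idxN <- (nD + 1L):length(y)
    if (any(y[seq_len(nD)] < -1e-9) || any(y[idxN] < -1e-9) ||
        any(y[idxN] > 1 + 1e-9)) next
    y[seq_len(nD)] <- pmax(y[seq_len(nD)], 0)
    y[idxN] <- pmin(pmax(y[idxN], 0), 1)
    r <- res_fn(y)
    if (is.null(r) || max(abs(r)) > tol) next
    key <- paste(signif(y, 8), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    y_full <- tile_vec(y, eff_period, params$n_cells, params$variant)
    r_full <- full_residual_vec(y_full, params)
    if (is.null(r_full) || max(abs(r_full)) > tol) next
    state <- vec_to_state(y_full, params$variant)
    J <- tryCatch(lattice_jacobian(state, params), error = function(e) NULL)
    if (is.null(J)) next
    ev <- eigen(J, only.values = TRUE)$values
    verdict <- assess_stability(ev, stability_tol)
    cls <- classify_spacing(state)
    collapsed <- !identical(cls$spacing, ansatz$spacing)
    rank <- if (!collapsed && verdict == "stable") 1
            else if (!collapsed) 2 else 3
    if (rank < best_rank) {
      best_rank <- rank
      best <- new_li_steady(
        found = TRUE, state = state, params = params,
        spacing_claimed = ansatz$spacing,
        spacing_observed = cls$spacing,
        collapsed = collapsed,
        residual_norm = max(abs(r_full)),
        eigenvalues = ev, verdict = verdict,
        restarts_used = a - 1L, seed = seed)
    }
    if (best_rank == 1) break
  }
  if (is.null(best)) {
    return(new_li_steady(found = FALSE, params = params,
                         spacing_claimed = ansatz$spacing, seed = seed))
  }
  best
}

new_li_steady <- function(found, params, spacing_claimed, seed,
                          state = NULL, spacing_observed = NA_integer_,
                          collapsed = NA, residual_norm = NA_real_,
                          eigenvalues = NULL, verdict = NA_character_,
                          restarts_used = NA_integer_) {
  structure(
    list(found = found, state = state, params = params,
         spacing_claimed = spacing_claimed, spacing_observed = spacing_observed,
         collapsed = collapsed, residual_norm = residual_norm,
         eigenvalues = eigenvalues, verdict = verdict,
         restarts_used = restarts_used, seed = seed),
    class = "li_steady"
  )
}

#' @export
print.li_steady <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<li_steady> spacing %d: no root found\n", x$spacing_claimed))
    return(invisible(x))
  }
  cat(sprintf(
    "<li_steady> spacing %d -> observed %s (%s), residual %.2e, max Re(eig) %.3e\n",
    x$spacing_claimed,
    ifelse(is.na(x$spacing_observed), "irregular", x$spacing_observed),
    x$verdict, x$residual_norm, max(Re(x$eigenvalues))))
  invisible(x)
}
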