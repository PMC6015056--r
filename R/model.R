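#' Construct a lattice state
#'
#' A lattice state records, for every cell of the periodic array, the
#' dimensionless Delta level `D` and the fractions of activated Notch on
#' the left (`N_left`) and right (`N_right`) sides of the cell. In the
#' pooled (`W = Inf`) variant the two sides are identical and both columns
#' carry the common value.
#'
#' @param D Numeric vector of per-cell Delta levels (>= 0).
#' @param N_left,N_right Numeric vectors of per-cell activated-Notch
#'   fractions, in \[0, 1\]. `N_right` defaults to `N_left`.
#' @return A tibble of class `li_state` with columns `cell` (0-based
#'   index), `D`, `N_left`, `N_right`.
#' @examples
#' lattice_state(D = c(0.8, 0.01, 0.8, 0.01), N_left = c(0.1, 0.9, 0.1, 0.9))
#' @export
lattice_state <- function(D, N_left, N_right = N_left) {
  n <- length(D)
  if (n < 2L || length(N_left) != n || length(N_right) != n) {
    abort_invalid_state("D, N_left and N_right must share length n_cells >= 2")
  }
  st <- tibble::tibble(
    cell = 0:(n - 1L),
    D = as.numeric(D),
    N_left = as.numeric(N_left),
    N_right = as.numeric(N_right)
  )
  class(st) <- c("li_state", class(st))
  validate_li_state(st)
  st
}

validate_li_state <- function(state) {
  if (!all(c("cell", "D", "N_left", "N_right") %in% names(state))) {
    abort_invalid_state("state must have columns cell, D, N_left, N_right")
  }
  vals <- c(state$D, state$N_left, state$N_right)
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort_invalid_state("state contains NA or non-finite values")
  }
  if (any(state$D < 0)) abort_invalid_state("Delta levels must be >= 0")
  if (any(state$N_left < 0 | state$N_left > 1 |
          state$N_right < 0 | state$N_right > 1)) {
    abort_invalid_state("Notch fractions must lie in [0, 1]")
  }
  invisible(state)
}

abort_invalid_state <- function(msg) {
  rlang::abort(msg, class = "tipstalk_error_invalid_state")
}

abort_degenerate_interface <- function() {
  rlang::abort(
    "degenerate interface: fully bound Notch with no free ligand (distance denominator ~ 0)",
    class = "tipstalk_error_degenerate_interface"
  )
}

abort_unsupported_variant <- function(msg) {
  rlang::abort(msg, class = "tipstalk_error_unsupported_variant")
}

# ---- internal vector packing --------------------------------------------
# heterogeneous: y = c(D, N_left, N_right); pooled: y = c(D, N)

state_to_vec <- function(state, variant) {
  if (variant == "pooled") c(state$D, (state$N_left + state$N_right) / 2)
  else c(state$D, state$N_left, state$N_right)
}

vec_to_state <- function(y, variant) {
  if (variant == "pooled") {
    n <- length(y) / 2L
    lattice_state(D = y[seq_len(n)], N_left = y[n + seq_len(n)])
  } else {
    n <- length(y) / 3L
    lattice_state(D = y[seq_len(n)], N_left = y[n + seq_len(n)],
                  N_right = y[2L * n + seq_len(n)])
  }
}

idx_next <- function(n) c(2:n, 1L)
idx_prev <- function(n) c(n, seq_len(n - 1L))

# Per-interface distance and binding rate from packed heterogeneous state.
# Returns list(x_m, kf) or NULL when an interface is degenerate.
interface_rates_vec <- function(D, N_l, N_r, p, tol = 1e-9) {
  n <- length(D)
  nx <- idx_next(n)
  denom <- pmax(1 - N_r, D[nx]) + pmax(1 - N_l[nx], D)
  if (any(denom <= tol)) return(NULL)
  x_m <- 1 / denom
  kf <- if (p$h > 0) p$kf0 * exp(-p$h * (x_m - p$lambda)^2) else rep(p$kf0, n)
  list(x_m = x_m, kf = kf)
}

# Right-hand side, heterogeneous variant, packed vector in/out.
# W may be overridden (used for the fast-diffusion Jacobian surrogate).
# Returns NULL on a degenerate interface so solvers can bail out cleanly.
rhs_het_vec <- function(y, p, W = p$W) {
  n <- p$n_cells
  D <- y[seq_len(n)]
  N_l <- y[n + seq_len(n)]
  N_r <- y[2L * n + seq_len(n)]
  ir <- interface_rates_vec(D, N_l, N_r, p)
  if (is.null(ir)) return(NULL)
  kf <- ir$kf
  nx <- idx_next(n)
  pv <- idx_prev(n)
  dD <- -D + p$b0 / (1 + ((N_l + N_r) / (2 * p$K))^p$hill)
  dNl <- -p$kd * N_l + kf[pv] * D[pv] * (1 - N_l) + W * (N_r - N_l)
  dNr <- -p$kd * N_r + kf * D[nx] * (1 - N_r) + W * (N_l - N_r)
  c(dD, dNl, dNr)
}

# Classical dynamics (single Notch pool, h = 0), packed c(D, N).
rhs_classical_vec <- function(y, p) {
  n <- p$n_cells
  D <- y[seq_len(n)]
  N <- y[n + seq_len(n)]
  dD <- -D + p$b0 / (1 + (N / p$K)^p$hill)
  dN <- -p$kd * N + p$kf0 * (D[idx_prev(n)] + D[idx_next(n)]) * (1 - N)
  c(dD, dN)
}

# Side-resolved steady-state residual for the pooled (W = Inf) variant with
# tension: at a fixed point of the fast-diffusion limit each side's
# activation equation must vanish separately. Unknowns c(D, N) (2n), residual
# c(rD, r_left, r_right) (3n). Returns NULL on a degenerate interface.
residual_pooled_sides <- function(y, p) {
  n <- p$n_cells
  D <- y[seq_len(n)]
  N <- y[n + seq_len(n)]
  ir <- interface_rates_vec(D, N, N, p)
  if (is.null(ir)) return(NULL)
  kf <- ir$kf
  nx <- idx_next(n)
  pv <- idx_prev(n)
  rD <- -D + p$b0 / (1 + (N / p$K)^p$hill)
  rL <- -p$kd * N + kf[pv] * D[pv] * (1 - N)
  rR <- -p$kd * N + kf * D[nx] * (1 - N)
  c(rD, rL, rR)
}

# Steady-state residual used to accept a root on the full lattice.
full_residual_vec <- function(y, p) {
  if (p$variant == "heterogeneous") rhs_het_vec(y, p)
  else if (p$h > 0) residual_pooled_sides(y, p)
  else rhs_classical_vec(y, p)
}

# ---- exported model surface ---------------------------------------------

#' Intercellular distance at a Delta-Notch interface
#'
#' The distance between two neighbouring cell membranes is taken to
#' decrease monotonically with the number of adherent Delta-Notch pairs at
#' the interface: `1 / (max(1 - N_r_j, D_next) + max(1 - N_l_next, D_j))`.
#' Free Notch (`1 - N`) on one membrane and Delta on the opposing membrane
#' both contribute adhesive bonds.
#'
#' @param N_r_j Activated-Notch fraction on the right side of cell j.
#' @param D_next Delta level of cell j+1.
#' @param N_l_next Activated-Notch fraction on the left side of cell j+1.
#' @param D_j Delta level of cell j.
#' @param tol Degeneracy floor for the denominator (default 1e-9).
#' @return The dimensionless intercellular distance (vectorized).
#' @examples
#' interface_distance(0.5, 0.8, 0.2, 0.1) # 1 / 1.6
#' @export
interface_distance <- function(N_r_j, D_next, N_l_next, D_j, tol = 1e-9) {
  stopifnot(all(N_r_j >= 0 & N_r_j <= 1), all(N_l_next >= 0 & N_l_next <= 1),
            all(D_next >= 0), all(D_j >= 0))
  denom <- pmax(1 - N_r_j, D_next) + pmax(1 - N_l_next, D_j)
  if (any(denom <= tol)) abort_degenerate_interface()
  1 / denom
}

#' Tension-dependent Delta-Notch binding rate
#'
#' Dembo-type constitutive law: `kf0 * exp(-h * (x_m - lambda)^2)`. The
#' rate is maximal (`kf0`) at the optimum intercellular distance `lambda`
#' and decays with the squared deviation, scaled by the sensitivity `h`.
#'
#' @param x_m Intercellular distance(s), > 0.
#' @param params An [li_params()] object supplying `kf0`, `h`, `lambda`.
#' @return Binding rate constant(s) in `(0, kf0]`.
#' @export
binding_rate <- function(x_m, params) {
  stopifnot(inherits(params, "li_params"), all(x_m > 0))
  params$kf0 * exp(-params$h * (x_m - params$lambda)^2)
}

#' Per-interface distances and binding rates of a lattice state
#'
#' @param state An [lattice_state()] tibble.
#' @param params An [li_params()] object.
#' @return A tibble with one row per interface: `interface` (0-based index
#'   of the interface between cell j and cell j+1), `x_m`, `kf`.
#' @export
interface_rates <- function(state, params) {
  validate_li_state(state)
  ir <- interface_rates_vec(state$D, state$N_left, state$N_right, params)
  if (is.null(ir)) abort_degenerate_interface()
  tibble::tibble(interface = 0:(nrow(state) - 1L), x_m = ir$x_m, kf = ir$kf)
}

#' Time derivatives of the heterogeneous-Notch model
#'
#' Evaluates the right-hand side of the lateral inhibition model with
#' left/right activated-Notch pools: Delta is repressed by the cell-mean
#' activated Notch through a Hill function, each Notch side is activated
#' by the apposed neighbour's Delta at the (possibly tension-dependent)
#' interface rate, and the two sides exchange Notch at rate `W`.
#'
#' @param state An [lattice_state()] tibble.
#' @param params An [li_params()] object with finite `W`.
#' @return A tibble with columns `cell`, `dD`, `dN_left`, `dN_right`.
#' @export
rhs_full <- function(state, params) {
  stopifnot(inherits(params, "li_params"))
  if (params$variant != "heterogeneous") {
    abort_unsupported_variant("rhs_full requires finite W; use rhs_classical for W = Inf")
  }
  validate_li_state(state)
  check_state_size(state, params)
  dy <- rhs_het_vec(state_to_vec(state, "heterogeneous"), params)
  if (is.null(dy)) abort_degenerate_interface()
  n <- params$n_cells
  tibble::tibble(cell = state$cell, dD = dy[seq_len(n)],
                 dN_left = dy[n + seq_len(n)], dN_right = dy[2L * n + seq_len(n)])
}

#' Time derivatives of the classical (single-pool) model
#'
#' Fast intracellular diffusion (`W = Inf`) equilibrates the two Notch
#' sides; the model reduces to one activated-Notch pool per cell driven by
#' the sum of both neighbours' Delta at the constant rate `kf0`.
#'
#' @param state An [lattice_state()] tibble; `N_left` and `N_right` must
#'   agree (they carry the common pool).
#' @param params An [li_params()] object with `W = Inf` and `h = 0`.
#' @return A tibble with columns `cell`, `dD`, `dN`.
#' @export
rhs_classical <- function(state, params) {
  stopifnot(inherits(params, "li_params"))
  if (params$variant != "pooled" || params$h > 0) {
    abort_unsupported_variant(
      "rhs_classical requires W = Inf and h = 0 (tension with W = Inf has steady states only)")
  }
  validate_li_state(state)
  check_state_size(state, params)
  dy <- rhs_classical_vec(state_to_vec(state, "pooled"), params)
  n <- params$n_cells
  tibble::tibble(cell = state$cell, dD = dy[seq_len(n)], dN = dy[n + seq_len(n)])
}

check_state_size <- function(state, params) {
  if (nrow(state) != params$n_cells) {
    abort_invalid_state(sprintf("state has %d cells but params$n_cells = %d",
                                nrow(state), params$n_cells))
  }
  invisible(state)
}
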