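# Shared helpers: independent oracles and lattice symmetry operations.

# rotate the lattice by k cells (cell j of the result is cell j+k of the input)
rotate_state <- function(state, k) {
  n <- nrow(state)
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  lattice_state(D = state$D[idx], N_left = state$N_left[idx],
                N_right = state$N_right[idx])
}

# mirror the lattice: reverse cell order and swap the Notch sides
reflect_state <- function(state) {
  idx <- rev(seq_len(nrow(state)))
  lattice_state(D = state$D[idx], N_left = state$N_right[idx],
                N_right = state$N_left[idx])
}

# damped fixed-point iteration for the classical uniform root, independent
# of the package's bracketed uniroot path
uniform_fixed_point_oracle <- function(b0, K, kd, kf0, hill = 2,
                                       iters = 2000L, damp = 0.5) {
  D <- b0 / 2
  N <- 0.5
  for (i in seq_len(iters)) {
    D_new <- b0 / (1 + (N / K)^hill)
    N_new <- kf0 * 2 * D / (kd + kf0 * 2 * D)
    D <- damp * D + (1 - damp) * D_new
    N <- damp * N + (1 - damp) * N_new
  }
  list(D = D, N = N)
}

# count and locate positive roots of x^2 - 2x^3 = K^2 by dense sign-change
# scanning plus bisection, independent of the package's bracketing choices
scan_m_prime_roots <- function(K, n_grid = 4000L) {
  x <- seq(1e-6, 0.6, length.out = n_grid)
  g <- x^2 - 2 * x^3 - K^2
  sgn <- sign(g)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  vapply(flips, function(i) {
    lo <- x[i]; hi <- x[i + 1]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if ((lo^2 - 2 * lo^3 - K^2) * (mid^2 - 2 * mid^3 - K^2) <= 0) hi <- mid
      else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# forward-difference Jacobian through the exported tibble interface,
# independent of lattice_jacobian's central-difference internals
jacobian_oracle <- function(state, params, step = 1e-7) {
  het <- params$variant == "heterogeneous"
  pack <- function(s) {
    if (het) c(s$D, s$N_left, s$N_right) else c(s$D, s$N_left)
  }
  unpack <- function(y) {
    n <- params$n_cells
    if (het) {
      lattice_state(D = y[seq_len(n)], N_left = y[n + seq_len(n)],
                    N_right = y[2L * n + seq_len(n)])
    } else {
      lattice_state(D = y[seq_len(n)], N_left = y[n + seq_len(n)])
    }
  }
  f <- function(y) {
    s <- unpack(y)
    if (het) {
      d <- rhs_full(s, params)
      c(d$dD, d$dN_left, d$dN_right)
    } else {
      d <- rhs_classical(s, params)
      c(d$dD, d$dN)
    }
  }
  y0 <- pack(state)
  r0 <- f(y0)
  J <- matrix(0, length(r0), length(y0))
  for (i in seq_along(y0)) {
    hstep <- step * max(1, abs(y0[i]))
    yp <- y0; yp[i] <- yp[i] + hstep
    J[, i] <- (f(yp) - r0) / hstep
  }
  J
}

# state distance used by the stability/dynamics agreement checks
state_distance <- function(a, b) {
  max(abs(a$D - b$D), abs(a$N_left - b$N_left), abs(a$N_right - b$N_right))
}
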