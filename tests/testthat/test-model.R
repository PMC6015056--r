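test_that("interface_distance follows the adhesive bond-count law", {
  # fully free Notch, no Delta: both membranes contribute their whole pool
  expect_equal(interface_distance(0, 0, 0, 0), 0.5)
  # hand evaluation: max(0.5, 0.8) + max(0.8, 0.1) = 1.6
  expect_equal(interface_distance(0.5, 0.8, 0.2, 0.1), 1 / 1.6)
  # fully bound Notch with no ligand has no adhesive bonds left
  expect_error(interface_distance(1, 0, 1, 0),
               class = "tipstalk_error_degenerate_interface")
  expect_error(interface_distance(-0.1, 0, 0, 0))
})

test_that("binding_rate implements the Dembo law", {
  p <- li_params(b0 = 0.9, K = 0.1, kd = 0.4, kf0 = 40, h = 0.076,
                 lambda = 10, W = 0)
  expect_equal(binding_rate(10, p), 40)           # optimum distance
  expect_equal(binding_rate(0.5, p), 40 * exp(-0.076 * 9.5^2))
  p0 <- li_params(b0 = 0.9, K = 0.1, kd = 0.4, kf0 = 40, h = 0, W = 0)
  expect_equal(binding_rate(c(0.5, 3, 100), p0), rep(40, 3)) # h = 0
  expect_true(all(binding_rate(c(0.6, 2, 30), p) <= 40))
})

test_that("interface rates are constant when binding is tension-free", {
  p <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.3, W = 0, n_cells = 6L)
  s <- withr::with_seed(7, lattice_state(
    D = runif(6, 0, 0.8), N_left = runif(6), N_right = runif(6)))
  ir <- interface_rates(s, p)
  expect_identical(nrow(ir), 6L)
  expect_equal(ir$kf, rep(0.3, 6))
  expect_true(all(ir$x_m >= 0.5)) # denominator is at most 2
})

test_that("rhs_full vanishes at the uniform root and respects W symmetry", {
  p <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.1, W = 0.5, n_cells = 6L)
  u <- uniform_state(p)
  d <- rhs_full(u, p)
  expect_lt(max(abs(c(d$dD, d$dN_left, d$dN_right))), 1e-10)

  # equal side pools: the diffusion term is exactly zero, so the derivative
  # is independent of W
  s <- withr::with_seed(11, lattice_state(
    D = runif(6, 0, 0.8), N_left = runif(6)))
  p2 <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.1, W = 100, n_cells = 6L)
  expect_equal(rhs_full(s, p), rhs_full(s, p2))
})

test_that("summed side equations reduce to the classical model at h = 0", {
  # with N_left = N_right = N, averaging the two side derivatives gives
  # -kd N + (kf0/2)(D_prev + D_next)(1 - N): the classical form once the
  # factor 2 is absorbed into the binding-rate convention
  ph <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.2, W = 2, n_cells = 8L)
  pc <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.1, W = Inf, n_cells = 8L)
  for (seed in 1:3) {
    s <- withr::with_seed(seed, lattice_state(
      D = runif(8, 0, 0.8), N_left = runif(8)))
    dh <- rhs_full(s, ph)
    dc <- rhs_classical(s, pc)
    expect_equal(dh$dD, dc$dD)
    expect_equal((dh$dN_left + dh$dN_right) / 2, dc$dN)
  }
})

test_that("rhs_classical matches its closed-form special cases", {
  p <- li_params(b0 = 0.5, K = 1, kd = 1, kf0 = 0.1, n_cells = 4L)
  # no inhibition: Delta relaxes to b0
  s0 <- lattice_state(D = rep(0.2, 4), N_left = rep(0, 4))
  expect_equal(rhs_classical(s0, p)$dD, rep(-0.2 + 0.5, 4))
  # half-maximal repression at N = K
  s1 <- lattice_state(D = rep(0, 4), N_left = rep(1, 4) * p$K)
  expect_equal(rhs_classical(s1, p)$dD, rep(0.5 / 2, 4))
  # the uniform fixed point zeroes the derivative
  u <- uniform_state(p)
  d <- rhs_classical(u, p)
  expect_lt(max(abs(c(d$dD, d$dN))), 1e-10)
})

test_that("variant guards reject mismatched calls", {
  s <- lattice_state(D = rep(0.1, 4), N_left = rep(0.1, 4))
  het <- li_params(b0 = 0.5, K = 1, kd = 1, kf0 = 0.1, W = 0, n_cells = 4L)
  cla <- li_params(b0 = 0.5, K = 1, kd = 1, kf0 = 0.1, n_cells = 4L)
  tens <- li_params(b0 = 0.5, K = 1, kd = 1, kf0 = 0.1, h = 0.1, lambda = 1,
                    n_cells = 4L)
  expect_error(rhs_full(s, cla), class = "tipstalk_error_unsupported_variant")
  expect_error(rhs_classical(s, het),
               class = "tipstalk_error_unsupported_variant")
  expect_error(rhs_classical(s, tens),
               class = "tipstalk_error_unsupported_variant")
  big <- lattice_state(D = rep(0.1, 6), N_left = rep(0.1, 6))
  expect_error(rhs_full(big, het), class = "tipstalk_error_invalid_state")
})

test_that("the derivative is equivariant under rotation and reflection", {
  p <- li_params(b0 = 0.9, K = 0.05, kd = 0.4, kf0 = 2, h = 0.08, lambda = 3,
                 W = 0.5, n_cells = 6L)
  s <- withr::with_seed(23, lattice_state(
    D = runif(6, 0, 0.9), N_left = runif(6), N_right = runif(6)))
  d <- rhs_full(s, p)
  for (k in c(1L, 3L)) {
    dr <- rhs_full(rotate_state(s, k), p)
    idx <- ((seq_len(6) - 1L + k) %% 6L) + 1L
    expect_equal(dr$dD, d$dD[idx])
    expect_equal(dr$dN_left, d$dN_left[idx])
    expect_equal(dr$dN_right, d$dN_right[idx])
  }
  # mirror symmetry swaps the two Notch sides
  dm <- rhs_full(reflect_state(s), p)
  idx <- rev(seq_len(6))
  expect_equal(dm$dD, d$dD[idx])
  expect_equal(dm$dN_left, d$dN_right[idx])
  expect_equal(dm$dN_right, d$dN_left[idx])
})
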