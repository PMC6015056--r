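test_that("build_ansatz does the period arithmetic and guards the lattice", {
  p <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.3, W = 0)
  a0 <- build_ansatz(0, p)
  expect_identical(a0$period, 1L)
  expect_identical(a0$n_unknowns, 3L)
  a2 <- build_ansatz(2, p)
  expect_identical(a2$period, 3L)
  expect_identical(length(unique(a2$tiling)), 3L)
  expect_identical(a2$n_unknowns, 9L)
  # pooled variant carries one Notch pool per cell
  pc <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.3)
  expect_identical(build_ansatz(2, pc)$n_unknowns, 6L)
  # 5 does not divide 12
  expect_error(build_ansatz(4, p),
               class = "tipstalk_error_incompatible_lattice")
  expect_error(build_ansatz(-1, p),
               class = "tipstalk_error_invalid_parameter")
})

test_that("uniform_state agrees with an independent fixed-point oracle", {
  p <- li_params(b0 = 0.5, K = 1, kd = 1, kf0 = 0.1)
  u <- uniform_state(p)
  oracle <- uniform_fixed_point_oracle(0.5, 1, 1, 0.1)
  expect_equal(u$D[1], oracle$D, tolerance = 1e-8)
  expect_equal(u$N_left[1], oracle$N, tolerance = 1e-8)
  expect_identical(nrow(u), 12L)
  expect_true(all(u$D == u$D[1]))
  # weak inhibition limit: Delta production is unopposed
  far <- uniform_state(li_params(b0 = 0.5, K = 1e6, kd = 1, kf0 = 0.1))
  expect_equal(far$D[1], 0.5, tolerance = 1e-4)
  # the uniform root also zeroes the tension-model side equations
  pt <- li_params(b0 = 0.9, K = 0.05, kd = 0.4021, kf0 = 38.6324,
                  h = 0.0761, lambda = 10)
  ut <- uniform_state(pt)
  ir <- interface_rates(ut, pt)
  expect_true(all(abs(ir$kf - ir$kf[1]) < 1e-12))
})

test_that("solve_pattern reproduces the tension-free reference patterns", {
  # salt-and-pepper at strong inhibition
  p1 <- reference_params("het_onecell")
  r1 <- solve_pattern(p1, 1)
  expect_true(r1$found)
  expect_identical(r1$verdict, "stable")
  expect_false(r1$collapsed)
  expect_identical(r1$spacing_observed, 1L)
  expect_lt(r1$residual_norm, 1e-10)

  # two-cell spacing with zero intracellular diffusion
  r2 <- solve_pattern(reference_params("het_twocell"), 2)
  expect_identical(r2$verdict, "stable")
  expect_identical(r2$spacing_observed, 2L)

  # spacing 0 equals the uniform scalar fixed point
  p0 <- reference_params("het_zerocell")
  r0 <- solve_pattern(p0, 0)
  expect_true(r0$found)
  expect_equal(r0$state$D, uniform_state(p0)$D, tolerance = 1e-9)
})

test_that("solve_pattern is deterministic and reports not-found as data", {
  p <- reference_params("het_twocell")
  a <- solve_pattern(p, 2, seed = 99)
  b <- solve_pattern(p, 2, seed = 99)
  expect_identical(a$state, b$state)
  expect_identical(a$eigenvalues, b$eigenvalues)

  # an ansatz can fail without raising: a tension ansatz far from any
  # admissible non-uniform root still returns an li_steady value
  res <- solve_pattern(li_params(b0 = 0.9, K = 0.19, kd = 0.0225,
                                 kf0 = 3.719, h = 0.0052, lambda = 30), 2)
  expect_s3_class(res, "li_steady")
  expect_true(is.logical(res$found))
})

test_that("the full-lattice residual bound holds for returned roots", {
  for (nm in c("het_onecell", "het_twocell", "het_twocell_W3")) {
    r <- solve_pattern(reference_params(nm),
                       reference_parameter_sets()$spacing[
                         reference_parameter_sets()$name == nm])
    st <- r$state
    d <- rhs_full(st, r$params)
    expect_lt(max(abs(c(d$dD, d$dN_left, d$dN_right))), 1e-10)
  }
})

test_that("lattice_jacobian has the expected tension-free block structure", {
  p <- reference_params("het_twocell")
  r <- solve_pattern(p, 2)
  J <- lattice_jacobian(r$state, p)
  n <- p$n_cells
  # dD_j has no direct D dependence beyond its own decay when h = 0
  expect_equal(J[seq_len(n), seq_len(n)], diag(-1, n), tolerance = 1e-6)
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
})

test_that("assess_stability applies the marginality band", {
  expect_identical(assess_stability(c(-1, -2)), "stable")
  expect_identical(assess_stability(c(-1, 0.5)), "unstable")
  expect_identical(assess_stability(c(-1, 5e-9)), "marginal")
  expect_identical(assess_stability(complex(real = c(-0.1, -0.2),
                                            imaginary = c(1, -1))), "stable")
})

test_that("stability verdicts are invariant under lattice rotation", {
  p <- reference_params("het_onecell")
  r <- solve_pattern(p, 1)
  ev0 <- sort(Re(r$eigenvalues))
  for (k in c(1L, 5L)) {
    J <- lattice_jacobian(rotate_state(r$state, k), p)
    ev <- sort(Re(eigen(J, only.values = TRUE)$values))
    expect_equal(ev, ev0, tolerance = 1e-6)
  }
})

test_that("check_interface_balance guards its variant and nulls at symmetry", {
  het <- solve_pattern(reference_params("het_twocell"), 2)
  expect_error(check_interface_balance(het),
               class = "tipstalk_error_unsupported_variant")
  # a pooled tension result at the uniform root balances exactly
  pt <- li_params(b0 = 0.9, K = 0.1, kd = 0.0225, kf0 = 3.719,
                  h = 0.0052, lambda = 30)
  rt <- solve_pattern(pt, 0)
  expect_true(rt$found)
  expect_lt(check_interface_balance(rt), 1e-12)
})
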