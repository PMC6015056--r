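test_that("li_params validates fields and assigns the variant", {
  p <- li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.1, W = 0)
  expect_s3_class(p, "li_params")
  expect_identical(p$variant, "heterogeneous")
  expect_identical(li_params(0.5, 1, 1, 0.1)$variant, "pooled")
  expect_identical(li_params(0.5, 1, 1, 0.1, W = 1e6)$variant, "heterogeneous")

  for (bad in list(list(b0 = -1), list(K = 0), list(kd = NA_real_),
                   list(kf0 = Inf), list(h = -0.1), list(W = -1),
                   list(n_cells = 1L), list(hill = 0.5),
                   list(lambda = Inf))) {
    args <- utils::modifyList(
      list(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.1), bad)
    expect_error(do.call(li_params, args),
                 class = "tipstalk_error_invalid_parameter")
  }
  # the error condition names the offending field
  err <- tryCatch(li_params(b0 = 0.8, K = 0.01, kd = -1, kf0 = 0.1),
                  error = function(e) e)
  expect_identical(err$field, "kd")
})

test_that("nondimensionalize maps dimensional rates onto the model", {
  dp <- function(...) {
    args <- utils::modifyList(
      list(B0 = 2, k_D = 1, k_N = 1, k = 0.5, K_F = 1,
           N0_total = 1, F_Notch = 0.1, L = 1), list(...))
    do.call(dimensional_params, args)
  }
  # identical decay rates give kd = 1
  expect_equal(nondimensionalize(dp(k_N = 3, k_D = 3))$kd, 1)
  # the inhibitory coefficient is the ratio k / N0_total
  expect_equal(nondimensionalize(dp(k = 2, N0_total = 2))$K, 1)
  # zero diffusion maps to zero W
  expect_equal(nondimensionalize(dp(F_Notch = 0))$W, 0)
  # full mapping: kd = k_N/k_D, D0 = kd/B0, b0 = B0/(k_D D0),
  # kf0 = K_F D0/(2 k_D), W = F_Notch/(L^2 k_D N0_total)
  p <- nondimensionalize(dp(B0 = 2, k_D = 4, k_N = 2, k = 0.25,
                            K_F = 8, N0_total = 0.5, F_Notch = 1, L = 2))
  kd <- 2 / 4
  D0 <- kd / 2
  expect_equal(p$kd, kd)
  expect_equal(p$b0, 2 / (4 * D0))
  expect_equal(p$K, 0.25 / 0.5)
  expect_equal(p$kf0, 8 * D0 / (2 * 4))
  expect_equal(p$W, 1 / (4 * 4 * 0.5))

  expect_error(dimensional_params(B0 = -1, k_D = 1, k_N = 1, k = 1, K_F = 1,
                                  N0_total = 1, F_Notch = 0, L = 1),
               class = "tipstalk_error_invalid_parameter")
})

test_that("lattice_state enforces the state invariants", {
  s <- lattice_state(D = c(0.8, 0.01), N_left = c(0.1, 0.9))
  expect_s3_class(s, "li_state")
  expect_identical(s$cell, 0:1)
  expect_identical(s$N_right, s$N_left)

  expect_error(lattice_state(D = 0.5, N_left = 0.5),
               class = "tipstalk_error_invalid_state")
  expect_error(lattice_state(D = c(-0.1, 0.5), N_left = c(0.1, 0.1)),
               class = "tipstalk_error_invalid_state")
  expect_error(lattice_state(D = c(0.1, 0.5), N_left = c(0.1, 1.1)),
               class = "tipstalk_error_invalid_state")
  expect_error(lattice_state(D = c(0.1, NA), N_left = c(0.1, 0.2)),
               class = "tipstalk_error_invalid_state")
})
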