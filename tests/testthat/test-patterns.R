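test_that("classify_spacing recognizes the constructed spacings", {
  fx <- generate_fixtures(seed = 1L)
  for (sp in 0:3) {
    st <- fx$spacing_states[[paste0("spacing", sp)]]
    expect_identical(classify_spacing(st)$spacing, sp)
  }
  # salt-and-pepper by hand
  s <- lattice_state(D = rep(c(0.8, 0.01), 3), N_left = rep(c(0.1, 0.9), 3))
  cls <- classify_spacing(s)
  expect_identical(cls$spacing, 1L)
  expect_identical(cls$period, 2L)
  expect_false(cls$uniform)
  # uniform, including the all-zero state guarded by the floor
  expect_true(classify_spacing(lattice_state(D = rep(0.3, 4),
                                             N_left = rep(0.1, 4)))$uniform)
  expect_identical(classify_spacing(lattice_state(D = rep(0, 4),
                                                  N_left = rep(0, 4)))$spacing,
                   0L)
})

test_that("unequal tip gaps are reported as irregular", {
  D <- rep(0.05, 12); D[c(1, 3, 8)] <- 0.8
  cls <- classify_spacing(lattice_state(D = D, N_left = rep(0.5, 12)))
  expect_true(cls$irregular)
  expect_true(is.na(cls$spacing))
})

test_that("classification is invariant under rotation and reflection", {
  fx <- generate_fixtures(seed = 1L)
  for (sp in 1:3) {
    st <- fx$spacing_states[[paste0("spacing", sp)]]
    for (k in c(1L, 4L, 7L)) {
      expect_identical(classify_spacing(rotate_state(st, k))$spacing, sp)
    }
    expect_identical(classify_spacing(reflect_state(st))$spacing, sp)
  }
})

test_that("label_cells separates tip, stalk and hybrid phenotypes", {
  # two-level salt-and-pepper: no hybrids
  s1 <- lattice_state(D = rep(c(0.8, 0.01), 3), N_left = rep(c(0.1, 0.9), 3))
  expect_setequal(unique(label_cells(s1)$label), c("tip", "stalk"))
  # a two-cell-spacing root: one tip per period, low-Delta stalks
  r <- solve_pattern(reference_params("het_twocell"), 2)
  lab <- label_cells(r$state)
  expect_identical(sum(lab$label == "tip"), 4L)
  expect_identical(sum(lab$label == "stalk"), 8L)
  # moderate-Delta cells are labelled hybrid
  s2 <- lattice_state(D = rep(c(0.8, 0.4, 0.02), 2),
                      N_left = rep(c(0.1, 0.5, 0.9), 2))
  expect_identical(label_cells(s2)$label[2], "hybrid")
  # uniform states share one label
  expect_true(all(label_cells(uniform_state(
    reference_params("het_zerocell")))$label == "uniform"))
  expect_error(label_cells(s1, tip_frac = 0.1, stalk_frac = 0.9),
               class = "tipstalk_error_invalid_parameter")
})

test_that("Notch asymmetry distinguishes one- from two-cell spacings", {
  r1 <- solve_pattern(reference_params("het_onecell"), 1)
  expect_lt(max(notch_asymmetry(r1$state)$asymmetry), 1e-8)
  r0 <- solve_pattern(reference_params("het_zerocell"), 0)
  expect_lt(max(notch_asymmetry(r0$state)$asymmetry), 1e-8)
  r2 <- solve_pattern(reference_params("het_twocell"), 2)
  expect_gt(max(notch_asymmetry(r2$state)$asymmetry), 1e-3)
  # equal sides by construction
  s <- lattice_state(D = rep(0.2, 4), N_left = rep(0.3, 4))
  expect_equal(notch_asymmetry(s)$asymmetry, rep(0, 4))
})
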