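test_that("pure diffusion conserves mass exactly (zero-flux boundary)", {
  f <- empty_field(20, 20, 1, "N")
  set.seed(3)
  f$values[] <- stats::runif(length(f$values))
  m0 <- field_mass(f)
  g <- f
  for (i in 1:50) g <- step_solute(g, source = 0, decay = 0, D = 1, dt = 0.2)
  expect_equal(field_mass(g), m0, tolerance = 1e-12)
  expect_true(all(g$values >= 0))
})

test_that("a uniform field is a diffusion fixed point", {
  f <- empty_field(15, 10, 1)
  f$values[] <- 3.7
  g <- step_solute(f, D = 2, dt = 0.1)
  expect_equal(g$values, f$values, tolerance = 1e-14)
})

test_that("decay is exact exponential and sources add mass linearly", {
  f <- empty_field(8, 8, 1)
  f$values[] <- 5
  g <- step_solute(f, decay = 0.1, dt = 1)
  expect_equal(g$values, f$values * exp(-0.1), tolerance = 1e-12)
  g2 <- step_solute(f, source = 2, dt = 0.5)
  expect_equal(field_mass(g2), field_mass(f) + 2 * 0.5 * 64, tolerance = 1e-10)
})

test_that("explicit stability violations are an error, not silent blow-up", {
  f <- empty_field(8, 8, 1)
  expect_error(step_solute(f, D = 10, dt = 1), "stab")
})

test_that("diffusion spreads mass down the gradient", {
  f <- empty_field(21, 21, 1)
  f$values[11, 11] <- 100
  g <- f
  for (i in 1:100) g <- step_solute(g, D = 1, dt = 0.2)
  expect_lt(g$values[11, 11], f$values[11, 11])
  expect_gt(g$values[1, 1], 0)
  # radially monotone-ish: center remains the max
  expect_equal(which.max(g$values), which.max(f$values))
})

test_that("binary masks and fields validate their inputs", {
  expect_error(solute_field(matrix("a", 2, 2), 1))
  expect_error(binary_mask(matrix(1, 2, 2), 1))
  m <- binary_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2), 0.5)
  expect_s3_class(m, "binary_mask")
  expect_equal(m$resolution, 0.5)
})
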