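# Phase III kinetics: limit identities of the exchange and production laws,
# conservation, determinism and monotone responses.

fp <- function() scaled_config()$factory

test_that("vessel-wall delivery vanishes at zero flow and saturates at high flow", {
  p <- fp()
  expect_equal(nutrient_delivery_rate(0, 3, 0, p), 0)
  # saturation plateau: rho_n * 2 pi r * k_l / (k_l + N)
  plateau <- p$rho_n * 2 * pi * 3 * p$k_l / (p$k_l + 0.5)
  expect_equal(nutrient_delivery_rate(1e12, 3, 0.5, p), plateau,
               tolerance = 1e-6)
  # direction-agnostic: |Q| is used
  expect_equal(nutrient_delivery_rate(-100, 3, 0.5, p),
               nutrient_delivery_rate(100, 3, 0.5, p))
  # delivery falls as the local nutrient builds up (product of the k_l term)
  expect_gt(nutrient_delivery_rate(100, 3, 0, p),
            nutrient_delivery_rate(100, 3, 10, p))
})

test_that("production is Michaelis-Menten in N and inhibited by X", {
  p <- fp()
  expect_equal(production_rate(0, 0, p, 10), 0)
  # half-saturation at N = k_p with no product
  expect_equal(production_rate(p$k_p, 0, p, 10), p$mu_p * 10 / 2)
  # N -> Inf approaches mu_p * M_p (no inhibition)
  expect_equal(production_rate(1e12, 0, p, 10), p$mu_p * 10, tolerance = 1e-6)
  # X -> Inf kills production
  expect_equal(production_rate(10, 1e15, p, 10), 0, tolerance = 1e-6)
  # monotone increasing in N at fixed X
  N <- seq(0, 50, by = 0.5)
  r <- production_rate(N, 1, p, 10)
  expect_true(all(diff(r) > 0))
  # monotone decreasing in X at fixed N
  X <- seq(0, 50, by = 0.5)
  r2 <- production_rate(10, X, p, 10)
  expect_true(all(diff(r2) < 0))
})

test_that("product uptake needs both flow and product, and saturates in both", {
  p <- fp()
  expect_equal(product_uptake_rate(0, 3, 5, p), 0)
  expect_equal(product_uptake_rate(100, 3, 0, p), 0)
  plateau <- p$rho_p * 2 * pi * 3   # Q -> Inf, X -> Inf
  expect_equal(product_uptake_rate(1e12, 3, 1e12, p), plateau,
               tolerance = 1e-5)
  expect_equal(product_uptake_rate(-50, 3, 2, p),
               product_uptake_rate(50, 3, 2, p))
})

test_that("consumption tracks production with the mu_n / mu_p ratio", {
  p <- fp()
  N <- c(0.1, 1, 5, 20); X <- c(0, 0.5, 2, 10)
  expect_equal(nutrient_consumption_rate(N, X, p, 10),
               production_rate(N, X, p, 10) * p$mu_n / p$mu_p,
               tolerance = 1e-12)
})

test_that("the factory conserves mass to numerical precision and keeps fields non-negative", {
  cfg <- tiny_config()
  cells <- make_initial_state(cfg, 42)
  st <- suppressWarnings(run_factory(cells, NULL, NULL, cfg))
  massN <- field_mass(st$field_N)
  massX <- field_mass(st$field_X)
  # Delta(total N) = delivered - consumed; Delta(total X) = produced - removed
  expect_lt(abs(massN - (sum(st$delivered) - st$consumed)) /
              max(sum(st$delivered), 1e-12), 1e-6)
  expect_lt(abs(massX - (st$produced - sum(st$removed))) /
              max(st$produced, 1e-12), 1e-6)
  expect_true(all(st$field_N$values >= 0))
  expect_true(all(st$field_X$values >= 0))
  expect_true(all(st$delivered >= 0))
  expect_true(all(st$removed >= 0))
})

test_that("factory runs are bit-identical on rerun", {
  cfg <- tiny_config()
  cells <- make_initial_state(cfg, 8)
  a <- suppressWarnings(run_factory(cells, NULL, NULL, cfg))
  b <- suppressWarnings(run_factory(cells, NULL, NULL, cfg))
  expect_identical(a$field_N$values, b$field_N$values)
  expect_identical(a$field_X$values, b$field_X$values)
  expect_identical(a$throughput_rate, b$throughput_rate)
  expect_identical(a$rate_series, b$rate_series)
})

test_that("raising mu_p does not decrease steady throughput", {
  cfg_lo <- tiny_config()
  cfg_hi <- tiny_config(factory.mu_p = 2 * cfg_lo$factory$mu_p)
  cells <- make_initial_state(cfg_lo, 21)
  lo <- suppressWarnings(run_factory(cells, NULL, NULL, cfg_lo))
  hi <- suppressWarnings(run_factory(cells, NULL, NULL, cfg_hi))
  expect_gte(hi$throughput_rate, lo$throughput_rate * (1 - 1e-9))
})

test_that("removing product inhibition cannot reduce throughput", {
  cfg <- tiny_config()
  cfg_free <- tiny_config(factory.k_i = 1e12)   # k_i -> Inf disables inhibition
  cells <- make_initial_state(cfg, 22)
  inh <- suppressWarnings(run_factory(cells, NULL, NULL, cfg))
  free <- suppressWarnings(run_factory(cells, NULL, NULL, cfg_free))
  expect_gte(free$throughput_rate, inh$throughput_rate * (1 - 1e-9))
})

test_that("an unstable factory time step is rejected", {
  cfg <- tiny_config()
  c0 <- unclass(cfg)
  c0$factory$dt <- 100
  c0$chemo$D_c_um2 <- NULL; c0$factory$D_p_um2 <- NULL
  cfg_bad <- vascufab:::as_sim_config(c0)
  cells <- make_initial_state(cfg, 1)
  expect_error(run_factory(cells, NULL, NULL, cfg_bad), "stability")
})

test_that("throughput integrates a constant removal rate exactly", {
  # stationarity contract of compute_throughput: the reported value is the
  # mean of the post-steady block rates over the window
  st <- structure(list(steady = TRUE, post_rates = rep(4.2, 10),
                       block_dt = 60, production_window = 600),
                  class = "factory_state")
  expect_equal(compute_throughput(st), 4.2)
  expect_equal(compute_throughput(st, window = 120), 4.2)
  st2 <- st; st2$steady <- FALSE
  expect_error(compute_throughput(st2), "steady")
})

test_that("the zero-vascular baseline starves the domain center", {
  # a wide slab: diffusion from the two columns cannot reach the middle
  cfg <- tiny_config(domain.width = 258, domain.height = 60,
                     cells.n_interior = 700, cells.n_circulatory = 180,
                     factory.max_time = 1800, factory.production_window = 120)
  bl <- suppressWarnings(baseline_throughput(cfg, 5))
  expect_gt(bl$throughput, 0)
  N <- bl$state$field_N$values
  center <- N[round(nrow(N) / 2), round(ncol(N) / 2)]
  expect_lt(center, cfg$factory$activation_threshold)
  # nutrient does penetrate the near-column boundary layer
  expect_gt(max(N[, 1:3]), cfg$factory$activation_threshold)
})
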