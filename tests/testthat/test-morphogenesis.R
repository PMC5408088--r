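# Limit identities of the secretion and chemotaxis laws, and behavioral
# contracts of the Phase I loop.

test_that("Monod secretion has the right limits and producer guard", {
  ch <- scaled_config()$chemo
  expect_equal(secretion_rate("VASCULAR", 10, 0, ch), 0)      # no substrate
  # saturation: N_c >> k approaches mu_c * biomass
  expect_equal(secretion_rate("VASCULAR", 10, 1e9, ch), ch$mu_c * 10,
               tolerance = 1e-6)
  # half-saturation at N_c = k
  expect_equal(secretion_rate("CIRC_SOURCE", 4, ch$k, ch), ch$mu_c * 4 / 2)
  expect_error(secretion_rate("PRODUCER", 10, 1, ch), "producer")
  expect_error(secretion_rate("VASCULAR", 10, -1, ch), "N_c")
})

test_that("the chemotactic force law saturates, signs and vanishes correctly", {
  lam <- 0.1; bs <- 1e-3
  expect_equal(chemotaxis_force_magnitude(3, 3, lam, bs), 0)   # no gradient
  expect_equal(chemotaxis_force_magnitude(0, 0, lam, bs), 0)
  # saturation: C+ -> Inf, C- = 0 approaches lambda / beta_sat
  expect_equal(chemotaxis_force_magnitude(1e12, 0, lam, bs), lam / bs,
               tolerance = 1e-6)
  # downhill sampling gives a negative magnitude ...
  expect_lt(chemotaxis_force_magnitude(0, 5, lam, bs), 0)
  # small concentrations: linear regime F ~ lambda * (C+ - C-)
  expect_equal(chemotaxis_force_magnitude(2e-4, 1e-4, lam, bs), lam * 1e-4,
               tolerance = 1e-6)
})

test_that("negative force magnitudes are never applied as motion", {
  # a field decreasing in every direction from zero concentration: sampled
  # C+ = C- = 0 or C+ < C-, so chemotaxis_force must return NULL
  f <- empty_field(20, 20, 1)
  f$values[1, 1] <- 10   # mass far away from the cell
  cell <- data.frame(x = 15, y = 15, radius = 2, kind = "VASCULAR")
  set.seed(42)
  for (i in 1:25) {
    res <- chemotaxis_force(cell, f, scaled_config()$chemo)
    if (!is.null(res)) {
      # when a force IS returned it must be strictly uphill
      expect_gt(sqrt(sum(res^2)), 0)
    }
  }
  # dead-flat field: never any force
  g <- empty_field(20, 20, 1)
  for (i in 1:10) expect_null(chemotaxis_force(cell, g, scaled_config()$chemo))
  expect_error(chemotaxis_force(transform(cell, kind = "PRODUCER"), f,
                                scaled_config()$chemo), "vascular")
})

test_that("pairwise adhesion is antisymmetric, attractive and short-ranged", {
  ch <- scaled_config()$chemo
  a <- data.frame(x = 0, y = 0, radius = 2, kind = "VASCULAR")
  b <- data.frame(x = 5, y = 0, radius = 2, kind = "VASCULAR")  # gap 1
  fab <- adhesion_force(a, b, ch)
  fba <- adhesion_force(b, a, ch)
  expect_equal(fab, -fba)
  expect_gt(fab[1], 0)          # pulls a towards b
  expect_equal(fab[2], 0)
  # beyond range: zero
  far <- transform(b, x = 4 + ch$adhesion_range + 1)
  expect_equal(adhesion_force(a, far, ch), c(0, 0))
  # overlapping: zero (shoving handles overlap, not adhesion)
  expect_equal(adhesion_force(a, transform(b, x = 3), ch), c(0, 0))
  expect_error(adhesion_force(a, transform(b, kind = "PRODUCER"), ch), "vascular")
})

test_that("morphogenesis is bit-identical for a fixed seed and moves only interior cells", {
  cfg <- tiny_config()
  m1 <- run_morphogenesis(cfg, 7)
  m2 <- run_morphogenesis(cfg, 7)
  expect_identical(m1$cells, m2$cells)
  expect_identical(m1$bonds, m2$bonds)
  expect_identical(m1$field_short$values, m2$field_short$values)

  init <- make_initial_state(cfg, 7)
  circ <- init$kind %in% c("CIRC_SOURCE", "CIRC_SINK")
  expect_equal(m1$cells$x[circ], init$x[circ])
  expect_equal(m1$cells$y[circ], init$y[circ])
  # producers are passive: they move only by shoving, vascular cells by
  # chemotaxis; vascular cells should move more on average
  dv <- sqrt((m1$cells$x - init$x)^2 + (m1$cells$y - init$y)^2)
  expect_gt(mean(dv[init$kind == "VASCULAR"]),
            mean(dv[init$kind == "PRODUCER"]))
})

test_that("morphogenesis condenses vascular cells and forms bonds", {
  cfg <- tiny_config(cells.n_interior = 150, convergence.max_steps = 40)
  m <- run_morphogenesis(cfg, 11)
  expect_true(is.matrix(m$bonds) && ncol(m$bonds) == 2)
  expect_gt(nrow(m$bonds), 0)
  # every bond touches at least one vascular cell, none touches a producer
  k1 <- m$cells$kind[m$bonds[, 1]]; k2 <- m$cells$kind[m$bonds[, 2]]
  expect_true(all(k1 == "VASCULAR" | k2 == "VASCULAR"))
  expect_false(any(k1 == "PRODUCER" | k2 == "PRODUCER"))
  # mean nearest-vascular-neighbor distance shrinks relative to the start
  init <- make_initial_state(cfg, 11)
  nnd <- function(cells) {
    v <- cells[cells$kind == "VASCULAR", ]
    d <- as.matrix(stats::dist(cbind(v$x, v$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(nnd(m$cells), nnd(init))
})

test_that("cells never leave the domain and never end up deeply overlapped", {
  cfg <- tiny_config(convergence.max_steps = 25)
  m <- run_morphogenesis(cfg, 13)
  W <- cfg$domain$width; H <- cfg$domain$height
  expect_true(all(m$cells$x >= 0 & m$cells$x <= W))
  expect_true(all(m$cells$y >= 0 & m$cells$y <= H))
  d <- as.matrix(stats::dist(cbind(m$cells$x, m$cells$y)))
  diag(d) <- Inf
  min_sep <- min(d)
  expect_gt(min_sep, 2 * cfg$cells$radius - 0.5)  # overlaps relaxed away
})
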