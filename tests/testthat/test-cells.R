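test_that("the initial state honors counts, kinds and geometry", {
  cfg <- scaled_config()
  cells <- make_initial_state(cfg, 5)
  expect_equal(nrow(cells), cfg$cells$n_interior + cfg$cells$n_circulatory)
  tab <- table(cells$kind)
  expect_equal(unname(tab["CIRC_SOURCE"]), cfg$cells$n_circulatory / 2,
               ignore_attr = TRUE)
  expect_equal(unname(tab["CIRC_SINK"]), cfg$cells$n_circulatory / 2,
               ignore_attr = TRUE)
  n_vasc <- sum(cells$kind == "VASCULAR")
  expect_equal(n_vasc, round(cfg$cells$n_interior * cfg$cells$vascular_fraction),
               tolerance = 1)
  # circulatory columns hug the left and right walls
  xs <- cells$x[cells$kind == "CIRC_SOURCE"]
  xk <- cells$x[cells$kind == "CIRC_SINK"]
  expect_true(all(xs < cfg$domain$width / 4))
  expect_true(all(xk > 3 * cfg$domain$width / 4))
  # everything inside the domain
  expect_true(all(cells$x >= 0 & cells$x <= cfg$domain$width))
  expect_true(all(cells$y >= 0 & cells$y <= cfg$domain$height))
})

test_that("initial placement is deterministic in the seed", {
  cfg <- tiny_config()
  expect_identical(make_initial_state(cfg, 7), make_initial_state(cfg, 7))
  a <- make_initial_state(cfg, 7)
  b <- make_initial_state(cfg, 8)
  expect_false(isTRUE(all.equal(a$x, b$x)))
})

test_that("shoving relaxation removes overlaps and leaves columns fixed", {
  cfg <- tiny_config()
  cells <- make_initial_state(cfg, 2)
  # force a hard overlap between two interior cells
  i <- which(cells$kind != "CIRC_SOURCE" & cells$kind != "CIRC_SINK")[1:2]
  cells$x[i[2]] <- cells$x[i[1]] + 0.1
  cells$y[i[2]] <- cells$y[i[1]]
  col_before <- cells[cells$kind %in% c("CIRC_SOURCE", "CIRC_SINK"),
                      c("x", "y")]
  res <- relax_shoving(cells, cfg$domain$width, cfg$domain$height)
  out <- res$cells
  d <- sqrt((out$x[i[1]] - out$x[i[2]])^2 + (out$y[i[1]] - out$y[i[2]])^2)
  expect_gte(d, out$radius[i[1]] + out$radius[i[2]] - 0.05)
  col_after <- out[out$kind %in% c("CIRC_SOURCE", "CIRC_SINK"), c("x", "y")]
  expect_equal(col_after, col_before)
})

test_that("cell tables round-trip through CSV exactly enough to re-rasterize", {
  cfg <- tiny_config()
  cells <- make_initial_state(cfg, 3)
  path <- tempfile(fileext = ".csv")
  write_cells(cells, path)
  back <- read_cells(path)
  expect_equal(back$x, cells$x, tolerance = 1e-12)
  expect_identical(back$kind, cells$kind)
  m1 <- rasterize_particles(cells, unique(cells$kind), 1,
                            cfg$domain$width, cfg$domain$height)
  m2 <- rasterize_particles(back, unique(back$kind), 1,
                            cfg$domain$width, cfg$domain$height)
  expect_identical(m1$values, m2$values)
})

test_that("malformed cell tables are rejected", {
  expect_error(vascufab:::check_cells(data.frame(x = 1)), "columns")
  cells <- make_initial_state(tiny_config(), 1)
  cells$kind[1] <- "ALIEN"
  expect_error(vascufab:::check_cells(cells), "kind")
})

test_that("requesting an impossible packing density errors up front", {
  expect_error(make_initial_state(tiny_config(cells.n_interior = 100000)),
               "packing")
})
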