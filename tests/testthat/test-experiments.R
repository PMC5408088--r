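test_that("derived seeds are deterministic, distinct and within integer range", {
  s <- derive_seeds(123456789, 50)
  expect_identical(s, derive_seeds(123456789, 50))
  expect_equal(anyDuplicated(s), 0)
  expect_true(all(s > 0 & s < 2^31))
  expect_type(s, "integer")
  # huge master seeds fold into range instead of overflowing
  s2 <- derive_seeds(2^40 + 17, 10)
  expect_true(all(s2 > 0 & s2 < 2^31))
})

test_that("a connectivity-only sweep returns one record per (fraction, rep)", {
  cfg <- tiny_config(cells.n_interior = 150, convergence.max_steps = 30)
  sw <- sweep_vascular_fraction(cfg, fractions = c(0.1, 0.5), reps = 2,
                                phases = 2, master_seed = 4)
  expect_equal(nrow(sw$records), 4)
  expect_setequal(unique(sw$records$vascular_fraction), c(0.1, 0.5))
  expect_type(sw$records$connected, "logical")
  expect_true(all(is.na(sw$records$throughput)))
  # aggregates match the per-run records (no aggregation drift)
  expect_equal(sw$summary$connected_runs,
               as.integer(tapply(sw$records$connected,
                                 factor(sw$records$vascular_fraction,
                                        levels = c(0.1, 0.5)), sum)))
  expect_equal(sw$summary$n, c(2L, 2L))
  # rerunning reproduces the records exactly
  sw2 <- sweep_vascular_fraction(cfg, fractions = c(0.1, 0.5), reps = 2,
                                 phases = 2, master_seed = 4)
  expect_identical(sw$records, sw2$records)
})

test_that("fraction zero has relative productivity exactly one by definition", {
  cfg <- tiny_config()
  sw <- sweep_vascular_fraction(cfg, fractions = 0, reps = 1, phases = 3,
                                master_seed = 9)
  expect_equal(sw$records$relative_productivity, 1)
  expect_equal(sw$records$throughput, sw$records$baseline)
})

test_that("the full pipeline is deterministic end to end", {
  cfg <- tiny_config(cells.n_interior = 150, convergence.max_steps = 30)
  a <- suppressWarnings(run_pipeline(cfg, 17))
  b <- suppressWarnings(run_pipeline(cfg, 17))
  expect_identical(a$connected, b$connected)
  expect_identical(a$throughput, b$throughput)
  expect_identical(a$morphogenesis$cells, b$morphogenesis$cells)
  expect_identical(a$extraction$graph$edges, b$extraction$graph$edges)
})

test_that("pipeline results serialize to a manifest and fields to CSV", {
  cfg <- tiny_config(cells.n_interior = 100, convergence.max_steps = 10)
  res <- suppressWarnings(run_pipeline(cfg, 3, phases = 2))
  path <- tempfile(fileext = ".json")
  write_manifest(res, path)
  man <- jsonlite::read_json(path)
  expect_equal(man$package, "vascufab")
  expect_equal(man$seed, 3)
  expect_equal(man$connected, res$connected)

  csv <- tempfile(fileext = ".csv")
  write_field_csv(res$extraction$mask, csv)
  m <- as.matrix(utils::read.csv(csv, header = FALSE))
  expect_equal(dim(m), dim(res$extraction$mask$values))
  expect_equal(sum(m), sum(res$extraction$mask$values))
})
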