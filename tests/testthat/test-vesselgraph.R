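# Extraction correctness on deterministic phantoms with known topology.

test_that("skeletonization preserves components and holes on all phantoms", {
  for (shape in c("strip", "cross", "ring")) {
    m <- make_phantom_mask(shape, size = 64, thickness = 5)
    sk <- skeletonize_mask(m)
    expect_equal(count_components(sk$values)$n, count_components(m$values)$n,
                 info = shape)
    expect_equal(count_holes(sk$values), count_holes(m$values), info = shape)
    # strictly thinner (or equal), subset of the original mask
    expect_true(all(m$values[sk$values]), info = shape)
    expect_lt(sum(sk$values), sum(m$values))
  }
  for (k in 2:4) {
    m <- make_phantom_mask("lattice", size = 96, thickness = 5, k = k)
    expect_equal(count_holes(m$values), (k - 1)^2)
    sk <- skeletonize_mask(m)
    expect_equal(count_holes(sk$values), (k - 1)^2)
    expect_equal(count_components(sk$values)$n, 1)
  }
})

test_that("a strip extracts to a single edge with the right width and length", {
  m <- make_phantom_mask("strip", size = 64, thickness = 5)
  w <- local_width_map(m)
  # the local width at the bar's spine is within a pixel of the bar thickness
  expect_lte(abs(max(w$values) - 5), 1)
  expect_true(all(w$values[!m$values] == 0))
  g <- skeleton_to_graph(skeletonize_mask(m), w)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  # edge length close to the drawn bar length, radius near thickness / 2
  expect_equal(g$edges$length, 52, tolerance = 0.1)
  expect_equal(g$edges$radius, 2.5, tolerance = 0.5)
})

test_that("a cross extracts to one 4-way junction and four arms", {
  m <- make_phantom_mask("cross", size = 64, thickness = 5)
  g <- skeleton_to_graph(skeletonize_mask(m), local_width_map(m))
  expect_equal(nrow(g$nodes), 5)
  expect_equal(nrow(g$edges), 4)
  deg <- table(c(g$edges$from, g$edges$to))
  expect_equal(sort(as.integer(deg)), c(1, 1, 1, 1, 4))
})

test_that("a ring extracts to a single cycle and a lattice to (k-1)^2 cycles", {
  m <- make_phantom_mask("ring", size = 64, thickness = 5)
  g <- skeleton_to_graph(skeletonize_mask(m), local_width_map(m))
  cycle_rank <- nrow(g$edges) - nrow(g$nodes) + 1   # one component
  expect_equal(cycle_rank, 1)

  ml <- make_phantom_mask("lattice", size = 96, thickness = 5, k = 3)
  gl <- skeleton_to_graph(skeletonize_mask(ml), local_width_map(ml))
  expect_equal(nrow(gl$edges) - nrow(gl$nodes) + 1, (3 - 1)^2)
})

test_that("spur pruning removes short dead ends but never severs junctions", {
  ml <- make_phantom_mask("lattice", size = 96, thickness = 5, k = 3)
  gl <- skeleton_to_graph(skeletonize_mask(ml), local_width_map(ml))
  pruned <- prune_graph(gl, min_spur_length = 30)
  # the marginal stubs are gone, the 4 lattice cycles survive
  expect_lt(nrow(pruned$edges), nrow(gl$edges))
  expect_equal(nrow(pruned$edges) - nrow(pruned$nodes) + 1, 4)
})

test_that("vessel graphs validate and round-trip through JSON", {
  nodes <- data.frame(id = 1:3, x = c(0, 10, 20), y = 0,
                      kind = c("SOURCE", "INTERIOR", "SINK"))
  edges <- data.frame(from = c(1, 2), to = c(2, 3), radius = 2, length = 10)
  g <- vessel_graph(nodes, edges)
  path <- tempfile(fileext = ".json")
  write_graph_json(g, path)
  back <- read_graph_json(path)
  expect_equal(back$nodes$id, g$nodes$id)
  expect_equal(back$edges$radius, g$edges$radius, tolerance = 1e-12)
  expect_identical(back$nodes$kind, g$nodes$kind)

  expect_error(vessel_graph(nodes[c(1, 1), ], edges), "unique")
  expect_error(vessel_graph(nodes, transform(edges, radius = -1)), "radii")
  expect_error(vessel_graph(nodes, transform(edges, to = 99)), "node ids")
})

test_that("extraction from cells attaches terminals and is deterministic", {
  cfg <- tiny_config(cells.n_interior = 150, convergence.max_steps = 40)
  m <- run_morphogenesis(cfg, 11)
  e1 <- extract_vessel_graph(m$cells, cfg, bonds = m$bonds)
  e2 <- extract_vessel_graph(m$cells, cfg, bonds = m$bonds)
  expect_identical(e1$graph$edges, e2$graph$edges)
  expect_true(any(e1$graph$nodes$kind == "SOURCE"))
  expect_true(any(e1$graph$nodes$kind == "SINK"))
  # all radii positive and no wider than half the domain
  if (nrow(e1$graph$edges) > 0) {
    expect_true(all(e1$graph$edges$radius > 0))
    expect_true(all(e1$graph$edges$radius <= cfg$domain$width / 2))
  }
  # the mask covers at least the vascular + circulatory pixels
  expect_s3_class(e1$mask, "binary_mask")
  expect_gt(sum(e1$mask$values), 0)
})
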