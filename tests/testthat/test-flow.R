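# Poiseuille/Kirchhoff solver: closed forms, residuals and an independent
# loop-formulation oracle.

test_that("a single pipe reproduces the Poiseuille closed form exactly", {
  p <- default_flow_params()
  g <- vessel_graph(
    data.frame(id = 1:2, x = c(0, 20), y = 0, kind = c("SOURCE", "SINK")),
    data.frame(from = 1, to = 2, radius = 3, length = 20))
  s <- solve_network_flow(g, p)
  exact <- pi * 3^4 * p$delta_P / (8 * p$eta * 20)
  expect_equal(s$total_flow, exact, tolerance = 1e-13)
  expect_equal(s$flows, exact, tolerance = 1e-13)
  expect_equal(unname(s$pressures), c(p$delta_P, 0))
})

test_that("parallel pipes add conductances and series pipes add resistances", {
  p <- default_flow_params()
  # two parallel pipes of different radii
  gp <- vessel_graph(
    data.frame(id = 1:2, x = c(0, 20), y = 0, kind = c("SOURCE", "SINK")),
    data.frame(from = c(1, 1), to = c(2, 2), radius = c(2, 3), length = 20))
  sp <- solve_network_flow(gp, p)
  exact <- sum(edge_conductance(c(2, 3), 20, p$eta)) * p$delta_P
  expect_equal(sp$total_flow, exact, tolerance = 1e-13)
  # two pipes in series
  gs <- vessel_graph(
    data.frame(id = 1:3, x = c(0, 10, 30), y = 0,
               kind = c("SOURCE", "INTERIOR", "SINK")),
    data.frame(from = c(1, 2), to = c(2, 3), radius = c(2, 3),
               length = c(10, 20)))
  ss <- solve_network_flow(gs, p)
  exact_s <- p$delta_P / sum(1 / edge_conductance(c(2, 3), c(10, 20), p$eta))
  expect_equal(ss$total_flow, exact_s, tolerance = 1e-12)
  # both edges carry the identical series flow
  expect_equal(ss$flows[1], ss$flows[2], tolerance = 1e-12)
})

test_that("a 2x2 lattice reduces to two independent horizontal pipes", {
  p <- default_flow_params()
  g <- make_lattice_graph(2, 2, radius = 3, pitch = 20)
  s <- solve_network_flow(g, p)
  gcond <- edge_conductance(3, 20, p$eta)
  expect_equal(s$total_flow, 2 * gcond * p$delta_P, tolerance = 1e-12)
  # vertical edges connect equal-pressure terminals: zero flow
  vert <- g$edges$length == 20 &
    g$nodes$x[match(g$edges$from, g$nodes$id)] ==
    g$nodes$x[match(g$edges$to, g$nodes$id)]
  expect_equal(s$flows[vert], rep(0, sum(vert)))
})

test_that("lattice generators have the expected counts", {
  g <- make_lattice_graph(3, 3)
  expect_equal(nrow(g$nodes), 9)
  expect_equal(nrow(g$edges), 12)
  g12 <- make_lattice_graph(1, 2)
  expect_equal(nrow(g12$edges), 1)  # a single pipe
  expect_setequal(g12$nodes$kind, c("SOURCE", "SINK"))
})

test_that("the nodal solver matches the loop-law oracle on random networks", {
  set.seed(271828)
  for (trial in 1:12) {
    n <- sample(5:30, 1)
    g <- random_pipe_graph(n, extra = sample(2:8, 1),
                          n_source = sample(1:2, 1),
                          n_sink = sample(1:2, 1))
    p <- default_flow_params()
    s <- solve_network_flow(g, p)
    oracle <- loop_law_flow_oracle(g, p)
    scale <- max(abs(oracle), 1)
    expect_lt(max(abs(s$flows - oracle)) / scale, 1e-8)
  }
})

test_that("interior node residuals vanish to solver precision", {
  set.seed(31415)
  for (trial in 1:8) {
    g <- random_pipe_graph(sample(8:30, 1), extra = sample(3:10, 1))
    s <- solve_network_flow(g, default_flow_params())
    v <- verify_flow(s, g, tol = 1e-9)
    expect_lt(v$rel_node_residual, 1e-9)
    expect_lt(v$rel_imbalance, 1e-9)
    expect_true(v$ok)
  }
})

test_that("the loop law holds around every independent cycle", {
  set.seed(999)
  g <- random_pipe_graph(20, extra = 10)
  s <- solve_network_flow(g, default_flow_params())
  v <- verify_flow(s, g)
  expect_lt(v$rel_cycle_residual, 1e-9)
})

test_that("dead ends, self-loops and off-component edges carry zero flow", {
  p <- default_flow_params()
  nodes <- data.frame(
    id = 1:6, x = c(0, 10, 20, 10, 30, 40), y = c(0, 0, 0, 10, 10, 10),
    kind = c("SOURCE", "INTERIOR", "SINK", "INTERIOR", "INTERIOR", "INTERIOR"))
  edges <- data.frame(
    from = c(1, 2, 2, 2, 5), to = c(2, 3, 4, 2, 6),
    radius = 2, length = 10)
  g <- vessel_graph(nodes, edges)
  s <- solve_network_flow(g, p)
  expect_equal(s$flows[3], 0)            # dead-end spur to node 4
  expect_equal(s$flows[4], 0)            # self-loop at node 2
  expect_equal(s$flows[5], 0)            # disconnected component 5-6
  expect_true(is.na(s$pressures["5"]))   # off-component pressure undefined
  expect_gt(s$total_flow, 0)
})

test_that("disconnected terminals are reported, not silently solved", {
  nodes <- data.frame(id = 1:2, x = c(0, 10), y = 0,
                      kind = c("SOURCE", "SINK"))
  edges <- data.frame(from = integer(0), to = integer(0),
                      radius = numeric(0), length = numeric(0))
  g <- vessel_graph(nodes, edges, paths = list())
  expect_false(source_sink_connected(g))
  expect_error(solve_network_flow(g, default_flow_params()), "not connected")
  g2 <- vessel_graph(data.frame(id = 1, x = 0, y = 0, kind = "INTERIOR"),
                     edges, paths = list())
  expect_error(source_sink_connected(g2), "SOURCE/SINK")
})

test_that("conductance follows the r^4 / l scaling law", {
  expect_equal(edge_conductance(2, 10, 1) / edge_conductance(1, 10, 1), 16)
  expect_equal(edge_conductance(1, 20, 1) / edge_conductance(1, 10, 1), 0.5)
  expect_error(edge_conductance(0, 10, 1), "> 0")
})
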