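# Shared fixtures for the test suite: small fast configurations, a
# loop-formulation flow oracle independent of the production solver, random
# pipe networks, and mask topology counters.

# A small, fast configuration derived from the scaled profile. Tiny geometry
# keeps whole-pipeline tests to a few seconds while exercising every phase.
tiny_config <- function(...) {
  cfg <- unclass(scaled_config())
  cfg$domain$width <- 60
  cfg$domain$height <- 60
  cfg$cells$n_interior <- 60
  cfg$cells$n_circulatory <- 20
  cfg$convergence$max_steps <- 15
  cfg$factory$max_time <- 600
  cfg$factory$production_window <- 120
  cfg$factory$steady_window <- 30
  mods <- list(...)
  for (nm in names(mods)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg[[parts]] <- mods[[nm]]
  }
  cfg$chemo$D_c_um2 <- NULL
  cfg$factory$D_p_um2 <- NULL
  cfg$chemo$dt_solute <- NULL
  cfg$factory$dt <- NULL
  vascufab:::as_sim_config(cfg)
}

default_flow_params <- function() list(delta_P = 1000, eta = 8.9e-4)

# Independent flow oracle: solves for the edge flows directly from the pipe
# laws, using edge flows as unknowns. Equations: (a) conservation at every
# non-terminal node, (b) zero net resistive pressure drop around each
# fundamental cycle of a spanning tree, (c) the resistive drop along the tree
# path between pinned terminals equals their pressure difference. This is a
# different formulation from the production solver (which solves for nodal
# pressures), so agreement is a genuine cross-check.
loop_law_flow_oracle <- function(graph, params) {
  nodes <- graph$nodes
  e <- graph$edges
  n <- nrow(nodes)
  m <- nrow(e)
  fi <- match(e$from, nodes$id)
  ti <- match(e$to, nodes$id)
  live_e <- fi != ti
  R <- rep(Inf, m)
  R[live_e] <- 8 * params$eta * e$length[live_e] / (pi * e$radius[live_e]^4)

  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (m > 0) ig <- igraph::add_edges(ig, rbind(fi, ti))
  comp <- igraph::components(ig)$membership
  live_comp <- intersect(unique(comp[nodes$kind == "SOURCE"]),
                         unique(comp[nodes$kind == "SINK"]))
  in_live <- comp %in% live_comp
  pinned <- nodes$kind != "INTERIOR"
  pval <- ifelse(nodes$kind == "SOURCE", params$delta_P, 0)

  sel <- which(live_e & in_live[fi] & in_live[ti])
  flows <- rep(0, m)
  if (length(sel) == 0) return(flows)
  live_nodes <- which(in_live)
  k <- length(sel)

  rows <- list(); rhs <- numeric(0)
  # (a) conservation at non-pinned live nodes
  for (v in live_nodes[!pinned[live_nodes]]) {
    a <- numeric(k)
    a[fi[sel] == v] <- a[fi[sel] == v] - 1
    a[ti[sel] == v] <- a[ti[sel] == v] + 1
    rows[[length(rows) + 1L]] <- a
    rhs <- c(rhs, 0)
  }
  # spanning tree over the live subgraph (dedup parallel edges for the tree)
  sub <- igraph::make_empty_graph(n = n, directed = FALSE)
  sub <- igraph::add_edges(sub, rbind(fi[sel], ti[sel]))
  mst <- igraph::mst(sub)
  tree_eids <- integer(0)   # edge ids inside mst
  tree_edges <- integer(0)  # positions in `sel` claimed as tree edges
  for (ei in seq_len(k)) {
    eid <- igraph::get_edge_ids(mst, c(fi[sel[ei]], ti[sel[ei]]))
    if (!is.na(eid) && eid > 0 && !eid %in% tree_eids) {
      tree_eids <- c(tree_eids, eid)
      tree_edges <- c(tree_edges, ei)
    }
  }
  # resistive drop (from u to v) along the tree path, as a coefficient row
  path_row <- function(u, v) {
    a <- numeric(k)
    vp <- suppressWarnings(igraph::shortest_paths(
      mst, from = u, to = v, output = "vpath"))$vpath[[1]]
    vp <- as.integer(vp)
    for (s in seq_len(length(vp) - 1)) {
      pa <- vp[s]; pb <- vp[s + 1]
      cand <- tree_edges[(fi[sel[tree_edges]] == pa & ti[sel[tree_edges]] == pb) |
                         (fi[sel[tree_edges]] == pb & ti[sel[tree_edges]] == pa)][1]
      sgn <- if (fi[sel[cand]] == pa) 1 else -1
      a[cand] <- a[cand] + sgn * R[sel[cand]]
    }
    a
  }
  # (b) loop law for every chord (includes parallel duplicates of tree edges)
  for (ei in setdiff(seq_len(k), tree_edges)) {
    a <- path_row(fi[sel[ei]], ti[sel[ei]])
    a[ei] <- a[ei] - R[sel[ei]]   # chord drop closes the cycle
    rows[[length(rows) + 1L]] <- a
    rhs <- c(rhs, 0)
  }
  # (c) terminal pressure constraints relative to one reference terminal
  pins <- live_nodes[pinned[live_nodes]]
  ref <- pins[1]
  for (p in pins[-1]) {
    rows[[length(rows) + 1L]] <- path_row(ref, p)
    rhs <- c(rhs, pval[ref] - pval[p])
  }
  A <- do.call(rbind, rows)
  flows[sel] <- as.numeric(qr.solve(A, rhs))
  flows
}

# Random connected pipe network with <= n_max nodes: a random spanning tree
# plus extra edges (possibly parallel), random radii and lengths, one or two
# SOURCE nodes and one or two SINK nodes.
random_pipe_graph <- function(n, extra = 5, n_source = 1, n_sink = 1) {
  stopifnot(n >= n_source + n_sink + 1)
  from <- integer(0); to <- integer(0)
  for (v in 2:n) { from <- c(from, sample.int(v - 1, 1)); to <- c(to, v) }
  for (j in seq_len(extra)) {
    uv <- sample.int(n, 2)
    from <- c(from, uv[1]); to <- c(to, uv[2])
  }
  kind <- rep("INTERIOR", n)
  picks <- sample.int(n, n_source + n_sink)
  kind[picks[seq_len(n_source)]] <- "SOURCE"
  kind[picks[n_source + seq_len(n_sink)]] <- "SINK"
  nodes <- data.frame(id = seq_len(n), x = stats::runif(n, 0, 100),
                      y = stats::runif(n, 0, 100), kind = kind,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = from, to = to,
                      radius = stats::runif(length(from), 0.5, 5),
                      length = stats::runif(length(from), 5, 50))
  vessel_graph(nodes, edges)
}

# Topology counters for small logical masks: 8-connected foreground
# components, and holes = 4-connected background components not touching the
# border (the complementary-connectivity convention).
count_components <- function(m, eight = TRUE) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  if (eight) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    di <- c(-1, 1, 0, 0); dj <- c(0, 0, -1, 1)
  }
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!m[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i0, j0), 1)
    lab[i0, j0] <- cur
    while (nrow(stack) > 0) {
      i <- stack[1, 1]; j <- stack[1, 2]
      stack <- stack[-1, , drop = FALSE]
      for (t in seq_along(di)) {
        ii <- i + di[t]; jj <- j + dj[t]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  list(n = cur, labels = lab)
}

count_holes <- function(m) {
  bg <- count_components(!m, eight = FALSE)
  if (bg$n == 0) return(0L)
  border <- unique(c(bg$labels[1, ], bg$labels[nrow(m), ],
                     bg$labels[, 1], bg$labels[, ncol(m)]))
  sum(!seq_len(bg$n) %in% border[border > 0])
}
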