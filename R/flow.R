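#' Phase II, solve half: Poiseuille/Kirchhoff network flow
#'
#' Each vessel is a cylindrical pipe obeying Poiseuille's law
#' `Q = pi r^4 dP / (8 eta l)`; mass conservation at every interior junction
#' and single-valued pressures (which make every loop's pressure drops sum to
#' zero automatically) close the system. The solver uses the nodal
#' (pressure-unknown) formulation: SOURCE nodes are pinned at `delta_P`,
#' SINK nodes at 0, and the sparse symmetric weighted-Laplacian system is
#' solved for the interior pressures.
#'
#' @name flow
NULL

#' Hydraulic conductance of a cylindrical vessel
#'
#' `pi r^4 / (8 eta l)` in um^3/(s Pa), so that `Q = conductance * dP` in
#' um^3/s. Vectorized.
#'
#' @param radius Vessel radius, um.
#' @param length Vessel length, um.
#' @param eta Dynamic viscosity, Pa s.
#' @return Conductance in um^3/(s Pa).
#' @export
edge_conductance <- function(radius, length, eta) {
  if (any(radius <= 0) || any(length <= 0) || eta <= 0)
    stop("radius, length and eta must be > 0", call. = FALSE)
  pi * radius^4 / (8 * eta * length)
}

graph_to_igraph <- function(graph, drop_loops = FALSE) {
  e <- graph$edges
  if (drop_loops && nrow(e) > 0) e <- e[e$from != e$to, , drop = FALSE]
  ids <- as.character(graph$nodes$id)
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(e) > 0)
    g <- igraph::add_edges(g, rbind(match(e$from, graph$nodes$id),
                                    match(e$to, graph$nodes$id)))
  g
}

#' Is the source connected to the sink?
#'
#' Graph traversal test: `TRUE` iff at least one SOURCE node and one SINK
#' node lie in the same connected component.
#'
#' @param graph A [vessel_graph()] with terminals attached.
#' @return Logical scalar.
#' @export
source_sink_connected <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  k <- graph$nodes$kind
  if (!any(k == "SOURCE") || !any(k == "SINK"))
    stop("graph has no SOURCE/SINK terminals attached", call. = FALSE)
  g <- graph_to_igraph(graph)
  comp <- igraph::components(g)$membership
  any(comp[k == "SOURCE"] %in% comp[k == "SINK"])
}

#' Solve the network flow
#'
#' Pins every SOURCE node at pressure `delta_P` and every SINK node at 0,
#' enforces zero net flow at all other nodes of the terminal-connected
#' component (Kirchhoff's node law; the loop law holds identically because
#' flows derive from a potential), and solves the sparse symmetric system.
#' Edges in components not containing the terminals, dead-end branches and
#' self-loops carry exactly zero flow.
#'
#' @param graph A [vessel_graph()] with terminals attached and source and
#'   sink connected.
#' @param params `flow` section of a `sim_config` (`delta_P`, `eta`), or a
#'   list with those fields.
#' @return A `flow_solution`: list with `pressures` (named by node id, Pa;
#'   `NA` off the flow-carrying component), `flows` (signed um^3/s per edge,
#'   positive from `from` to `to`), `conductance` per edge, `node_residuals`
#'   (named, um^3/s) and `total_flow` (um^3/s out of the sources).
#' @export
solve_network_flow <- function(graph, params) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!source_sink_connected(graph))
    stop("source and sink are not connected; no flow solution exists",
         call. = FALSE)
  nodes <- graph$nodes; e <- graph$edges
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)
  gcond <- rep(0, nrow(e))
  live_e <- e$from != e$to
  gcond[live_e] <- edge_conductance(e$radius[live_e], e$length[live_e],
                                    params$eta)

  # nodes in components containing a terminal participate in the solve
  ig <- graph_to_igraph(graph)
  comp <- igraph::components(ig)$membership
  term_comp <- unique(comp[nodes$kind != "INTERIOR"])
  src_comp <- unique(comp[nodes$kind == "SOURCE"])
  snk_comp <- unique(comp[nodes$kind == "SINK"])
  live_comp <- intersect(src_comp, snk_comp)
  in_live <- comp %in% live_comp

  pinned <- nodes$kind != "INTERIOR"
  pval <- ifelse(nodes$kind == "SOURCE", params$delta_P, 0)
  P <- rep(NA_real_, n)
  P[pinned] <- pval[pinned]

  unknown <- which(in_live & !pinned)
  if (length(unknown) > 0) {
    sel <- which(live_e & in_live[idx[as.character(e$from)]])
    fi <- idx[as.character(e$from[sel])]
    ti <- idx[as.character(e$to[sel])]
    gv <- gcond[sel]
    # weighted Laplacian over live nodes
    L <- Matrix::sparseMatrix(
      i = c(fi, ti, fi, ti), j = c(ti, fi, fi, ti),
      x = c(-gv, -gv, gv, gv), dims = c(n, n)
    )
    uu <- L[unknown, unknown, drop = FALSE]
    pin_live <- which(in_live & pinned)
    b <- -(L[unknown, pin_live, drop = FALSE] %*% P[pin_live])
    sol <- Matrix::solve(uu, b)
    P[unknown] <- as.numeric(sol)
  }
  # off-component interior nodes keep NA pressure and zero flow
  flows <- rep(0, nrow(e))
  if (nrow(e) > 0) {
    fi <- idx[as.character(e$from)]
    ti <- idx[as.character(e$to)]
    ok <- live_e & in_live[fi] & in_live[ti] & !is.na(P[fi]) & !is.na(P[ti])
    flows[ok] <- gcond[ok] * (P[fi][ok] - P[ti][ok])
  }
  res <- node_flow_residuals(graph, flows)
  src_ids <- nodes$id[nodes$kind == "SOURCE"]
  total <- sum(flows[e$from %in% src_ids]) - sum(flows[e$to %in% src_ids])
  structure(list(pressures = stats::setNames(P, nodes$id), flows = flows,
                 conductance = gcond,
                 node_residuals = res, total_flow = total),
            class = "flow_solution")
}

node_flow_residuals <- function(graph, flows) {
  nodes <- graph$nodes; e <- graph$edges
  res <- stats::setNames(rep(0, nrow(nodes)), nodes$id)
  if (nrow(e) > 0) {
    out_ <- tapply(flows, factor(e$from, levels = nodes$id), sum)
    in_ <- tapply(flows, factor(e$to, levels = nodes$id), sum)
    out_[is.na(out_)] <- 0; in_[is.na(in_)] <- 0
    res <- res + as.numeric(in_) - as.numeric(out_)
    names(res) <- nodes$id
  }
  res
}

#' Verify a flow solution
#'
#' Reports the largest interior-node flow residual (node law), the largest
#' pressure-drop sum around an independent cycle basis (loop law; fundamental
#' cycles of a spanning tree), and the source/sink balance, each also as a
#' value relative to the total through-flow.
#'
#' @param solution A `flow_solution`.
#' @param graph The [vessel_graph()] it was solved on.
#' @param tol Relative tolerance used for the `ok` flag.
#' @return List with `max_node_residual`, `max_cycle_residual`,
#'   `source_sink_imbalance`, their relative counterparts and `ok`.
#' @export
verify_flow <- function(solution, graph, tol = 1e-9) {
  nodes <- graph$nodes; e <- graph$edges
  res <- node_flow_residuals(graph, solution$flows)
  interior <- nodes$kind == "INTERIOR"
  max_node <- if (any(interior)) max(abs(res[interior])) else 0

  # cycle-basis pressure residuals
  max_cycle <- 0
  live <- which(e$from != e$to & solution$conductance > 0)
  if (length(live) > 1) {
    ids <- nodes$id
    g <- graph_to_igraph(graph)
    sub <- igraph::subgraph_from_edges(g, live, delete.vertices = FALSE)
    mst <- igraph::mst(sub)
    in_tree <- !is.na(igraph::get_edge_ids(
      mst, t(igraph::as_edgelist(sub, names = FALSE))))
    # map sub edges back to original edge rows
    chords <- live[!in_tree]
    dP <- rep(NA_real_, nrow(e))
    dP[live] <- solution$flows[live] / solution$conductance[live]
    for (ce in chords) {
      u <- match(e$from[ce], ids); v <- match(e$to[ce], ids)
      path <- suppressWarnings(
        igraph::shortest_paths(mst, from = u, to = v, output = "vpath"))$vpath[[1]]
      if (length(path) < 2) next
      s <- dP[ce]                      # chord drop from u to v
      vp <- as.integer(path)
      # walk tree path v_1 .. v_k and subtract its drops (u -> v)
      drop_uv <- 0
      for (k in seq_len(length(vp) - 1)) {
        a <- ids[vp[k]]; b <- ids[vp[k + 1]]
        ei <- which((e$from == a & e$to == b) | (e$from == b & e$to == a))
        ei <- intersect(ei, live)[1]
        sgn <- if (e$from[ei] == a) 1 else -1
        drop_uv <- drop_uv + sgn * dP[ei]
      }
      max_cycle <- max(max_cycle, abs(s - drop_uv))
    }
  }
  src_ids <- nodes$id[nodes$kind == "SOURCE"]
  snk_ids <- nodes$id[nodes$kind == "SINK"]
  out_src <- sum(solution$flows[e$from %in% src_ids]) -
    sum(solution$flows[e$to %in% src_ids])
  in_snk <- sum(solution$flows[e$to %in% snk_ids]) -
    sum(solution$flows[e$from %in% snk_ids])
  imb <- abs(out_src - in_snk)
  scale <- max(abs(solution$total_flow), max(abs(solution$flows), 0), 1e-300)
  list(max_node_residual = max_node,
       max_cycle_residual = max_cycle,
       source_sink_imbalance = imb,
       rel_node_residual = max_node / scale,
       rel_cycle_residual = max_cycle / max(abs(solution$pressures), na.rm = TRUE),
       rel_imbalance = imb / scale,
       ok = (max_node / scale < tol) && (imb / scale < tol))
}
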