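#' Vessel graphs
#'
#' A `vessel_graph` is the network-of-pipes representation of the vascular
#' morphology: `nodes` is a data frame (`id`, `x`, `y` in um, `kind` one of
#' `"INTERIOR"`, `"SOURCE"`, `"SINK"`), `edges` a data frame (`from`, `to`
#' node ids, `radius` um, `length` um), and `paths` a list (one entry per
#' edge) of 2-column integer matrices of the (row, col) skeleton pixels the
#' edge traverses (empty for virtual terminal edges). The graph is
#' undirected; parallel edges and self-loops are permitted (a lacuna can
#' close onto a single junction).
#'
#' @param nodes,edges,paths See description.
#' @param resolution Grid spacing in um.
#' @return A `vessel_graph`.
#' @export
vessel_graph <- function(nodes, edges, paths = rep(list(matrix(integer(0), 0, 2)),
                                                   nrow(edges)),
                         resolution = 1) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  if (nrow(edges) > 0) {
    if (any(edges$radius <= 0)) stop("edge radii must be > 0", call. = FALSE)
    if (any(edges$length <= 0)) stop("edge lengths must be > 0", call. = FALSE)
    if (!all(c(edges$from, edges$to) %in% nodes$id))
      stop("edge endpoints must be node ids", call. = FALSE)
  }
  if (length(paths) != nrow(edges))
    stop("one path entry per edge required", call. = FALSE)
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 resolution = resolution),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d edges at %g um/px\n",
              nrow(x$nodes), nrow(x$edges), x$resolution))
  invisible(x)
}

#' Local vessel width map
#'
#' Width at a foreground pixel is twice the Euclidean distance (exact
#' distance transform) to the nearest background pixel center, in um -- the
#' local-thickness approximation sampled later along the skeleton. Background
#' pixels have width 0.
#'
#' @param mask A [binary_mask()].
#' @return A list with `values` (numeric width matrix, um) and `resolution`,
#'   of class `width_map`.
#' @export
local_width_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (all(mask$values))
    stop("mask has no background pixels; local width is undefined", call. = FALSE)
  w <- 2 * mask$resolution * cpp_edt(mask$values)
  structure(list(values = w, resolution = mask$resolution), class = "width_map")
}

#' Skeletonize a binary mask
#'
#' Topology-preserving medial-axis thinning: simple pixels (whose removal
#' keeps the local foreground 8-topology intact) that are not endpoints are
#' deleted sequentially, ordered by ascending distance transform so the
#' skeleton stays medial. The result is a one-pixel-wide, 8-connected
#' skeleton with the same number of connected components and holes as the
#' input.
#'
#' @param mask A [binary_mask()].
#' @return A [binary_mask()] holding the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) return(mask)
  pri <- cpp_edt(mask$values)
  binary_mask(cpp_thin(mask$values, pri), mask$resolution)
}

# Yokoi 8-connectivity number for every pixel of a logical matrix: the number
# of distinct 8-connected foreground components touching each pixel. A
# foreground pixel with C == 1 and 2..7 neighbors is "simple": deleting it
# preserves the component and hole counts.
yokoi_matrix <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  sh <- function(di, dj) p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  # circular neighbor order: E, NE, N, NW, W, SW, S, SE
  b <- list(sh(0, 1), sh(1, 1), sh(1, 0), sh(1, -1),
            sh(0, -1), sh(-1, -1), sh(-1, 0), sh(-1, 1))
  C <- matrix(0L, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (k in 1:8) cnt <- cnt + b[[k]]
  for (k in c(1L, 3L, 5L, 7L)) {
    k2 <- if (k == 7L) 1L else k + 2L
    C <- C + (!b[[k]] & (b[[k + 1L]] | b[[k2]]))
  }
  C[C == 0L & cnt == 8L] <- 1L
  C
}

# 8-neighbor foreground counts of a logical matrix
neighbor_count_matrix <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m * 1L
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    cnt <- cnt + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  cnt
}

#' Extract a vessel graph from a skeleton
#'
#' Skeleton pixels are classified by 8-neighbor count (1 endpoint, 2 slab,
#' 3+ junction); 8-adjacent junction pixels are merged into one node at
#' their centroid; branches are traced slab to slab between nodes. Edge
#' length sums the step lengths along the traced pixel path (`h` axial,
#' `h * sqrt(2)` diagonal); edge radius is half the mean local width over the
#' path pixels. Closed loops without any junction become a self-loop anchored
#' at their lexicographically smallest pixel. Deterministic for a fixed mask.
#'
#' @param skeleton A [binary_mask()] holding a 1-pixel-wide skeleton.
#' @param widths A `width_map` from [local_width_map()] (computed on the
#'   original mask).
#' @return A [vessel_graph()].
#' @export
skeleton_to_graph <- function(skeleton, widths) {
  stopifnot(inherits(skeleton, "binary_mask"))
  sk <- skeleton$values
  h <- skeleton$resolution
  nr <- nrow(sk); nc <- ncol(sk)
  # Reject inputs that are not fully thinned: a solid 2x2 foreground block
  # that still contains a simple (deletable) non-endpoint pixel means the
  # mask is wider than one pixel. Solid 2x2 blocks whose pixels are all
  # non-simple are irreducible junction clusters (every deletion would change
  # the topology); they are kept and merged into a single junction node below.
  if (nr > 1 && nc > 1) {
    blk <- sk[-nr, -nc] & sk[-1, -nc] & sk[-nr, -1] & sk[-1, -1]
    if (any(blk)) {
      yk <- yokoi_matrix(sk)
      cnt8 <- neighbor_count_matrix(sk)
      del <- sk & yk == 1L & cnt8 >= 2L & cnt8 < 8L
      bad <- blk & (del[-nr, -nc] | del[-1, -nc] | del[-nr, -1] | del[-1, -1])
      if (any(bad)) {
        ij <- which(bad, arr.ind = TRUE)[1, ]
        stop(sprintf("skeleton is wider than one pixel at (%d, %d)",
                     ij[1], ij[2]), call. = FALSE)
      }
    }
  }
  W <- widths$values
  cnt <- neighbor_count_matrix(sk)
  is_node_px <- sk & (cnt != 2L)

  # node labels: junction clusters (8-connected) + endpoints/isolated pixels
  label <- matrix(0L, nr, nc)
  node_xy <- list(); node_id <- 0L
  jidx <- which(sk & cnt >= 3L)
  if (length(jidx) > 0) {
    ji <- ((jidx - 1L) %% nr) + 1L
    jj <- ((jidx - 1L) %/% nr) + 1L
    # adjacency among junction pixels
    key <- match(jidx, jidx)
    pos <- stats::setNames(seq_along(jidx), jidx)
    el <- list()
    for (k in seq_along(jidx)) {
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        i2 <- ji[k] + di; j2 <- jj[k] + dj
        if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
        q <- i2 + (j2 - 1L) * nr
        p2 <- pos[as.character(q)]
        if (!is.na(p2) && p2 > k) el[[length(el) + 1L]] <- c(k, p2)
      }
    }
    g <- igraph::make_empty_graph(n = length(jidx), directed = FALSE)
    if (length(el) > 0)
      g <- igraph::add_edges(g, as.vector(t(do.call(rbind, el))))
    comp <- igraph::components(g)$membership
    for (cid in seq_len(max(comp))) {
      node_id <- node_id + 1L
      members <- jidx[comp == cid]
      label[members] <- node_id
      mi <- ((members - 1L) %% nr) + 1L
      mj <- ((members - 1L) %/% nr) + 1L
      node_xy[[node_id]] <- c(mean((mj - 0.5) * h), mean((mi - 0.5) * h))
    }
  }
  eidx <- which(sk & cnt <= 1L)  # endpoints and isolated pixels
  for (q in eidx) {
    node_id <- node_id + 1L
    label[q] <- node_id
    i <- ((q - 1L) %% nr) + 1L; j <- ((q - 1L) %/% nr) + 1L
    node_xy[[node_id]] <- c((j - 0.5) * h, (i - 0.5) * h)
  }

  used <- matrix(FALSE, nr, nc)  # consumed slab pixels
  edges_from <- integer(0); edges_to <- integer(0)
  edges_r <- numeric(0); edges_l <- numeric(0)
  paths <- list()

  nbrs <- function(i, j) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    cbind(ii[ok], jj[ok])
  }
  path_stats <- function(path) {
    # path: k x 2 matrix of (i, j)
    if (nrow(path) < 2) return(c(len = h, rad = max(W[path], h / 2)))
    steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
                           path[-nrow(path), , drop = FALSE])^2))
    len <- sum(steps) * h
    wv <- W[path]
    c(len = len, rad = mean(wv[wv > 0]) / 2)
  }
  add_edge <- function(a, b, path) {
    st <- path_stats(path)
    rad <- st[["rad"]]
    if (!is.finite(rad) || rad <= 0) rad <- h / 2
    edges_from[length(edges_from) + 1L] <<- a
    edges_to[length(edges_to) + 1L] <<- b
    edges_l[length(edges_l) + 1L] <<- max(st[["len"]], h / 2)
    edges_r[length(edges_r) + 1L] <<- rad
    paths[[length(paths) + 1L]] <<- path
  }

  trace_branch <- function(pi, pj, qi, qj) {
    path <- rbind(c(pi, pj), c(qi, qj))
    used[qi, qj] <<- TRUE
    prev <- c(pi, pj); cur <- c(qi, qj)
    repeat {
      nb <- nbrs(cur[1], cur[2])
      fgn <- nb[sk[nb] & !(nb[, 1] == prev[1] & nb[, 2] == prev[2]), ,
                drop = FALSE]
      if (nrow(fgn) == 0) return(NULL)           # should not happen on 1px skeletons
      lab <- label[fgn]
      if (any(lab > 0)) {
        nxt <- fgn[which(lab > 0)[1], ]
        path <- rbind(path, nxt)
        return(list(end = label[nxt[1], nxt[2]], path = path))
      }
      slab <- fgn[!used[fgn], , drop = FALSE]
      if (nrow(slab) == 0) return(NULL)          # already consumed (loop back)
      nxt <- slab[1, ]
      used[nxt[1], nxt[2]] <<- TRUE
      path <- rbind(path, nxt)
      prev <- cur; cur <- nxt
    }
  }

  node_px <- which(label > 0)
  for (q in node_px) {
    i <- ((q - 1L) %% nr) + 1L; j <- ((q - 1L) %/% nr) + 1L
    a <- label[i, j]
    nb <- nbrs(i, j)
    for (k in seq_len(nrow(nb))) {
      i2 <- nb[k, 1]; j2 <- nb[k, 2]
      if (!sk[i2, j2]) next
      b <- label[i2, j2]
      if (b > 0) {
        # direct node-node adjacency (count once, skip intra-cluster)
        if (b != a && (i + (j - 1L) * nr) < (i2 + (j2 - 1L) * nr))
          add_edge(a, b, rbind(c(i, j), c(i2, j2)))
      } else if (!used[i2, j2]) {
        tr <- trace_branch(i, j, i2, j2)
        if (!is.null(tr)) add_edge(a, tr$end, tr$path)
      }
    }
  }

  # pure cycles: slab components never reached from a node
  rest <- which(sk & !is_node_px & !used)
  while (length(rest) > 0) {
    q <- min(rest)                        # lexicographically smallest anchor
    i <- ((q - 1L) %% nr) + 1L; j <- ((q - 1L) %/% nr) + 1L
    node_id <- node_id + 1L
    label[i, j] <- node_id
    node_xy[[node_id]] <- c((j - 0.5) * h, (i - 0.5) * h)
    nb <- nbrs(i, j)
    fgn <- nb[sk[nb] & !used[nb] & label[nb] == 0L, , drop = FALSE]
    if (nrow(fgn) > 0) {
      tr <- trace_branch(i, j, fgn[1, 1], fgn[1, 2])
      if (!is.null(tr)) add_edge(node_id, tr$end, tr$path)
    }
    rest <- which(sk & !is_node_px & !used & label == 0L)
  }

  nodes <- if (node_id > 0) {
    xy <- do.call(rbind, node_xy)
    data.frame(id = seq_len(node_id), x = xy[, 1], y = xy[, 2],
               kind = "INTERIOR", stringsAsFactors = FALSE)
  } else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    kind = character(0), stringsAsFactors = FALSE)
  edges <- data.frame(from = edges_from, to = edges_to,
                      radius = edges_r, length = edges_l)
  vessel_graph(nodes, edges, paths, h)
}

node_degrees <- function(graph) {
  deg <- stats::setNames(rep(0L, nrow(graph$nodes)), graph$nodes$id)
  if (nrow(graph$edges) > 0) {
    t1 <- table(factor(graph$edges$from, levels = graph$nodes$id))
    t2 <- table(factor(graph$edges$to, levels = graph$nodes$id))
    deg <- deg + as.integer(t1) + as.integer(t2)
    names(deg) <- graph$nodes$id
  }
  deg
}

drop_edges <- function(graph, idx) {
  graph$edges <- graph$edges[-idx, , drop = FALSE]
  graph$paths <- graph$paths[-idx]
  graph
}

#' Prune short spurs and simplify a vessel graph
#'
#' Iteratively removes edges that end in a degree-1 interior node and are
#' shorter than `min_spur_length` (skeletonization spurs from single-cell
#' bumps); edges incident to SOURCE/SINK terminals are never removed.
#' Resulting degree-2 interior nodes are merged, concatenating paths, summing
#' lengths and length-weighting radii. Orphaned interior nodes are dropped.
#'
#' @param graph A [vessel_graph()].
#' @param min_spur_length Spur threshold in um (`0` leaves the graph
#'   unchanged).
#' @return The pruned [vessel_graph()].
#' @export
prune_graph <- function(graph, min_spur_length) {
  stopifnot(inherits(graph, "vessel_graph"), min_spur_length >= 0)
  if (min_spur_length == 0 || nrow(graph$edges) == 0) return(graph)
  terminals <- graph$nodes$id[graph$nodes$kind != "INTERIOR"]
  repeat {
    deg <- node_degrees(graph)
    leaf <- as.integer(names(deg)[deg == 1L])
    leaf <- setdiff(leaf, terminals)
    if (length(leaf) == 0) break
    e <- graph$edges
    spur <- which((e$from %in% leaf | e$to %in% leaf) &
                    e$length < min_spur_length &
                    !(e$from %in% terminals) & !(e$to %in% terminals))
    if (length(spur) == 0) break
    graph <- drop_edges(graph, spur)
  }
  graph <- merge_degree2(graph)
  deg <- node_degrees(graph)
  orphan <- as.integer(names(deg)[deg == 0L])
  orphan <- setdiff(orphan, terminals)
  graph$nodes <- graph$nodes[!graph$nodes$id %in% orphan, , drop = FALSE]
  graph
}

merge_degree2 <- function(graph) {
  repeat {
    deg <- node_degrees(graph)
    cand <- as.integer(names(deg)[deg == 2L])
    cand <- intersect(cand, graph$nodes$id[graph$nodes$kind == "INTERIOR"])
    merged <- FALSE
    for (v in cand) {
      ei <- which(graph$edges$from == v | graph$edges$to == v)
      if (length(ei) != 2) next                 # self-loop at v: leave it
      e1 <- graph$edges[ei[1], ]; e2 <- graph$edges[ei[2], ]
      a <- if (e1$from == v) e1$to else e1$from
      b <- if (e2$from == v) e2$to else e2$from
      # orient paths a -> v -> b
      p1 <- graph$paths[[ei[1]]]
      if (e1$from == v && nrow(p1) > 0) p1 <- p1[nrow(p1):1, , drop = FALSE]
      p2 <- graph$paths[[ei[2]]]
      if (e2$to == v && nrow(p2) > 0) p2 <- p2[nrow(p2):1, , drop = FALSE]
      path <- rbind(p1, if (nrow(p2) > 1) p2[-1, , drop = FALSE] else NULL)
      len <- e1$length + e2$length
      rad <- (e1$radius * e1$length + e2$radius * e2$length) / len
      graph <- drop_edges(graph, ei)
      graph$edges <- rbind(graph$edges,
                           data.frame(from = a, to = b, radius = rad,
                                      length = len))
      graph$paths[[length(graph$paths) + 1L]] <-
        if (is.null(path)) matrix(integer(0), 0, 2) else path
      graph$nodes <- graph$nodes[graph$nodes$id != v, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  graph
}

#' Attach source and sink supernodes
#'
#' Adds one SOURCE and one SINK supernode and connects every interior node
#' lying within `terminal_band` of the left (right) circulatory column to it
#' by a short, wide, effectively zero-resistance edge (radius = the graph's
#' maximum edge radius, length = one pixel). If no node lies near a column
#' the graph is returned unaugmented on that side (the flow solve then
#' reports disconnection).
#'
#' @param graph A [vessel_graph()].
#' @param config A `sim_config` (supplies domain width, cell radius and the
#'   terminal band width).
#' @return The augmented [vessel_graph()].
#' @export
attach_terminals <- function(graph, config) {
  stopifnot(inherits(graph, "vessel_graph"))
  W <- config$domain$width; H <- config$domain$height
  band <- config$extraction$terminal_band
  h <- graph$resolution
  rmax <- if (nrow(graph$edges) > 0) max(graph$edges$radius) else config$cells$radius
  nid <- if (nrow(graph$nodes) > 0) max(graph$nodes$id) else 0L
  src_id <- nid + 1L; snk_id <- nid + 2L
  graph$nodes <- rbind(graph$nodes,
                       data.frame(id = c(src_id, snk_id), x = c(0, W),
                                  y = c(H / 2, H / 2),
                                  kind = c("SOURCE", "SINK"),
                                  stringsAsFactors = FALSE))
  interior <- graph$nodes[graph$nodes$kind == "INTERIOR", , drop = FALSE]
  near_src <- interior$id[interior$x <= band]
  near_snk <- interior$id[interior$x >= W - band]
  from <- c(rep(src_id, length(near_src)), rep(snk_id, length(near_snk)))
  to <- c(near_src, near_snk)
  new_edges <- data.frame(from = from, to = to,
                          radius = rep(rmax, length(from)),
                          length = rep(h, length(from)))
  if (nrow(new_edges) > 0) {
    graph$edges <- rbind(graph$edges, new_edges)
    graph$paths <- c(graph$paths,
                     rep(list(matrix(integer(0), 0, 2)), nrow(new_edges)))
  }
  graph
}

#' Full mask-to-graph extraction pipeline
#'
#' Rasterizes the vascular cells (plus, when adhesion bonds are in use, the
#' vessel cord segments spanned by bonded cell pairs, drawn as capsules of
#' one cell radius), computes the local width map, skeletonizes, traces the
#' skeleton into a graph, attaches the terminal supernodes and prunes spurs.
#'
#' @param cells Cell data frame (Phase I output).
#' @param config A `sim_config`.
#' @param bonds Optional two-column matrix of bonded cell-row pairs (the
#'   `bonds` element of a `morphogenesis_state`). When `NULL` and
#'   `config$chemo$bond_form` is set, bonds are approximated as all
#'   vascular--vascular and vascular--circulatory pairs with surface gap at
#'   most `config$chemo$bond_form` (stretched bonds carried over from the
#'   simulation are missed, so prefer passing the simulated bond set).
#' @return List with `mask`, `widths`, `skeleton` and `graph`.
#' @export
extract_vessel_graph <- function(cells, config, bonds = NULL) {
  mask <- rasterize_particles(cells, "VASCULAR", config$domain$resolution,
                              config$domain$width, config$domain$height)
  if (!is.null(config$chemo$bond_form)) {
    if (is.null(bonds)) {
      sel <- cells$kind != "PRODUCER"
      bonds <- cpp_pairs_within(cells$x, cells$y, cells$radius, sel,
                                config$chemo$bond_form,
                                config$domain$width, config$domain$height)
      isv <- cells$kind == "VASCULAR"
      bonds <- bonds[isv[bonds[, 1]] | isv[bonds[, 2]], , drop = FALSE]
    }
    if (!is.null(bonds) && nrow(bonds) > 0) {
      caps <- cpp_rasterize_capsules(
        cells$x[bonds[, 1]], cells$y[bonds[, 1]],
        cells$x[bonds[, 2]], cells$y[bonds[, 2]],
        config$cells$radius, nrow(mask$values), ncol(mask$values),
        config$domain$resolution)
      mask$values <- mask$values | caps
    }
  }
  if (!any(mask$values)) {
    g <- vessel_graph(
      data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                 kind = character(0), stringsAsFactors = FALSE),
      data.frame(from = integer(0), to = integer(0),
                 radius = numeric(0), length = numeric(0)),
      list(), config$domain$resolution)
    g <- attach_terminals(g, config)
    return(list(mask = mask, widths = NULL, skeleton = mask, graph = g))
  }
  widths <- local_width_map(mask)
  skeleton <- skeletonize_mask(mask)
  graph <- skeleton_to_graph(skeleton, widths)
  # attach terminals before pruning: the short skeleton fingers that reach
  # into the terminal bands would otherwise be removed as spurs, and
  # attachment raises their endpoints above degree 1, protecting them
  graph <- attach_terminals(graph, config)
  graph <- prune_graph(graph, config$extraction$min_spur_length)
  list(mask = mask, widths = widths, skeleton = skeleton, graph = graph)
}

#' Serialize / load a vessel graph as JSON
#'
#' @param graph A [vessel_graph()].
#' @param path File path.
#' @return `read_graph_json` returns the [vessel_graph()]; `write_graph_json`
#'   returns `path` invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "vessel_graph"))
  obj <- list(resolution = graph$resolution, nodes = graph$nodes,
              edges = graph$edges,
              paths = lapply(graph$paths, function(p) unclass(p)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  paths <- lapply(obj$paths, function(p) {
    if (is.null(p) || length(p) == 0) matrix(integer(0), 0, 2)
    else matrix(as.integer(p), ncol = 2)
  })
  nodes <- as.data.frame(obj$nodes)
  edges <- as.data.frame(obj$edges)
  if (nrow(edges) == 0)
    edges <- data.frame(from = integer(0), to = integer(0),
                        radius = numeric(0), length = numeric(0))
  vessel_graph(nodes, edges, paths, obj$resolution)
}
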