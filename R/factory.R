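#' Phase III: running the factory
#'
#' Once flow is solved, every vessel delivers nutrient N and removes product
#' X through its wall along its length; producer cells convert N to X with
#' Michaelis-Menten kinetics under product inhibition; both solutes diffuse.
#' The simulation runs to a steady throughput and then integrates removed
#' product over a production window.
#'
#' @name factory
NULL

#' Vessel-wall nutrient delivery rate
#'
#' `rho_n * 2 pi r * |Q| / (k_out + |Q|) * k_l / (k_l + N)`, per unit vessel
#' length (pg/(um s)). Delivery saturates with flow and *increases* as the
#' local nutrient is depleted. Vectorized.
#'
#' @param Q Vessel flow rate, um^3/s (absolute value is used).
#' @param r Vessel radius, um.
#' @param N_local Nutrient concentration in the vessel's microenvironment.
#' @param p `factory` section of a `sim_config`.
#' @return Delivery rate per unit length, pg/(um s).
#' @export
nutrient_delivery_rate <- function(Q, r, N_local, p) {
  q <- abs(Q)
  p$rho_n * 2 * pi * r * q / (p$k_out + q) * p$k_l / (p$k_l + N_local)
}

#' Producer synthesis rate
#'
#' `mu_p * N / (N + k_p) * k_i / (X + k_i) * M_p` per producer cell (pg/s):
#' Michaelis-Menten in nutrient, multiplicatively inhibited by accumulated
#' product. Vectorized.
#'
#' @param N,X Local nutrient and product concentrations.
#' @param p `factory` section of a `sim_config`.
#' @param M_p Producer biomass, pg.
#' @return Production rate, pg/s per cell.
#' @export
production_rate <- function(N, X, p, M_p) {
  p$mu_p * N / (N + p$k_p) * p$k_i / (X + p$k_i) * M_p
}

#' Vessel-wall product uptake rate
#'
#' `rho_p * 2 pi r * |Q| / (k_in + |Q|) * X / (k_p + X)` per unit vessel
#' length (pg/(um s)): removal saturates with flow and increases with local
#' product. Stagnant vessels (`Q = 0`) remove nothing. Vectorized.
#'
#' @inheritParams nutrient_delivery_rate
#' @param X_local Product concentration in the vessel's microenvironment.
#' @return Uptake rate per unit length, pg/(um s).
#' @export
product_uptake_rate <- function(Q, r, X_local, p) {
  q <- abs(Q)
  p$rho_p * 2 * pi * r * q / (p$k_in + q) * X_local / (p$k_p + X_local)
}

#' Producer nutrient consumption rate
#'
#' Same saturation and inhibition structure as [production_rate()] but at
#' rate `mu_n`: consumption tracks production with ratio `mu_n / mu_p`.
#'
#' @inheritParams production_rate
#' @return Consumption rate, pg/s per cell.
#' @export
nutrient_consumption_rate <- function(N, X, p, M_p) {
  p$mu_n * N / (N + p$k_p) * p$k_i / (p$k_i + X) * M_p
}

# pixel coverage (0-based linear indices, i + j*nr) of each cell in `rows`
cell_pixel_indices <- function(cells, rows, nr, nc, h) {
  lapply(rows, function(k) {
    x <- cells$x[k]; y <- cells$y[k]; r <- cells$radius[k]
    j0 <- max(floor((x - r) / h - 0.5), 0); j1 <- min(ceiling((x + r) / h - 0.5), nc - 1)
    i0 <- max(floor((y - r) / h - 0.5), 0); i1 <- min(ceiling((y + r) / h - 0.5), nr - 1)
    jj <- rep(j0:j1, each = i1 - i0 + 1)
    ii <- rep(i0:i1, times = j1 - j0 + 1)
    keep <- ((jj + 0.5) * h - x)^2 + ((ii + 0.5) * h - y)^2 <= r^2
    idx <- ii[keep] + jj[keep] * nr
    if (length(idx) == 0) {
      j <- min(max(floor(x / h), 0), nc - 1); i <- min(max(floor(y / h), 0), nr - 1)
      idx <- i + j * nr
    }
    as.integer(idx)
  })
}

# 1-pixel-radius neighborhood (union) of a set of path pixels, 0-based linear
path_neighborhood <- function(idx, nr, nc) {
  i <- idx %% nr; j <- idx %/% nr
  out <- integer(0)
  for (di in -1:1) for (dj in -1:1) {
    ii <- i + di; jj <- j + dj
    ok <- ii >= 0 & ii < nr & jj >= 0 & jj < nc
    out <- c(out, ii[ok] + jj[ok] * nr)
  }
  unique(out)
}

# assemble the per-edge exchange structures for the factory stepper; the two
# circulatory columns always exchange (single-pipe Poiseuille flow along the
# column), and the extracted network's edges add to that.
factory_exchange <- function(graph, flow_solution, config, nr, nc) {
  h <- config$domain$resolution
  W <- config$domain$width; H <- config$domain$height
  r_col <- config$cells$radius
  paths <- list(); nbhd <- list()
  Q <- numeric(0); rad <- numeric(0); len <- numeric(0); lab <- character(0)
  if (config$cells$n_circulatory > 0) {
    jL <- max(1L, as.integer(ceiling(r_col / h)))
    jR <- nc - jL + 1L
    Q_col <- edge_conductance(r_col, H, config$flow$eta) * config$flow$delta_P
    rows <- 0:(nr - 1)
    for (j in c(jL, jR)) {
      idx <- as.integer(rows + (j - 1L) * nr)
      paths[[length(paths) + 1L]] <- idx
      nbhd[[length(nbhd) + 1L]] <- path_neighborhood(idx, nr, nc)
      Q <- c(Q, Q_col); rad <- c(rad, r_col); len <- c(len, H)
      lab <- c(lab, if (j == jL) "column_source" else "column_sink")
    }
  }
  if (!is.null(graph) && !is.null(flow_solution) && nrow(graph$edges) > 0) {
    for (e in seq_len(nrow(graph$edges))) {
      p <- graph$paths[[e]]
      if (nrow(p) == 0) next                      # virtual terminal edges
      if (flow_solution$flows[e] == 0) next       # stagnant: no exchange
      idx <- as.integer((p[, 1] - 1L) + (p[, 2] - 1L) * nr)
      paths[[length(paths) + 1L]] <- idx
      nbhd[[length(nbhd) + 1L]] <- path_neighborhood(idx, nr, nc)
      Q <- c(Q, abs(flow_solution$flows[e]))
      rad <- c(rad, graph$edges$radius[e])
      len <- c(len, graph$edges$length[e])
      lab <- c(lab, paste0("edge_", e))
    }
  }
  list(paths = paths, nbhd = nbhd, Q = Q, radius = rad, length = len,
       labels = lab)
}

#' Run the factory to steady state
#'
#' Starting from zero N and X fields, repeatedly: deliver nutrient along
#' each flowing vessel (Hill-limited by flow, inhibited by local N), remove
#' product along each vessel (clipped so X stays non-negative), apply
#' producer synthesis and consumption, and diffuse both fields with `D_p`.
#' Throughput (product mass removed per unit time) is monitored over
#' `steady_window`-second blocks; the run is steady when its relative change
#' stays below `steady_tol` for two consecutive blocks. After steady state
#' the run continues for `production_window` seconds, over which the removed
#' product is integrated. Deterministic.
#'
#' @param cells Cell data frame (Phase I output or initial state).
#' @param graph A [vessel_graph()] with terminals, or `NULL` for a factory
#'   with no vascular network (circulatory columns only).
#' @param flow_solution Matching `flow_solution`, or `NULL`.
#' @param config A `sim_config`.
#' @param verbose Print progress to stderr.
#' @return A `factory_state`: fields `field_N`, `field_X` ([solute_field()]),
#'   `t` (s), per-exchange-edge `delivered` and `removed` (pg, named),
#'   `produced`, `consumed` (pg), `producer_active` (logical per producer),
#'   `active_fraction`, `throughput_rate` (ug/h), `steady`, `steady_time`,
#'   `rate_series` (ug/h per block), `post_rates` (ug/h per block after
#'   steady), `block_dt` (s) and `production_window` (s).
#' @export
run_factory <- function(cells, graph, flow_solution, config, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  check_cells(cells)
  fa <- config$factory
  h <- config$domain$resolution
  W <- config$domain$width; H <- config$domain$height
  nr <- as.integer(round(H / h)); nc <- as.integer(round(W / h))
  D <- fa$D_p_um2; dt <- fa$dt
  if (dt > h^2 / (4 * D) * (1 + 1e-12))
    stop("factory dt violates the explicit diffusion stability bound",
         call. = FALSE)

  ex <- factory_exchange(graph, flow_solution, config, nr, nc)
  prod_rows <- which(cells$kind == "PRODUCER")
  prod_px <- cell_pixel_indices(cells, prod_rows, nr, nc, h)
  M_p <- config$cells$biomass_producer

  N <- matrix(0, nr, nc); X <- matrix(0, nr, nc)
  delivered <- stats::setNames(rep(0, length(ex$paths)), ex$labels)
  removed <- delivered
  produced <- 0; consumed <- 0
  block_steps <- max(1L, as.integer(round(fa$steady_window / dt)))
  block_dt <- block_steps * dt
  to_ugh <- 3600 / 1e6                         # pg/s -> ug/h

  rate_series <- numeric(0)
  steady <- FALSE; steady_time <- NA_real_
  t <- 0
  stable_blocks <- 0L
  while (t < fa$max_time) {
    res <- cpp_factory_run(N, X, ex$paths, ex$nbhd, ex$Q, ex$radius, ex$length,
                           prod_px, fa$rho_n, fa$rho_p, fa$k_out, fa$k_in,
                           fa$k_l, fa$mu_p, fa$mu_n, fa$k_p, fa$k_i, M_p,
                           D, dt, h, block_steps, block_steps,
                           delivered, removed, produced, consumed)
    N <- res$N; X <- res$X
    delivered <- stats::setNames(res$delivered, ex$labels)
    removed <- stats::setNames(res$removed, ex$labels)
    produced <- res$produced; consumed <- res$consumed
    t <- t + block_dt
    rate <- res$rate_series[length(res$rate_series)]
    rate_series <- c(rate_series, rate)
    nrec <- length(rate_series)
    if (nrec >= 2) {
      prev <- rate_series[nrec - 1]
      rel <- abs(rate - prev) / max(abs(rate), abs(prev), 1e-12)
      stable_blocks <- if (rel < fa$steady_tol) stable_blocks + 1L else 0L
      if (stable_blocks >= 2L) { steady <- TRUE; steady_time <- t; break }
    }
    if (verbose && nrec %% 5 == 0)
      message(sprintf("  factory t = %.0f s: throughput %.4g ug/h",
                      t, rate * to_ugh))
  }
  if (!steady)
    warning("factory did not reach steady state within max_time; returning partial result",
            call. = FALSE)

  # production window at steady state
  post_rates <- numeric(0)
  if (steady && length(ex$paths) > 0) {
    win_steps <- as.integer(round(fa$production_window / dt))
    nblk <- max(1L, as.integer(ceiling(win_steps / block_steps)))
    res <- cpp_factory_run(N, X, ex$paths, ex$nbhd, ex$Q, ex$radius, ex$length,
                           prod_px, fa$rho_n, fa$rho_p, fa$k_out, fa$k_in,
                           fa$k_l, fa$mu_p, fa$mu_n, fa$k_p, fa$k_i, M_p,
                           D, dt, h, nblk * block_steps, block_steps,
                           delivered, removed, produced, consumed)
    N <- res$N; X <- res$X
    delivered <- stats::setNames(res$delivered, ex$labels)
    removed <- stats::setNames(res$removed, ex$labels)
    produced <- res$produced; consumed <- res$consumed
    t <- t + nblk * block_dt
    post_rates <- res$rate_series
  }

  Nloc <- vapply(prod_px, function(ix) mean(N[ix + 1L]), numeric(1))
  active <- Nloc > fa$activation_threshold
  cells$active[prod_rows] <- active

  throughput <- if (length(post_rates) > 0) mean(post_rates) * to_ugh
                else if (length(rate_series) > 0) rate_series[length(rate_series)] * to_ugh
                else 0

  structure(list(
    field_N = solute_field(N, h, "N"), field_X = solute_field(X, h, "X"),
    cells = cells, t = t,
    delivered = delivered, removed = removed,
    produced = produced, consumed = consumed,
    producer_active = active,
    active_fraction = if (length(active) > 0) mean(active) else NA_real_,
    throughput_rate = throughput,
    steady = steady, steady_time = steady_time,
    rate_series = rate_series * to_ugh,
    post_rates = post_rates * to_ugh,
    block_dt = block_dt,
    production_window = fa$production_window
  ), class = "factory_state")
}

#' @export
print.factory_state <- function(x, ...) {
  cat(sprintf("<factory_state> t = %.0f s (%s), throughput %.4g ug/h, active fraction %.2f\n",
              x$t, if (x$steady) "steady" else "not steady",
              x$throughput_rate, x$active_fraction))
  invisible(x)
}

#' Steady-state throughput over a trailing window
#'
#' Mean product-removal rate (ug/h) over the trailing `window` seconds of the
#' post-steady production run, i.e. total removed mass in the window divided
#' by the window. Requires steady state. The per-volume variant divides by
#' domain area times a slab depth of one cell diameter (the 2D-to-3D
#' reporting convention).
#'
#' @param state A `factory_state` from [run_factory()].
#' @param window Averaging window in seconds (defaults to the state's
#'   production window). Must not exceed the integrated window.
#' @param per_volume Report ug/h per um^3 of culture instead of ug/h.
#' @param config Required when `per_volume = TRUE`.
#' @return Throughput in ug/h (or ug/h/um^3).
#' @export
compute_throughput <- function(state, window = state$production_window,
                               per_volume = FALSE, config = NULL) {
  stopifnot(inherits(state, "factory_state"))
  if (!state$steady)
    stop("throughput is defined at steady state only", call. = FALSE)
  nblk <- length(state$post_rates)
  if (nblk == 0) return(0)
  use <- min(nblk, max(1L, as.integer(round(window / state$block_dt))))
  tp <- mean(state$post_rates[(nblk - use + 1L):nblk])
  if (per_volume) {
    stopifnot(!is.null(config))
    depth <- 2 * config$cells$radius
    tp <- tp / (config$domain$width * config$domain$height * depth)
  }
  tp
}

#' Throughput of the factory without a vascular network
#'
#' Runs the factory with `vascular_fraction = 0`: all interior cells are
#' producers and only the two circulatory columns exchange nutrient and
#' product (single-pipe Poiseuille flow along each column). Nutrient then
#' penetrates only a diffusion boundary layer next to the columns, so interior
#' producers starve; this is the denominator of relative productivity.
#'
#' @param config A `sim_config`.
#' @param seed Seed for the (producer) placement; defaults to `config$seed`.
#' @param verbose Print progress.
#' @return A list with `throughput` (ug/h) and the `factory_state`.
#' @export
baseline_throughput <- function(config, seed = config$seed, verbose = FALSE) {
  cfg0 <- unclass(config)
  cfg0$cells$vascular_fraction <- 0
  cfg0 <- as_sim_config(cfg0)
  cells <- make_initial_state(cfg0, seed)
  state <- run_factory(cells, NULL, NULL, cfg0, verbose = verbose)
  tp <- if (state$steady) compute_throughput(state) else state$throughput_rate
  list(throughput = tp, state = state)
}
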