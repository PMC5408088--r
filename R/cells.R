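#' Cell populations
#'
#' Cells are off-lattice circular particles stored as a data frame with one
#' row per cell and columns `id` (integer), `kind` (one of `"VASCULAR"`,
#' `"CIRC_SOURCE"`, `"CIRC_SINK"`, `"PRODUCER"`), continuous positions `x`,
#' `y` in um inside the half-open domain `[0, W) x [0, H)`, `radius` um,
#' `biomass` pg and `active` (producers only; `FALSE` until the factory
#' runs). Circulatory cells are immobile; only vascular cells receive
#' chemotactic and adhesive forces.
#'
#' @name cells
NULL

CELL_KINDS <- c("VASCULAR", "CIRC_SOURCE", "CIRC_SINK", "PRODUCER")

#' Construct the initial random cell arrangement
#'
#' Places the two fixed circulatory columns (left = sources, right = sinks,
#' `n_circulatory / 2` cells each, evenly spaced over the full height, one
#' cell diameter wide) and scatters `n_interior` cells uniformly at random
#' strictly between the columns, each vascular with probability
#' `vascular_fraction` and a producer otherwise. Initial overlaps are left to
#' the shoving relaxation of Phase I. The result is a pure function of
#' `(config, seed)`.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A cell data frame (see [cells]).
#' @export
make_initial_state <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  W <- config$domain$width; H <- config$domain$height
  r <- config$cells$radius
  n_circ <- config$cells$n_circulatory
  n_int <- config$cells$n_interior
  frac <- config$cells$vascular_fraction
  # close-packing guard for the interior seeding region
  interior_area <- (W - 4 * r) * H
  if (n_int * pi * r^2 > 0.9069 * interior_area)
    stop("requested cell density exceeds close packing of the interior region",
         call. = FALSE)

  per_col <- n_circ / 2
  ys <- if (per_col > 0) (seq_len(per_col) - 0.5) * H / per_col else numeric(0)
  circ <- data.frame(
    kind = rep(c("CIRC_SOURCE", "CIRC_SINK"), each = per_col),
    x = c(rep(r, per_col), rep(W - r, per_col)),
    y = c(ys, ys),
    stringsAsFactors = FALSE
  )

  set.seed(seed)
  x <- stats::runif(n_int, min = 2 * r, max = W - 2 * r)
  y <- stats::runif(n_int, min = 0, max = H)
  vasc <- stats::runif(n_int) < frac
  interior <- data.frame(
    kind = ifelse(vasc, "VASCULAR", "PRODUCER"),
    x = x, y = y, stringsAsFactors = FALSE
  )

  cells <- rbind(circ, interior)
  cells$id <- seq_len(nrow(cells))
  cells$radius <- r
  cells$biomass <- ifelse(cells$kind == "PRODUCER",
                          config$cells$biomass_producer,
                   ifelse(cells$kind == "VASCULAR",
                          config$cells$biomass_vascular,
                          config$cells$biomass_circulatory))
  cells$active <- FALSE
  cells[, c("id", "kind", "x", "y", "radius", "biomass", "active")]
}

check_cells <- function(cells) {
  need <- c("id", "kind", "x", "y", "radius", "biomass")
  if (!is.data.frame(cells) || !all(need %in% names(cells)))
    stop("cells must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(cells$kind %in% CELL_KINDS))
    stop("unknown cell kind(s): ",
         paste(setdiff(unique(cells$kind), CELL_KINDS), collapse = ", "),
         call. = FALSE)
  invisible(cells)
}

#' Rasterize particles to a binary mask
#'
#' A pixel is foreground iff its center lies within one radius of any cell of
#' a selected kind. The union of disks is taken, so overlaps are not double
#' counted. An empty selection gives an all-false mask.
#'
#' @param cells Cell data frame.
#' @param kinds Character vector of cell kinds to include.
#' @param resolution Grid spacing in um.
#' @param width,height Domain extent in um.
#' @return A [binary_mask()].
#' @export
rasterize_particles <- function(cells, kinds, resolution, width, height) {
  check_cells(cells)
  stopifnot(resolution > 0)
  nr <- as.integer(round(height / resolution))
  nc <- as.integer(round(width / resolution))
  sel <- cells$kind %in% kinds
  m <- cpp_rasterize(cells$x[sel], cells$y[sel], cells$radius[sel],
                     nr, nc, resolution)
  binary_mask(m, resolution)
}

#' Write / read cells as CSV
#'
#' @param cells Cell data frame.
#' @param path File path.
#' @return `read_cells` returns the cell data frame; `write_cells` returns
#'   `path` invisibly.
#' @export
write_cells <- function(cells, path) {
  check_cells(cells)
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cells(cells)
  cells
}
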