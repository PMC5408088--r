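#' Synthetic fixtures: phantom masks and lattice pipe networks
#'
#' Deterministic inputs with known topology and closed-form flow, used by the
#' extraction and flow tests and available for experimentation.
#'
#' @name phantoms
NULL

#' Phantom binary masks with known topology
#'
#' \describe{
#'   \item{strip}{a horizontal bar: 1 component, 0 holes.}
#'   \item{cross}{a plus sign: 1 component, 0 holes, one 4-way junction.}
#'   \item{ring}{an annulus: 1 component, 1 hole.}
#'   \item{lattice}{a `k x k` grid of bars: 1 component, `(k-1)^2` holes.}
#' }
#'
#' @param shape One of `"strip"`, `"cross"`, `"ring"`, `"lattice"`.
#' @param size Mask side length in pixels (square).
#' @param thickness Bar thickness in pixels.
#' @param k Number of bars per direction for `"lattice"`.
#' @param resolution um per pixel.
#' @return A [binary_mask()].
#' @export
make_phantom_mask <- function(shape = c("strip", "cross", "ring", "lattice"),
                              size = 64, thickness = 5, k = 3, resolution = 1) {
  shape <- match.arg(shape)
  stopifnot(size >= 4 * thickness)
  m <- matrix(FALSE, size, size)
  mid <- size / 2
  half <- thickness / 2
  band <- function(c0) {
    lo <- max(1L, as.integer(ceiling(c0 - half)))
    hi <- min(size, as.integer(floor(c0 + half)))
    lo:hi
  }
  margin <- as.integer(ceiling(thickness))
  run <- margin:(size - margin)
  if (shape == "strip") {
    m[band(mid), run] <- TRUE
  } else if (shape == "cross") {
    m[band(mid), run] <- TRUE
    m[run, band(mid)] <- TRUE
  } else if (shape == "ring") {
    R <- size / 2 - margin
    ii <- matrix(seq_len(size) - 0.5, size, size)
    jj <- t(ii)
    d <- sqrt((ii - mid)^2 + (jj - mid)^2)
    m[d >= R - half & d <= R + half] <- TRUE
  } else {
    pos <- seq(margin + half, size - margin - half, length.out = k)
    for (p in pos) {
      m[band(p), run] <- TRUE
      m[run, band(p)] <- TRUE
    }
  }
  binary_mask(m, resolution)
}

#' Regular lattice pipe network
#'
#' A `rows x cols` grid of nodes at spacing `pitch`, joined by identical
#' pipes of the given radius. Nodes of the left column are SOURCE nodes and
#' nodes of the right column SINK nodes (all pinned by the solver), so small
#' cases have exact series/parallel closed forms.
#'
#' @param rows,cols Grid dimensions (>= 1; `cols >= 2` for a usable network).
#' @param radius Pipe radius, um.
#' @param pitch Node spacing (= pipe length), um.
#' @return A [vessel_graph()].
#' @export
make_lattice_graph <- function(rows, cols, radius = 3, pitch = 20) {
  stopifnot(rows >= 1, cols >= 1)
  id <- matrix(seq_len(rows * cols), rows, cols)
  nodes <- data.frame(
    id = as.integer(id),
    x = as.numeric((col(id) - 1) * pitch),
    y = as.numeric((row(id) - 1) * pitch),
    kind = "INTERIOR", stringsAsFactors = FALSE
  )
  nodes$kind[nodes$x == 0] <- "SOURCE"
  nodes$kind[nodes$x == (cols - 1) * pitch] <- "SINK"
  from <- integer(0); to <- integer(0)
  if (cols > 1)
    for (j in 1:(cols - 1)) { from <- c(from, id[, j]); to <- c(to, id[, j + 1]) }
  if (rows > 1)
    for (i in 1:(rows - 1)) { from <- c(from, id[i, ]); to <- c(to, id[i + 1, ]) }
  edges <- data.frame(from = from, to = to, radius = radius, length = pitch)
  vessel_graph(nodes, edges, resolution = 1)
}
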