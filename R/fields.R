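#' Scalar concentration fields on the simulation grid
#'
#' A `solute_field` holds a non-negative 2D concentration array on the regular
#' grid shared by all modules: row `i` is the y index with row 1 at the bottom
#' of the domain, column `j` the x index, and the center of pixel `(i, j)`
#' sits at `((j - 0.5) h, (i - 0.5) h)` micrometres. Concentrations are areal
#' (pg/um^2). All four domain edges are zero-flux.
#'
#' @param values Numeric matrix of concentrations (non-negative).
#' @param resolution Grid spacing `h` in um.
#' @param name Field label (e.g. `"N"`, `"X"`, `"C_short"`).
#' @return A `solute_field`.
#' @export
solute_field <- function(values, resolution, name = "field") {
  stopifnot(is.matrix(values), is.numeric(values), resolution > 0)
  if (any(values < 0)) stop("solute_field values must be non-negative", call. = FALSE)
  structure(list(name = name, values = values, resolution = resolution),
            class = "solute_field")
}

#' Create an all-zero field for a domain
#'
#' @param width,height Domain extent in um.
#' @param resolution Grid spacing in um.
#' @param name Field label.
#' @return A `solute_field` of zeros with `round(height/h)` rows and
#'   `round(width/h)` columns.
#' @export
empty_field <- function(width, height, resolution, name = "field") {
  nr <- as.integer(round(height / resolution))
  nc <- as.integer(round(width / resolution))
  solute_field(matrix(0, nr, nc), resolution, name)
}

#' One explicit diffusion-decay-source step
#'
#' Advances a field by one forward-Euler step of the reaction-diffusion
#' equation dC/dt = D lap(C) + S - beta C. Diffusion uses the 5-point
#' Laplacian with zero-flux (mirror) borders and must respect the explicit
#' stability bound `dt <= h^2 / (4 D)` (checked). Decay is applied as an
#' exact exponential factor, which is unconditionally stable and
#' sign-preserving, so fields stay non-negative for any admissible `dt`.
#' With `decay = 0` and `source = 0` total mass is conserved to floating
#' point.
#'
#' @param field A `solute_field`.
#' @param source Per-pixel source rate (concentration per second): a matrix
#'   of the field's dimensions, or a single number recycled everywhere.
#' @param decay First-order decay rate beta (1/s), `>= 0`.
#' @param D Diffusion coefficient in um^2/s.
#' @param dt Time step in seconds.
#' @return The advanced `solute_field`.
#' @export
step_solute <- function(field, source = 0, decay = 0, D = 0, dt = 1) {
  stopifnot(inherits(field, "solute_field"))
  h <- field$resolution
  if (D < 0 || decay < 0 || dt <= 0) stop("D, decay must be >= 0 and dt > 0", call. = FALSE)
  if (D > 0 && dt > h^2 / (4 * D) * (1 + 1e-12))
    stop(sprintf("explicit stability bound violated: dt = %g > h^2/(4D) = %g",
                 dt, h^2 / (4 * D)), call. = FALSE)
  S <- as_source_matrix(source, field)
  field$values <- cpp_step_solute(field$values, S, D, decay, dt, h)
  field
}

as_source_matrix <- function(source, field) {
  v <- field$values
  if (is.matrix(source)) {
    if (!all(dim(source) == dim(v)))
      stop("source matrix dimensions must match the field", call. = FALSE)
    source
  } else if (length(source) == 1) {
    matrix(as.numeric(source), nrow(v), ncol(v))
  } else stop("source must be a matrix or a scalar", call. = FALSE)
}

# relax a field to quasi-steady state (warm start); internal
relax_solute <- function(field, source, decay, D, dt, max_iters, tol) {
  S <- as_source_matrix(source, field)
  res <- cpp_relax_solute(field$values, S, D, decay, dt, field$resolution,
                          as.integer(max_iters), tol)
  field$values <- res$field
  attr(field, "relax_iters") <- res$iters
  attr(field, "rel_change") <- res$rel_change
  field
}

#' Total solute mass in a field
#'
#' Sum of concentrations times pixel area, in pg.
#' @param field A `solute_field`.
#' @return Scalar mass in pg.
#' @export
field_mass <- function(field) {
  sum(field$values) * field$resolution^2
}

#' Binary masks on the simulation grid
#'
#' Same grid convention as [solute_field()], but logical values.
#'
#' @param values Logical matrix.
#' @param resolution Grid spacing in um.
#' @return A `binary_mask`.
#' @export
binary_mask <- function(values, resolution) {
  stopifnot(is.matrix(values), is.logical(values), resolution > 0)
  structure(list(values = values, resolution = resolution), class = "binary_mask")
}

#' @export
print.solute_field <- function(x, ...) {
  cat(sprintf("<solute_field '%s'> %d x %d px at %g um/px, total mass %.4g pg\n",
              x$name, nrow(x$values), ncol(x$values), x$resolution, field_mass(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px at %g um/px, %d foreground px\n",
              nrow(x$values), ncol(x$values), x$resolution, sum(x$values)))
  invisible(x)
}
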