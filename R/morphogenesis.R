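#' Phase I: self-organization of the vascular network
#'
#' Vascular and circulatory cells secrete diffusible chemoattractants
#' (Monod-limited secretion, first-order decay); vascular cells move uphill
#' along sampled gradients with a saturating response, adhere to each other,
#' and are kept from overlapping by a shoving relaxation. The loop interleaves
#' quasi-steady relaxation of the chemoattractant fields with mechanical
#' steps (operator splitting), mirroring individual-based biofilm
#' frameworks, until motion and fields settle or `max_steps` is reached.
#'
#' @name morphogenesis
NULL

#' Chemoattractant secretion rate of a cell
#'
#' Monod-limited secretion: `mu_c * N_c / (N_c + k) * biomass`, in pg/s per
#' cell. The substrate `N_c` is held constant (non-depleting). Producers do
#' not secrete chemoattractant and are an error here.
#'
#' @param kind Cell kind string.
#' @param biomass Cell biomass in pg.
#' @param N_c Secretion-substrate concentration (>= 0).
#' @param chemo `chemo` section of a `sim_config`.
#' @return Secretion rate in pg/s.
#' @export
secretion_rate <- function(kind, biomass, N_c, chemo) {
  if (any(kind == "PRODUCER"))
    stop("producer cells do not secrete chemoattractant", call. = FALSE)
  if (any(N_c < 0)) stop("N_c must be >= 0", call. = FALSE)
  chemo$mu_c * N_c / (N_c + chemo$k) * biomass
}

#' Saturating chemotactic force magnitude
#'
#' The response to concentrations `C+` (ahead) and `C-` (behind) sampled one
#' radius from the cell center along a random unit direction:
#' `F = lambda * (C+ / (1 + beta_sat C+) - C- / (1 + beta_sat C-))`.
#' The force is applied along the sampled direction only when `F > 0`
#' (cells move uphill or not at all).
#'
#' @param C_plus,C_minus Sampled concentrations (>= 0).
#' @param lambda Response magnitude.
#' @param beta_sat Saturation constant of the force law.
#' @return Signed force magnitude (callers apply it only when positive).
#' @export
chemotaxis_force_magnitude <- function(C_plus, C_minus, lambda, beta_sat) {
  lambda * (C_plus / (1 + beta_sat * C_plus) - C_minus / (1 + beta_sat * C_minus))
}

#' Chemotactic force on one vascular cell
#'
#' Draws a uniform random unit vector, samples the field one radius ahead and
#' behind the cell (bilinear interpolation, sample points clamped into the
#' domain), and returns `F * c` when the magnitude `F` is positive, otherwise
#' `NULL`.
#'
#' @param cell One-row cell data frame (must be `VASCULAR`).
#' @param field A `solute_field`.
#' @param chemo `chemo` section of a `sim_config`.
#' @return Numeric length-2 force vector, or `NULL` when no force applies.
#' @export
chemotaxis_force <- function(cell, field, chemo) {
  if (cell$kind != "VASCULAR")
    stop("only vascular cells respond to chemoattractant", call. = FALSE)
  theta <- stats::runif(1, 0, 2 * pi)
  cvec <- c(cos(theta), sin(theta))
  Cp <- cpp_bilinear(field$values, cell$x + cell$radius * cvec[1],
                     cell$y + cell$radius * cvec[2], field$resolution)
  Cm <- cpp_bilinear(field$values, cell$x - cell$radius * cvec[1],
                     cell$y - cell$radius * cvec[2], field$resolution)
  f <- chemotaxis_force_magnitude(Cp, Cm, chemo$lambda, chemo$beta_sat)
  if (f > 0) f * cvec else NULL
}

#' Homotypic adhesion force between two vascular cells
#'
#' For a surface gap `g = |a - b| - (r_a + r_b)` in `(0, adhesion_range]` the
#' force on `a` is attractive along `b - a` with magnitude
#' `adhesion_strength * (1 - g / adhesion_range)`; zero otherwise. The force
#' is pairwise antisymmetric.
#'
#' @param cell_a,cell_b One-row cell data frames (both `VASCULAR`).
#' @param chemo `chemo` section of a `sim_config`.
#' @return Length-2 force vector acting on `cell_a`.
#' @export
adhesion_force <- function(cell_a, cell_b, chemo) {
  if (cell_a$kind != "VASCULAR" || cell_b$kind != "VASCULAR")
    stop("adhesion is modeled between vascular cells only", call. = FALSE)
  d <- c(cell_b$x - cell_a$x, cell_b$y - cell_a$y)
  dist <- sqrt(sum(d^2))
  g <- dist - (cell_a$radius + cell_b$radius)
  if (g <= 0 || g > chemo$adhesion_range || dist == 0) return(c(0, 0))
  chemo$adhesion_strength * (1 - g / chemo$adhesion_range) * d / dist
}

#' Shoving relaxation of overlapping cells
#'
#' Iteratively displaces each overlapping pair half the overlap apart along
#' their separation axis (circulatory cells are immovable; their partner
#' takes the full overlap), clamping positions into the domain, until no
#' overlap exceeds `tol_overlap` or `max_iters` passes have run
#' (non-convergence is a warning, not an error).
#'
#' @param cells Cell data frame.
#' @param width,height Domain extent in um.
#' @param tol_overlap Largest overlap tolerated, um.
#' @param max_iters Maximum number of relaxation passes.
#' @return List with the relaxed `cells` and `max_displacement` (um), the
#'   largest single-cell displacement of the final pass.
#' @export
relax_shoving <- function(cells, width, height, tol_overlap = 0.05,
                          max_iters = 200) {
  check_cells(cells)
  movable <- !(cells$kind %in% c("CIRC_SOURCE", "CIRC_SINK"))
  res <- cpp_relax_shoving(cells$x, cells$y, cells$radius, movable,
                           tol_overlap, as.integer(max_iters), width, height)
  if (!res$converged)
    warning("shoving did not fully relax in ", max_iters, " passes",
            call. = FALSE)
  cells$x <- res$x
  cells$y <- res$y
  list(cells = cells, max_displacement = res$max_displacement)
}

# sum values into an accumulator of length n at the given indices
scatter_add <- function(values, idx, n) {
  out <- numeric(n)
  s <- rowsum(values, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# secretion source field for a set of cells (pg/s deposited over each cell's
# covered pixels, divided by covered area)
secretion_source <- function(cells, sel, chemo, nr, nc, h) {
  base <- matrix(0, nr, nc)
  if (!any(sel)) return(base)
  rate <- secretion_rate(cells$kind[sel], cells$biomass[sel], chemo$N_c0, chemo)
  cpp_deposit(base, cells$x[sel], cells$y[sel], cells$radius[sel], rate, h)
}

#' Run Phase I to convergence
#'
#' Per mechanical step: (1) both chemoattractant fields (short-range, secreted
#' by vascular cells, decay `beta_v`; long-range, secreted by circulatory
#' cells, decay `beta_c`) are relaxed towards quasi-steady state with a warm
#' start; (2) each vascular cell receives one chemotactic force sample
#' against the summed field, attenuated by the cell's vascular contact count
#' (contact-inhibited chemotaxis: the response is scaled by
#' `max(0, 1 - contacts / contact_inhibition)`, so buried cells stop
#' chemotaxing and aggregates extend rather than round up), plus adhesion
#' forces, integrated into a velocity with memory
#' `v <- persistence * v + mobility * F * dt_mech` and applied as the step
#' displacement, capped at half a radius (with `persistence = 0` this is
#' pure overdamped motion); (3) shoving relaxation resolves overlaps. The loop stops when the
#' largest per-step displacement stays below `eps_move` and the relative
#' field change below `eps_field` for `patience` consecutive steps, or at
#' `max_steps`. Deterministic given `(config, seed)`.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param cells Optional starting cells (defaults to
#'   [make_initial_state()]).
#' @param verbose Print progress lines to stderr.
#' @return A `morphogenesis_state`: list with `cells`, `field_short`,
#'   `field_long`, `steps`, `converged`, `max_displacement_last`.
#' @export
run_morphogenesis <- function(config, seed = config$seed, cells = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  W <- config$domain$width; H <- config$domain$height
  h <- config$domain$resolution
  ch <- config$chemo
  cv <- config$convergence
  if (is.null(cells)) cells <- make_initial_state(config, seed)
  set.seed(seed + 1L)

  nr <- as.integer(round(H / h)); nc <- as.integer(round(W / h))
  f_short <- empty_field(W, H, h, "C_short")
  f_long <- empty_field(W, H, h, "C_long")
  is_vasc <- cells$kind == "VASCULAR"
  is_circ <- cells$kind %in% c("CIRC_SOURCE", "CIRC_SINK")
  movable <- !is_circ
  D <- ch$D_c_um2; dt_s <- ch$dt_solute

  # the circulatory (long-range) field never changes: relax it fully once
  S_long <- secretion_source(cells, is_circ, ch, nr, nc, h)
  f_long <- relax_solute(f_long, S_long, ch$beta_c, D, dt_s,
                         max(ch$relax_max_iters, 20000), cv$eps_field / 10)

  sh <- relax_shoving(cells, W, H, max_iters = 500)
  cells <- sh$cells

  cap <- 0.5 * config$cells$radius
  vx <- numeric(nrow(cells)); vy <- numeric(nrow(cells))
  # persistent adhesion bonds (vascular-vascular and vascular-circulatory):
  # seeded from the initial configuration, extended whenever two adhesive
  # cells come within bond_form, broken only when stretched past bond_break
  use_bonds <- !is.null(ch$bond_form)
  bondable <- is_vasc | is_circ
  bonds <- NULL
  if (use_bonds) {
    bonds <- cpp_pairs_within(cells$x, cells$y, cells$radius, bondable,
                              ch$bond_form, W, H)
    keep <- is_vasc[bonds[, 1]] | is_vasc[bonds[, 2]]
    bonds <- bonds[keep, , drop = FALSE]
  }
  quiet <- 0L
  converged <- FALSE
  step <- 0L
  max_disp <- Inf
  n_v <- sum(is_vasc)

  while (step < cv$max_steps) {
    step <- step + 1L
    # (1) relax the vascular chemoattractant (warm start)
    S_short <- secretion_source(cells, is_vasc, ch, nr, nc, h)
    f_short <- relax_solute(f_short, S_short, ch$beta_v, D, dt_s,
                            ch$relax_max_iters, cv$eps_field)
    field_rel <- attr(f_short, "rel_change")

    # (2) forces on vascular cells
    disp <- 0
    if (n_v > 0 && (ch$lambda > 0 || ch$adhesion_strength > 0)) {
      Ctot <- f_short$values + f_long$values
      Fx <- numeric(nrow(cells)); Fy <- numeric(nrow(cells))
      if (ch$lambda > 0) {
        # one random unit vector per vascular cell per step (id order)
        theta <- stats::runif(n_v, 0, 2 * pi)
        cx <- cos(theta); cy <- sin(theta)
        r <- cells$radius[is_vasc]
        xp <- cells$x[is_vasc] + r * cx; yp <- cells$y[is_vasc] + r * cy
        xm <- cells$x[is_vasc] - r * cx; ym <- cells$y[is_vasc] - r * cy
        Cp <- cpp_bilinear(Ctot, xp, yp, h)
        Cm <- cpp_bilinear(Ctot, xm, ym, h)
        f <- chemotaxis_force_magnitude(Cp, Cm, ch$lambda, ch$beta_sat)
        f[f < 0] <- 0
        if (is.finite(ch$contact_inhibition) || ch$contact_range > 0) {
          # contact-inhibited chemotaxis: protrusive motion happens only on
          # the free surface. A contacting cell may chemotax only along
          # directions pointing away from its contacts (so aggregates extend
          # tendrils instead of rounding up), and the response is attenuated
          # by max(0, 1 - contacts / contact_inhibition).
          cv_ <- cpp_contact_vectors(cells$x, cells$y, cells$radius, is_vasc,
                                     ch$contact_range, W, H)
          k_ <- cv_$count[is_vasc]
          into <- k_ > 0 & (cx * cv_$vx[is_vasc] + cy * cv_$vy[is_vasc]) > 0
          f[into] <- 0
          if (is.finite(ch$contact_inhibition))
            f <- f * pmax(0, 1 - k_ / ch$contact_inhibition)
        }
        Fx[is_vasc] <- f * cx; Fy[is_vasc] <- f * cy
      }
      if (ch$adhesion_strength > 0) {
        if (use_bonds) {
          # update the bond set: drop over-stretched bonds, add new contacts
          dxb <- cells$x[bonds[, 2]] - cells$x[bonds[, 1]]
          dyb <- cells$y[bonds[, 2]] - cells$y[bonds[, 1]]
          db <- sqrt(dxb^2 + dyb^2)
          gb <- db - (cells$radius[bonds[, 1]] + cells$radius[bonds[, 2]])
          bonds <- bonds[gb <= ch$bond_break, , drop = FALSE]
          fresh <- cpp_pairs_within(cells$x, cells$y, cells$radius, bondable,
                                    ch$bond_form, W, H)
          fresh <- fresh[is_vasc[fresh[, 1]] | is_vasc[fresh[, 2]], ,
                         drop = FALSE]
          all_b <- rbind(bonds, fresh)
          key <- (all_b[, 1] - 1) * nrow(cells) + all_b[, 2]
          bonds <- all_b[!duplicated(key), , drop = FALSE]
          # spring pull on stretched bonds
          dxb <- cells$x[bonds[, 2]] - cells$x[bonds[, 1]]
          dyb <- cells$y[bonds[, 2]] - cells$y[bonds[, 1]]
          db <- sqrt(dxb^2 + dyb^2)
          gb <- db - (cells$radius[bonds[, 1]] + cells$radius[bonds[, 2]])
          pull <- gb > 0 & db > 0
          if (any(pull)) {
            # constant-force contraction, ramped over the first micron so the
            # pull vanishes smoothly at contact
            magb <- ch$adhesion_strength * pmin(1, gb[pull])
            fbx <- magb * dxb[pull] / db[pull]
            fby <- magb * dyb[pull] / db[pull]
            i1 <- bonds[pull, 1]; i2 <- bonds[pull, 2]
            n_all <- nrow(cells)
            Fx <- Fx + scatter_add(fbx, i1, n_all) - scatter_add(fbx, i2, n_all)
            Fy <- Fy + scatter_add(fby, i1, n_all) - scatter_add(fby, i2, n_all)
          }
        } else {
          Fa <- cpp_adhesion_forces(cells$x, cells$y, cells$radius, is_vasc,
                                    ch$adhesion_strength, ch$adhesion_range, W, H)
          Fx <- Fx + Fa[, 1]; Fy <- Fy + Fa[, 2]
        }
      }
      # velocity memory: with persistence > 0 cells integrate force impulses
      # into a drift and overshoot local maxima, piling into filaments;
      # persistence = 0 recovers pure overdamped motion
      vx <- ch$persistence * vx + ch$mobility * Fx * config$mech$dt_mech
      vy <- ch$persistence * vy + ch$mobility * Fy * config$mech$dt_mech
      mag <- sqrt(vx^2 + vy^2)
      over <- mag > cap
      if (any(over)) {
        vx[over] <- vx[over] * cap / mag[over]
        vy[over] <- vy[over] * cap / mag[over]
        mag[over] <- cap
      }
      vx[!movable] <- 0; vy[!movable] <- 0
      dx <- vx; dy <- vy
      cells$x <- pmin(pmax(cells$x + dx, 0), W - 1e-6)
      cells$y <- pmin(pmax(cells$y + dy, 0), H - 1e-6)
      disp <- max(mag[movable], 0)
    }

    # (3) shoving
    res <- cpp_relax_shoving(cells$x, cells$y, cells$radius, movable,
                             0.05, 100L, W, H)
    cells$x <- res$x; cells$y <- res$y
    max_disp <- max(disp, res$max_displacement)

    if (verbose && step %% 25 == 0)
      message(sprintf("  morphogenesis step %d: max displacement %.3f um, field change %.2e",
                      step, max_disp, field_rel))

    if (max_disp < cv$eps_move && field_rel < cv$eps_field) {
      quiet <- quiet + 1L
      if (quiet >= cv$patience) { converged <- TRUE; break }
    } else quiet <- 0L
  }
  if (verbose)
    message(sprintf("morphogenesis %s after %d steps (last max displacement %.3f um)",
                    if (converged) "converged" else "stopped", step, max_disp))

  structure(list(cells = cells, field_short = f_short, field_long = f_long,
                 bonds = bonds, steps = step, converged = converged,
                 max_displacement_last = max_disp),
            class = "morphogenesis_state")
}

#' @export
print.morphogenesis_state <- function(x, ...) {
  cat(sprintf("<morphogenesis_state> %d cells, %d steps (%s)\n",
              nrow(x$cells), x$steps,
              if (x$converged) "converged" else "max steps"))
  invisible(x)
}
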