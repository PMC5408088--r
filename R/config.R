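#' Simulation configuration
#'
#' A `sim_config` is a validated, nested list of every parameter the
#' three-phase simulation needs. Internal units are micrometres, seconds,
#' picograms and pascals throughout; concentrations are areal
#' (pg per square micrometre). Diffusion coefficients are *supplied* in SI
#' (m^2/s), as they are usually quoted, and converted to um^2/s on load
#' (1e-13 m^2/s = 0.1 um^2/s).
#'
#' Sections and fields (defaults in parentheses):
#' \describe{
#'   \item{domain}{`height` um (516), `width` um (1028), `resolution` um per
#'     pixel (1).}
#'   \item{cells}{`n_circulatory` (780, split into a left source column and a
#'     right sink column), `n_interior` (24000), `vascular_fraction` (0.30),
#'     `radius` um (2), `biomass_vascular` pg (10), `biomass_producer` pg
#'     (10), `biomass_circulatory` pg (0.5; `NULL` = `biomass_vascular`; sets
#'     the amplitude of the long-range column field through the Monod
#'     secretion term).}
#'   \item{chemo}{`D_c` m^2/s (1e-13); `mu_c` 1/s; `k` and `N_c0`
#'     concentrations for the Monod secretion term; decay rates `beta_v`
#'     (fast, short-range field) and `beta_c` (slow, long-range field) 1/s;
#'     chemotactic magnitude `lambda`; force-law saturation `beta_sat`;
#'     `adhesion_strength` and `adhesion_range` um; `contact_inhibition`
#'     (number of vascular contacts at which the chemotactic response is
#'     fully suppressed; `Inf` disables) and `contact_range` um (0.5;
#'     `NULL` = `adhesion_range`); `persistence` in `[0, 1)`, the per-step velocity
#'     memory of vascular cells (0 = fully overdamped; values near 1 make
#'     cells overshoot and pile into filaments); `bond_form` and `bond_break`
#'     um (8 and `Inf`; `NULL` disables): when set, adhesion acts through
#'     persistent bonds that form when the surface gap of two adhesive cells
#'     drops to `bond_form` and survive until it exceeds `bond_break`
#'     (`Inf` = permanent junctions), pulling with a constant contraction
#'     force `adhesion_strength` (ramped over the final micron before
#'     contact); vascular cells bond to
#'     each other and to circulatory cells (heterotypic anchoring); when
#'     `NULL`, adhesion is the memoryless pairwise law of
#'     [adhesion_force()]; `mobility` (displacement
#'     per unit force per
#'     mechanical step); `dt_solute` s (`NULL` = 90% of the explicit
#'     stability bound); `relax_max_iters`.}
#'   \item{flow}{`delta_P` Pa (1000), `eta` Pa s (8.9e-4, water at 25 C).}
#'   \item{factory}{transfer constants `rho_n`, `rho_p` pg/(um s); flow
#'     half-saturations `k_out`, `k_in` um^3/s; delivery half-saturation
#'     `k_l`; rates `mu_p`, `mu_n` 1/s; Michaelis constant `k_p`; inhibition
#'     constant `k_i`; diffusivity `D_p` m^2/s; `activation_threshold`
#'     (default `k_p/10`); `dt` s (`NULL` = auto); `steady_tol`;
#'     `steady_window` s; `production_window` s (7200); `max_time` s.}
#'   \item{mech}{`dt_mech` s per mechanical step (1).}
#'   \item{convergence}{`eps_move` um (0.05), `eps_field` (5e-3), `patience`
#'     (10), `max_steps` (5000).}
#'   \item{extraction}{`min_spur_length` um (2 x cell radius),
#'     `terminal_band` um (12 = `bond_form` + one cell diameter: a vessel
#'     end within bonding reach of a column is plumbed into the manifold).}
#'   \item{seed}{integer master seed (1).}
#' }
#'
#' @param profile `"full"` for the full-scale study geometry (516 x 1028 um,
#'   24000 interior cells) or `"scaled"` for the desk-scale profile
#'   (258 x 258 um, 3000 interior cells, 390 circulatory cells) used by the
#'   bundled experiments and tests.
#' @return A `sim_config` object.
#' @export
default_config <- function(profile = c("full", "scaled")) {
  profile <- match.arg(profile)
  cfg <- list(
    domain = list(height = 516, width = 1028, resolution = 1),
    cells = list(
      n_circulatory = 780, n_interior = 24000, vascular_fraction = 0.30,
      radius = 2, biomass_vascular = 10, biomass_producer = 10,
      biomass_circulatory = 0.5
    ),
    chemo = list(
      D_c = 1e-13, mu_c = 0.2, k = 1, N_c0 = 1,
      beta_v = 1e-4, beta_c = 2.5e-5,
      lambda = 0.1, beta_sat = 1e-3,
      adhesion_strength = 1, adhesion_range = 2,
      contact_inhibition = 4, contact_range = 0.5,
      persistence = 0,
      bond_form = 8, bond_break = Inf,
      mobility = 1, dt_solute = NULL, relax_max_iters = 2000
    ),
    flow = list(delta_P = 1000, eta = 8.9e-4),
    factory = list(
      rho_n = 0.25, rho_p = 0.25, k_out = 1e4, k_in = 1e4, k_l = 1,
      mu_p = 0.3, mu_n = 1.5, k_p = 5, k_i = 1, D_p = 5e-12,
      activation_threshold = NULL, dt = NULL,
      steady_tol = 0.02, steady_window = 60,
      production_window = 7200, max_time = 7200
    ),
    mech = list(dt_mech = 1),
    convergence = list(eps_move = 0.05, eps_field = 5e-3,
                       patience = 10, max_steps = 5000),
    extraction = list(min_spur_length = NULL, terminal_band = 12),
    seed = 1L
  )
  if (profile == "scaled") {
    cfg$domain$width <- 258
    cfg$domain$height <- 258
    cfg$cells$n_interior <- 3000
    cfg$cells$n_circulatory <- 390
    cfg$convergence$max_steps <- 400
    cfg$factory$production_window <- 240
    cfg$factory$max_time <- 3600
  }
  as_sim_config(cfg)
}

#' @rdname default_config
#' @export
scaled_config <- function() default_config("scaled")

# fill derived defaults, convert SI diffusivities, validate, and class
as_sim_config <- function(cfg) {
  cfg <- fill_config_defaults(cfg)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

fill_config_defaults <- function(cfg) {
  h <- cfg$domain$resolution
  # SI -> internal units for diffusivities (m^2/s -> um^2/s)
  cfg$chemo$D_c_um2 <- cfg$chemo$D_c * 1e12
  cfg$factory$D_p_um2 <- cfg$factory$D_p * 1e12
  if (is.null(cfg$chemo$dt_solute))
    cfg$chemo$dt_solute <- 0.9 * h^2 / (4 * cfg$chemo$D_c_um2)
  if (is.null(cfg$chemo$contact_range))
    cfg$chemo$contact_range <- cfg$chemo$adhesion_range
  if (is.null(cfg$cells$biomass_circulatory))
    cfg$cells$biomass_circulatory <- cfg$cells$biomass_vascular
  if (is.null(cfg$factory$dt))
    cfg$factory$dt <- 0.9 * h^2 / (4 * cfg$factory$D_p_um2)
  if (is.null(cfg$factory$activation_threshold))
    cfg$factory$activation_threshold <- cfg$factory$k_p / 10
  if (is.null(cfg$extraction$min_spur_length))
    cfg$extraction$min_spur_length <- 2 * cfg$cells$radius
  if (is.null(cfg$extraction$terminal_band))
    cfg$extraction$terminal_band <- 4 * cfg$cells$radius
  cfg
}

cfg_fail <- function(field, msg) {
  stop("config field `", field, "`: ", msg, call. = FALSE)
}

validate_config <- function(cfg) {
  dm <- cfg$domain
  if (!is.numeric(dm$height) || dm$height <= 0) cfg_fail("domain.height", "must be > 0")
  if (!is.numeric(dm$width) || dm$width <= 0) cfg_fail("domain.width", "must be > 0")
  if (!is.numeric(dm$resolution) || dm$resolution <= 0)
    cfg_fail("domain.resolution", "must be > 0")
  cl <- cfg$cells
  if (cl$n_circulatory < 0) cfg_fail("cells.n_circulatory", "must be >= 0")
  if (cl$n_circulatory %% 2 != 0)
    cfg_fail("cells.n_circulatory", "must be even (two equal columns)")
  if (cl$n_interior < 0) cfg_fail("cells.n_interior", "must be >= 0")
  if (cl$vascular_fraction < 0 || cl$vascular_fraction > 1)
    cfg_fail("cells.vascular_fraction", "must be in [0, 1]")
  if (cl$radius <= 0) cfg_fail("cells.radius", "must be > 0")
  if (cl$biomass_vascular <= 0) cfg_fail("cells.biomass_vascular", "must be > 0")
  if (cl$biomass_producer <= 0) cfg_fail("cells.biomass_producer", "must be > 0")
  if (cl$biomass_circulatory <= 0)
    cfg_fail("cells.biomass_circulatory", "must be > 0")
  if (dm$resolution > cl$radius)
    cfg_fail("domain.resolution", "must be <= cells.radius (a cell must span at least one pixel)")
  ch <- cfg$chemo
  if (ch$D_c <= 0) cfg_fail("chemo.D_c", "must be > 0")
  if (ch$beta_v <= 0 || ch$beta_c <= 0 || ch$beta_v <= ch$beta_c)
    cfg_fail("chemo.beta_v/beta_c", "need beta_v > beta_c > 0")
  if (ch$lambda < 0) cfg_fail("chemo.lambda", "must be >= 0")
  if (ch$beta_sat < 0) cfg_fail("chemo.beta_sat", "must be >= 0")
  if (ch$mu_c < 0) cfg_fail("chemo.mu_c", "must be >= 0")
  if (ch$k <= 0) cfg_fail("chemo.k", "must be > 0")
  if (ch$N_c0 < 0) cfg_fail("chemo.N_c0", "must be >= 0")
  if (ch$adhesion_strength < 0) cfg_fail("chemo.adhesion_strength", "must be >= 0")
  if (ch$adhesion_range <= 0) cfg_fail("chemo.adhesion_range", "must be > 0")
  if (ch$contact_inhibition <= 0)
    cfg_fail("chemo.contact_inhibition", "must be > 0 (use Inf to disable)")
  if (ch$contact_range < 0) cfg_fail("chemo.contact_range", "must be >= 0")
  if (ch$persistence < 0 || ch$persistence >= 1)
    cfg_fail("chemo.persistence", "must be in [0, 1)")
  if (!is.null(ch$bond_form)) {
    if (ch$bond_form < 0) cfg_fail("chemo.bond_form", "must be >= 0")
    if (is.null(ch$bond_break) || ch$bond_break < ch$bond_form)
      cfg_fail("chemo.bond_break", "must be >= chemo.bond_form")
  }
  if (ch$dt_solute <= 0) cfg_fail("chemo.dt_solute", "must be > 0")
  fl <- cfg$flow
  if (fl$delta_P <= 0) cfg_fail("flow.delta_P", "must be > 0")
  if (fl$eta <= 0) cfg_fail("flow.eta", "must be > 0")
  fa <- cfg$factory
  for (f in c("rho_n", "rho_p", "k_out", "k_in", "k_l", "mu_p", "mu_n",
              "k_p", "k_i", "D_p", "dt", "production_window", "steady_tol",
              "steady_window", "max_time"))
    if (fa[[f]] <= 0) cfg_fail(paste0("factory.", f), "must be > 0")
  if (cfg$mech$dt_mech <= 0) cfg_fail("mech.dt_mech", "must be > 0")
  cv <- cfg$convergence
  for (f in c("eps_move", "eps_field", "patience", "max_steps"))
    if (cv[[f]] <= 0) cfg_fail(paste0("convergence.", f), "must be > 0")
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over the defaults of
#' [default_config()]. The file is a nested document mirroring the
#' `sim_config` sections (`domain`, `cells`, `chemo`, `flow`, `factory`,
#' `mech`, `convergence`, `extraction`, `seed`), plus an optional top-level
#' `profile: scaled` selecting the desk-scale base profile. Unknown keys are
#' an error, so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  profile <- raw$profile %||% "full"
  raw$profile <- NULL
  base <- unclass(default_config(profile))
  # strip derived fields so they are recomputed after the merge
  base$chemo$D_c_um2 <- NULL
  base$factory$D_p_um2 <- NULL
  for (sec in names(raw)) {
    if (sec == "seed") { base$seed <- as.integer(raw$seed); next }
    if (!sec %in% names(base))
      stop("unknown config section `", sec, "`", call. = FALSE)
    if (!is.list(raw[[sec]]))
      stop("config section `", sec, "` must be a mapping", call. = FALSE)
    for (key in names(raw[[sec]])) {
      if (!key %in% names(base[[sec]]))
        stop("unknown config field `", sec, ".", key, "`", call. = FALSE)
      base[[sec]][key] <- list(raw[[sec]][[key]])
    }
  }
  as_sim_config(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  domain: %g x %g um at %g um/px\n",
              x$domain$width, x$domain$height, x$domain$resolution))
  cat(sprintf("  cells: %d interior (vascular fraction %.2f), %d circulatory, radius %g um\n",
              x$cells$n_interior, x$cells$vascular_fraction,
              x$cells$n_circulatory, x$cells$radius))
  cat(sprintf("  flow: delta_P %g Pa, eta %g Pa s\n", x$flow$delta_P, x$flow$eta))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
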