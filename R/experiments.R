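#' Evaluation experiments
#'
#' The three study harnesses: a vascular-fraction sweep (productivity vs the
#' initial vascular/producer ratio), a robustness study (throughput over
#' random seeds at a fixed 30% fraction), and a width-scaling study
#' (per-volume productivity as the circulatory columns are separated). Each
#' run is fully determined by `(config, master seed)`; per-run seeds derive
#' from the master seed by a fixed counter scheme.
#'
#' @name experiments
NULL

#' Derive per-run seeds from a master seed
#'
#' `seed_i = (master mod 2^20) + 7919 * i`: reproducible, collision-free for
#' the experiment sizes used here, and always below 2^31.
#'
#' @param master Master integer seed.
#' @param n Number of seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  as.integer((master %% 2^20) + 7919 * seq_len(n))
}

config_with <- function(config, ...) {
  cfg <- unclass(config)
  mods <- list(...)
  for (nm in names(mods)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg[[parts]] <- mods[[nm]]
  }
  cfg$chemo$D_c_um2 <- NULL
  cfg$factory$D_p_um2 <- NULL
  as_sim_config(cfg)
}

#' Sweep the vascular fraction
#'
#' Runs the full three-phase pipeline for every (fraction, replicate) pair at
#' constant total cell count, plus one zero-vascular baseline per replicate
#' seed, and reports per-run records and per-fraction aggregates. Relative
#' productivity is the run's throughput divided by the baseline throughput of
#' the same seed. Disconnected networks are recorded (`connected = FALSE`),
#' not errors.
#'
#' @param config A `sim_config`.
#' @param fractions Vascular fractions in `[0, 1]`.
#' @param reps Replicates per fraction.
#' @param phases Highest phase to run (2 skips the factory and reports
#'   connectivity only).
#' @param master_seed Master seed (defaults to `config$seed`).
#' @param verbose Print progress.
#' @return A list with `records` (one row per run: `vascular_fraction`,
#'   `width`, `seed`, `connected`, `throughput`, `baseline`,
#'   `relative_productivity`, `active_fraction`, `per_volume_productivity`)
#'   and `summary` (per-fraction mean and sd).
#' @export
sweep_vascular_fraction <- function(config, fractions, reps = 3, phases = 3,
                                    master_seed = config$seed,
                                    verbose = FALSE) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  seeds <- derive_seeds(master_seed, reps)
  depth <- 2 * config$cells$radius
  vol <- config$domain$width * config$domain$height * depth

  baselines <- rep(NA_real_, reps)
  if (phases >= 3) {
    for (i in seq_len(reps)) {
      if (verbose) message(sprintf("baseline rep %d (seed %d)", i, seeds[i]))
      baselines[i] <- baseline_throughput(config, seeds[i])$throughput
    }
  }

  records <- list()
  for (f in fractions) {
    cfg <- config_with(config, cells.vascular_fraction = f)
    for (i in seq_len(reps)) {
      if (verbose)
        message(sprintf("fraction %.2f rep %d (seed %d)", f, i, seeds[i]))
      if (f == 0 && phases >= 3) {
        tp <- baselines[i]
        rec <- data.frame(vascular_fraction = f, width = config$domain$width,
                          seed = seeds[i], connected = FALSE,
                          throughput = tp, baseline = baselines[i],
                          relative_productivity = 1,
                          active_fraction = NA_real_,
                          per_volume_productivity = tp / vol)
      } else {
        res <- run_pipeline(cfg, seeds[i], phases = phases, verbose = FALSE)
        tp <- res$throughput
        rec <- data.frame(
          vascular_fraction = f, width = config$domain$width,
          seed = seeds[i], connected = isTRUE(res$connected),
          throughput = tp, baseline = baselines[i],
          relative_productivity = if (phases >= 3) tp / baselines[i] else NA_real_,
          active_fraction = if (!is.null(res$factory))
            res$factory$active_fraction else NA_real_,
          per_volume_productivity = if (phases >= 3) tp / vol else NA_real_)
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, records)
  agg <- function(v, f) tapply(v, factor(records$vascular_fraction,
                                         levels = unique(fractions)), f)
  summary <- data.frame(
    vascular_fraction = unique(fractions),
    n = as.integer(agg(records$seed, length)),
    connected_runs = as.integer(agg(records$connected, sum)),
    mean_throughput = as.numeric(agg(records$throughput, mean)),
    sd_throughput = as.numeric(agg(records$throughput, stats::sd)),
    mean_relative_productivity =
      as.numeric(agg(records$relative_productivity, mean)),
    mean_active_fraction = as.numeric(agg(records$active_fraction, mean))
  )
  list(records = records, summary = summary)
}

#' Robustness of self-organization over random seeds
#'
#' Runs the fixed-fraction (default 30%) pipeline over `n_seeds` distinct
#' seeds and summarizes the spread of steady-state throughput. Disconnected
#' runs are excluded from the mean/sd/CV and reported separately.
#'
#' @param config A `sim_config`.
#' @param n_seeds Number of seeds (>= 2).
#' @param fraction Vascular fraction to hold fixed.
#' @param master_seed Master seed.
#' @param verbose Print progress.
#' @return List with `throughputs` (connected runs), `mean`, `sd`, `cv`,
#'   `n_connected`, `n_disconnected`, `disconnected_seeds` and the per-run
#'   `records`.
#' @export
robustness_study <- function(config, n_seeds = 10, fraction = 0.30,
                             master_seed = config$seed, verbose = FALSE) {
  stopifnot(n_seeds >= 2)
  cfg <- config_with(config, cells.vascular_fraction = fraction)
  seeds <- derive_seeds(master_seed, n_seeds)
  recs <- list()
  for (i in seq_len(n_seeds)) {
    if (verbose) message(sprintf("robustness run %d/%d (seed %d)",
                                 i, n_seeds, seeds[i]))
    res <- run_pipeline(cfg, seeds[i], phases = 3)
    recs[[i]] <- data.frame(seed = seeds[i], connected = isTRUE(res$connected),
                            throughput = res$throughput)
  }
  records <- do.call(rbind, recs)
  ok <- records$connected
  tps <- records$throughput[ok]
  m <- mean(tps)
  s <- if (length(tps) > 1) stats::sd(tps) else 0
  list(throughputs = tps, mean = m, sd = s,
       cv = if (length(tps) > 1 && m > 0) s / m else NA_real_,
       n_connected = sum(ok), n_disconnected = sum(!ok),
       disconnected_seeds = records$seed[!ok], records = records)
}

#' Width-scaling study
#'
#' Runs the pipeline at fixed height over a set of domain widths and reports
#' per-volume productivity for each, plus the maximum relative spread across
#' widths and whether total throughput grows with width.
#'
#' @param config A `sim_config`. Interior cell count is scaled with width to
#'   keep the areal cell density fixed.
#' @param widths Domain widths in um.
#' @param reps Replicates per width.
#' @param master_seed Master seed.
#' @param verbose Print progress.
#' @return List with `table` (per width: mean throughput, mean per-volume
#'   productivity), `records`, `max_relative_spread` and
#'   `throughput_monotone`.
#' @export
width_scaling_study <- function(config, widths, reps = 3,
                                master_seed = config$seed, verbose = FALSE) {
  stopifnot(all(widths > 0))
  base_density <- config$cells$n_interior /
    ((config$domain$width - 4 * config$cells$radius) * config$domain$height)
  seeds <- derive_seeds(master_seed, reps)
  recs <- list()
  for (w in widths) {
    n_int <- as.integer(round(base_density *
                                (w - 4 * config$cells$radius) *
                                config$domain$height))
    cfg <- config_with(config, domain.width = w, cells.n_interior = n_int)
    depth <- 2 * cfg$cells$radius
    vol <- cfg$domain$width * cfg$domain$height * depth
    for (i in seq_len(reps)) {
      if (verbose) message(sprintf("width %g rep %d (seed %d)", w, i, seeds[i]))
      res <- run_pipeline(cfg, seeds[i], phases = 3)
      recs[[length(recs) + 1L]] <-
        data.frame(width = w, seed = seeds[i], connected = isTRUE(res$connected),
                   throughput = res$throughput,
                   per_volume_productivity = res$throughput / vol)
    }
  }
  records <- do.call(rbind, recs)
  pv <- tapply(records$per_volume_productivity, records$width, mean)
  tp <- tapply(records$throughput, records$width, mean)
  spread <- if (length(pv) > 1) (max(pv) - min(pv)) / mean(pv) else 0
  list(table = data.frame(width = as.numeric(names(pv)),
                          mean_throughput = as.numeric(tp),
                          mean_per_volume = as.numeric(pv)),
       records = records,
       max_relative_spread = spread,
       throughput_monotone = !is.unsorted(as.numeric(tp)))
}
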