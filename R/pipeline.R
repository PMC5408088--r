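#' Run the full three-phase pipeline
#'
#' Phase I (morphogenesis) self-organizes the vascular network, Phase II
#' extracts the pipe graph and solves Poiseuille/Kirchhoff flow, Phase III
#' runs the factory to steady state and measures throughput. When the
#' extracted network does not connect source to sink, the factory still runs
#' with the circulatory columns alone (the network contributes no exchange),
#' mirroring how disconnected runs score at baseline-like levels.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param phases Highest phase to run: 1 (morphogenesis), 2 (+ extraction and
#'   flow) or 3 (+ factory).
#' @param verbose Print per-phase progress lines to stderr.
#' @return A `pipeline_result`: list with `config`, `seed`, `morphogenesis`
#'   (a `morphogenesis_state`), `extraction` (mask/widths/skeleton/graph),
#'   `connected` (logical), `flow` (a `flow_solution` or `NULL`), `factory`
#'   (a `factory_state` or `NULL`) and `throughput` (ug/h or `NA`).
#' @export
run_pipeline <- function(config, seed = config$seed, phases = 3,
                         verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"), phases %in% 1:3)
  if (verbose) message(sprintf("phase I: morphogenesis (seed %d)", seed))
  morph <- run_morphogenesis(config, seed, verbose = verbose)
  out <- list(config = config, seed = seed, morphogenesis = morph,
              extraction = NULL, connected = NA, flow = NULL,
              factory = NULL, throughput = NA_real_)
  class(out) <- "pipeline_result"
  if (phases < 2) return(out)

  if (verbose) message("phase II: extraction and flow")
  ext <- extract_vessel_graph(morph$cells, config, bonds = morph$bonds)
  out$extraction <- ext
  out$connected <- tryCatch(source_sink_connected(ext$graph),
                            error = function(e) FALSE)
  if (out$connected) {
    out$flow <- solve_network_flow(ext$graph, config$flow)
    if (verbose)
      message(sprintf("  connected: %d nodes, %d edges, total flow %.4g um^3/s",
                      nrow(ext$graph$nodes), nrow(ext$graph$edges),
                      out$flow$total_flow))
  } else if (verbose) {
    message("  network does not connect source to sink")
  }
  if (phases < 3) return(out)

  if (verbose) message("phase III: factory")
  out$factory <- run_factory(morph$cells,
                             if (out$connected) ext$graph else NULL,
                             if (out$connected) out$flow else NULL,
                             config, verbose = verbose)
  out$throughput <- if (out$factory$steady) compute_throughput(out$factory)
                    else out$factory$throughput_rate
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d, connected: %s, throughput %.4g ug/h\n",
              x$seed, x$connected, x$throughput))
  invisible(x)
}

#' Write a machine-readable run manifest
#'
#' JSON record of a run: configuration (with a content hash), seed, package
#' version, connectivity and throughput.
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  cfg <- unclass(result$config)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "vascufab",
    version = as.character(utils::packageVersion("vascufab")),
    seed = result$seed,
    config_hash = sum(utf8ToInt(as.character(cfg_json)) *
                        (seq_len(nchar(cfg_json)) %% 97 + 1)) %% 2^31,
    config = cfg,
    connected = result$connected,
    throughput_ug_per_h = result$throughput,
    morphogenesis_steps = result$morphogenesis$steps,
    converged = result$morphogenesis$converged
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a field as CSV
#'
#' Portable plain-text serialization of a [solute_field()] or [binary_mask()]
#' matrix (row 1 = bottom of the domain).
#'
#' @param field A `solute_field` or `binary_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  v <- field$values
  if (is.logical(v)) v <- v * 1L
  utils::write.table(v, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
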