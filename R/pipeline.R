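## Config-driven orchestration: run a list of analysis stages over either a
## synthetic-generator dataset or files on disk, writing CSV/JSON products
## plus a JSON manifest (inputs, parameters, seed, output paths).

.PIPELINE_STAGES <- c("synth_markov", "synth_bd", "synth_isotherm",
                      "rdf", "shell", "isotherm_fit", "kinetics", "shape",
                      "energetics", "clusters", "msd", "affinity", "grid")

#' Validate a pipeline configuration
#'
#' @param config list (or YAML file path) with fields: `stages` (named list
#'   of per-stage parameter lists, executed in dependency order), optional
#'   `input` (`topology`, `trajectory`, `dt`, `discard`), `seed`, `out`.
#' @return The normalized config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  if (is.null(config$stages) || !length(config$stages))
    stop("config validation: field 'stages' is required and must name at ",
         "least one stage", call. = FALSE)
  bad <- setdiff(names(config$stages), .PIPELINE_STAGES)
  if (length(bad))
    stop("config validation: unknown stage(s): ",
         paste(bad, collapse = ", "), " (known: ",
         paste(.PIPELINE_STAGES, collapse = ", "), ")", call. = FALSE)
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$out <- if (is.null(config$out)) "coronadsorb_out" else config$out
  config
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order (generation first,
#' then per-frame analyses, then fits built on them) and writes one JSON
#' manifest listing inputs, parameters, seed and every product file.
#' Physical defaults are the conventional ones used throughout the package:
#' 5 Angstrom shell cutoff, majority/all-atom hysteresis thresholds, twice
#' the bulk density for grid thresholding, 300 K.
#'
#' @param config see [validate_config()].
#' @return The manifest list, invisibly; products are written under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = names(cfg$stages),
                   parameters = cfg$stages, outputs = list())
  set.seed(cfg$seed)
  dataset <- NULL; truth <- NULL
  emit <- function(name, writer) {
    path <- file.path(cfg$out, name)
    writer(path)
    manifest$outputs[[name]] <<- path
    path
  }
  stage_par <- function(name) {
    p <- cfg$stages[[name]]
    if (is.null(p) || isTRUE(p)) list() else p
  }

  if ("synth_markov" %in% names(cfg$stages)) {
    p <- stage_par("synth_markov"); p$seed <- cfg$seed
    dataset <- generate_markov_trajectory(do.call(markov_params, p))
    truth <- dataset$truth
    emit("ground_truth_states.csv", function(f) {
      df <- data.frame(frame = rep(seq_len(nrow(truth$states)),
                                   ncol(truth$states)),
                       chain = rep(seq_len(ncol(truth$states)),
                                   each = nrow(truth$states)),
                       adsorbed = as.integer(truth$states))
      write.csv(df, f, row.names = FALSE)
    })
    emit("ground_truth.json", function(f)
      jsonlite::write_json(truth[c("p", "mean_adsorbed", "mean_free",
                                   "k_on", "k_off")],
                           f, auto_unbox = TRUE, digits = NA))
  }
  if ("synth_bd" %in% names(cfg$stages)) {
    p <- stage_par("synth_bd"); p$seed <- cfg$seed
    dataset <- generate_bd_trajectory(do.call(bd_params, p))
  }
  if ("synth_isotherm" %in% names(cfg$stages)) {
    p <- stage_par("synth_isotherm"); p$seed <- cfg$seed
    iso <- do.call(generate_isotherm_data, p)
    emit("isotherm_points.csv", function(f) write.csv(iso, f,
                                                      row.names = FALSE))
    if ("isotherm_fit" %in% names(cfg$stages)) {
      fp <- stage_par("isotherm_fit")
      fit <- fit_langmuir(iso, fix_psmax = fp$fix_psmax)
      emit("isotherm_fit.json", function(f)
        jsonlite::write_json(fit[c("Ps_max", "Ka", "rss", "fixed_psmax")],
                             f, auto_unbox = TRUE, digits = NA))
    }
  }
  if (is.null(dataset) && !is.null(cfg$input)) {
    sys <- load_topology(cfg$input$topology)
    traj <- load_trajectory(cfg$input$trajectory, sys,
                            dt = cfg$input$dt %||% 0.01,
                            discard = cfg$input$discard %||% 10)
    dataset <- list(system = sys, traj = traj)
  }
  needs_data <- intersect(names(cfg$stages),
                          c("rdf", "shell", "kinetics", "shape", "energetics",
                            "clusters", "msd", "affinity", "grid"))
  if (length(needs_data) && is.null(dataset))
    stop("dependency error: stage(s) ", paste(needs_data, collapse = ", "),
         " need a dataset (a synth_* stage or config$input)", call. = FALSE)

  series <- NULL
  if (any(c("kinetics", "energetics", "shape") %in% names(cfg$stages))) {
    p <- stage_par("kinetics")
    series <- chain_state_series(dataset$traj, dataset$system,
                                 cutoff = p$cutoff %||% 5.0)
  }
  if ("rdf" %in% names(cfg$stages)) {
    p <- stage_par("rdf")
    curve <- polymer_rdf(dataset$traj, dataset$system,
                         bin_width = p$bin_width %||% 0.25,
                         r_max = p$r_max %||% 15)
    emit("rdf.csv", function(f) write.csv(as.data.frame(curve), f,
                                          row.names = FALSE))
  }
  if ("shell" %in% names(cfg$stages)) {
    p <- stage_par("shell")
    sf <- shell_fraction(dataset$traj, dataset$system,
                         cutoff = p$cutoff %||% 5.0)
    emit("shell_fractions.csv", function(f)
      write.csv(data.frame(frame = seq_along(sf$ap), ap = sf$ap), f,
                row.names = FALSE))
    emit("shell_summary.json", function(f)
      jsonlite::write_json(sf[c("mean", "sd", "as_bulk", "cutoff")], f,
                           auto_unbox = TRUE, digits = NA))
  }
  if ("kinetics" %in% names(cfg$stages)) {
    ev <- detect_events(series)
    emit("events.csv", function(f) write.csv(as.data.frame(ev), f,
                                             row.names = FALSE))
    rates <- event_rates(ev, series)
    comp <- ev[!ev$censored, ]
    summ <- list(
      adsorption_rate = rates$adsorption_rate,
      desorption_rate = rates$desorption_rate,
      mean_adsorbed = rates$mean_adsorbed, sd_adsorbed = rates$sd_adsorbed)
    for (stname in c("adsorbed", "free")) {
      dd <- comp$duration[comp$state == stname]
      if (length(dd))
        summ[[paste0("time_", stname)]] <- lognormal_summary(dd)[
          c("gm", "plus", "minus", "n")]
    }
    emit("kinetics_summary.json", function(f)
      jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA))
  }
  if ("shape" %in% names(cfg$stages)) {
    sh <- shape_distributions(dataset$traj, dataset$system, series)
    emit("shape_samples.csv", function(f) write.csv(sh$samples, f,
                                                    row.names = FALSE))
    emit("shape_summary.csv", function(f)
      write.csv(data.frame(population = rownames(sh$summary), sh$summary),
                f, row.names = FALSE))
  }
  if ("energetics" %in% names(cfg$stages)) {
    p <- stage_par("energetics")
    vol <- shell_volume(dataset$system, cutoff = p$cutoff %||% 5.0,
                        seed = cfg$seed,
                        frame = frame_coords(dataset$traj, 1))
    en <- adsorption_free_energy(series, vol$shell, vol$bulk,
                                 temperature = p$temperature %||% 300)
    emit("energetics.json", function(f)
      jsonlite::write_json(c(en[c("dG", "dG_se", "rho_ads", "rho_free",
                                  "p_adsorbed")],
                             list(shell_volume = vol$shell,
                                  bulk_volume = vol$bulk)),
                           f, auto_unbox = TRUE, digits = NA))
  }
  if ("clusters" %in% names(cfg$stages)) {
    p <- stage_par("clusters")
    rep_ <- cluster_report(dataset$traj, dataset$system,
                           cutoff = p$cutoff %||% 4.5)
    emit("clusters.csv", function(f) write.csv(rep_, f, row.names = FALSE))
  }
  if ("msd" %in% names(cfg$stages)) {
    sel <- heavy_atoms(dataset$system, "polymer")
    dres <- diffusion_coefficient(dataset$traj, sel)
    emit("msd.csv", function(f) write.csv(dres$msd, f, row.names = FALSE))
    emit("diffusion.json", function(f)
      jsonlite::write_json(dres[c("D", "D_se", "r_squared", "fit_window")],
                           f, auto_unbox = TRUE, digits = NA))
  }
  if ("affinity" %in% names(cfg$stages)) {
    p <- stage_par("affinity")
    tab <- residue_shell_counts(dataset$traj, dataset$system,
                                cutoff = p$cutoff %||% 5.0)
    emit("residue_affinity.csv", function(f)
      write.csv(tab$residues, f, row.names = FALSE))
    emit("type_affinity.csv", function(f)
      write.csv(tab$types, f, row.names = FALSE))
  }
  if ("grid" %in% names(cfg$stages)) {
    p <- stage_par("grid")
    grid <- polymer_density_grid(dataset$traj, dataset$system,
                                 voxel = p$voxel %||% 1.0)
    emit("polymer_density.dx", function(f) write_dx(grid, f))
    thr <- threshold_regions(grid, factor = p$factor %||% 2.0)
    emit("grid_threshold.json", function(f)
      jsonlite::write_json(list(factor = p$factor %||% 2.0,
                                n_voxels = thr$n_voxels,
                                threshold = thr$threshold),
                           f, auto_unbox = TRUE, digits = NA))
  }
  manifest$outputs[["manifest.json"]] <- file.path(cfg$out, "manifest.json")
  jsonlite::write_json(manifest, manifest$outputs[["manifest.json"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
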