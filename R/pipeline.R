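# Configuration-driven orchestration: validate a YAML config, run the
# requested generator/analysis stages in order, write all outputs and a
# manifest sufficient to reproduce the run.

config_schema <- list(
  top = c("scenario", "seed", "output_dir", "volume", "population", "coloc",
          "acquisition", "release", "quantal", "latency", "mini", "minis",
          "n_trials", "noise_sd_pa", "duration_s", "burst_rate_hz",
          "window_ms"),
  volume = c("shape_xy", "n_z", "voxel_size_um", "background_mean", "background_sd"),
  population = c("count", "p_glyt2", "p_syt12", "p_yfp", "alpha", "rho", "bleed",
                 "epsilon_sd", "peak_mean", "peak_sd", "sigma_xy_um", "sigma_z_um",
                 "noise_sd", "neighbor_fraction", "neighbor_distance_um",
                 "min_separation_um", "margin_um", "max_attempts", "region_label"),
  coloc = c("voi_um", "edge_shell_um", "anticorrelation_floor", "glyt2_pos",
            "glyt2_neg", "yfp_pos", "syt_pos", "smooth_sigma_vox", "min_peak",
            "min_separation_um", "edge_intensity_k", "min_voxels"),
  acquisition = c("sampling_rate_hz", "filter_cutoff_hz", "sweep_duration_s",
                  "holding_mv", "reversal_mv", "stimulus_times_s", "artifact_blank_ms"),
  release = c("transmitter_mix", "quantal_content", "count_model",
              "train_plasticity", "async_buildup"),
  quantal = c("gaba", "glycine"),
  latency = c("mode", "mu_sync_ms", "sigma_sync_ms", "tau_async_ms",
              "delay_async_ms", "mix_weight"),
  mini = c("rate_hz", "amplitude_pa", "cv", "transmitter"),
  minis = c("deriv_k", "integ_k", "min_interval_ms", "smooth_cutoff_hz",
            "peak_window_ms", "baseline_ms", "max_decay_ms")
)

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("config error in '%s': unknown key(s) %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible(NULL)
}

#' Validate a pipeline run configuration
#'
#' Checks the config (a YAML file path or an already-parsed list) against
#' the known per-module parameter blocks, rejecting unknown keys, and fills
#' in defaults for scenario, seed and output directory.
#'
#' @param config path to a YAML config file, or a named list.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  check_keys(config, config_schema$top, "top level")
  for (blk in intersect(names(config), names(config_schema))) {
    if (blk == "top") next
    check_keys(config[[blk]], config_schema[[blk]], blk)
  }
  if (!is.null(config$latency))
    check_keys(config$latency, config_schema$latency, "latency")
  config$scenario <- config$scenario %||% "imaging"
  known <- c("imaging", "sync", "async", "mixed", "train", "train_async",
             "minis", "bursty", "mixed_source")
  if (!config$scenario %in% known)
    stop(sprintf("config error: unknown scenario '%s' (known: %s)",
                 config$scenario, paste(known, collapse = ", ")), call. = FALSE)
  config$seed <- config$seed %||% 1L
  config
}

build_from_config <- function(constructor, block) {
  if (is.null(block)) return(constructor())
  do.call(constructor, block)
}

scenario_release <- function(config) {
  scen <- config$scenario
  lat_args <- config$latency %||% list()
  rel_args <- config$release %||% list()
  q <- config$quantal %||% list()
  gaba <- if (is.null(q$gaba)) gaba_quantal() else do.call(gaba_quantal, q$gaba)
  gly <- if (is.null(q$glycine)) glycine_quantal() else do.call(glycine_quantal, q$glycine)
  lat <- switch(scen,
    sync = do.call(latency_model, c(list(mode = "synchronous"), lat_args)),
    async = do.call(latency_model, c(list(mode = "asynchronous"), lat_args)),
    mixed = ,
    mixed_source = do.call(latency_model,
      c(list(mode = "mixed"), utils::modifyList(list(mix_weight = 0.5), lat_args))),
    train = do.call(latency_model, c(list(mode = "synchronous"), lat_args)),
    train_async = do.call(latency_model,
      c(list(mode = "asynchronous"),
        utils::modifyList(list(tau_async_ms = 150), lat_args))),
    bursty = do.call(latency_model, c(list(mode = "synchronous"), lat_args)),
    do.call(latency_model, c(list(mode = "synchronous"), lat_args)))
  defaults <- switch(scen,
    train = list(train_plasticity = 0.8, quantal_content = 10),
    train_async = list(quantal_content = 200),
    list())
  do.call(release_model,
          c(list(gaba = gaba, glycine = gly, latency = lat),
            utils::modifyList(defaults, rel_args)))
}

scenario_acquisition <- function(config) {
  args <- config$acquisition %||% list()
  if (config$scenario %in% c("train", "train_async") && is.null(args$stimulus_times_s)) {
    args$stimulus_times_s <- 0.05 + (0:9) * 0.02 # 50 Hz x 10
    args$sweep_duration_s <- args$sweep_duration_s %||% 1.0
  }
  if (config$scenario == "async" && is.null(args$sweep_duration_s))
    args$sweep_duration_s <- 1.0
  do.call(acquisition_spec, args)
}

#' Run the configured pipeline end to end
#'
#' Executes the stages implied by the scenario (imaging: volume generation,
#' bouton detection/scoring, region summaries; electrophysiology scenarios:
#' trace simulation and kinetic analysis; `mixed_source` runs both), writes
#' every output under the output directory and returns (and writes) a
#' manifest echoing parameters, seeds and produced files. All stage seeds
#' derive deterministically from the global seed, so a config re-run
#' reproduces every output byte for byte.
#'
#' @param config YAML path or config list (see [validate_config()]).
#' @param output_dir overrides the config's output directory.
#' @return the manifest list, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- validate_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop("no output_dir configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  scen <- config$scenario
  outputs <- character(0)
  results <- list()
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if (scen %in% c("imaging", "mixed_source")) {
    spec <- build_from_config(volume_spec, config$volume)
    pop <- build_from_config(bouton_population, config$population)
    note("generating volume: %d x %d x %d, %d boutons",
         spec$shape_xy[1L], spec$shape_xy[2L], spec$n_z, pop$count)
    vol <- generate_volume(spec, pop, seed = seed)
    vp <- file.path(out_dir, "volume.tif")
    write_volume(vol$stack, vp, spec$voxel_size_um)
    tp <- file.path(out_dir, "volume_truth.csv")
    utils::write.csv(vol$truth, tp, row.names = FALSE)
    cc <- build_from_config(coloc_config, config$coloc)
    boutons <- analyze_volume(vol$stack, cc, spec$voxel_size_um)
    boutons$region <- pop$region_label
    bp <- file.path(out_dir, "boutons.csv")
    utils::write.csv(boutons, bp, row.names = FALSE)
    summ <- summarize_regions(boutons)
    sp <- file.path(out_dir, "region_summary.csv")
    utils::write.csv(summ$table, sp, row.names = FALSE)
    note("detected %d boutons (%d GlyT2+)", nrow(boutons),
         sum(boutons$glyt2_label == "pos"))
    outputs <- c(outputs, vp, sidecar_path(vp), tp, bp, sp)
    results$n_boutons <- nrow(boutons)
  }

  if (scen %in% c("sync", "async", "mixed", "train", "train_async", "bursty",
                  "mixed_source")) {
    acq <- scenario_acquisition(config)
    rel <- scenario_release(config)
    n_trials <- config$n_trials %||% 20L
    noise <- config$noise_sd_pa %||% 2
    note("simulating %d evoked trials (%s scenario)", n_trials, scen)
    sweeps <- simulate_evoked(rel, acq, n_trials = n_trials,
                              noise_sd_pa = noise, seed = seed + 101L)
    if (scen == "bursty") {
      tmpl <- gap_burst_template(acq)
      sweeps <- inject_gap_bursts(sweeps, tmpl, config$burst_rate_hz %||% 2,
                                  seed = seed + 202L)
    }
    swp <- file.path(out_dir, "sweeps.csv")
    write_sweepset(sweeps, swp)
    outputs <- c(outputs, swp, sidecar_path(swp), paste0(swp, ".truth.csv"))
    if (scen %in% c("train", "train_async")) {
      tr <- analyze_train(sweeps)
      tdf <- data.frame(stimulus = seq_along(tr$charge_pc),
                        charge_pc = tr$charge_pc,
                        normalized_charge = tr$normalized_charge)
      tp2 <- file.path(out_dir, "train_charge.csv")
      utils::write.csv(tdf, tp2, row.names = FALSE)
      outputs <- c(outputs, tp2)
      results$last_ipsc_decay_tau_ms <- tr$last_ipsc_decay_tau_ms
    } else {
      win <- config$window_ms %||% (if (scen == "async") 500 else 100)
      kin <- compute_kinetics(sweeps, window_ms = win)
      kdf <- data.frame(jitter_ms = kin$jitter_ms, half_rise_ms = kin$half_rise_ms,
                        decay_tau_ms = kin$decay_tau_ms,
                        peak_amplitude_pa = kin$peak_amplitude_pa,
                        peak_time_ms = kin$peak_time_ms, charge_pc = kin$charge_pc,
                        n_trials = kin$n_trials)
      kp <- file.path(out_dir, "kinetics.csv")
      utils::write.csv(kdf, kp, row.names = FALSE)
      outputs <- c(outputs, kp)
      results$jitter_ms <- kin$jitter_ms
    }
  }

  if (scen == "minis") {
    acq <- scenario_acquisition(config)
    mm <- build_from_config(mini_model, config$mini)
    dur <- config$duration_s %||% 60
    note("simulating %g s of minis at %g Hz", dur, mm$rate_hz)
    sweeps <- simulate_minis(mm, if (mm$transmitter == "glycine") glycine_quantal() else gaba_quantal(),
                             acq, duration_s = dur,
                             noise_sd_pa = config$noise_sd_pa %||% 2,
                             seed = seed + 303L)
    swp <- file.path(out_dir, "mini_sweeps.csv")
    write_sweepset(sweeps, swp)
    mp <- build_from_config(mini_params, config$minis)
    ev <- detect_minis(sweeps, params = mp)
    ep <- file.path(out_dir, "mini_events.csv")
    utils::write.csv(as.data.frame(ev), ep, row.names = FALSE)
    ms <- summarize_minis(ev, sweeps = sweeps)
    msp <- file.path(out_dir, "mini_summary.csv")
    utils::write.csv(data.frame(n_events = ms$n_events, frequency_hz = ms$frequency_hz,
                                mean_amplitude_pa = ms$mean_amplitude_pa,
                                mean_decay_ms = ms$mean_decay_ms),
                     msp, row.names = FALSE)
    note("detected %d mini events (%.2f Hz)", ms$n_events, ms$frequency_hz)
    outputs <- c(outputs, swp, sidecar_path(swp), paste0(swp, ".truth.csv"), ep, msp)
    results$mini_frequency_hz <- ms$frequency_hz
  }

  manifest <- list(
    package = "synquant",
    version = as.character(utils::packageVersion("synquant")),
    scenario = scen, seed = seed,
    parameters = config,
    outputs = basename(outputs),
    results = results)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}
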