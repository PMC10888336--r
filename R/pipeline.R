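#' Built-in study presets
#'
#' `functional_preset()` returns the full parameter block for a simulated
#' 15-min calcium-imaging session on a hydrogel culture. Two conditions are
#' provided, emulating the phenomenology of a soft ("T1-like") and a stiff
#' ("T2-like") gel: the soft condition has a denser ground-truth network and
#' a global synchronous drive (network bursts), the stiff one a sparser
#' network, no synchronous drive and a lower spontaneous rate.
#'
#' `rheology_preset()` returns the per-DIV modulus trajectory of a rheology
#' monitoring campaign over three weeks (3 replicates per DIV): "T1" soft and
#' decaying early, "T2" stiff and gradually decaying (about a factor two from
#' early to mature), "T3" flat (no developing neurons perturbing the gel).
#'
#' @param name preset name.
#' @return a named config list consumed by [run_functional()] /
#'   [run_rheology()].
#' @export
functional_preset <- function(name = c("T1", "T2")) {
  name <- match.arg(name)
  base <- list(
    label = name,
    network = list(n_neurons = 60, density = 0.06, n_communities = 4,
                   spatial_decay = 600, radius_um = 3000, height_um = 600),
    spikes = list(duration = 900, dt = 1 / 33, baseline_rate = 0.0074,
                  coupling_scale = 0.22, transmission_delay = 3 / 33,
                  refractory = 1.0, sync_drive_rate = 0.025,
                  sync_strength = 0.85),
    calcium = list(amplitude_per_spike = 0.8, rise_time = 0.2,
                   decay_time = 1.0, baseline_F0 = 100, noise_sd = 2,
                   drift_amplitude = 3, drift_period = 300, frame_rate = 33),
    detection = list(min_frames = 3),
    te = list(bin_s = 2 / 33, markov_order = 2, z_threshold = 2,
              delay_bins = 1, conditioning = "exclude_bursts",
              burst_fraction = 0.4),
    population = list(window = 0.5, step = 0.1, z_pk = 3))
  if (name == "T2") {
    base$network$density <- 0.04
    base$spikes$sync_drive_rate <- 0
    base$spikes$baseline_rate <- 0.0167
  }
  base
}

#' @rdname functional_preset
#' @export
rheology_preset <- function(name = c("T1", "T2", "T3")) {
  name <- match.arg(name)
  div <- c(1, 2, 3, 5, 6, 8, 13, 16, 20)
  traj <- switch(name,
    # G' plateau trajectories (Pa); E = 2 sqrt(G1^2 + G2^2) (1 + nu)
    T1 = c(120, 116, 112, 92, 86, 80, 80, 78, 80),
    T2 = c(235, 223, 211, 191, 175, 159, 151, 143, 135),
    T3 = rep(100, 9))
  list(label = name,
       DIV = div,
       plateau_G1 = traj,
       n_replicates = 3,
       truth = list(loss_ratio = 0.1, thickening_onset = 50,
                    thickening_exponent = 2,
                    transient_time_true = if (name == "T2") 300 else 150,
                    transient_depth = 0.4, noise_cv = 0.05),
       nu = 0.25)
}

#' Run the functional pipeline (simulate -> process -> infer -> metrics)
#'
#' Chains the full functional analysis on synthetic data: ground-truth
#' network generation, cascade spiking, fluorescence rendering, dF/F
#' normalization, Schmitt event detection, population activity and
#' synchronization peaks, firing rate, transfer-entropy effective
#' connectivity, and graph traits. All randomness derives from `seed`, so a
#' rerun with the same config and seed reproduces every output bit-exactly.
#'
#' @param config a [functional_preset()] list (or one with the same shape).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir optional directory; when given, the raster, population
#'   activity, adjacency, GraphML network, traits and run report are written
#'   there with JSON sidecars.
#' @return object of class `run_report` with the stage outputs and headline
#'   metrics (`mean_k`, `GE`, `Q`, `firing_rate_per_min`, `n_sync_peaks`).
#' @export
run_functional <- function(config = functional_preset("T1"), seed = 1,
                           out_dir = NULL) {
  validate_config(config, kind = "functional")
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  warnings_seen <- character(0)
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  net <- do.call(generate_network,
                 c(config$network, list(seed = derive_seed(seed, 1))))
  tick("network")
  sim <- do.call(spike_sim_params,
                 c(config$spikes, list(seed = derive_seed(seed, 2))))
  raster_true <- simulate_spikes(net, sim)
  tick("spikes")
  cal <- do.call(calcium_params,
                 c(config$calcium, list(seed = derive_seed(seed, 3))))
  rec <- render_fluorescence(raster_true, cal)
  tick("fluorescence")
  norm <- normalize_traces(rec)
  raster <- wcollect(do.call(schmitt_detect,
                             c(list(traces = norm), config$detection)))
  tick("detection")
  pa <- population_activity(raster, config$population$window,
                            config$population$step)
  peaks <- detect_sync_peaks(pa, z_pk = config$population$z_pk)
  rate <- firing_rate(raster)
  tick("population")
  tecfg <- do.call(te_config, c(config$te, list(seed = derive_seed(seed, 4))))
  bins <- binarize_raster(raster, tecfg$bin_s)
  ec <- wcollect(te_matrix(bins, tecfg))
  tick("te")
  traits <- network_traits(ec$A, seed = derive_seed(seed, 5))
  tick("metrics")

  report <- structure(list(
    kind = "functional", label = config$label %||% "custom", seed = seed,
    config = config,
    net = net, raster_true = raster_true, raster = raster, pa = pa,
    peaks = peaks, ec = ec, traits = traits,
    headline = list(n_neurons = net$n_neurons,
                    firing_rate_per_min = rate,
                    n_sync_peaks = length(peaks),
                    mean_k = traits$mean_k, GE = traits$GE, Q = traits$Q,
                    L = traits$L),
    warnings = warnings_seen, timings = as.list(timings)),
    class = "run_report")
  if (!is.null(out_dir)) write_run_outputs(report, out_dir)
  report
}

#' Run the rheology pipeline (simulate sweeps -> reduce -> compare)
#'
#' For each DIV and replicate, generates the three SAOS tests from the
#' preset's modulus trajectory, applies the torque-floor filter to the
#' strain sweep, checks the LVR, detects the time-sweep transient, reduces
#' the frequency sweep to plateau moduli, converts to Young's modulus, and
#' finally groups estimates into developmental stages and runs the pairwise
#' Student's t-tests.
#'
#' @param config a [rheology_preset()] list.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return object of class `run_report` with `estimates` (per DIV/replicate
#'   Young's moduli), `comparison` (a [compare_stages()] result), `tT`
#'   estimates, and headline per-stage means.
#' @export
run_rheology <- function(config = rheology_preset("T2"), seed = 1,
                         out_dir = NULL) {
  validate_config(config, kind = "rheology")
  warnings_seen <- character(0)
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  rows <- list()
  tTs <- list()
  lvr <- list()
  sweeps <- list()
  kk <- 0L
  for (i in seq_along(config$DIV)) {
    for (r in seq_len(config$n_replicates)) {
      kk <- kk + 1L
      truth <- do.call(rheo_truth, c(
        list(plateau_G1 = config$plateau_G1[i],
             seed = derive_seed(seed, 100 * i + r)),
        config$truth))
      fs <- generate_sweeps(truth, "frequency", DIV = config$DIV[i],
                            replicate = r)
      ss <- generate_sweeps(truth, "strain", DIV = config$DIV[i],
                            replicate = r)
      ts <- generate_sweeps(truth, "time", DIV = config$DIV[i],
                            replicate = r)
      ss <- wcollect(filter_torque_floor(ss))
      lvr[[kk]] <- check_lvr(ss)
      tr <- detect_transient(ts)
      tTs[[kk]] <- data.frame(DIV = config$DIV[i], replicate = r, tT = tr$tT,
                              settled = tr$settled)
      ms <- plateau_modulus(fs)
      est <- youngs_modulus(ms$plateau_G1, ms$plateau_G2, nu = config$nu,
                            DIV = config$DIV[i])
      est$replicate <- r
      rows[[kk]] <- est
      sweeps[[kk]] <- rbind(fs, ss, ts)
    }
  }
  estimates <- do.call(rbind, rows)
  class(estimates) <- c("youngs_modulus", "data.frame")
  groups <- wcollect(stage_group(estimates))
  comparison <- compare_stages(groups)
  tT <- do.call(rbind, tTs)
  report <- structure(list(
    kind = "rheology", label = config$label %||% "custom", seed = seed,
    config = config, estimates = groups, all_estimates = estimates,
    comparison = comparison, tT = tT, lvr = lvr,
    sweeps = do.call(rbind, sweeps),
    headline = list(stage_means_E = as.list(comparison$means),
                    stage_sds_E = as.list(comparison$sds),
                    p_values = stats::setNames(as.list(comparison$tests$p),
                                               comparison$tests$pair),
                    mean_tT = mean(tT$tT)),
    warnings = warnings_seen),
    class = "run_report")
  if (!is.null(out_dir)) write_run_outputs(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s pipeline, preset %s, seed %d\n",
              x$kind, x$label, x$seed))
  utils::str(x$headline, give.attr = FALSE)
  invisible(x)
}

# Persist a run's artifacts with sidecars carrying the config hash.
write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(report$config, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (report$kind == "functional") {
    write_raster(report$raster, file.path(out_dir, "raster.csv"))
    write_population_activity(report$pa, file.path(out_dir, "population_activity.csv"))
    write_adjacency(report$ec, file.path(out_dir, "adjacency.csv"))
    export_network(report$ec, file.path(out_dir, "network.graphml"),
                   positions = report$net$positions,
                   communities = report$traits$communities)
    write_traits(report$traits, file.path(out_dir, "traits.json"))
    write_ground_truth(report$net, file.path(out_dir, "ground_truth.json"))
  } else {
    write_sweeps(report$sweeps, file.path(out_dir, "sweeps.csv"))
    utils::write.csv(report$all_estimates,
                     file.path(out_dir, "youngs_modulus.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(kind = report$kind, label = report$label, seed = report$seed,
         headline = report$headline, warnings = report$warnings,
         timings = report$timings,
         config_md5 = unname(tools::md5sum(cfg_file))),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Reject configs with unknown keys so typos do not silently fall back to
# defaults.
validate_config <- function(config, kind) {
  known <- if (kind == "functional") {
    c("label", "network", "spikes", "calcium", "detection", "te", "population")
  } else {
    c("label", "DIV", "plateau_G1", "n_replicates", "truth", "nu")
  }
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (kind == "rheology" &&
      length(config$DIV) != length(config$plateau_G1)) {
    stop("DIV and plateau_G1 must have the same length", call. = FALSE)
  }
  invisible(config)
}

#' Load a run configuration from YAML
#'
#' One YAML file with the per-module blocks of [functional_preset()] or
#' [rheology_preset()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param kind "functional" or "rheology".
#' @return validated config list.
#' @export
load_run_config <- function(path, kind = c("functional", "rheology")) {
  kind <- match.arg(kind)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg, kind)
  cfg
}
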