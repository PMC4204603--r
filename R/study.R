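#' Run the full study from one configuration
#'
#' End-to-end reproduction of the study's analyses from a single config:
#' trial simulation across conditions and coherences, trial-averaged traces,
#' psychometric and chronometric tables, baseline differences, the
#' threshold-compensation sweep, phase-plane summaries, and the
#' ideal-observer analysis. All outputs are written as CSV/JSON under
#' `out_dir` together with a manifest (config hash, seed, file list).
#'
#' @param config a [load_config()] result (or a path to a YAML config).
#' @param out_dir output directory, created if needed.
#' @param n_trials,seed optional overrides of the config values.
#' @param phase_coherence coherence (percent) at which manifold geometry is
#'   computed (default 4, the worked-example difficulty).
#' @param verbose log per-stage progress.
#' @return Invisibly, a list with the in-memory results (`batch`, `fits`,
#'   `chrono`, `baselines`, `sweep`, `phase`, `observer`, `manifest`).
#' @export
run_study <- function(config = load_config(), out_dir, n_trials = NULL,
                      seed = NULL, phase_coherence = 4, verbose = TRUE) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(n_trials)) config$n_trials <- as.integer(n_trials)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character()
  put_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, name)
    f
  }
  put_json <- function(x, name) {
    f <- file.path(out_dir, name)
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, name)
    f
  }

  t0 <- Sys.time()
  say("simulating %d trials x %d coherences x %d conditions (seed %d)",
      config$n_trials, length(config$coherences), length(config$conditions),
      config$seed)
  batch <- run_batch(config$conditions, config$coherences, config$n_trials,
                     config$schedule, config$theta, config$seed,
                     config$params, sustain_ms = config$sustain_ms,
                     verbose = verbose)
  say("simulation done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  put_csv(batch$records[, c("condition", "coherence", "trial", "seed",
                            "choice", "decision_time", "correct",
                            "baseline_rate")], "trial_records.csv")

  # trial-averaged traces at the phase/worked-example coherence
  avg <- do.call(rbind, lapply(names(config$conditions), function(nm) {
    tr <- trial_average_traces(batch, nm, phase_coherence, "correct")
    tr$condition <- nm
    tr
  }))
  put_csv(avg, "trial_averaged_traces.csv")

  # behavior
  fits <- lapply(names(config$conditions), function(nm) {
    fit_psychometric(accuracy_table(
      batch$records[batch$records$condition == nm, ]))
  })
  names(fits) <- names(config$conditions)
  put_json(lapply(fits, function(f) f[c("alpha", "beta", "c75")]),
           "psychometric_fits.json")
  chrono <- chronometric_summary(batch$records)
  put_csv(chrono, "chronometric_summary.csv")
  bd <- baseline_deltas(batch)
  put_json(list(baseline_means_hz = as.list(bd$means),
                delta_ns_hz = bd$delta_ns, delta_na_hz = bd$delta_na),
           "baselines.json")

  say("threshold sweep over %d thresholds", length(config$theta_grid))
  sweep <- threshold_sweep(batch, config$theta_grid,
                           bd$delta_ns, bd$delta_na)
  put_csv(as.data.frame(sweep), "threshold_sweep.csv")
  put_csv(compensation_summary(sweep, config$theta), "compensation.csv")

  say("phase-plane analysis")
  phase <- lapply(names(config$conditions), function(nm) {
    cond <- config$conditions[[nm]]
    rec <- batch$records[batch$records$condition == nm, ]
    S_init <- c(mean(rec$S1_onset), mean(rec$S2_onset))
    phase_portrait(cond, phase_coherence, config$params, S_init = S_init)
  })
  names(phase) <- names(config$conditions)
  tau_tab <- do.call(rbind, lapply(names(config$conditions), function(nm) {
    cond <- config$conditions[[nm]]
    do.call(rbind, lapply(config$coherences, function(cc) {
      sad <- select_saddle(find_fixed_points(cond, cc, TRUE, config$params))
      data.frame(condition = nm, coherence = cc,
                 tau_eff_ms = effective_time_constant(sad),
                 saddle_r1_hz = sad$rates[1], saddle_r2_hz = sad$rates[2])
    }))
  }))
  put_csv(tau_tab, "effective_time_constants.csv")
  put_json(lapply(phase, function(p) list(
    tau_eff_ms = p$tau_eff,
    saddle_rates_hz = p$saddle$rates,
    init_rates_hz = p$initial_state$rates,
    init_rates_stim_on_hz = p$initial_state$rates_stim_on,
    init_distance_hz = p$init_distance)), "phase_summary.json")
  for (nm in names(phase)) {
    man <- phase[[nm]]$manifolds
    poly <- rbind(
      data.frame(manifold = "stable", S1 = man$stable$S[, 1],
                 S2 = man$stable$S[, 2], r1_hz = man$stable$rates[, 1],
                 r2_hz = man$stable$rates[, 2]),
      data.frame(manifold = "unstable", S1 = man$unstable$S[, 1],
                 S2 = man$unstable$S[, 2], r1_hz = man$unstable$rates[, 1],
                 r2_hz = man$unstable$rates[, 2]))
    put_csv(poly, sprintf("manifolds_%s_c%g.csv", nm, phase_coherence))
  }

  say("ideal-observer analysis")
  obs <- observer_summary(batch, config$observer$criterion,
                          config$observer$sustain_bins,
                          config$observer$smooth_ms)
  put_csv(obs$per_coherence, "observer_per_coherence.csv")
  put_csv(obs$pooled, "observer_pooled.csv")
  put_csv(obs$last_intersection, "observer_last_intersection.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("satdyn")),
    seed = config$seed, n_trials = config$n_trials,
    coherences = config$coherences,
    conditions = lapply(config$conditions, function(x) unclass(x)),
    theta_hz = config$theta,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files)
  put_json(manifest, "manifest.json")
  say("study complete: %d files in %s", length(files), out_dir)
  invisible(list(batch = batch, fits = fits, chrono = chrono,
                 baselines = bd, sweep = sweep, phase = phase,
                 tau_table = tau_tab, observer = obs, manifest = manifest))
}
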