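#' Model parameters for the reduced two-population attractor model
#'
#' Constructs and validates the full biophysical parameter set of the
#' two-variable mean-field model of decision making. Defaults are the
#' canonical published values of the reduced model; only the background
#' current `I0` and its noise amplitude vary across task conditions (see
#' [condition_spec()]).
#'
#' Units are fixed by convention throughout the package: time in ms, rates
#' in Hz, currents in nA. The transfer function `H` returns Hz; where it
#' enters the gating dynamics (per ms) it is scaled by `1e-3`.
#'
#' @param a f-I curve gain (Hz/nA).
#' @param b f-I curve offset (Hz).
#' @param d f-I curve curvature (s).
#' @param gamma synaptic coupling factor (dimensionless).
#' @param tau_S NMDA synaptic gating time constant (ms).
#' @param tau_noise noise-current correlation time (ms); must be < `tau_S`.
#' @param J_self recurrent self-coupling strength (nA), identical for both
#'   populations.
#' @param J_cross cross-inhibition coupling strength (nA), identical in both
#'   directions.
#' @param J_ext external input scaling (nA per Hz of stimulus rate).
#' @param mu0 stimulus reference rate (Hz).
#' @param I0 mean nonselective background current (nA); per-condition values
#'   in [condition_spec()] override this.
#' @param sigma_noise stationary standard deviation of the noise current (nA).
#'
#' @return A list of class `"sat_params"`.
#' @examples
#' p <- model_parameters()
#' transfer_rate(p$b / p$a, p) # limit value 1/d
#' @export
model_parameters <- function(a = 270, b = 108, d = 0.154, gamma = 0.641,
                             tau_S = 100, tau_noise = 2,
                             J_self = 0.2609, J_cross = 0.0497,
                             J_ext = 5.2e-4, mu0 = 30,
                             I0 = 0.321, sigma_noise = 0.02) {
  p <- list(a = a, b = b, d = d, gamma = gamma, tau_S = tau_S,
            tau_noise = tau_noise, J_self = J_self, J_cross = J_cross,
            J_ext = J_ext, mu0 = mu0, I0 = I0, sigma_noise = sigma_noise)
  validate_params(p)
  structure(p, class = "sat_params")
}

validate_params <- function(p) {
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("non-finite or non-scalar model parameter(s): ",
         paste(names(p)[!num], collapse = ", "))
  }
  pos <- c("a", "b", "d", "gamma", "tau_S", "tau_noise", "J_self", "J_cross",
           "J_ext", "mu0")
  bad <- pos[vapply(pos, function(k) p[[k]] <= 0, logical(1))]
  if (length(bad)) stop("parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (p$tau_noise >= p$tau_S) stop("tau_noise must be smaller than tau_S")
  if (p$I0 <= 0 || p$I0 >= 1) {
    stop("I0 must lie in (0, 1) nA; got ", p$I0,
         " (values in pA must be divided by 1000)")
  }
  if (p$sigma_noise < 0) stop("sigma_noise must be >= 0")
  invisible(p)
}

#' Task-condition specification
#'
#' A condition binds a name (speed / neutral / accuracy) to a background
#' current `I0` and a noise amplitude. The speed-accuracy manipulation is
#' entirely through `I0`: more nonselective excitation (speed) raises
#' baseline rates and strengthens the network dynamics.
#'
#' @param name condition label, one of `"speed"`, `"neutral"`, `"accuracy"`
#'   (other labels are allowed for custom sweeps).
#' @param I0 background current in nA (values > 1 are rejected; divide pA
#'   by 1000).
#' @param sigma_noise noise-current standard deviation (nA).
#' @return A list of class `"sat_condition"`.
#' @export
condition_spec <- function(name, I0, sigma_noise = 0.02) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(I0) || length(I0) != 1L || I0 <= 0 || I0 >= 1) {
    stop("I0 must be a single value in (0, 1) nA")
  }
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  structure(list(name = name, I0 = I0, sigma_noise = sigma_noise),
            class = "sat_condition")
}

#' Default speed / neutral / accuracy conditions
#'
#' Background currents 325, 321 and 316 pA for the speed, neutral and
#' accuracy conditions, with a common noise amplitude.
#'
#' @param sigma_noise noise std (nA) applied to all three conditions.
#' @return Named list of three [condition_spec()] objects, ordered
#'   speed, neutral, accuracy.
#' @export
default_conditions <- function(sigma_noise = 0.02) {
  list(speed    = condition_spec("speed",    0.325, sigma_noise),
       neutral  = condition_spec("neutral",  0.321, sigma_noise),
       accuracy = condition_spec("accuracy", 0.316, sigma_noise))
}

#' Trial epoch schedule
#'
#' @param t_prestim pre-stimulus duration (ms).
#' @param t_stim stimulus duration (ms).
#' @param dt integration step (ms). Durations must be (near-)integer
#'   multiples of `dt`.
#' @return A list of class `"sat_schedule"`.
#' @export
epoch_schedule <- function(t_prestim = 2500, t_stim = 5000, dt = 0.1) {
  stopifnot(t_prestim > 0, t_stim > 0, dt > 0)
  for (tt in c(t_prestim, t_stim)) {
    k <- tt / dt
    if (abs(k - round(k)) > 1e-8) {
      stop("epoch durations must be multiples of dt")
    }
  }
  structure(list(t_prestim = t_prestim, t_stim = t_stim, dt = dt),
            class = "sat_schedule")
}

#' Path to the shipped reference configuration
#' @return Path to the package's canonical YAML config.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "satdyn",
              mustWork = TRUE)
}

config_known_keys <- list(
  top = c("model", "conditions", "schedule", "task", "sweep", "observer",
          "seed"),
  model = c("a", "b", "d", "gamma", "tau_S", "tau_noise", "J_self",
            "J_cross", "J_ext", "mu0"),
  condition = c("I0_pA", "sigma_noise"),
  schedule = c("t_prestim_ms", "t_stim_ms", "dt_ms"),
  task = c("coherences_pct", "n_trials", "theta_hz", "sustain_ms"),
  sweep = c("theta_grid_hz"),
  observer = c("criterion", "sustain_bins", "bin_ms", "smooth_ms")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in config section '", where, "': ",
         paste(extra, collapse = ", "))
  }
}

#' Load and validate an experiment configuration
#'
#' Reads a flat YAML config (see [default_config_path()] for the reference
#' file), converts `I0` from pA to nA, validates all values and rejects
#' unknown keys.
#'
#' @param path YAML file path; defaults to the shipped reference config.
#' @return A validated list of class `"sat_config"` with elements
#'   `params` ([model_parameters()]), `conditions`, `schedule`
#'   ([epoch_schedule()]), `coherences`, `n_trials`, `theta`,
#'   `theta_grid`, `observer`, `seed`.
#' @export
load_config <- function(path = default_config_path()) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_known_keys$top, "<top level>")
  check_keys(raw$model, config_known_keys$model, "model")
  check_keys(raw$schedule, config_known_keys$schedule, "schedule")
  check_keys(raw$task, config_known_keys$task, "task")
  check_keys(raw$sweep, config_known_keys$sweep, "sweep")
  check_keys(raw$observer, config_known_keys$observer, "observer")

  params <- do.call(model_parameters, raw$model)
  conds <- lapply(names(raw$conditions), function(nm) {
    cc <- raw$conditions[[nm]]
    check_keys(cc, config_known_keys$condition, paste0("conditions$", nm))
    condition_spec(nm, cc$I0_pA / 1000, cc$sigma_noise)
  })
  names(conds) <- names(raw$conditions)
  sched <- epoch_schedule(raw$schedule$t_prestim_ms, raw$schedule$t_stim_ms,
                          raw$schedule$dt_ms)
  coh <- as.numeric(raw$task$coherences_pct)
  if (any(coh < 0 | coh > 100)) stop("coherences must lie in [0, 100] %")
  if (raw$task$n_trials < 1) stop("n_trials must be >= 1")
  if (raw$task$theta_hz <= 0) stop("theta must be positive")
  sus <- if (is.null(raw$task$sustain_ms)) 2 else raw$task$sustain_ms
  if (sus < 0) stop("sustain_ms must be >= 0")
  obs <- raw$observer
  structure(list(
    params = params, conditions = conds, schedule = sched,
    coherences = coh, n_trials = as.integer(raw$task$n_trials),
    theta = raw$task$theta_hz, sustain_ms = sus,
    theta_grid = as.numeric(raw$sweep$theta_grid_hz),
    observer = list(criterion = obs$criterion,
                    sustain_bins = as.integer(obs$sustain_bins),
                    bin_ms = obs$bin_ms, smooth_ms = obs$smooth_ms),
    seed = as.integer(raw$seed)
  ), class = "sat_config")
}

#' Print the reference configuration
#'
#' Echoes the shipped canonical config file, which documents every default.
#' @return The config text, invisibly.
#' @export
print_default_config <- function() {
  txt <- readLines(default_config_path())
  cat(txt, sep = "\n")
  invisible(txt)
}
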