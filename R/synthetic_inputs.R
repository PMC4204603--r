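#' One Euler step of the Ornstein-Uhlenbeck noise current
#'
#' Discretisation `I <- I + dt (-I/tau) + sigma sqrt(2 dt / tau) xi` with
#' `xi` a standard-normal draw. The discrete process has stationary mean 0,
#' stationary standard deviation `sigma` (to O(dt/tau)) and autocorrelation
#' time `tau`.
#'
#' @param I_noise current value (nA).
#' @param dt step (ms); must satisfy `dt <= tau/2` for stability.
#' @param sigma stationary std (nA).
#' @param tau correlation time (ms).
#' @param rng_draw standard-normal draw(s); defaults to `rnorm`.
#' @return Updated noise current (nA).
#' @export
ou_step <- function(I_noise, dt, sigma, tau, rng_draw = stats::rnorm(length(I_noise))) {
  if (dt > tau / 2) {
    stop("dt must be <= tau/2 for a stable explicit OU step")
  }
  I_noise + dt * (-I_noise / tau) + sigma * sqrt(2 * dt / tau) * rng_draw
}

#' Generate an Ornstein-Uhlenbeck noise series
#'
#' Vectorised generator for a full trial-length noise stream, initialised at
#' the stationary distribution (no burn-in transient). Uses the same update
#' rule as [ou_step()], expressed as a first-order recursive filter.
#'
#' @param n number of steps.
#' @param dt step (ms).
#' @param sigma stationary std (nA).
#' @param tau correlation time (ms).
#' @return Numeric vector of length `n` (the value after each step, with the
#'   stationary initial value prepended is not included).
#' @export
ou_series <- function(n, dt, sigma, tau) {
  if (dt > tau / 2) stop("dt must be <= tau/2 for a stable explicit OU step")
  phi <- 1 - dt / tau
  innov <- sigma * sqrt(2 * dt / tau) * stats::rnorm(n)
  i0 <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = i0))
}

#' Stimulus currents at a time point within a trial
#'
#' Zero during the pre-stimulus epoch; during the stimulus epoch the target
#' and distractor populations receive `J_ext mu0 (1 + c/100)` and
#' `J_ext mu0 (1 - c/100)` respectively.
#'
#' @param t time since trial start (ms).
#' @param c coherence (percent).
#' @param sched an [epoch_schedule()].
#' @param params a [model_parameters()].
#' @return Numeric vector `c(I_stim1, I_stim2)` (nA).
#' @export
stimulus_schedule <- function(t, c, sched, params) {
  if (t < 0 || t > sched$t_prestim + sched$t_stim) {
    stop("time ", t, " ms lies outside the trial")
  }
  if (t < sched$t_prestim) {
    c(0, 0)
  } else {
    params$J_ext * params$mu0 * c(1 + c / 100, 1 - c / 100)
  }
}

#' Derive the per-trial seed table for an experiment
#'
#' One master seed determines every trial's private seed: the table is a
#' deterministic function of (master seed, condition index, coherence index,
#' trial index), so any single trial can be re-simulated in isolation.
#'
#' @param master_seed integer master seed.
#' @param n_cond,n_coh,n_trials grid dimensions.
#' @return Integer array `[n_cond, n_coh, n_trials]` of seeds in
#'   `[1, 2^31 - 1]`.
#' @export
trial_seeds <- function(master_seed, n_cond, n_coh, n_trials) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))
  array(sample.int(.Machine$integer.max, n_cond * n_coh * n_trials,
                   replace = TRUE),
        dim = c(n_cond, n_coh, n_trials))
}

#' Write sample noise traces and stimulus schedules to CSV
#'
#' Small inspection bundle: one OU noise trace per population and the
#' stimulus-current schedule for each requested coherence.
#'
#' @param out_dir output directory (created if needed).
#' @param coherences coherences (percent) to tabulate.
#' @param sched an [epoch_schedule()].
#' @param params a [model_parameters()].
#' @param sigma,tau noise std (nA) and correlation time (ms).
#' @param seed RNG seed.
#' @param n_ms length of the noise sample (ms).
#' @return Paths of the files written, invisibly.
#' @export
write_fixtures <- function(out_dir, coherences = c(0, 4, 32),
                           sched = epoch_schedule(),
                           params = model_parameters(),
                           sigma = 0.02, tau = 2, seed = 1, n_ms = 500) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  n <- round(n_ms / sched$dt)
  noise <- data.frame(t_ms = seq_len(n) * sched$dt,
                      I_noise1_nA = ou_series(n, sched$dt, sigma, tau),
                      I_noise2_nA = ou_series(n, sched$dt, sigma, tau))
  f1 <- file.path(out_dir, "noise_sample.csv")
  utils::write.csv(noise, f1, row.names = FALSE)
  tt <- c(sched$t_prestim / 2, sched$t_prestim + sched$t_stim / 2)
  sched_tab <- do.call(rbind, lapply(coherences, function(cc) {
    do.call(rbind, lapply(tt, function(t) {
      s <- stimulus_schedule(t, cc, sched, params)
      data.frame(t_ms = t, coherence_pct = cc,
                 I_stim1_nA = s[1], I_stim2_nA = s[2])
    }))
  }))
  f2 <- file.path(out_dir, "stimulus_schedule.csv")
  utils::write.csv(sched_tab, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
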