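#' Simulate a single decision trial
#'
#' Euler-Maruyama integration of the two-variable attractor model through a
#' pre-stimulus epoch and a stimulus epoch, with independent
#' Ornstein-Uhlenbeck noise currents to the two populations. A choice is
#' registered at the first crossing of the firing-rate threshold `theta` by
#' either population during the stimulus epoch; population 1 is the target
#' (it receives the stronger input for `c > 0`).
#'
#' @param cond a [condition_spec()].
#' @param c coherence (percent).
#' @param sched an [epoch_schedule()].
#' @param theta choice threshold (Hz).
#' @param seed integer seed for this trial.
#' @param params a [model_parameters()].
#' @param sustain_ms duration (ms) the rate must stay at or above `theta`
#'   to register a choice (default 2, one noise correlation time). The
#'   instantaneous rate tracks the noise current through the steep f-I
#'   curve, so one-step spikes would otherwise trigger spurious choices;
#'   a window of one correlation time suppresses them while leaving
#'   genuine attractor excursions untouched. The stored envelopes are
#'   envelopes of the same windowed-minimum rate, so threshold
#'   re-detection applies the identical rule.
#' @param keep_env,env_bin store per-bin maximum-rate envelopes over the
#'   whole trial at `env_bin` ms resolution (for threshold re-detection).
#' @param keep_traces,trace_bin store per-bin mean-rate traces at
#'   `trace_bin` ms resolution.
#' @param stop_at_choice halt integration at the threshold crossing when no
#'   envelopes/traces are requested.
#' @param S_init initial gating state (relaxes to the spontaneous state
#'   during the pre-stimulus epoch).
#' @return A list of class `"sat_trial"`: `choice` (`"target"`,
#'   `"distractor"` or `"undecided"`), `decision_time` (ms from stimulus
#'   onset; `NA` if undecided), `correct`, `baseline_rate` (Hz, mean over
#'   the last 1000 ms of the pre-stimulus epoch), `S_onset`, and optional
#'   `env`/`trace` matrices with their time grids.
#' @export
run_trial <- function(cond, c, sched, theta, seed,
                      params = model_parameters(), sustain_ms = 2,
                      keep_env = FALSE, env_bin = 5,
                      keep_traces = FALSE, trace_bin = 10,
                      stop_at_choice = TRUE, S_init = c(0.1, 0.1)) {
  stopifnot(theta > 0, sustain_ms >= 0)
  if (c < 0 || c > 100) stop("coherence must lie in [0, 100] %")
  sustain <- max(1L, as.integer(round(sustain_ms / sched$dt)))
  set.seed(as.integer(seed))
  res <- tryCatch(
    sim_trial_cpp(unclass(params), cond$I0, cond$sigma_noise, c,
                  sched$dt, sched$t_prestim, sched$t_stim,
                  theta, as.integer(sustain), env_bin, trace_bin,
                  keep_env, keep_traces, stop_at_choice,
                  S_init[1], S_init[2]),
    error = function(e) {
      stop("trial failed (condition=", cond$name, ", c=", c, ", seed=", seed,
           "): ", conditionMessage(e))
    })
  choice <- c("undecided", "target", "distractor")[res$choice + 1L]
  out <- list(
    condition = cond$name, coherence = c, seed = as.integer(seed),
    choice = choice,
    decision_time = res$decision_time,
    correct = if (choice == "undecided") NA else choice == "target",
    baseline_rate = res$baseline_rate,
    S_onset = res$S_onset)
  if (keep_env) {
    out$env <- cbind(target = res$env_target, distractor = res$env_distractor)
    out$env_time <- seq_len(nrow(out$env)) * env_bin - env_bin / 2 -
      sched$t_prestim
  }
  if (keep_traces) {
    out$trace <- cbind(target = res$trace_target,
                       distractor = res$trace_distractor)
    out$trace_time <- seq_len(nrow(out$trace)) * trace_bin - trace_bin / 2 -
      sched$t_prestim
  }
  class(out) <- "sat_trial"
  out
}

#' Simulate a full batch of trials over conditions and coherences
#'
#' Runs `n_trials` independent trials for every (condition, coherence) cell
#' under a reproducible per-trial seed scheme derived from `master_seed`
#' (see [trial_seeds()]). By default the integrator also stores, per trial,
#' the within-bin maximum-rate envelope (for paired threshold re-detection,
#' see [threshold_sweep()]) and the binned mean-rate traces (for
#' trial-averaged rates and the ideal-observer analysis).
#'
#' @param conditions named list of [condition_spec()] objects.
#' @param coherences numeric vector of coherences (percent).
#' @param n_trials trials per cell.
#' @param sched an [epoch_schedule()].
#' @param theta choice threshold (Hz).
#' @param master_seed integer master seed.
#' @param params a [model_parameters()].
#' @param keep_env,env_bin,keep_traces,trace_bin,sustain_ms see
#'   [run_trial()].
#' @param verbose print per-cell progress (trial counts, undecided trials).
#' @return A list of class `"sat_batch"`: `records` (one-row-per-trial
#'   data frame), `cells` (per-cell envelope/trace arrays), `env_time`,
#'   `trace_time` (ms, stimulus onset at 0), and the batch settings.
#' @export
run_batch <- function(conditions, coherences, n_trials, sched, theta,
                      master_seed, params = model_parameters(),
                      keep_env = TRUE, env_bin = 5,
                      keep_traces = TRUE, trace_bin = 10,
                      sustain_ms = 2, verbose = FALSE) {
  stopifnot(n_trials >= 1)
  seeds <- trial_seeds(master_seed, length(conditions), length(coherences),
                       n_trials)
  recs <- vector("list", length(conditions) * length(coherences))
  cells <- list()
  env_time <- trace_time <- NULL
  idx <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    for (ki in seq_along(coherences)) {
      cc <- coherences[ki]
      et <- dt_ <- ch <- bl <- numeric(n_trials)
      s1o <- s2o <- numeric(n_trials)
      env_t <- env_d <- tr_t <- tr_d <- NULL
      for (tr in seq_len(n_trials)) {
        trial <- run_trial(cond, cc, sched, theta, seeds[ci, ki, tr],
                           params, sustain_ms, keep_env, env_bin,
                           keep_traces, trace_bin,
                           stop_at_choice = !(keep_env || keep_traces))
        ch[tr] <- match(trial$choice, c("undecided", "target", "distractor"))
        dt_[tr] <- if (is.na(trial$decision_time)) NA_real_ else trial$decision_time
        bl[tr] <- trial$baseline_rate
        s1o[tr] <- trial$S_onset[1]; s2o[tr] <- trial$S_onset[2]
        if (keep_env) {
          if (is.null(env_t)) {
            env_t <- matrix(0, n_trials, nrow(trial$env))
            env_d <- matrix(0, n_trials, nrow(trial$env))
            env_time <- trial$env_time
          }
          env_t[tr, ] <- trial$env[, "target"]
          env_d[tr, ] <- trial$env[, "distractor"]
        }
        if (keep_traces) {
          if (is.null(tr_t)) {
            tr_t <- matrix(0, n_trials, nrow(trial$trace))
            tr_d <- matrix(0, n_trials, nrow(trial$trace))
            trace_time <- trial$trace_time
          }
          tr_t[tr, ] <- trial$trace[, "target"]
          tr_d[tr, ] <- trial$trace[, "distractor"]
        }
      }
      choice <- c("undecided", "target", "distractor")[ch]
      idx <- idx + 1L
      recs[[idx]] <- data.frame(
        condition = cond$name, coherence = cc, trial = seq_len(n_trials),
        seed = seeds[ci, ki, ], choice = choice,
        decision_time = dt_,
        correct = ifelse(choice == "undecided", NA, choice == "target"),
        baseline_rate = bl, S1_onset = s1o, S2_onset = s2o,
        stringsAsFactors = FALSE)
      cells[[cell_key(cond$name, cc)]] <-
        list(env_target = env_t, env_distractor = env_d,
             trace_target = tr_t, trace_distractor = tr_d)
      if (verbose) {
        message(sprintf("cell %s c=%g%%: %d trials, %d undecided",
                        cond$name, cc, n_trials, sum(choice == "undecided")))
      }
    }
  }
  structure(list(
    records = do.call(rbind, recs), cells = cells,
    env_time = env_time, trace_time = trace_time,
    env_bin = if (keep_env) env_bin else NULL,
    trace_bin = if (keep_traces) trace_bin else NULL,
    conditions = conditions, coherences = coherences,
    n_trials = n_trials, sched = sched, theta = theta,
    master_seed = master_seed, params = params, sustain_ms = sustain_ms
  ), class = "sat_batch")
}

cell_key <- function(condition, coherence) paste(condition, coherence, sep = "|")

#' Trial-averaged firing-rate traces for one cell
#'
#' Mean target and distractor rate over trials, aligned to stimulus onset
#' (t = 0). By convention the average is over correct trials; for c = 0,
#' where "correct" is an arbitrary labelling, choose `which = "all"`.
#'
#' @param batch a [run_batch()] result with traces kept.
#' @param condition,coherence cell selector.
#' @param which `"correct"` (default), `"error"` or `"all"`.
#' @return Data frame `t_ms`, `r_target_hz`, `r_distractor_hz`, `n_trials`.
#' @export
trial_average_traces <- function(batch, condition, coherence,
                                 which = c("correct", "error", "all")) {
  which <- match.arg(which)
  cell <- batch$cells[[cell_key(condition, coherence)]]
  if (is.null(cell$trace_target)) stop("batch was run without keep_traces")
  rec <- batch$records[batch$records$condition == condition &
                         batch$records$coherence == coherence, ]
  keep <- switch(which,
                 correct = which(!is.na(rec$correct) & rec$correct),
                 error = which(!is.na(rec$correct) & !rec$correct),
                 all = seq_len(nrow(rec)))
  if (!length(keep)) stop("no ", which, " trials in cell ", condition,
                          " c=", coherence)
  data.frame(
    t_ms = batch$trace_time,
    r_target_hz = colMeans(cell$trace_target[keep, , drop = FALSE]),
    r_distractor_hz = colMeans(cell$trace_distractor[keep, , drop = FALSE]),
    n_trials = length(keep))
}

#' First-crossing choice detection on rate traces
#'
#' Applies the threshold rule to a pair of rate traces: the first population
#' whose rate reaches `theta` (at or after stimulus onset) determines the
#' choice and decision time; no crossing means undecided.
#'
#' @param target_trace,distractor_trace rate series (Hz).
#' @param theta threshold (Hz).
#' @param times time grid (ms from stimulus onset) matching the traces;
#'   samples with `times < 0` (pre-stimulus) are ignored.
#' @return List with `choice` and `decision_time` (ms; `NA` if undecided).
#' @export
detect_choice <- function(target_trace, distractor_trace, theta,
                          times = seq_along(target_trace)) {
  stopifnot(length(target_trace) == length(distractor_trace),
            length(times) == length(target_trace))
  ok <- times >= 0
  i1 <- which(ok & target_trace >= theta)[1]
  i2 <- which(ok & distractor_trace >= theta)[1]
  if (is.na(i1) && is.na(i2)) {
    return(list(choice = "undecided", decision_time = NA_real_))
  }
  if (is.na(i2) || (!is.na(i1) && i1 < i2)) {
    list(choice = "target", decision_time = times[i1])
  } else if (is.na(i1) || i2 < i1) {
    list(choice = "distractor", decision_time = times[i2])
  } else { # same sample: higher rate wins
    ch <- if (target_trace[i1] >= distractor_trace[i2]) "target" else "distractor"
    list(choice = ch, decision_time = times[i1])
  }
}

#' Baseline firing-rate difference between two record sets
#'
#' Difference of across-trial mean baseline rates (each trial's baseline is
#' the mean rate over the last 1000 ms of the pre-stimulus epoch). Used for
#' the threshold-compensation deltas: `Delta_ns = baseline(speed) -
#' baseline(neutral)` and `Delta_na = baseline(neutral) - baseline(accuracy)`.
#'
#' @param records_A,records_B data frames with a `baseline_rate` column
#'   (e.g. subsets of `batch$records`).
#' @return List with `delta` (Hz), `se` (standard error of the difference),
#'   and the two means.
#' @export
baseline_difference <- function(records_A, records_B) {
  if (!nrow(records_A) || !nrow(records_B)) stop("empty record set")
  mA <- mean(records_A$baseline_rate); mB <- mean(records_B$baseline_rate)
  se <- sqrt(stats::var(records_A$baseline_rate) / nrow(records_A) +
               stats::var(records_B$baseline_rate) / nrow(records_B))
  list(delta = mA - mB, se = se, mean_A = mA, mean_B = mB)
}

#' Per-condition baseline summary and compensation deltas
#'
#' @param batch a [run_batch()] result containing the speed, neutral and
#'   accuracy conditions.
#' @return List with per-condition mean baselines (`means`), standard
#'   errors, and `delta_ns`, `delta_na` (Hz).
#' @export
baseline_deltas <- function(batch) {
  rec <- batch$records
  sub <- function(nm) rec[rec$condition == nm, ]
  ns <- baseline_difference(sub("speed"), sub("neutral"))
  na <- baseline_difference(sub("neutral"), sub("accuracy"))
  means <- tapply(rec$baseline_rate, rec$condition, mean)
  ses <- tapply(rec$baseline_rate, rec$condition,
                function(v) stats::sd(v) / sqrt(length(v)))
  list(means = means, se = ses,
       delta_ns = ns$delta, delta_ns_se = ns$se,
       delta_na = na$delta, delta_na_se = na$se)
}
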