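#' ROC area between two rate samples
#'
#' Probability that a randomly drawn target-population rate exceeds a
#' randomly drawn distractor-population rate, ties counted half. Computed
#' from the rank-sum statistic, equivalent to brute-force pair counting.
#'
#' @param x target-population sample.
#' @param y distractor-population sample.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("empty sample")
  r <- rank(c(x, y))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Time-resolved ideal-observer discriminability
#'
#' For each time bin, the area under the ROC curve comparing the
#' across-trial distribution of target-population rates against
#' distractor-population rates. AUC 0.5 means an ideal observer cannot tell
#' the populations apart; 1 means complete separation.
#'
#' @param target,distractor `n_trials x n_bins` binned rate matrices.
#' @param times bin-centre time grid (ms from stimulus onset).
#' @return Data frame `t_ms`, `auc`.
#' @export
auc_timecourse <- function(target, distractor, times = seq_len(ncol(target))) {
  stopifnot(ncol(target) == ncol(distractor),
            length(times) == ncol(target))
  if (nrow(target) < 2 || nrow(distractor) < 2) {
    stop("need at least 2 trials per population")
  }
  auc <- vapply(seq_len(ncol(target)),
                function(j) roc_auc(target[, j], distractor[, j]),
                numeric(1))
  data.frame(t_ms = times, auc = auc)
}

#' Ideal-observer discrimination time
#'
#' First time at which the AUC reaches the criterion and stays at or above
#' it for `sustain` consecutive bins.
#'
#' @param auc AUC values (or an [auc_timecourse()] data frame).
#' @param times bin times (ms); taken from the data frame if omitted.
#' @param criterion AUC criterion (default 0.75).
#' @param sustain consecutive bins the criterion must hold (default 3).
#' @return Discrimination time (ms), or `NA_real_` if never reached.
#' @export
discrimination_time <- function(auc, times = NULL, criterion = 0.75,
                                sustain = 3L) {
  if (is.data.frame(auc)) {
    if (is.null(times)) times <- auc$t_ms
    auc <- auc$auc
  }
  stopifnot(length(times) == length(auc), sustain >= 1)
  ok <- auc >= criterion
  if (sustain > 1L) {
    run <- stats::filter(as.numeric(ok), rep(1, sustain), sides = 1)
    i <- which(run == sustain)[1] - (sustain - 1L)
  } else {
    i <- which(ok)[1]
  }
  if (is.na(i) || i < 1) NA_real_ else times[i]
}

#' Firing rate at discrimination time and its baseline difference
#'
#' Mean target-population rate at the discrimination time, and that rate
#' minus the baseline rate (the discrimination-baseline difference).
#'
#' @param target `n_trials x n_bins` target-rate matrix.
#' @param times bin times (ms).
#' @param t_disc discrimination time (ms); must not be `NA`.
#' @param baseline baseline rate to subtract (Hz).
#' @return List with `rate` (Hz) and `diff` (Hz).
#' @export
rate_at_discrimination <- function(target, times, t_disc, baseline) {
  if (is.na(t_disc)) stop("discrimination time is absent")
  j <- which.min(abs(times - t_disc))
  rate <- mean(target[, j])
  list(rate = rate, diff = rate - baseline)
}

#' Last intersection of target and distractor traces
#'
#' Alternative read-out of decision time: the latest time at which the
#' (smoothed) target and distractor rates cross during the stimulus epoch.
#' The implied choice is the population with the higher rate after that
#' crossing; if the traces never cross, the initially higher population.
#'
#' @param target,distractor single-trial binned rate traces (Hz).
#' @param times bin times (ms from stimulus onset); pre-stimulus bins are
#'   ignored.
#' @param smooth_ms centred moving-average window (ms); the instantaneous
#'   rates carry fast noise that produces spurious micro-crossings.
#' @param bin_ms trace bin width (ms).
#' @return List with `time` (ms, `NA` if no crossing), `choice` (`"target"`
#'   or `"distractor"`), and `rate` (Hz): the common rate of the two
#'   smoothed traces at the crossing (`NA` if no crossing).
#' @export
last_intersection_time <- function(target, distractor, times,
                                   smooth_ms = 50, bin_ms = 10) {
  k <- max(1L, round(smooth_ms / bin_ms))
  if (k %% 2 == 0) k <- k + 1L
  sm <- function(v) {
    if (k == 1L) return(v)
    as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  }
  st <- sm(target); sd_ <- sm(distractor)
  keep <- times >= 0 & !is.na(st) & !is.na(sd_)
  d <- st[keep] - sd_[keep]
  tt <- times[keep]
  s <- sign(d)
  chg <- which(s[-1] != s[-length(s)] & s[-1] != 0)
  if (!length(chg)) {
    ch <- if (d[1] >= 0) "target" else "distractor"
    return(list(time = NA_real_, choice = ch, rate = NA_real_))
  }
  i <- chg[length(chg)]
  # linear interpolation of the crossing within the bin pair
  w <- d[i] / (d[i] - d[i + 1])
  list(time = tt[i] + w * (tt[i + 1] - tt[i]),
       choice = if (d[i + 1] > 0) "target" else "distractor",
       rate = (1 - w) * (st[keep][i] + sd_[keep][i]) / 2 +
         w * (st[keep][i + 1] + sd_[keep][i + 1]) / 2)
}

#' Ideal-observer summary of a simulated batch
#'
#' Runs the signal-detection analysis on the stored rate traces: per-
#' coherence AUC time courses and discrimination times, the mean target
#' rate at discrimination (pooled across positive coherences as the
#' unweighted mean of per-coherence rates), the discrimination-baseline
#' difference, and the last-intersection alternative read-out.
#'
#' @param batch a [run_batch()] result with traces kept.
#' @param criterion,sustain see [discrimination_time()].
#' @param smooth_ms smoothing window for [last_intersection_time()].
#' @param trials `"all"` (default) computes the AUC over every trial of the
#'   cell; low-coherence cells whose across-trial distributions never
#'   separate (the AUC asymptotes near the accuracy level, below the
#'   criterion) get `t_disc = NA` and drop out of the pooled mean, with the
#'   count reported as `n_coherences`. `"correct"` restricts to correct
#'   trials, as in target-selection analyses of choice-sorted neural data;
#'   the criterion is then reachable at every positive coherence but
#'   discrimination occurs very early, while rates are still near baseline.
#'   The last-intersection read-out always uses all trials.
#' @return List of class `"sat_observer"`: `per_coherence` (data frame),
#'   `pooled` (per-condition rate at discrimination, baseline, difference),
#'   `last_intersection` (per-condition mean separation time/rate, baseline
#'   difference, and concordance of the implied choice with the threshold
#'   choice on decided trials), and `auc` (list of AUC time courses).
#' @export
observer_summary <- function(batch, criterion = 0.75, sustain = 3L,
                             smooth_ms = 50, trials = c("all", "correct")) {
  trials <- match.arg(trials)
  if (is.null(batch$trace_bin)) stop("batch was run without keep_traces")
  times <- batch$trace_time
  stim <- times >= 0
  conds <- names(batch$conditions)
  pos_coh <- batch$coherences[batch$coherences > 0]
  per <- list(); aucs <- list(); pooled <- list(); lastx <- list()
  for (nm in conds) {
    rec_cond <- batch$records[batch$records$condition == nm, ]
    base_cond <- mean(rec_cond$baseline_rate)
    rates <- c()
    li_time <- li_rate <- li_agree <- li_n <- c()
    for (cc in pos_coh) {
      cell <- batch$cells[[cell_key(nm, cc)]]
      rec <- rec_cond[rec_cond$coherence == cc, ]
      use <- if (trials == "correct") {
        which(!is.na(rec$correct) & rec$correct)
      } else {
        seq_len(nrow(rec))
      }
      if (length(use) < 2) {
        stop("fewer than 2 ", trials, " trials in cell ", nm, " c=", cc)
      }
      ac <- auc_timecourse(cell$trace_target[use, stim, drop = FALSE],
                           cell$trace_distractor[use, stim, drop = FALSE],
                           times[stim])
      aucs[[cell_key(nm, cc)]] <- ac
      td <- discrimination_time(ac, criterion = criterion, sustain = sustain)
      base_cc <- mean(rec$baseline_rate)
      if (!is.na(td)) {
        rd <- rate_at_discrimination(cell$trace_target[use, stim, drop = FALSE],
                                     times[stim], td, base_cc)
        rates <- c(rates, rd$rate)
      } else {
        rd <- list(rate = NA_real_, diff = NA_real_)
      }
      per[[length(per) + 1L]] <- data.frame(
        condition = nm, coherence = cc, t_disc_ms = td,
        rate_at_disc_hz = rd$rate, baseline_hz = base_cc,
        disc_baseline_diff_hz = rd$diff)
      # last-intersection read-out, per trial
      for (tr in seq_len(nrow(cell$trace_target))) {
        li <- last_intersection_time(cell$trace_target[tr, ],
                                     cell$trace_distractor[tr, ], times,
                                     smooth_ms, batch$trace_bin)
        li_n <- c(li_n, 1)
        if (!is.na(li$time)) {
          li_time <- c(li_time, li$time)
          li_rate <- c(li_rate, li$rate)
        }
        if (rec$choice[tr] != "undecided") {
          li_agree <- c(li_agree,
                        li$choice == rec$choice[tr])
        }
      }
    }
    pooled[[length(pooled) + 1L]] <- data.frame(
      condition = nm,
      rate_at_disc_hz = mean(rates),
      baseline_hz = base_cond,
      disc_baseline_diff_hz = mean(rates) - base_cond,
      n_coherences = length(rates))
    lastx[[length(lastx) + 1L]] <- data.frame(
      condition = nm,
      mean_time_ms = mean(li_time),
      mean_rate_hz = mean(li_rate),
      rate_baseline_diff_hz = mean(li_rate) - base_cond,
      concordance = mean(li_agree),
      n_crossing = length(li_time), n_trials = length(li_n))
  }
  structure(list(per_coherence = do.call(rbind, per),
                 pooled = do.call(rbind, pooled),
                 last_intersection = do.call(rbind, lastx),
                 auc = aucs, criterion = criterion, sustain = sustain,
                 smooth_ms = smooth_ms),
            class = "sat_observer")
}
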