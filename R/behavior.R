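#' Per-coherence accuracy table
#'
#' Counts correct choices among decided trials for each coherence within a
#' record set. Undecided trials are excluded and reported separately.
#'
#' @param records a data frame with `coherence`, `correct`, `choice` columns
#'   (rows of `batch$records`, typically one condition).
#' @return Data frame `coherence`, `n_correct`, `n_decided`, `n_undecided`,
#'   `accuracy`.
#' @export
accuracy_table <- function(records) {
  if (!nrow(records)) stop("empty record set")
  out <- do.call(rbind, lapply(split(records, records$coherence), function(r) {
    dec <- r[!is.na(r$correct), ]
    data.frame(coherence = r$coherence[1],
               n_correct = sum(dec$correct),
               n_decided = nrow(dec),
               n_undecided = sum(is.na(r$correct)))
  }))
  out <- out[order(out$coherence), ]
  out$accuracy <- out$n_correct / out$n_decided
  rownames(out) <- NULL
  out
}

weibull_p <- function(c, alpha, beta) {
  0.5 + 0.5 * (1 - exp(-(c / alpha)^beta))
}

#' Fit a Weibull psychometric function
#'
#' Binomial maximum-likelihood fit of
#' `P(c) = 0.5 + 0.5 (1 - exp(-(c/alpha)^beta))` to per-coherence accuracy
#' counts. The curve is 0.5 at c = 0 and increases monotonically; the
#' 75%-accuracy coherence follows in closed form,
#' `c75 = alpha (ln 2)^(1/beta)`.
#'
#' @param acc an [accuracy_table()] result (or any data frame with
#'   `coherence`, `n_correct`, `n_decided`).
#' @return List of class `"sat_psychfit"`: `alpha` (% coherence), `beta`,
#'   `c75` (%), `logLik`, `converged`, `data`.
#' @export
fit_psychometric <- function(acc) {
  acc <- acc[acc$n_decided > 0, ]
  if (nrow(acc) < 3) stop("need at least 3 coherence levels with trials")
  obs <- acc$n_correct / acc$n_decided
  pos <- acc$coherence > 0
  if (all(obs[pos] > 0.995) || all(obs[pos] < 0.55)) {
    stop("degenerate psychometric data (accuracies ",
         paste(round(obs, 3), collapse = ", "),
         "): Weibull scale is unidentifiable")
  }
  nll <- function(par) {
    p <- weibull_p(acc$coherence, exp(par[1]), exp(par[2]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(acc$n_correct * log(p) + (acc$n_decided - acc$n_correct) * log(1 - p))
  }
  # start alpha near the coherence closest to 75% observed accuracy
  a0 <- acc$coherence[pos][which.min(abs(obs[pos] - 0.75))]
  if (!length(a0) || a0 <= 0) a0 <- stats::median(acc$coherence[pos])
  fit <- stats::optim(c(log(a0), log(1.5)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  alpha <- exp(fit$par[1]); beta <- exp(fit$par[2])
  structure(list(alpha = alpha, beta = beta,
                 c75 = alpha * log(2)^(1 / beta),
                 logLik = -fit$value, converged = fit$convergence == 0,
                 data = acc),
            class = "sat_psychfit")
}

#' @export
print.sat_psychfit <- function(x, ...) {
  cat(sprintf("Weibull psychometric fit: alpha = %.3f%%, beta = %.3f, c75 = %.3f%%\n",
              x$alpha, x$beta, x$c75))
  invisible(x)
}

#' Chronometric summary of decision times
#'
#' Mean decision time and standard error per (condition, coherence) cell,
#' separately for correct and error trials. Undecided trials are excluded;
#' cell sizes are reported.
#'
#' @param records trial records (rows of `batch$records`).
#' @return Data frame `condition`, `coherence`, `outcome`
#'   (`"correct"`/`"error"`), `n`, `mean_dt_ms`, `se_dt_ms` (`NA` when
#'   n < 2).
#' @export
chronometric_summary <- function(records) {
  if (!nrow(records)) stop("empty record set")
  dec <- records[!is.na(records$correct), ]
  grp <- split(dec, list(dec$condition, dec$coherence, dec$correct),
               drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(r) {
    data.frame(condition = r$condition[1], coherence = r$coherence[1],
               outcome = if (r$correct[1]) "correct" else "error",
               n = nrow(r),
               mean_dt_ms = mean(r$decision_time),
               se_dt_ms = if (nrow(r) >= 2) {
                 stats::sd(r$decision_time) / sqrt(nrow(r))
               } else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$coherence, out$outcome), ]
}

# First-crossing re-detection from running-max envelopes.
# cm_*: n_trials x n_bins running-max matrices over stimulus-epoch bins.
redetect_from_envelopes <- function(cm_t, cm_d, theta, bin_width) {
  nb <- ncol(cm_t)
  b1 <- rowSums(cm_t < theta) + 1L
  b2 <- rowSums(cm_d < theta) + 1L
  choice <- integer(nrow(cm_t)) # 0 undecided
  choice[b1 <= nb & b1 < b2] <- 1L
  choice[b2 <= nb & b2 < b1] <- 2L
  tie <- b1 == b2 & b1 <= nb
  if (any(tie)) { # same bin: the higher running max crossed first
    ti <- which(tie)
    v1 <- cm_t[cbind(ti, b1[ti])]
    v2 <- cm_d[cbind(ti, b2[ti])]
    choice[ti] <- ifelse(v1 >= v2, 1L, 2L)
  }
  dt <- rep(NA_real_, nrow(cm_t))
  dec <- choice > 0L
  bfirst <- pmin(b1, b2)
  dt[dec] <- (bfirst[dec] - 0.5) * bin_width
  list(choice = choice, decision_time = dt)
}

#' Threshold sweep with baseline-difference compensation
#'
#' The threshold-compensation experiment: choices are re-detected from the
#' stored per-trial maximum-rate envelopes for every threshold in
#' `theta_grid`, for each condition both unadjusted and (for speed /
#' accuracy) adjusted by the baseline differences: speed uses
#' `theta + delta_ns`, accuracy uses `theta - delta_na`, neutral is never
#' adjusted. Re-detection from the same trials makes all comparisons paired,
#' so differences between thresholds carry no fresh Monte-Carlo noise. Each
#' entry reports the 75%-accuracy coherence of a Weibull fit and the mean
#' decision time pooled over all decided trials at the probe coherences.
#'
#' @param batch a [run_batch()] result with envelopes kept, covering enough
#'   coherence levels for a psychometric fit.
#' @param theta_grid thresholds (Hz) to evaluate.
#' @param delta_ns,delta_na baseline differences (Hz); computed from the
#'   batch via [baseline_deltas()] when `NULL`.
#' @param probe_coherences coherences at which mean decision times are
#'   tabulated (default 1 and 32%).
#' @return Data frame of class `"sat_sweep"`: one row per (condition,
#'   theta, adjusted) with `theta_applied`, `c75`, `alpha`, `beta`, per-probe
#'   mean decision times, `undecided_frac`, `prestim_cross_frac` (fraction
#'   of trials crossing the applied threshold before stimulus onset;
#'   breakdown flag when > 5%) and `degenerate`. `delta_ns`/`delta_na` are
#'   attached as attributes.
#' @export
threshold_sweep <- function(batch, theta_grid = 9:21,
                            delta_ns = NULL, delta_na = NULL,
                            probe_coherences = c(1, 32)) {
  if (is.null(batch$env_bin)) stop("batch was run without keep_env")
  if (is.null(delta_ns) || is.null(delta_na)) {
    bd <- baseline_deltas(batch)
    if (is.null(delta_ns)) delta_ns <- bd$delta_ns
    if (is.null(delta_na)) delta_na <- bd$delta_na
  }
  stim <- batch$env_time >= 0
  conds <- names(batch$conditions)
  # per-cell running-max envelopes over stimulus bins + pre-stimulus maxima
  cms <- list()
  for (nm in conds) {
    for (cc in batch$coherences) {
      cell <- batch$cells[[cell_key(nm, cc)]]
      cms[[cell_key(nm, cc)]] <- list(
        t = t(apply(cell$env_target[, stim, drop = FALSE], 1, cummax)),
        d = t(apply(cell$env_distractor[, stim, drop = FALSE], 1, cummax)),
        pre_max = pmax(
          apply(cell$env_target[, !stim, drop = FALSE], 1, max),
          apply(cell$env_distractor[, !stim, drop = FALSE], 1, max)))
    }
  }
  eval_entry <- function(cond_name, theta_applied) {
    acc <- data.frame(coherence = batch$coherences, n_correct = NA_integer_,
                      n_decided = NA_integer_)
    dts <- stats::setNames(rep(NA_real_, length(probe_coherences)),
                           probe_coherences)
    dts_se <- dts
    n_all <- n_undec <- 0L
    pre_cross <- 0L
    for (i in seq_along(batch$coherences)) {
      cc <- batch$coherences[i]
      cm <- cms[[cell_key(cond_name, cc)]]
      det <- redetect_from_envelopes(cm$t, cm$d, theta_applied, batch$env_bin)
      dec <- det$choice > 0L
      acc$n_correct[i] <- sum(det$choice == 1L)
      acc$n_decided[i] <- sum(dec)
      n_all <- n_all + length(det$choice)
      n_undec <- n_undec + sum(!dec)
      pre_cross <- pre_cross + sum(cm$pre_max >= theta_applied)
      if (cc %in% probe_coherences && any(dec)) {
        v <- det$decision_time[dec]
        dts[as.character(cc)] <- mean(v)
        dts_se[as.character(cc)] <- if (length(v) >= 2) {
          stats::sd(v) / sqrt(length(v))
        } else NA_real_
      }
    }
    fit <- tryCatch(fit_psychometric(acc), error = function(e) NULL)
    data.frame(
      condition = cond_name, theta_applied = theta_applied,
      c75 = if (is.null(fit)) NA_real_ else fit$c75,
      alpha = if (is.null(fit)) NA_real_ else fit$alpha,
      beta = if (is.null(fit)) NA_real_ else fit$beta,
      dt_c1 = unname(dts[1]), dt_c1_se = unname(dts_se[1]),
      dt_c32 = unname(dts[2]), dt_c32_se = unname(dts_se[2]),
      undecided_frac = n_undec / n_all,
      prestim_cross_frac = pre_cross / n_all,
      degenerate = any(acc$n_decided == 0) || is.null(fit))
  }
  rows <- list()
  for (th in theta_grid) {
    for (nm in conds) {
      adj_delta <- switch(nm, speed = delta_ns, accuracy = -delta_na, 0)
      for (adjusted in c(FALSE, TRUE)) {
        if (adjusted && nm == "neutral") next # neutral is never adjusted
        entry <- eval_entry(nm, th + if (adjusted) adj_delta else 0)
        entry$theta <- th
        entry$adjusted <- adjusted
        rows[[length(rows) + 1L]] <- entry
      }
    }
  }
  out <- do.call(rbind, rows)
  out$breakdown <- out$prestim_cross_frac > 0.05
  attr(out, "delta_ns") <- delta_ns
  attr(out, "delta_na") <- delta_na
  class(out) <- c("sat_sweep", class(out))
  out
}

#' Fraction of the condition-neutral gap closed by threshold adjustment
#'
#' For each measure (c75 and pooled mean decision time at the probe
#' coherences), the fraction of the gap between a condition and neutral that
#' is recovered by adjusting the condition's threshold by its baseline
#' difference: 0 means the adjustment achieved nothing, 1 means it fully
#' reinstated neutral behavior.
#'
#' @param sweep a [threshold_sweep()] result.
#' @param theta nominal threshold (Hz) at which to evaluate.
#' @return Data frame `condition`, `measure`, `unadjusted`, `adjusted`,
#'   `neutral`, `gap_closed`.
#' @export
compensation_summary <- function(sweep, theta = 15) {
  pick <- function(cond, adj, col) {
    v <- sweep[sweep$condition == cond & sweep$theta == theta &
                 sweep$adjusted == adj, col]
    if (!length(v)) NA_real_ else v[1]
  }
  rows <- list()
  for (cond in c("speed", "accuracy")) {
    for (col in c("c75", "dt_c1", "dt_c32")) {
      u <- pick(cond, FALSE, col)
      a <- pick(cond, TRUE, col)
      n <- pick("neutral", FALSE, col)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, measure = col,
        unadjusted = u, adjusted = a, neutral = n,
        gap_closed = (a - u) / (n - u))
    }
  }
  do.call(rbind, rows)
}
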