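# Independent oracles and shared fixtures, built in code.

# Vectorised noise-free drift field over gating-state vectors.
drift_field <- function(S1, S2, c, stim_on, cond, params) {
  stim1 <- if (stim_on) params$J_ext * params$mu0 * (1 + c / 100) else 0
  stim2 <- if (stim_on) params$J_ext * params$mu0 * (1 - c / 100) else 0
  x1 <- params$J_self * S1 - params$J_cross * S2 + cond$I0 + stim1
  x2 <- params$J_self * S2 - params$J_cross * S1 + cond$I0 + stim2
  r1 <- transfer_rate(x1, params)
  r2 <- transfer_rate(x2, params)
  list(f1 = -S1 / params$tau_S + (1 - S1) * params$gamma * r1 * 1e-3,
       f2 = -S2 / params$tau_S + (1 - S2) * params$gamma * r2 * 1e-3)
}

# Brute-force fixed-point oracle: sign-change scan of the two nullclines on
# a dense grid, refined by repeated subgrid bisection. Independent of the
# package's Newton solver.
oracle_fixed_points <- function(cond, c, stim_on, params, n = 2001,
                                refine = 6) {
  g <- seq(0, 1, length.out = n)
  f <- drift_field(rep(g, times = n), rep(g, each = n), c, stim_on, cond,
                   params)
  F1 <- matrix(f$f1, n, n); F2 <- matrix(f$f2, n, n)
  sgn_change <- function(M) {
    a <- M[-n, -n]; b <- M[-1, -n]; cc <- M[-n, -1]; d <- M[-1, -1]
    lo <- pmin(a, b, cc, d); hi <- pmax(a, b, cc, d)
    lo <= 0 & hi >= 0
  }
  cand <- which(sgn_change(F1) & sgn_change(F2), arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(numeric(0), 0, 2))
  h <- g[2] - g[1]
  # f1 is strictly decreasing in S2 (cross-inhibition), so the first
  # nullcline S2 = g1(S1) is found by bisection; the fixed point is then the
  # root of f2(S1, g1(S1)) along that nullcline, also by bisection.
  null1 <- function(S1) {
    lo <- 0; hi <- 1
    flo <- drift_field(S1, lo, c, stim_on, cond, params)$f1
    fhi <- drift_field(S1, hi, c, stim_on, cond, params)$f1
    if (sign(flo) == sign(fhi)) return(NA_real_)
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      fm <- drift_field(S1, mid, c, stim_on, cond, params)$f1
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }
  along <- function(S1) {
    S2 <- null1(S1)
    if (is.na(S2)) return(NA_real_)
    drift_field(S1, S2, c, stim_on, cond, params)$f2
  }
  pts <- matrix(NA_real_, nrow(cand), 2)
  for (i in seq_len(nrow(cand))) {
    lo1 <- g[cand[i, 1]] - h; hi1 <- g[cand[i, 1]] + 2 * h
    flo <- along(lo1); fhi <- along(hi1)
    if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi)) next
    for (k in 1:60) {
      mid <- (lo1 + hi1) / 2
      fm <- along(mid)
      if (sign(fm) == sign(flo)) { lo1 <- mid; flo <- fm } else hi1 <- mid
    }
    S1 <- (lo1 + hi1) / 2
    pts[i, ] <- c(S1, null1(S1))
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (!nrow(pts)) return(pts)
  # cluster duplicates from adjacent candidate cells
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pts))) {
      if (j <= i || !keep[j]) next
      if (max(abs(pts[i, ] - pts[j, ])) < 2e-3) keep[j] <- FALSE
    }
  }
  pts[keep, , drop = FALSE]
}

# Brute-force AUC over all ordered pairs, ties counted half.
brute_auc <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  mean(cmp)
}

# Central finite-difference Jacobian of the drift.
fd_jacobian <- function(S1, S2, c, stim_on, cond, params, h = 1e-6) {
  f <- function(s1, s2) {
    d <- drift_field(s1, s2, c, stim_on, cond, params)
    c(d$f1, d$f2)
  }
  cbind((f(S1 + h, S2) - f(S1 - h, S2)) / (2 * h),
        (f(S1, S2 + h) - f(S1, S2 - h)) / (2 * h))
}

# Small fast-mode schedule for simulator contract tests.
fast_schedule <- function() epoch_schedule(t_prestim = 500, t_stim = 1500,
                                           dt = 0.5)
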