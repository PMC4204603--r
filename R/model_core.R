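#' Population transfer function (f-I curve)
#'
#' Simplified frequency-current relation of the reduced model,
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`. The removable singularity
#' at `a x = b` is filled with its limit `1/d` via a series expansion, so
#' the function is continuous and strictly increasing everywhere.
#'
#' @param x total input current (nA); may be a vector.
#' @param params a [model_parameters()] object.
#' @return Firing rate(s) in Hz, non-negative and finite.
#' @export
transfer_rate <- function(x, params) {
  if (any(!is.finite(x))) {
    stop("non-finite input current: invalid state upstream")
  }
  y <- params$a * x - params$b
  u <- params$d * y
  out <- numeric(length(y))
  small <- abs(u) < 1e-6
  # series of y / (1 - exp(-dy)) about dy = 0
  out[small] <- (1 + 0.5 * u[small] + u[small]^2 / 12) / params$d
  out[!small] <- y[!small] / (1 - exp(-u[!small]))
  out
}

# derivative dH/dx, used by the analytic Jacobian
transfer_rate_deriv <- function(x, params) {
  y <- params$a * x - params$b
  u <- params$d * y
  out <- numeric(length(y))
  small <- abs(u) < 1e-4
  # series: d/dy [ y / (1 - exp(-dy)) ] = 1/2 + dy/6 + O((dy)^3)
  out[small] <- params$a * (0.5 + u[small] / 6)
  e <- exp(-u[!small])
  out[!small] <- params$a * ((1 - e) - y[!small] * params$d * e) / (1 - e)^2
  out
}

#' Total input currents to the two populations
#'
#' Each population receives recurrent self-excitation, cross-inhibition,
#' the nonselective background current, the coherence-scaled stimulus
#' current (when on) and its private noise current:
#' `x1 = J_self S1 - J_cross S2 + I0 + I_stim1 + I_noise1` (symmetric for
#' population 2). Stimulus currents are `J_ext mu0 (1 +/- c/100)`, the `+`
#' going to the target population.
#'
#' @param state list/vector with `S1`, `S2` (gating variables) and
#'   `I_noise1`, `I_noise2` (nA; default 0).
#' @param c coherence in percent, within \[0, 100\].
#' @param stim_on logical; stimulus currents applied?
#' @param cond a [condition_spec()]; supplies `I0`.
#' @param params a [model_parameters()].
#' @return Numeric vector `c(x1, x2)` in nA.
#' @export
input_currents <- function(state, c, stim_on, cond, params) {
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 100) {
    stop("coherence must be a single percentage in [0, 100]")
  }
  S1 <- state$S1; S2 <- state$S2
  In1 <- if (is.null(state$I_noise1)) 0 else state$I_noise1
  In2 <- if (is.null(state$I_noise2)) 0 else state$I_noise2
  stim1 <- if (stim_on) params$J_ext * params$mu0 * (1 + c / 100) else 0
  stim2 <- if (stim_on) params$J_ext * params$mu0 * (1 - c / 100) else 0
  x1 <- params$J_self * S1 - params$J_cross * S2 + cond$I0 + stim1 + In1
  x2 <- params$J_self * S2 - params$J_cross * S1 + cond$I0 + stim2 + In2
  c(x1, x2)
}

#' Drift of the synaptic gating variables
#'
#' `dS_i/dt = -S_i / tau_S + (1 - S_i) gamma H(x_i) * 1e-3` in ms^-1
#' (the `1e-3` converts the Hz rate to per-ms).
#'
#' @inheritParams input_currents
#' @return Numeric vector `c(dS1, dS2)` in ms^-1.
#' @export
drift <- function(state, c, stim_on, cond, params) {
  x <- input_currents(state, c, stim_on, cond, params)
  r <- transfer_rate(x, params)
  S <- c(state$S1, state$S2)
  -S / params$tau_S + (1 - S) * params$gamma * r * 1e-3
}

#' Jacobian of the noise-free drift
#'
#' Analytic partial derivatives of [drift()] with respect to `(S1, S2)`,
#' evaluated with noise currents set to zero. Needed for Newton refinement
#' of fixed points and for the saddle eigenstructure that defines the
#' effective time constant of integration.
#'
#' @param S1,S2 gating variables.
#' @inheritParams input_currents
#' @return 2x2 numeric matrix (ms^-1 per unit S).
#' @export
jacobian <- function(S1, S2, c, stim_on, cond, params) {
  st <- list(S1 = S1, S2 = S2, I_noise1 = 0, I_noise2 = 0)
  x <- input_currents(st, c, stim_on, cond, params)
  r <- transfer_rate(x, params)
  rp <- transfer_rate_deriv(x, params)
  g <- params$gamma * 1e-3
  J <- matrix(0, 2, 2)
  J[1, 1] <- -1 / params$tau_S - g * r[1] + (1 - S1) * g * rp[1] * params$J_self
  J[1, 2] <- (1 - S1) * g * rp[1] * (-params$J_cross)
  J[2, 1] <- (1 - S2) * g * rp[2] * (-params$J_cross)
  J[2, 2] <- -1 / params$tau_S - g * r[2] + (1 - S2) * g * rp[2] * params$J_self
  J
}

#' Noise-free population rates for a gating state
#'
#' Maps `(S1, S2)` to firing rates `(r1, r2)` through the noise-free input
#' currents, with or without the stimulus.
#'
#' @param S1,S2 gating variables (vectors of equal length allowed).
#' @inheritParams input_currents
#' @return Matrix with columns `r1`, `r2` (Hz).
#' @export
state_rates <- function(S1, S2, c, stim_on, cond, params) {
  stim1 <- if (stim_on) params$J_ext * params$mu0 * (1 + c / 100) else 0
  stim2 <- if (stim_on) params$J_ext * params$mu0 * (1 - c / 100) else 0
  x1 <- params$J_self * S1 - params$J_cross * S2 + cond$I0 + stim1
  x2 <- params$J_self * S2 - params$J_cross * S1 + cond$I0 + stim2
  cbind(r1 = transfer_rate(x1, params), r2 = transfer_rate(x2, params))
}
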