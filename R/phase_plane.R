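drift_S <- function(S, c, stim_on, cond, params) {
  drift(list(S1 = S[1], S2 = S[2], I_noise1 = 0, I_noise2 = 0),
        c, stim_on, cond, params)
}

classify_fp <- function(J) {
  e <- eigen(J)
  ev <- e$values
  if (all(abs(Im(ev)) < 1e-12)) {
    ev <- Re(ev)
    if (prod(ev) < 0) return(list(class = "saddle", values = ev,
                                  vectors = Re(e$vectors)))
    if (all(ev < 0)) return(list(class = "stable node", values = ev,
                                 vectors = Re(e$vectors)))
    return(list(class = "unstable", values = ev, vectors = Re(e$vectors)))
  }
  cls <- if (all(Re(ev) < 0)) "stable focus" else "unstable"
  list(class = cls, values = ev, vectors = e$vectors)
}

#' Fixed points of the noise-free system
#'
#' Damped-Newton refinement from a dense grid of initial guesses over the
#' unit square of gating states, followed by deduplication and linear
#' stability classification via the analytic Jacobian.
#'
#' @param cond a [condition_spec()].
#' @param c coherence (percent).
#' @param stim_on logical; stimulus currents applied?
#' @param params a [model_parameters()].
#' @param grid_n seeds per axis (default 21).
#' @param tol Newton convergence tolerance on the drift norm.
#' @return List of fixed points, each with `S` (gating coordinates),
#'   `rates` (Hz), `eigenvalues` (ms^-1), `eigenvectors` (columns), and
#'   `classification` (`"stable node"`, `"stable focus"`, `"saddle"` or
#'   `"unstable"`). Every returned point has drift norm < 1e-9 ms^-1.
#' @export
find_fixed_points <- function(cond, c, stim_on, params = model_parameters(),
                              grid_n = 21, tol = 1e-12) {
  seeds <- as.matrix(expand.grid(S1 = seq(0, 1, length.out = grid_n),
                                 S2 = seq(0, 1, length.out = grid_n)))
  found <- list()
  for (i in seq_len(nrow(seeds))) {
    S <- seeds[i, ]
    f <- drift_S(S, c, stim_on, cond, params)
    ok <- FALSE
    for (it in 1:100) {
      nf <- sqrt(sum(f^2))
      if (nf < tol) { ok <- TRUE; break }
      J <- jacobian(S[1], S[2], c, stim_on, cond, params)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        Snew <- S + lam * step
        fnew <- drift_S(Snew, c, stim_on, cond, params)
        if (sqrt(sum(fnew^2)) < nf || lam < 1e-4) break
        lam <- lam / 2
      }
      S <- Snew; f <- fnew
      if (any(S < -0.5) || any(S > 1.5)) break
    }
    if (!ok || any(S < -1e-9) || any(S > 1 + 1e-9)) next
    if (sqrt(sum(drift_S(S, c, stim_on, cond, params)^2)) >= 1e-9) next
    dup <- any(vapply(found, function(p) max(abs(p$S - S)) < 1e-6, logical(1)))
    if (dup) next
    J <- jacobian(S[1], S[2], c, stim_on, cond, params)
    cl <- classify_fp(J)
    found[[length(found) + 1L]] <- list(
      S = unname(S),
      rates = unname(state_rates(S[1], S[2], c, stim_on, cond, params)[1, ]),
      eigenvalues = cl$values, eigenvectors = cl$vectors,
      classification = cl$class)
  }
  if (!length(found)) {
    stop("no fixed points found from a ", grid_n, "x", grid_n,
         " seeding grid (condition=", cond$name, ", c=", c,
         ", stim_on=", stim_on, ")")
  }
  # deterministic order: by S1 then S2
  ord <- order(vapply(found, function(p) p$S[1], numeric(1)),
               vapply(found, function(p) p$S[2], numeric(1)))
  found[ord]
}

#' Select the decision saddle from a fixed-point list
#'
#' The saddle separating the two choice attractors; at low coherence it lies
#' close to the symmetric diagonal, so among saddle points the one with the
#' smallest |S1 - S2| is returned.
#'
#' @param fps result of [find_fixed_points()].
#' @return A single fixed point with classification `"saddle"`.
#' @export
select_saddle <- function(fps) {
  sad <- Filter(function(p) p$classification == "saddle", fps)
  if (!length(sad)) stop("no saddle point in the fixed-point set")
  asym <- vapply(sad, function(p) abs(p$S[1] - p$S[2]), numeric(1))
  sad[[which.min(asym)]]
}

stable_attractors <- function(fps) {
  Filter(function(p) startsWith(p$classification, "stable"), fps)
}

#' Effective time constant of integration
#'
#' Reciprocal of the saddle's positive (repelling) eigenvalue: the time
#' constant of the unstable manifold, which sets how long the network can
#' integrate evidence before it is committed to an attractor.
#'
#' @param saddle a fixed point classified as a saddle.
#' @return Time constant in ms.
#' @export
effective_time_constant <- function(saddle) {
  if (saddle$classification != "saddle") {
    stop("effective_time_constant() requires a saddle point")
  }
  lam <- Re(saddle$eigenvalues)
  1 / lam[lam > 0][1]
}

#' Trace the stable and unstable manifolds of the saddle
#'
#' The unstable manifold is obtained by forward integration of the
#' noise-free flow from the saddle displaced by `eps` along each direction
#' of the unstable eigenvector (each branch ends at a choice attractor).
#' The stable manifold is obtained by integrating the time-reversed flow
#' from displacements along the stable eigenvector; branches are truncated
#' at the boundary of the unit square of gating states. Both polylines are
#' returned in gating coordinates and mapped to rate space.
#'
#' @param saddle the decision saddle (see [select_saddle()]).
#' @param cond,c,params system specification (stimulus-on flow).
#' @param stim_on logical (default TRUE, the decision landscape).
#' @param attractors stable fixed points used to terminate the unstable
#'   branches; found automatically if `NULL`.
#' @param eps eigenvector displacement for seeding (gating units).
#' @param delta termination distance to an attractor (gating units).
#' @param s_max maximum arclength per branch (gating units).
#' @param ds output spacing of the polylines (arclength, gating units).
#' @return List of class `"sat_manifolds"`: `stable` and `unstable`, each
#'   with `S` and `rates` polyline matrices (the saddle is an interior
#'   vertex), plus `truncated` flags.
#' @details Branches are integrated in arclength parameterisation
#'   (`dS/ds = +/- F(S)/|F(S)|`), which keeps the step size uniform through
#'   the slow regions near equilibria and saddle-node ghosts; integration
#'   stops, via root detection, at an attractor (unstable branches), at a
#'   vanishing vector field, or at the boundary of the unit square.
#' @export
trace_manifolds <- function(saddle, cond, c, params = model_parameters(),
                            stim_on = TRUE, attractors = NULL,
                            eps = 1e-4, delta = 1e-3, s_max = 4,
                            ds = 0.001) {
  if (saddle$classification != "saddle") stop("not a saddle point")
  if (is.null(attractors)) {
    attractors <- stable_attractors(
      find_fixed_points(cond, c, stim_on, params))
  }
  lam <- Re(saddle$eigenvalues)
  vu <- Re(saddle$eigenvectors[, which.max(lam)])
  vs <- Re(saddle$eigenvectors[, which.min(lam)])
  vu <- vu / sqrt(sum(vu^2)); vs <- vs / sqrt(sum(vs^2))

  unit_flow <- function(s, S, parms, sgn) {
    f <- drift_S(S, c, stim_on, cond, params)
    list(sgn * f / max(sqrt(sum(f^2)), 1e-14))
  }
  root_fn <- function(s, S, parms, sgn) {
    f <- drift_S(S, c, stim_on, cond, params)
    roots <- c(sqrt(sum(f^2)) - 1e-11,          # true equilibrium
               S[1] + 1e-6, 1 + 1e-6 - S[1],    # domain boundary
               S[2] + 1e-6, 1 + 1e-6 - S[2])
    if (sgn > 0 && length(attractors)) {
      dmin <- min(vapply(attractors, function(att)
        sqrt(sum((S - att$S)^2)), numeric(1)))
      roots <- c(roots, dmin - delta)           # reached an attractor
    }
    roots
  }
  run_branch <- function(start, sgn) {
    sol <- deSolve::lsodar(y = start, times = seq(0, s_max, by = ds),
                           func = unit_flow, parms = NULL, sgn = sgn,
                           rootfunc = root_fn,
                           rtol = 1e-9, atol = 1e-11)
    S <- unname(sol[, 2:3, drop = FALSE])
    hit_att <- FALSE
    if (sgn > 0 && length(attractors)) {
      endd <- min(vapply(attractors, function(att)
        sqrt(sum((S[nrow(S), ] - att$S)^2)), numeric(1)))
      hit_att <- endd <= delta * 1.01
    }
    list(S = S, converged = if (sgn > 0) hit_att else TRUE)
  }
  assemble <- function(b_minus, b_plus) {
    S <- rbind(b_minus$S[rev(seq_len(nrow(b_minus$S))), , drop = FALSE],
               saddle$S,
               b_plus$S)
    # drop consecutive duplicates
    keep <- c(TRUE, rowSums(abs(diff(S))) > 1e-12)
    S <- S[keep, , drop = FALSE]
    list(S = S,
         rates = state_rates(S[, 1], S[, 2], c, stim_on, cond, params))
  }
  up <- run_branch(saddle$S + eps * vu, +1)
  um <- run_branch(saddle$S - eps * vu, +1)
  sp <- run_branch(saddle$S + eps * vs, -1)
  sm <- run_branch(saddle$S - eps * vs, -1)
  structure(list(
    unstable = assemble(um, up),
    stable = assemble(sm, sp),
    truncated = list(unstable = !(up$converged && um$converged))
  ), class = "sat_manifolds")
}

#' Minimal distance from a point to a polyline
#'
#' Exact point-to-segment minimisation over every segment of the polyline.
#'
#' @param point numeric length-2 point.
#' @param polyline two-column matrix of vertices.
#' @return Minimal Euclidean distance (same units as the inputs).
#' @export
point_polyline_distance <- function(point, polyline) {
  if (is.null(polyline) || nrow(polyline) == 0) stop("empty polyline")
  if (nrow(polyline) == 1) {
    return(sqrt(sum((point - polyline[1, ])^2)))
  }
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  ab <- b - a
  ap <- cbind(point[1] - a[, 1], point[2] - a[, 2])
  denom <- rowSums(ab^2)
  t <- ifelse(denom > 0, pmin(1, pmax(0, rowSums(ap * ab) / denom)), 0)
  proj <- a + ab * t
  min(sqrt((point[1] - proj[, 1])^2 + (point[2] - proj[, 2])^2))
}

#' Distance from the network's initial state to the stable manifold
#'
#' The stable manifold of the decision saddle is the basin boundary whose
#' crossing by noise produces errors; the closer the initial (end of
#' pre-stimulus) state sits to it, the more error-prone the condition.
#' Distance is measured in rate space (Hz), the coordinate system of the
#' decision-space figures.
#'
#' @param portrait a [phase_portrait()] result (or any list with
#'   `manifolds$stable$rates`).
#' @param initial_state length-2 rate-space point (Hz); defaults to the
#'   portrait's own initial state.
#' @return Distance in Hz.
#' @export
initial_state_distance <- function(portrait, initial_state = portrait$initial_state$rates) {
  poly <- portrait$manifolds$stable$rates
  if (is.null(poly) || !nrow(poly)) stop("empty stable-manifold polyline")
  point_polyline_distance(as.numeric(initial_state), poly)
}

#' Spontaneous (pre-stimulus) network state
#'
#' The low-rate stable fixed point of the stimulus-off system around which
#' baseline activity fluctuates.
#'
#' @param cond a [condition_spec()].
#' @param params a [model_parameters()].
#' @return List with `S` and `rates` (Hz, stimulus-off mapping).
#' @export
spontaneous_state <- function(cond, params = model_parameters()) {
  fps <- find_fixed_points(cond, 0, FALSE, params)
  st <- stable_attractors(fps)
  if (!length(st)) stop("no stable fixed point in the stimulus-off system")
  nrm <- vapply(st, function(p) sum(p$S^2), numeric(1))
  low <- st[[which.min(nrm)]]
  list(S = low$S, rates = low$rates)
}

#' Full phase portrait for one condition and coherence
#'
#' Combines fixed points, saddle selection, the effective time constant,
#' manifold polylines, and the initial-state geometry into one object.
#'
#' The initial state is the network state at the end of the pre-stimulus
#' epoch. By default it is the spontaneous fixed point of the stimulus-off
#' system; supply `S_init` (e.g. the across-trial mean gating state at
#' stimulus onset from [run_batch()]) to use a simulated estimate. It is
#' mapped to rates both with stimulus-off currents (`rates`, the activity
#' actually observed before evidence onset, used for the distance) and with
#' stimulus-on currents (`rates_stim_on`), since the manifolds are those of
#' the stimulus-on landscape the network lands on at evidence onset.
#'
#' @param cond a [condition_spec()].
#' @param c coherence (percent) of the stimulus-on landscape.
#' @param params a [model_parameters()].
#' @param S_init optional length-2 gating state overriding the spontaneous
#'   fixed point.
#' @param ... passed to [trace_manifolds()].
#' @return A list of class `"sat_portrait"`: `fixed_points`, `saddle`,
#'   `tau_eff` (ms), `manifolds`, `initial_state`, `init_distance` (Hz).
#' @export
phase_portrait <- function(cond, c, params = model_parameters(),
                           S_init = NULL, ...) {
  fps <- find_fixed_points(cond, c, TRUE, params)
  saddle <- select_saddle(fps)
  tau_eff <- effective_time_constant(saddle)
  man <- trace_manifolds(saddle, cond, c, params, stim_on = TRUE,
                         attractors = stable_attractors(fps), ...)
  if (is.null(S_init)) {
    S_init <- spontaneous_state(cond, params)$S
  }
  init <- list(
    S = S_init,
    rates = unname(state_rates(S_init[1], S_init[2], 0, FALSE, cond,
                               params)[1, ]),
    rates_stim_on = unname(state_rates(S_init[1], S_init[2], c, TRUE, cond,
                                       params)[1, ]))
  out <- list(fixed_points = fps, saddle = saddle, tau_eff = tau_eff,
              manifolds = man, initial_state = init,
              condition = cond$name, coherence = c)
  out$init_distance <- initial_state_distance(out, init$rates)
  class(out) <- "sat_portrait"
  out
}
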