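p <- model_parameters()
conds <- default_conditions()

test_that("fixed points match the grid-scan oracle one to one", {
  for (nm in names(conds)) {
    fps <- find_fixed_points(conds[[nm]], 4, TRUE, p)
    pts <- t(vapply(fps, function(f) f$S, numeric(2)))
    orc <- oracle_fixed_points(conds[[nm]], 4, TRUE, p)
    expect_equal(nrow(orc), nrow(pts))
    # each oracle point has exactly one Newton point within 1e-4
    for (i in seq_len(nrow(orc))) {
      d <- sqrt((pts[, 1] - orc[i, 1])^2 + (pts[, 2] - orc[i, 2])^2)
      expect_equal(sum(d < 1e-4), 1)
    }
  }
})

test_that("every fixed point satisfies the drift tolerance", {
  for (stim in c(TRUE, FALSE)) {
    fps <- find_fixed_points(conds$neutral, 4, stim, p)
    for (f in fps) {
      d <- drift(list(S1 = f$S[1], S2 = f$S[2], I_noise1 = 0, I_noise2 = 0),
                 4, stim, conds$neutral, p)
      expect_lt(sqrt(sum(d^2)), 1e-9)
    }
  }
})

test_that("the zero-coherence fixed-point set has the swap symmetry", {
  fps <- find_fixed_points(conds$neutral, 0, TRUE, p)
  pts <- t(vapply(fps, function(f) f$S, numeric(2)))
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((pts[, 1] - pts[i, 2])^2 + (pts[, 2] - pts[i, 1])^2)
    expect_lt(min(d), 1e-6) # the mirror point is also in the set
  }
  sad <- select_saddle(fps)
  expect_lt(abs(sad$S[1] - sad$S[2]), 1e-8)
})

test_that("classification matches the eigenstructure", {
  fps <- find_fixed_points(conds$neutral, 4, TRUE, p)
  for (f in fps) {
    ev <- f$eigenvalues
    if (f$classification == "saddle") {
      expect_true(all(Im(ev) == 0) && prod(Re(ev)) < 0)
    } else if (startsWith(f$classification, "stable")) {
      expect_true(all(Re(ev) < 0))
    }
  }
})

test_that("effective time constant is the reciprocal repelling eigenvalue", {
  fake <- list(classification = "saddle", eigenvalues = c(0.005, -0.002))
  expect_equal(effective_time_constant(fake), 200)
  not_saddle <- list(classification = "stable node",
                     eigenvalues = c(-0.01, -0.002))
  expect_error(effective_time_constant(not_saddle), "saddle")
})

test_that("saddle eigenvalue agrees with a finite-difference Jacobian", {
  sad <- select_saddle(find_fixed_points(conds$neutral, 4, TRUE, p))
  Jfd <- fd_jacobian(sad$S[1], sad$S[2], 4, TRUE, conds$neutral, p)
  lam_fd <- max(Re(eigen(Jfd)$values))
  lam <- max(Re(sad$eigenvalues))
  expect_lt(abs(lam - lam_fd) / lam, 1e-3)
})

test_that("unstable manifold branches terminate at the choice attractors", {
  fps <- find_fixed_points(conds$neutral, 4, TRUE, p)
  sad <- select_saddle(fps)
  att <- Filter(function(f) startsWith(f$classification, "stable"), fps)
  man <- trace_manifolds(sad, conds$neutral, 4, p, attractors = att)
  expect_false(man$truncated$unstable)
  ends <- man$unstable$S[c(1, nrow(man$unstable$S)), ]
  for (i in 1:2) {
    d <- min(vapply(att, function(a) sqrt(sum((ends[i, ] - a$S)^2)),
                    numeric(1)))
    expect_lt(d, 2e-3)
  }
})

test_that("the drift is tangent to the manifold polylines", {
  fps <- find_fixed_points(conds$neutral, 4, TRUE, p)
  sad <- select_saddle(fps)
  man <- trace_manifolds(sad, conds$neutral, 4, p,
                         attractors = Filter(function(f)
                           startsWith(f$classification, "stable"), fps))
  check_tangency <- function(S) {
    n <- nrow(S)
    idx <- seq(50, n - 50, by = 100)
    for (i in idx) {
      seg <- S[i + 1, ] - S[i - 1, ]
      seg <- seg / sqrt(sum(seg^2))
      f <- drift_field(S[i, 1], S[i, 2], 4, TRUE, conds$neutral, p)
      v <- c(f$f1, f$f2); v <- v / sqrt(sum(v^2))
      ang <- acos(pmin(1, abs(sum(seg * v)))) * 180 / pi
      expect_lt(ang, 1)
    }
  }
  check_tangency(man$unstable$S)
  check_tangency(man$stable$S)
})

test_that("point-to-polyline distance is exact on constructed cases", {
  poly <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(point_polyline_distance(c(0.5, 0), poly), 0)
  expect_equal(point_polyline_distance(c(0.5, 0.3), poly), 0.3)
  expect_equal(point_polyline_distance(c(2, 2), poly), sqrt(2))
  expect_error(point_polyline_distance(c(0, 0), poly[0, , drop = FALSE]),
               "empty")
})

test_that("initial-state distance agrees with a densified-polyline scan", {
  pp <- phase_portrait(conds$neutral, 4, p)
  poly <- pp$manifolds$stable$rates
  dense <- do.call(rbind, lapply(seq_len(nrow(poly) - 1), function(i) {
    w <- seq(0, 1, length.out = 11)[-11]
    cbind(poly[i, 1] * (1 - w) + poly[i + 1, 1] * w,
          poly[i, 2] * (1 - w) + poly[i + 1, 2] * w)
  }))
  pt <- pp$initial_state$rates
  d_scan <- min(sqrt((dense[, 1] - pt[1])^2 + (dense[, 2] - pt[2])^2))
  expect_lt(abs(pp$init_distance - d_scan) / d_scan, 0.01)
  # a vertex of the polyline itself is at distance zero
  expect_equal(initial_state_distance(pp, poly[100, ]), 0, tolerance = 1e-12)
})

test_that("the spontaneous state is a low-rate attractor below threshold", {
  for (nm in names(conds)) {
    s <- spontaneous_state(conds[[nm]], p)
    expect_true(all(s$rates < 15))
    expect_true(all(s$rates > 0))
  }
})
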