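p <- model_parameters()
neutral <- condition_spec("neutral", 0.321)

test_that("transfer function fills the removable singularity with 1/d", {
  x0 <- p$b / p$a
  expect_equal(transfer_rate(x0, p), 1 / p$d, tolerance = 1e-10)
  expect_lt(abs(transfer_rate(x0 + 1e-9, p) - 1 / p$d), 1e-4)
  expect_lt(abs(transfer_rate(x0 - 1e-9, p) - 1 / p$d), 1e-4)
})

test_that("transfer function has the right asymptotes", {
  # linear regime a*x >> b: H ~ a*x - b
  expect_equal(transfer_rate(1.0, p), p$a * 1.0 - p$b, tolerance = 1e-6)
  # at zero current the rate is positive but vanishingly small
  expect_gt(transfer_rate(0, p), 0)
  expect_lt(transfer_rate(0, p), 1e-4)
})

test_that("transfer function is strictly increasing and rejects bad input", {
  x <- seq(0, 1.5, length.out = 1000)
  expect_true(all(diff(transfer_rate(x, p)) > 0))
  expect_error(transfer_rate(NaN, p), "non-finite")
  expect_error(transfer_rate(Inf, p), "non-finite")
})

test_that("input currents obey symmetry and their formula endpoints", {
  st <- list(S1 = 0.15, S2 = 0.15, I_noise1 = 0.003, I_noise2 = 0.003)
  x <- input_currents(st, 0, TRUE, neutral, p)
  expect_identical(x[1], x[2])
  # full coherence routes all stimulus current to the target
  st0 <- list(S1 = 0.1, S2 = 0.1, I_noise1 = 0, I_noise2 = 0)
  x100 <- input_currents(st0, 100, TRUE, neutral, p)
  x_off <- input_currents(st0, 100, FALSE, neutral, p)
  expect_equal(x100[1] - x_off[1], 2 * p$J_ext * p$mu0)
  expect_equal(x100[2] - x_off[2], 0)
  expect_error(input_currents(st0, -1, TRUE, neutral, p), "coherence")
  expect_error(input_currents(st0, 101, TRUE, neutral, p), "coherence")
})

test_that("input currents match an independent hand calculation", {
  # x1 = 0.2609*0.1 - 0.0497*0.2 + 0.321, x2 = 0.2609*0.2 - 0.0497*0.1 + 0.321
  st <- list(S1 = 0.1, S2 = 0.2, I_noise1 = 0, I_noise2 = 0)
  x <- input_currents(st, 0, FALSE, neutral, p)
  expect_equal(x[1], 0.33715, tolerance = 1e-12)
  expect_equal(x[2], 0.36821, tolerance = 1e-12)
})

test_that("drift has the saturation and empty-gating limits", {
  st1 <- list(S1 = 1, S2 = 1, I_noise1 = 0, I_noise2 = 0)
  d1 <- drift(st1, 0, FALSE, neutral, p)
  expect_equal(d1, rep(-1 / p$tau_S, 2))
  # S = 0 with input current ~ 0 gives H ~ 0 and so drift ~ 0
  low <- condition_spec("low", 1e-4)
  st0 <- list(S1 = 0, S2 = 0, I_noise1 = 0, I_noise2 = 0)
  expect_lt(max(abs(drift(st0, 0, FALSE, low, p))), 1e-6)
})

test_that("swapping populations swaps the drift exactly at zero coherence", {
  st <- list(S1 = 0.31, S2 = 0.12, I_noise1 = 0.004, I_noise2 = -0.002)
  sw <- list(S1 = 0.12, S2 = 0.31, I_noise1 = -0.002, I_noise2 = 0.004)
  expect_identical(drift(st, 0, TRUE, neutral, p),
                   rev(drift(sw, 0, TRUE, neutral, p)))
})

test_that("analytic Jacobian matches central finite differences", {
  probes <- rbind(c(0.1, 0.1), c(0.3, 0.2), c(0.05, 0.7), c(0.5, 0.5),
                  c(0.9, 0.05))
  for (cc in c(0, 4, 32)) {
    for (i in seq_len(nrow(probes))) {
      J <- jacobian(probes[i, 1], probes[i, 2], cc, TRUE, neutral, p)
      Jfd <- fd_jacobian(probes[i, 1], probes[i, 2], cc, TRUE, neutral, p)
      expect_lt(max(abs(J - Jfd)), 1e-5)
    }
  }
})

test_that("Jacobian reflects the system's exchange symmetry on the diagonal", {
  J <- jacobian(0.2, 0.2, 0, TRUE, neutral, p)
  expect_equal(J[1, 1], J[2, 2])
  expect_equal(J[1, 2], J[2, 1])
})

test_that("parameter validation enforces the physical constraints", {
  expect_error(model_parameters(tau_noise = 200), "tau_noise")
  expect_error(model_parameters(I0 = 321), "I0")
  expect_error(model_parameters(a = -1), "positive")
  expect_error(condition_spec("x", 316), "I0")
  expect_error(epoch_schedule(2500, 5000, dt = 0.3), "multiples")
})
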