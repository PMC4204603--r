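p <- model_parameters()
conds <- default_conditions()
noiseless <- lapply(conds, function(cc) condition_spec(cc$name, cc$I0, 0))

test_that("noiseless trials are deterministic and choose the target", {
  sched <- epoch_schedule()
  t1 <- run_trial(noiseless$neutral, 8, sched, 15, seed = 1, p)
  t2 <- run_trial(noiseless$neutral, 8, sched, 15, seed = 999, p)
  expect_identical(t1$choice, "target")
  expect_identical(t1$decision_time, t2$decision_time)
  expect_true(t1$decision_time > 0 && t1$decision_time <= sched$t_stim)
})

test_that("noiseless zero-coherence trials stay symmetric and undecided", {
  sched <- epoch_schedule()
  tr <- run_trial(noiseless$neutral, 0, sched, 15, seed = 1, p,
                  keep_traces = TRUE, trace_bin = 10)
  expect_identical(tr$choice, "undecided")
  expect_true(is.na(tr$decision_time))
  expect_equal(tr$trace[, "target"], tr$trace[, "distractor"])
})

test_that("compiled integrator reproduces the R drift step for step", {
  # noise-free Euler in plain R vs the compiled path, fine-grained traces
  sched <- epoch_schedule(t_prestim = 50, t_stim = 100, dt = 0.5)
  tr <- run_trial(noiseless$neutral, 16, sched, 1e6, seed = 1, p,
                  keep_traces = TRUE, trace_bin = 0.5)
  n <- (sched$t_prestim + sched$t_stim) / sched$dt
  S <- c(0.1, 0.1); r_ref <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    on <- (k - 1) * sched$dt >= sched$t_prestim
    st <- list(S1 = S[1], S2 = S[2], I_noise1 = 0, I_noise2 = 0)
    x <- input_currents(st, 16, on, noiseless$neutral, p)
    r_ref[k, ] <- transfer_rate(x, p)
    S <- pmin(1, pmax(0, S + sched$dt * drift(st, 16, on, noiseless$neutral, p)))
  }
  expect_equal(unname(tr$trace[, "target"]), r_ref[, 1], tolerance = 1e-12)
  expect_equal(unname(tr$trace[, "distractor"]), r_ref[, 2], tolerance = 1e-12)
})

test_that("choice detection applies the first-crossing rule", {
  t <- seq(0, 1000, by = 10)
  rising <- pmin(30, 0.025 * t)       # crosses 15 Hz at t = 600
  flat <- rep(5, length(t))
  expect_equal(detect_choice(rising, flat, 15, t),
               list(choice = "target", decision_time = 600))
  expect_equal(detect_choice(flat, flat, 15, t)$choice, "undecided")
  early <- pmin(30, 0.05 * t)         # crosses 15 Hz at t = 300
  d <- detect_choice(rising, early, 15, t)
  expect_equal(d$choice, "distractor")
  expect_equal(d$decision_time, 300)
})

test_that("batches are exactly reproducible and complete", {
  sched <- fast_schedule()
  b1 <- run_batch(conds[c("speed", "neutral")], c(0, 16), 3, sched, 15, 42, p)
  b2 <- run_batch(conds[c("speed", "neutral")], c(0, 16), 3, sched, 15, 42, p)
  expect_identical(b1$records, b2$records)
  expect_identical(b1$cells, b2$cells)
  expect_equal(nrow(b1$records), 2 * 2 * 3)
  expect_equal(as.vector(table(b1$records$condition)), c(6, 6))
  b3 <- run_batch(conds["neutral"], 16, 1, sched, 15, 1, p,
                  keep_env = FALSE, keep_traces = FALSE)
  expect_equal(nrow(b3$records), 1)
})

test_that("single trials can be reproduced in isolation from the seed table", {
  sched <- fast_schedule()
  b <- run_batch(conds["neutral"], c(0, 16), 4, sched, 15, 7, p,
                 keep_env = FALSE, keep_traces = FALSE)
  seeds <- trial_seeds(7, 1, 2, 4)
  tr <- run_trial(conds$neutral, 16, sched, 15, seeds[1, 2, 3], p)
  rec <- b$records[b$records$coherence == 16 & b$records$trial == 3, ]
  expect_identical(tr$choice, rec$choice)
  expect_identical(tr$baseline_rate, rec$baseline_rate)
})

test_that("baseline difference is zero for identical sets and errors when empty", {
  r <- data.frame(baseline_rate = c(1.5, 2.1, 1.9))
  expect_equal(baseline_difference(r, r)$delta, 0)
  expect_error(baseline_difference(r[0, , drop = FALSE], r), "empty")
})

test_that("undecided trials carry no decision time or correctness", {
  sched <- epoch_schedule(t_prestim = 500, t_stim = 200, dt = 0.5)
  # very high threshold: nothing can cross within a 200 ms stimulus
  b <- run_batch(conds["accuracy"], 4, 5, sched, 60, 3, p,
                 keep_env = FALSE, keep_traces = FALSE)
  expect_true(all(b$records$choice == "undecided"))
  expect_true(all(is.na(b$records$decision_time)))
  expect_true(all(is.na(b$records$correct)))
})
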