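p <- model_parameters()
conds <- default_conditions()

test_that("accuracy table counts decided and undecided trials", {
  rec <- data.frame(
    coherence = c(4, 4, 4, 8, 8),
    choice = c("target", "distractor", "undecided", "target", "target"),
    correct = c(TRUE, FALSE, NA, TRUE, TRUE))
  tab <- accuracy_table(rec)
  expect_equal(tab$n_decided, c(2, 2))
  expect_equal(tab$n_undecided, c(1, 0))
  expect_equal(tab$accuracy, c(0.5, 1))
})

test_that("Weibull curve has its closed-form landmarks", {
  # P(alpha) = 0.5 + 0.5 (1 - 1/e); c75 = alpha (ln 2)^(1/beta)
  acc <- data.frame(coherence = c(0, 1, 2, 4, 8, 16, 32))
  n <- 1e6
  set.seed(2)
  acc$n_decided <- n
  acc$n_correct <- rbinom(7, n, 0.5 + 0.5 * (1 - exp(-(acc$coherence / 6)^1.5)))
  fit <- fit_psychometric(acc)
  pfun <- function(c, a, b) 0.5 + 0.5 * (1 - exp(-(c / a)^b))
  expect_equal(pfun(fit$alpha, fit$alpha, fit$beta), 0.5 + 0.5 * (1 - exp(-1)))
  expect_equal(fit$c75, fit$alpha * log(2)^(1 / fit$beta))
  expect_equal(6 * log(2)^(1 / 1.5), 4.696, tolerance = 1e-3)
})

test_that("Weibull fit recovers generating parameters from binomial data", {
  set.seed(8)
  alpha0 <- 6; beta0 <- 1.5; n <- 1e6
  cohs <- c(0, 1, 2, 4, 8, 16, 32)
  pr <- 0.5 + 0.5 * (1 - exp(-(cohs / alpha0)^beta0))
  acc <- data.frame(coherence = cohs, n_correct = rbinom(7, n, pr),
                    n_decided = n)
  fit <- fit_psychometric(acc)
  expect_lt(abs(fit$alpha - alpha0) / alpha0, 0.01)
  expect_lt(abs(fit$beta - beta0) / beta0, 0.02)
})

test_that("degenerate psychometric data raise an informative error", {
  flat <- data.frame(coherence = c(0, 4, 8), n_correct = c(50, 51, 49),
                     n_decided = 100)
  expect_error(fit_psychometric(flat), "degenerate")
  perfect <- data.frame(coherence = c(0, 4, 8), n_correct = c(50, 100, 100),
                        n_decided = 100)
  expect_error(fit_psychometric(perfect), "degenerate")
  expect_error(fit_psychometric(flat[1:2, ]), "3 coherence")
})

test_that("chronometric summary reduces to the expected arithmetic", {
  rec <- data.frame(condition = "neutral", coherence = 4,
                    choice = "target", correct = TRUE,
                    decision_time = c(400, 600))
  s <- chronometric_summary(rec)
  expect_equal(s$mean_dt_ms, 500)
  expect_equal(s$se_dt_ms, 100)
  one <- chronometric_summary(rec[1, ])
  expect_equal(one$mean_dt_ms, 400)
  expect_true(is.na(one$se_dt_ms))
})

# shared small batch for the sweep contracts
sweep_batch <- local({
  sched <- epoch_schedule(t_prestim = 500, t_stim = 1500, dt = 0.5)
  run_batch(conds, c(0, 4, 16, 32), 40, sched, 15, 13, p,
            keep_traces = FALSE)
})

test_that("zero adjustment reproduces the unadjusted sweep bit for bit", {
  sw <- threshold_sweep(sweep_batch, theta_grid = c(12, 15),
                        delta_ns = 0, delta_na = 0)
  df <- as.data.frame(sw)
  for (cond in c("speed", "accuracy")) {
    for (th in c(12, 15)) {
      u <- df[df$condition == cond & df$theta == th & !df$adjusted, ]
      a <- df[df$condition == cond & df$theta == th & df$adjusted, ]
      cols <- c("theta_applied", "c75", "alpha", "beta", "dt_c1", "dt_c32",
                "undecided_frac", "prestim_cross_frac")
      expect_identical(unname(unlist(u[cols])), unname(unlist(a[cols])))
    }
  }
})

test_that("raising the threshold acts monotonically on every paired trial", {
  cell <- sweep_batch$cells[[paste("neutral", 16, sep = "|")]]
  stim <- sweep_batch$env_time >= 0
  cm_t <- t(apply(cell$env_target[, stim], 1, cummax))
  cm_d <- t(apply(cell$env_distractor[, stim], 1, cummax))
  lo <- satdyn:::redetect_from_envelopes(cm_t, cm_d, 12, sweep_batch$env_bin)
  hi <- satdyn:::redetect_from_envelopes(cm_t, cm_d, 18, sweep_batch$env_bin)
  both <- lo$choice > 0 & hi$choice > 0
  expect_true(all(hi$decision_time[both] >= lo$decision_time[both]))
  # decided can become undecided as theta rises, never the reverse
  expect_true(all(lo$choice[hi$choice > 0] > 0))
})

test_that("compensation summary computes gap fractions correctly", {
  sw <- data.frame(
    condition = c("speed", "speed", "neutral", "accuracy", "accuracy"),
    theta = 15, adjusted = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    c75 = c(10, 9, 6, 4, 4.5),
    dt_c1 = c(300, 320, 500, 900, 850),
    dt_c32 = c(200, 205, 250, 400, 390))
  cs <- compensation_summary(sw, 15)
  sp_c75 <- cs[cs$condition == "speed" & cs$measure == "c75", ]
  expect_equal(sp_c75$gap_closed, (9 - 10) / (6 - 10)) # 25% of the gap
  ac_dt <- cs[cs$condition == "accuracy" & cs$measure == "dt_c1", ]
  expect_equal(ac_dt$gap_closed, (850 - 900) / (500 - 900))
})
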