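test_that("probability walks stay within reflecting bounds and drift slowly", {
  cfg <- walk_config(seed = 3)
  sch <- generate_schedule(cfg)
  expect_equal(dim(sch$p_win), c(240, 4))
  expect_true(all(sch$p_win >= 0.2 & sch$p_win <= 0.8))
  expect_true(all(sch$p_loss >= 0.2 & sch$p_loss <= 0.8))
  expect_equal(table(sch$run), table(rep(1:4, each = 60)), ignore_attr = TRUE)
  # zero step size freezes the walks at their start
  frozen <- generate_schedule(walk_config(step_sd = 0, init = 0.5, seed = 1))
  expect_true(all(frozen$p_win == 0.5))
  # reflection holds over long horizons
  long <- generate_schedule(walk_config(n_trials = 10000, seed = 9))
  expect_true(all(long$p_win >= 0.2 & long$p_win <= 0.8))
  # slow drift: high lag-1 autocorrelation at default settings
  ac <- cor(sch$p_win[-240, 1], sch$p_win[-1, 1])
  expect_gt(ac, 0.95)
  # win and loss streams are distinct
  expect_false(isTRUE(all.equal(sch$p_win, sch$p_loss)))
  expect_identical(generate_schedule(cfg), generate_schedule(cfg))
  expect_error(walk_config(step_sd = -1))
  expect_error(walk_config(bounds = c(0.8, 0.2)))
})

test_that("outcomes are independent Bernoulli draws in the task coding", {
  sch <- generate_schedule(walk_config(n_trials = 10, seed = 4))
  sch$p_win[1, 1] <- 1; sch$p_loss[1, 1] <- 0
  set.seed(1)
  o <- sample_outcomes(sch, 1, 1)
  expect_equal(o[c("win", "loss")], list(win = 1, loss = 0))
  sch$p_loss[1, 1] <- 1
  set.seed(2)
  o2 <- sample_outcomes(sch, 1, 1)   # the win-and-lose outcome
  expect_equal(o2[c("win", "loss")], list(win = 1, loss = -1))
  expect_error(sample_outcomes(sch, 99, 1), "trial")
  expect_error(sample_outcomes(sch, 1, 5), "choice")
  # empirical rate over many draws
  sch$p_win[2, 3] <- 0.3
  set.seed(3)
  wins <- replicate(1e4, sample_outcomes(sch, 2, 3)$win)
  expect_lt(abs(mean(wins) - 0.3), 0.015)
})

test_that("simulated agents are reproducible and behave sensibly", {
  model <- bandit_model(5)
  sch <- generate_schedule(walk_config(seed = 6))
  th <- c(R = 0, P = 0, lr_r = 0.5, lr_p = 0.5, d = 0, xi = 0)
  a0 <- simulate_agent(model, th, sch, seed = 7)
  expect_equal(nrow(a0), 240)
  expect_true(all(a0$choice %in% 1:4))
  expect_true(all(a0$win %in% c(0, 1)) && all(a0$loss %in% c(0, -1)))
  # insensitive agent chooses uniformly
  big <- do.call(rbind, lapply(1:20, function(i)
    simulate_agent(model, th, sch, seed = 100 + i)))
  freq <- table(big$choice) / nrow(big)
  expect_true(all(abs(freq - 0.25) < 0.02))
  # a reward-sensitive (but still exploring, via lapse) agent exploits a
  # dominant static arm
  sch2 <- generate_schedule(walk_config(step_sd = 0, init = 0.2, seed = 8))
  sch2$p_win[, 2] <- 0.8
  hi <- simulate_agent(bandit_model(4),
                       c(R = 10, P = 2, lr_r = 0.5, lr_p = 0.5,
                         d = 0, xi = 0.1), sch2, seed = 9)
  expect_gt(mean(hi$choice[141:240] == 2), 0.6)
  expect_identical(simulate_agent(model, th, sch, seed = 7), a0)
})

test_that("cohorts carry admissible ground truth at the planted group gap", {
  sim <- simulate_cohort(model = 1, n_subjects = 6, seed = 10,
                         group = "arthritis",
                         walk = list(n_trials = 30, n_runs = 1))
  expect_equal(dim(sim$true_params), c(6L, 6L))
  expect_true(all(sim$true_params[, c("R", "P")] >= 0 &
                  sim$true_params[, c("R", "P")] <= 30))
  expect_true(all(sim$true_params[, c("lr_r", "lr_p", "d", "xi")] >= 0 &
                  sim$true_params[, c("lr_r", "lr_p", "d", "xi")] <= 1))
  expect_s3_class(sim$data, "bandit_data")
  expect_equal(sim$data$n_subjects, 6L)
  # degenerate hyper-SDs clone the hypermean
  sim0 <- simulate_cohort(model = 5, n_subjects = 3, seed = 11,
                          hyper = list(R = c(8, 0), P = c(4, 0),
                                       lr_r = c(0.5, 0), lr_p = c(0.5, 0)),
                          group = "x",
                          walk = list(n_trials = 20, n_runs = 1))
  expect_true(all(apply(sim0$true_params, 2, sd) == 0))
  # the default two-group design plants the punishment-sensitivity gap
  gap <- cohort_defaults("arthritis")$P[1] - cohort_defaults("control")$P[1]
  expect_equal(gap, 4.175)
  expect_error(simulate_cohort(model = 1, n_subjects = 1), "2 subjects")
})

test_that("parcel generator plants a hub detectable by the graph pipeline", {
  g0 <- generate_parcel_timeseries(30, 500, hub_node = 5, hub_strength = 0,
                                   seed = 12)
  cc0 <- correlation_matrix(g0$ts)
  expect_lt(max(abs(cc0[upper.tri(cc0)])), 0.35)
  hits <- vapply(1:5, function(r) {
    g <- generate_parcel_timeseries(40, 300, hub_node = 3,
                                    hub_strength = 1.2, n_linked = 15,
                                    seed = 400 + r)
    deg <- centralities(threshold_to_density(correlation_matrix(g$ts), 0.1),
                        measures = "degree")$degree
    which.max(deg) == 3
  }, logical(1))
  expect_gte(sum(hits), 4)
  expect_identical(generate_parcel_timeseries(10, 50, seed = 1)$ts,
                   generate_parcel_timeseries(10, 50, seed = 1)$ts)
  expect_error(generate_parcel_timeseries(10, 50, hub_strength = -1))
  expect_error(generate_parcel_timeseries(10, 50, hub_node = 11))
})

test_that("clinical scores converge on the requested correlation", {
  set.seed(13)
  cent <- rnorm(1000)
  sc <- generate_clinical_scores(cent, 0.6, seed = 14)
  expect_equal(cor(cent, sc), 0.6, tolerance = 0.04)
  sc0 <- generate_clinical_scores(cent, 0, seed = 15)
  expect_lt(abs(cor(cent, sc0)), 0.1)
  expect_error(generate_clinical_scores(rep(1, 10), 0.5), "constant")
  expect_error(generate_clinical_scores(cent, 1.2))
})
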