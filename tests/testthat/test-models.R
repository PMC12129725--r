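test_that("model specifications match the five-model family", {
  flags <- t(vapply(1:5, function(i) {
    m <- bandit_model(i)
    c(coupled = m$coupled_learning_rates, decay = m$has_decay,
      lapse = m$has_lapse)
  }, logical(3)))
  expect_equal(flags[, "coupled"], c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(flags[, "decay"], c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(flags[, "lapse"], c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(bandit_model(6))
  expect_error(bandit_model(0))
})

test_that("prediction errors compare the scaled outcome with the tracked value", {
  p <- c(R = 7, P = 5)
  # fully learned cue: expectation equals the scaled outcome, zero error
  expect_equal(scaled_prediction_errors(p, c(7, 0, 0, 0), rep(0, 4),
                                        1, 1, 0)$delta_r, 0)
  expect_equal(scaled_prediction_errors(p, rep(0, 4), rep(0, 4),
                                        2, 0, -1)$delta_p, -5)
  # hand arithmetic with the arthritis-level reward sensitivity
  p2 <- c(R = 12.750, P = 1)
  expect_equal(scaled_prediction_errors(p2, c(0.5, 0, 0, 0), rep(0, 4),
                                        1, 1, 0)$delta_r, 12.25)
  expect_error(scaled_prediction_errors(p, c(NaN, 0, 0, 0), rep(0, 4),
                                        1, 1, 0))
  expect_error(scaled_prediction_errors(p, rep(0, 4), rep(0, 4), 5, 1, 0))
})

test_that("value updates touch only the chosen cue with the right rates", {
  p <- c(lr_r = 0.6, lr_p = 0.4)   # alpha = 0.5, beta = 0.1
  up <- update_values(p, rep(0, 4), rep(0, 4), 1, 1, -1)
  expect_equal(up$q_reward, c(0.6, 0, 0, 0))
  expect_equal(up$q_punish, c(-0.4, 0, 0, 0))
  up2 <- update_values(c(lr_r = 0.7, lr_p = 0.7), c(1, 2, 3, 4), rep(0, 4),
                       3, 0, 0)
  expect_equal(up2$q_reward, c(1, 2, 3, 4))
  expect_error(update_values(c(lr_r = 1.2, lr_p = 0.5), rep(0, 4),
                             rep(0, 4), 1, 1, 0))
})

test_that("decay shrinks all cues multiplicatively", {
  expect_equal(apply_decay(c(d = 0), c(1, 2, 3, 4), c(-1, 0, 0, 0)),
               list(q_reward = c(1, 2, 3, 4), q_punish = c(-1, 0, 0, 0)))
  expect_equal(apply_decay(c(d = 1), c(1, 2, 3, 4), c(-1, 0, 0, 0))$q_reward,
               rep(0, 4))
  expect_equal(apply_decay(c(d = 0.25), c(2, 0, 0, 0), rep(0, 4))$q_reward,
               c(1.5, 0, 0, 0))
  expect_error(apply_decay(c(d = 1.5), rep(0, 4), rep(0, 4)))
})

test_that("choice probabilities are a stabilized softmax with lapse mixing", {
  m4 <- bandit_model(4)
  expect_equal(choice_probabilities(m4, c(xi = 0), rep(2, 4), rep(0, 4)),
               rep(0.25, 4))
  expect_equal(choice_probabilities(m4, c(xi = 1), c(9, 0, 0, 0), rep(0, 4)),
               rep(0.25, 4))
  p <- choice_probabilities(m4, c(xi = 0), c(1, 0, 0, 0), rep(0, 4))
  expect_equal(p[1], exp(1) / (exp(1) + 3), tolerance = 1e-10)
  # overflow-prone values stay finite and normalized
  p_big <- choice_probabilities(m4, c(xi = 0.1), c(900, 0, 0, 0), rep(0, 4))
  expect_false(any(is.nan(p_big)))
  expect_equal(sum(p_big), 1, tolerance = 1e-10)
  # invariants on random draws: sum to 1 and floor at xi/4
  for (s in 1:20) {
    th <- random_params(m4, 900 + s)
    q <- list(rnorm(4, 0, 3), rnorm(4, 0, 3))
    pr <- choice_probabilities(m4, th, q[[1]], q[[2]])
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_true(min(pr) >= th[["xi"]] / 4 - 1e-12)
  }
})

test_that("run_trials matches a naive unvectorized reference loop", {
  for (s in 1:25) {
    mid <- ((s - 1) %% 5) + 1
    model <- bandit_model(mid)
    trials <- random_trials(60, 3000 + s)
    th <- random_params(model, 4000 + s)
    tr <- run_trials(model, th, trials)
    expect_equal(attr(tr, "loglik"),
                 oracle_trace_loglik(model, th, trials),
                 tolerance = 1e-10)
    expect_equal(sum(tr$log_lik), attr(tr, "loglik"), tolerance = 1e-10)
    expect_equal(unname(rowSums(as.matrix(tr[paste0("p", 1:4)]))),
                 rep(1, nrow(trials)), tolerance = 1e-10)
  }
  # a full-length session, with and without run resets
  trials <- random_trials(240, 99)
  trials$run <- sort(rep_len(1:4, 240))
  th <- random_params(bandit_model(1), 100)
  for (rr in c(FALSE, TRUE)) {
    expect_equal(attr(run_trials(bandit_model(1), th, trials,
                                 reset_runs = rr), "loglik"),
                 oracle_trace_loglik(bandit_model(1), th, trials,
                                     reset_runs = rr),
                 tolerance = 1e-10)
  }
})

test_that("model nesting identities hold on random data", {
  trials <- random_trials(120, 11)
  base <- random_params(bandit_model(1), 12)
  # Model 1 with beta = 0 (lr_r = lr_p) == Model 3 with alpha_r = alpha_p
  th13 <- base; th13[["lr_p"]] <- th13[["lr_r"]]
  expect_equal(attr(run_trials(bandit_model(1), th13, trials), "loglik"),
               attr(run_trials(bandit_model(3), th13, trials), "loglik"),
               tolerance = 1e-10)
  # Model 1 with d = 0 == Model 2
  th12 <- base; th12[["d"]] <- 0
  expect_equal(attr(run_trials(bandit_model(1), th12, trials), "loglik"),
               attr(run_trials(bandit_model(2), th12, trials), "loglik"),
               tolerance = 1e-10)
  # Model 3 with d = 0 == Model 4
  expect_equal(attr(run_trials(bandit_model(3), th12, trials), "loglik"),
               attr(run_trials(bandit_model(4), th12, trials), "loglik"),
               tolerance = 1e-10)
  # Model 4 with xi = 0 == Model 5
  th45 <- base; th45[["d"]] <- 0; th45[["xi"]] <- 0
  expect_equal(attr(run_trials(bandit_model(4), th45, trials), "loglik"),
               attr(run_trials(bandit_model(5), th45, trials), "loglik"),
               tolerance = 1e-10)
})

test_that("degenerate agents give the uniform-policy likelihood", {
  trials <- random_trials(240, 21)
  th_lapse <- c(R = 5, P = 5, lr_r = 0.5, lr_p = 0.5, d = 0, xi = 1)
  expect_equal(attr(run_trials(bandit_model(1), th_lapse, trials), "loglik"),
               240 * log(0.25), tolerance = 1e-10)
  expect_equal(negative_log_likelihood(bandit_model(1), th_lapse, trials)[1],
               240 * log(4), tolerance = 1e-10)
  # insensitive agent: Q never moves, all probabilities uniform
  th0 <- c(R = 0, P = 0, lr_r = 0.8, lr_p = 0.3, d = 0, xi = 0)
  tr <- run_trials(bandit_model(2), th0, trials)
  expect_true(all(abs(as.matrix(tr[paste0("p", 1:4)]) - 0.25) < 1e-12))
})

test_that("negative log-likelihood is deterministic with pointwise trials", {
  trials <- random_trials(80, 31)
  th <- random_params(bandit_model(3), 32)
  n1 <- negative_log_likelihood(bandit_model(3), th, trials)
  n2 <- negative_log_likelihood(bandit_model(3), th, trials)
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_length(attr(n1, "pointwise"), 80)
  expect_equal(-sum(attr(n1, "pointwise")), as.numeric(n1))
})

test_that("regressor export produces per-run 3-column event tables", {
  sched <- generate_schedule(walk_config(n_trials = 40, n_runs = 2, seed = 5))
  model <- bandit_model(1)
  th <- bandit_params(model, R = 8, P = 6, alpha = 0.5, beta = 0.05,
                      d = 0.3, xi = 0.08)
  agent <- simulate_agent(model, th, sched, seed = 6)
  tr <- run_trials(model, th, agent)
  regs <- export_regressors(tr)
  expect_named(regs, c("run1", "run2"))
  expect_setequal(names(regs$run1),
                  c("reward_outcome", "punishment_outcome", "rpe", "ppe",
                    "cue", "keypress"))
  r1 <- regs$run1
  expect_equal(names(r1$rpe), c("onset", "duration", "value"))
  expect_true(all(r1$rpe$duration == 0))
  # RPE/PPE columns equal the latent trace in trial order
  expect_equal(c(r1$rpe$value, regs$run2$rpe$value), tr$delta_r)
  expect_equal(c(r1$ppe$value, regs$run2$ppe$value), tr$delta_p)
  # zero outcomes produce zero-valued outcome events
  zero <- tr$win == 0
  expect_equal(c(r1$reward_outcome$value,
                 regs$run2$reward_outcome$value)[zero],
               rep(0, sum(zero)))
  expect_true(all(r1$cue$value == 1))
  # missing onsets fail loudly with the subject named
  tr2 <- tr; tr2$outcome_onset <- NULL
  expect_error(export_regressors(tr2, subject_id = "s07"), "s07")
})
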