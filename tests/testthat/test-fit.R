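test_that("probit transforms hit their landmarks and round-trip", {
  expect_equal(constrain_params(0, "xi"), c(xi = 0.5))
  expect_equal(constrain_params(0, "R"), c(R = 15))
  expect_equal(constrain_params(-50, "d"), c(d = 0), tolerance = 1e-12)
  set.seed(4)
  x <- rnorm(50, 0, 2)
  for (p in c("R", "P", "lr_r", "d", "xi")) {
    expect_equal(unname(unconstrain_params(constrain_params(x, p), p)), x,
                 tolerance = 1e-10)
  }
  expect_error(constrain_params(0, "nonsense"))
})

test_that("joint log-posterior gradient matches numerical differentiation", {
  sim <- tiny_cohort(model_id = 1, n_subjects = 3, n_trials = 50, seed = 8)
  flat <- banditrl:::flatten_cohort(sim$data, FALSE)
  for (cc in c(TRUE, FALSE)) {
    lpg <- banditrl:::make_lp_grad(flat, bandit_model(1), bandit_prior(), 3,
                                   centered = cc)
    set.seed(9)
    par <- rnorm(2 * 6 + 3 * 6, 0, 0.4)
    g <- lpg(par)$grad
    ng <- vapply(seq_along(par), function(i) {
      e <- numeric(length(par)); e[i] <- 1e-6
      (lpg(par + e)$lp - lpg(par - e)$lp) / 2e-6
    }, 0)
    expect_equal(g, ng, tolerance = 1e-5)
  }
})

test_that("C++ posterior density agrees with the R reference", {
  # drive the C++ sampler one leapfrog's worth by running a 1-iteration
  # chain and comparing its recorded lp with the R implementation
  sim <- tiny_cohort(model_id = 4, n_subjects = 2, n_trials = 30, seed = 18)
  flat <- banditrl:::flatten_cohort(sim$data, FALSE)
  model <- bandit_model(4)
  act <- which(model$active)
  K <- length(act)
  lpg <- banditrl:::make_lp_grad(flat, model, bandit_prior(), 2,
                                 centered = TRUE)
  set.seed(3)
  init <- rnorm(2 * K + 2 * K, 0, 0.3)
  set.seed(10)
  ch <- banditrl:::cpp_nuts_chain(
    init, flat$choice, flat$win, flat$loss, flat$subj_start, flat$reset,
    as.integer(act - 1L), c(30, 30, 1, 1, 1)[seq_len(K)],
    model$has_decay, model$has_lapse, FALSE, TRUE, 1, 1,
    5L, 3L, 0.85, 6L, rep(1, length(init)), 3L, 1e-3)
  for (r in 1:3)
    expect_equal(ch$lp[r], lpg(ch$draws[r, ])$lp, tolerance = 1e-8)
})

test_that("hierarchical fitting rejects degenerate cohorts", {
  sim <- tiny_cohort(n_subjects = 2, n_trials = 30, seed = 5)
  one <- sim$data
  one$subjects <- one$subjects[1]
  one$n_subjects <- 1L
  one$n_trials <- one$n_trials[1]
  expect_error(fit_bandit(one, 5), "2 subjects")
})

test_that("identical seed gives identical draws; MAP fit is deterministic", {
  sim <- tiny_cohort(model_id = 5, n_subjects = 3, n_trials = 40, seed = 14)
  f1 <- fit_bandit(sim$data, 5, chains = 2, warmup = 40, iter = 40,
                   seed = 77, pointwise = FALSE,
                   control = list(max_depth = 5))
  f2 <- fit_bandit(sim$data, 5, chains = 2, warmup = 40, iter = 40,
                   seed = 77, pointwise = FALSE,
                   control = list(max_depth = 5))
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_identical(f1$draws$theta, f2$draws$theta)
  m1 <- fit_bandit(sim$data, 5, method = "map", seed = 3)
  m2 <- fit_bandit(sim$data, 5, method = "map", seed = 3)
  expect_identical(m1$estimates$subject, m2$estimates$subject)
})

test_that("prior-only sampling reproduces the hyperprior", {
  sim <- tiny_cohort(model_id = 5, n_subjects = 3, n_trials = 20, seed = 25)
  fit <- fit_bandit(sim$data, 5, chains = 2, warmup = 300, iter = 500,
                    seed = 5, prior_only = TRUE, pointwise = FALSE)
  mu_draws <- fit$draws$mu
  # hypermeans are a priori standard normal
  for (p in colnames(mu_draws)) {
    expect_lt(abs(mean(mu_draws[, p])), 0.3)
    expect_gt(sd(mu_draws[, p]), 0.6)
    expect_lt(sd(mu_draws[, p]), 1.5)
  }
  # prior-predictive subject draws always satisfy admissibility
  theta <- fit$draws$theta
  for (j in 1:3) {
    blk <- theta[, 6 * (j - 1) + which(bandit_model(5)$active)]
    expect_true(all(blk[, 1:2] >= 0 & blk[, 1:2] <= 30))
    expect_true(all(blk[, 3:4] >= 0 & blk[, 3:4] <= 1))
  }
})

test_that("summaries report constrained means with derived composites", {
  sim <- tiny_cohort(model_id = 2, n_subjects = 3, n_trials = 40, seed = 33)
  fit <- fit_bandit(sim$data, 2, chains = 2, warmup = 60, iter = 60,
                    seed = 11, pointwise = FALSE,
                    control = list(max_depth = 6))
  s <- summary(fit)
  expect_setequal(s$hyper$parameter,
                  c("R", "P", "lr_r", "lr_p", "xi", "alpha", "beta"))
  # per-draw derived composites are linear in the learning-rate draws
  a <- hyper_draws(fit, "alpha")
  expect_equal(a, (hyper_draws(fit, "lr_r") + hyper_draws(fit, "lr_p")) / 2)
  expect_equal(mean(a), s$hyper$mean[s$hyper$parameter == "alpha"])
  expect_error(hyper_draws(fit, "d"), "not active")
  # degenerate draws: constant vector summarizes to mean c, sd 0
  expect_equal(unname(hdi(rep(2.5, 500))), c(2.5, 2.5))
  # subject-level posterior means respect ranges
  sm <- subject_means(fit)
  expect_true(all(sm[, c("lr_r", "lr_p", "xi")] >= 0 &
                  sm[, c("lr_r", "lr_p", "xi")] <= 1))
})

test_that("fit methods expose coefficients, likelihood and predictions", {
  sim <- tiny_cohort(model_id = 5, n_subjects = 3, n_trials = 40, seed = 44)
  fit <- fit_bandit(sim$data, 5, chains = 2, warmup = 60, iter = 60,
                    seed = 21, control = list(max_depth = 6))
  co <- coef(fit)
  expect_named(co, c("R", "P", "lr_r", "lr_p"))
  expect_equal(dim(coef(fit, level = "subject")), c(3L, 4L))
  ll <- logLik(fit)
  expect_true(is.finite(as.numeric(ll)))
  pr <- predict(fit)
  expect_equal(nrow(pr), 3 * 40)
  expect_equal(unname(rowSums(as.matrix(pr[paste0("p", 1:4)]))),
               rep(1, nrow(pr)), tolerance = 1e-8)
  res <- residuals(fit)
  expect_true(all(res >= 0 & res <= 1))
  sims <- simulate(fit, nsim = 1, seed = 2)
  expect_s3_class(sims[[1]], "bandit_data")
  expect_equal(sims[[1]]$n_subjects, 3L)
})

test_that("recovery simulation brackets known hypermeans for both sensitivities", {
  # 12 lapse-free-model subjects at 240 trials, generating means at the
  # patient-group magnitudes
  sim <- simulate_cohort(model = 5, n_subjects = 12, seed = 61,
                         group = "arthritis")
  fit <- fit_bandit(sim$data, 5, chains = 2, warmup = 200, iter = 200,
                    seed = 62, control = list(max_depth = 8,
                                              min_step = 0.003))
  for (p in c("R", "P")) {
    ci <- hdi(hyper_draws(fit, p, scale = "hypermean"), mass = 0.95)
    truth <- mean(sim$true_params[, p])
    expect_lt(ci[1], truth)
    expect_gt(ci[2], truth)
  }
  sm <- subject_means(fit)
  expect_gte(cor(sm[, "P"], sim$true_params[, "P"], method = "spearman"),
             0.5)
})
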