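#' Hierarchical prior for bandit model parameters
#'
#' Priors follow the convention of hierarchical reinforcement-learning
#' toolchains: on the unconstrained scale each parameter has a group
#' hypermean with a Normal(0, 1) prior and a group hyper-SD with a
#' half-Normal(0, 1) prior; subject effects are non-centered standard
#' normals. Unit-interval parameters map through the probit
#' (`theta = pnorm(x)`), sensitivities through a scaled probit
#' (`theta = sens_ub * pnorm(x)`, default upper bound 30).
#'
#' @param sens_ub Upper bound of the sensitivity range.
#' @param mu_scale SD of the hypermean prior.
#' @param sd_scale Scale of the half-normal hyper-SD prior.
#' @return A `bandit_prior` list.
#' @export
bandit_prior <- function(sens_ub = 30, mu_scale = 1, sd_scale = 1) {
  stopifnot(sens_ub > 0, mu_scale > 0, sd_scale > 0)
  structure(list(sens_ub = sens_ub, mu_scale = mu_scale,
                 sd_scale = sd_scale),
            class = "bandit_prior")
}

param_upper_bounds <- function(prior) {
  c(R = prior$sens_ub, P = prior$sens_ub, lr_r = 1, lr_p = 1, d = 1, xi = 1)
}

#' Map unconstrained draws to the constrained parameter scale
#'
#' Unit-interval parameters use the probit map `pnorm(x)`; sensitivities
#' use `sens_ub * pnorm(x)`. [constrain_params()] and its inverse
#' [unconstrain_params()] round-trip to numerical precision.
#'
#' @param x Numeric vector/matrix of unconstrained values.
#' @param param Parameter name(s) (recycled): one of `"R"`, `"P"`,
#'   `"lr_r"`, `"lr_p"`, `"d"`, `"xi"` (aliases `"alpha_r"` = `"lr_r"`,
#'   `"alpha_p"` = `"lr_p"`).
#' @param prior A `bandit_prior` (supplies the sensitivity bound).
#' @return Values on the constrained scale (same shape as `x`).
#' @export
constrain_params <- function(x, param, prior = bandit_prior()) {
  ub <- param_upper_bounds(prior)[canonical_param(param)]
  pnorm(x) * ub
}

#' @rdname constrain_params
#' @export
unconstrain_params <- function(x, param, prior = bandit_prior()) {
  ub <- param_upper_bounds(prior)[canonical_param(param)]
  qnorm(pmin(pmax(x / ub, 1e-15), 1 - 1e-15))
}

canonical_param <- function(param) {
  map <- c(alpha_r = "lr_r", alpha_p = "lr_p", lapse = "xi", decay = "d")
  out <- ifelse(param %in% names(map), map[param], param)
  bad <- setdiff(out, .param_names)
  if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "))
  out
}

# ---- cohort flattening for the C++ likelihood ----

flatten_cohort <- function(data, reset_runs) {
  stopifnot(inherits(data, "bandit_data"))
  tr <- lapply(data$subjects, function(s) s$trials)
  choice <- unlist(lapply(tr, function(t) as.integer(t$choice)),
                   use.names = FALSE) - 1L
  win <- unlist(lapply(tr, function(t) as.numeric(t$win)), use.names = FALSE)
  loss <- unlist(lapply(tr, function(t) as.numeric(t$loss)), use.names = FALSE)
  reset <- unlist(lapply(tr, reset_vector, reset_runs = reset_runs),
                  use.names = FALSE)
  subj_start <- c(0L, cumsum(vapply(tr, nrow, 0L)))
  list(choice = choice, win = win, loss = loss,
       reset = as.integer(reset), subj_start = as.integer(subj_start))
}

# ---- joint log posterior on the unconstrained scale ----
#
# Parameter vector layout: c(mu[K], s[K], subject block[J*K]) with
# sigma = exp(s). The subject block holds raw unconstrained parameters
# x[j,k] ~ N(mu_k, sigma_k) (centered; the default, appropriate when each
# subject carries many trials) or standardized effects z[j,k] ~ N(0,1)
# with x = mu + sigma * z (non-centered). Reference implementation of the
# density sampled by the C++ NUTS path.

make_lp_grad <- function(flat, model, prior, J, prior_only = FALSE,
                         centered = TRUE) {
  act <- which(model$active)
  K <- length(act)
  ub <- unname(param_upper_bounds(prior)[.param_names])
  mu_sc2 <- prior$mu_scale^2
  sd_sc2 <- prior$sd_scale^2

  function(par) {
    mu <- par[seq_len(K)]
    s <- par[K + seq_len(K)]
    sigma <- exp(s)
    blk <- matrix(par[2 * K + seq_len(J * K)], nrow = J, ncol = K)
    x <- if (centered) blk
         else sweep(sweep(blk, 2, sigma, `*`), 2, mu, `+`)
    theta <- matrix(0, nrow = J, ncol = 6)
    theta[, act] <- pnorm(x) * rep(ub[act], each = J)

    if (prior_only) {
      ll <- 0
      gth <- matrix(0, J, 6)
    } else {
      res <- cpp_cohort_loglik_grad(theta, flat$choice, flat$win, flat$loss,
                                    flat$subj_start, flat$reset,
                                    model$has_decay, model$has_lapse)
      ll <- res$loglik
      gth <- res$grad
    }
    lp <- ll - 0.5 * sum(mu^2) / mu_sc2 - 0.5 * sum(sigma^2) / sd_sc2 +
      sum(s)
    gx <- gth[, act, drop = FALSE] * dnorm(x) * rep(ub[act], each = J)
    if (centered) {
      r <- sweep(sweep(x, 2, mu, `-`), 2, sigma, `/`)
      lp <- lp - 0.5 * sum(r^2) - J * sum(s)
      gblk <- gx - sweep(r, 2, sigma, `/`)
      gmu <- colSums(sweep(r, 2, sigma, `/`)) - mu / mu_sc2
      gs <- colSums(r^2) - J - sigma^2 / sd_sc2 + 1
    } else {
      lp <- lp - 0.5 * sum(blk^2)
      gblk <- sweep(gx, 2, sigma, `*`) - blk
      gmu <- colSums(gx) - mu / mu_sc2
      gs <- colSums(gx * blk) * sigma - sigma^2 / sd_sc2 + 1
    }
    list(lp = lp, grad = c(gmu, gs, as.numeric(gblk)))
  }
}

#' Fit a bandit learning model hierarchically to a group of subjects
#'
#' Joint Bayesian estimation of group hypermeans, hyper-SDs and
#' subject-level parameters with the trial-wise softmax likelihood, by the
#' No-U-Turn sampler on the probit-transformed parameterization
#' (`method = "hmc"`, the reference path; centered by default, which suits
#' the many-trials-per-subject regime), or a fast deterministic
#' approximation (`method = "map"`: penalized maximum likelihood per
#' subject with moment-matched hyperparameters).
#'
#' @param data A `bandit_data` cohort (>= 2 subjects) or a long-format data
#'   frame accepted by [bandit_data()].
#' @param model A `bandit_model` or model id 1..5.
#' @param method `"hmc"` or `"map"`.
#' @param prior A [bandit_prior()].
#' @param chains,warmup,iter MCMC geometry (post-warmup draws per chain =
#'   `iter`). Defaults follow the study protocol: 4 chains, 1000 burn-in,
#'   2000 samples.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param reset_runs Reset Q-values at run boundaries (default: carry over).
#' @param pointwise Record the per-trial log-likelihood matrix needed for
#'   PSIS-LOO (default TRUE for HMC).
#' @param prior_only Sample from the prior (likelihood disabled); used for
#'   sampler validation.
#' @param parameterization Subject-level parameterization: `"centered"`
#'   (default) or `"noncentered"`.
#' @param control Sampler options: `target_accept` (0.85), `max_depth`
#'   (9), `min_step` (1e-3, step-size floor), `retries` (1, extra whole
#'   passes on diagnostic failure), `map_starts` (4, optimizer starts per
#'   subject for initialization), `inv_mass` (fixed diagonal mass).
#' @return A `bandit_fit` object; see [summary.bandit_fit()],
#'   [hyper_draws()], [bandit_loo()].
#' @export
fit_bandit <- function(data, model = 1, method = c("hmc", "map"),
                       prior = bandit_prior(), chains = 4, warmup = 1000,
                       iter = 2000, seed = 1, reset_runs = FALSE,
                       pointwise = TRUE, prior_only = FALSE,
                       parameterization = c("centered", "noncentered"),
                       control = list()) {
  parameterization <- match.arg(parameterization)
  centered <- parameterization == "centered"
  method <- match.arg(method)
  if (!inherits(model, "bandit_model")) model <- bandit_model(model)
  data <- bandit_data(data)
  J <- data$n_subjects
  if (J < 2L) stop("hierarchical fit requires >= 2 subjects")
  if (length(unique(data$n_trials)) > 1L)
    warning("subjects differ in trial counts")
  flat <- flatten_cohort(data, reset_runs)
  act <- which(model$active)
  K <- length(act)
  pn <- .param_names[act]

  if (method == "map")
    return(fit_bandit_map(data, model, prior, flat, seed, reset_runs))

  ctl <- modifyList(list(target_accept = 0.85, max_depth = 9L,
                         retries = 1L, min_step = 1e-3, map_starts = 4L,
                         inv_mass = NULL), control)
  lp_grad <- make_lp_grad(flat, model, prior, J, prior_only = prior_only,
                          centered = centered)

  # Initialize chains near the penalized-ML solution: the likelihood has a
  # wide plateau at R = P = 0 (uniform policy) that short trajectories
  # escape poorly, so data-informed inits keep chains in the dominant basin.
  if (prior_only) {
    mu0 <- rep(0, K); s0 <- rep(-1, K)
    z0 <- if (centered) matrix(rep(0, J * K), J, K) else matrix(0, J, K)
  } else {
    map0 <- fit_bandit_map(data, model, prior, flat, seed, reset_runs,
                           n_starts = ctl$map_starts)
    x0 <- map0$estimates$subject_unconstrained
    mu0 <- colMeans(x0)
    sd0 <- pmax(apply(x0, 2, sd), 0.15)
    s0 <- log(sd0)
    z0 <- if (centered) x0
          else pmin(pmax(sweep(sweep(x0, 2, mu0), 2, sd0, `/`), -2.5), 2.5)
  }
  # Seed the diagonal mass matrix from the curvature at the init point:
  # per-coordinate curvature spans several orders of magnitude here, which
  # no step size can serve with a unit mass.
  init0 <- c(mu0, s0, as.numeric(z0))
  if (is.null(ctl$inv_mass)) {
    g_at <- function(p) lp_grad(p)$grad
    h <- 1e-4
    hd <- vapply(seq_along(init0), function(i) {
      e <- numeric(length(init0)); e[i] <- h
      (g_at(init0 + e)[i] - g_at(init0 - e)[i]) / (2 * h)
    }, 0)
    ctl$inv_mass <- 1 / pmin(pmax(-hd, 0.5), 1e8)
  }
  ub_all <- unname(param_upper_bounds(prior)[.param_names])

  # On a diagnostics failure (frozen or disagreeing chains, usually from
  # step-size collapse against a likelihood cliff) the whole sampling pass
  # is retried with a shifted seed; the failure is still reported if the
  # last attempt fails too.
  best <- NULL
  for (attempt in 0:ctl$retries) {
    seed_a <- seed + 7000L * attempt
    chains_out <- vector("list", chains)
    for (ch in seq_len(chains)) {
      set.seed(seed_a + ch - 1L)
      init <- c(mu0 + rnorm(K, 0, 0.1), s0 + rnorm(K, 0, 0.1),
                as.numeric(z0) + rnorm(J * K, 0, 0.1))
      chains_out[[ch]] <- cpp_nuts_chain(
        init, flat$choice, flat$win, flat$loss, flat$subj_start, flat$reset,
        as.integer(act - 1L), ub_all[act], model$has_decay, model$has_lapse,
        prior_only, centered, prior$mu_scale, prior$sd_scale,
        as.integer(warmup), as.integer(iter), ctl$target_accept,
        as.integer(ctl$max_depth), ctl$inv_mass,
        as.integer(adapt_windows(warmup)), ctl$min_step)
    }
    rhat_try <- vapply(seq_len(2 * K), function(k)
      split_rhat(sapply(chains_out, function(cc) cc$draws[, k])), 0)
    score <- if (all(is.finite(rhat_try))) max(rhat_try) else Inf
    if (is.null(best) || score < best$score)
      best <- list(chains_out = chains_out, score = score,
                   attempt = attempt)
    if (score <= 1.05) break
  }
  chains_out <- best$chains_out
  attempt <- best$attempt
  draws <- do.call(rbind, lapply(chains_out, `[[`, "draws"))
  S <- nrow(draws)
  mu <- draws[, seq_len(K), drop = FALSE]
  sigma <- exp(draws[, K + seq_len(K), drop = FALSE])
  colnames(mu) <- colnames(sigma) <- pn
  z <- draws[, 2 * K + seq_len(J * K), drop = FALSE]
  ub <- unname(param_upper_bounds(prior)[.param_names])

  # subject-level constrained draws: S x (J*6), subject-major blocks
  theta_draws <- matrix(0, S, J * 6)
  for (j in seq_len(J)) {
    blk <- z[, (seq_len(K) - 1) * J + j, drop = FALSE]
    xj <- if (centered) blk else mu + sigma * blk
    block <- 6 * (j - 1)
    for (kk in seq_len(K))
      theta_draws[, block + act[kk]] <- pnorm(xj[, kk]) * ub[act[kk]]
  }

  pw <- NULL
  if (pointwise && !prior_only)
    pw <- cpp_pointwise_loglik(theta_draws, flat$choice, flat$win, flat$loss,
                               flat$subj_start, flat$reset,
                               model$has_decay, model$has_lapse)

  # diagnostics over hyperparameters, per chain
  hyper_chains <- lapply(seq_len(2 * K), function(k)
    sapply(chains_out, function(cc) cc$draws[, k]))
  rhat <- vapply(hyper_chains, split_rhat, 0)
  ess <- vapply(hyper_chains, ess_basic, 0)
  names(rhat) <- names(ess) <- c(paste0("mu_", pn), paste0("sigma_", pn))
  div_frac <- sum(vapply(chains_out, `[[`, 0L, "divergences")) / S
  diag_ok <- is.finite(max(rhat)) && max(rhat) <= 1.05 && div_frac <= 0.05

  structure(
    list(model = model, data = data, prior = prior, method = "hmc",
         param_names = pn, active = act,
         draws = list(mu = mu, sigma = sigma, theta = theta_draws),
         pointwise = pw,
         diagnostics = list(rhat = rhat, ess = ess,
                            divergence_frac = div_frac, ok = diag_ok,
                            attempts = attempt + 1L,
                            accept_rate = vapply(chains_out, `[[`, 0,
                                                 "accept_rate"),
                            step_size = vapply(chains_out, `[[`, 0,
                                               "step_size")),
         chains = chains, warmup = warmup, iter = iter, seed = seed,
         reset_runs = reset_runs, prior_only = prior_only,
         parameterization = parameterization),
    class = "bandit_fit")
}

# Deterministic fallback: per-subject penalized ML (ridge on the
# unconstrained scale) + moment-matched hyperparameters. At the parameter
# scales typical of this task the policy is nearly deterministic and the
# likelihood surface has cliffs, so each subject is optimized by graded
# smoothing (a temporarily fixed lapse bounds the gradients) from several
# starts, keeping the best refined solution.
fit_bandit_map <- function(data, model, prior, flat, seed, reset_runs,
                           n_starts = 4) {
  J <- data$n_subjects
  act <- which(model$active)
  K <- length(act)
  pn <- .param_names[act]
  ub <- unname(param_upper_bounds(prior)[.param_names])
  xi_col <- 6L
  objective <- function(idx, lapse_fix) {
    fixed <- !is.na(lapse_fix) && !model$has_lapse
    list(
      fn = function(x) {
        theta <- matrix(0, 1, 6)
        theta[, act] <- pnorm(x) * ub[act]
        if (fixed) theta[, xi_col] <- lapse_fix
        res <- cpp_cohort_loglik_grad(theta, flat$choice[idx], flat$win[idx],
                                      flat$loss[idx], c(0L, length(idx)),
                                      flat$reset[idx], model$has_decay,
                                      model$has_lapse || fixed)
        -(res$loglik - 0.5 * sum(x^2))
      },
      gr = function(x) {
        theta <- matrix(0, 1, 6)
        theta[, act] <- pnorm(x) * ub[act]
        if (fixed) theta[, xi_col] <- lapse_fix
        res <- cpp_cohort_loglik_grad(theta, flat$choice[idx], flat$win[idx],
                                      flat$loss[idx], c(0L, length(idx)),
                                      flat$reset[idx], model$has_decay,
                                      model$has_lapse || fixed)
        -(res$grad[1, act] * dnorm(x) * ub[act] - x)
      })
  }
  xhat <- matrix(0, J, K)
  set.seed(derive_seed(seed, "map-starts"))
  for (j in seq_len(J)) {
    idx <- (flat$subj_start[j] + 1L):flat$subj_start[j + 1L]
    hard <- objective(idx, NA)
    best <- NULL
    for (s in seq_len(n_starts)) {
      x0 <- if (s == 1) rep(0, K) else rnorm(K, 0, 0.8)
      for (xi_fix in c(0.25, 0.1, 0.03, 0.01)) {
        soft <- objective(idx, xi_fix)
        x0 <- optim(x0, soft$fn, soft$gr, method = "BFGS",
                    control = list(maxit = 200))$par
      }
      o <- optim(x0, hard$fn, hard$gr, method = "BFGS",
                 control = list(maxit = 300))
      # derivative-free polish: BFGS stalls on the cliff structure
      o2 <- optim(o$par, hard$fn, method = "Nelder-Mead",
                  control = list(maxit = 1500))
      o3 <- optim(o2$par, hard$fn, hard$gr, method = "BFGS",
                  control = list(maxit = 200))
      o <- if (o3$value < o2$value) o3 else o2
      if (is.null(best) || o$value < best$value) best <- o
    }
    xhat[j, ] <- best$par
  }
  theta_hat <- pnorm(xhat) * rep(ub[act], each = J)
  colnames(theta_hat) <- pn
  mu_hat <- colMeans(xhat)
  sd_hat <- apply(xhat, 2, sd)
  names(mu_hat) <- names(sd_hat) <- pn
  structure(
    list(model = model, data = data, prior = prior, method = "map",
         param_names = pn, active = act,
         estimates = list(subject_unconstrained = xhat,
                          subject = theta_hat,
                          mu = mu_hat, sigma = sd_hat),
         chains = 0L, seed = seed, reset_runs = reset_runs,
         prior_only = FALSE),
    class = "bandit_fit")
}
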