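#' @export
print.bandit_fit <- function(x, ...) {
  cat(sprintf("Hierarchical bandit fit (model %d, %s), group '%s'\n",
              x$model$model_id, x$method, x$data$group))
  cat(sprintf("  %d subjects, %d trials total\n",
              x$data$n_subjects, sum(x$data$n_trials)))
  if (x$method == "hmc") {
    cat(sprintf("  %d chains x %d draws (+%d warmup)%s\n", x$chains, x$iter,
                x$warmup, if (x$prior_only) " [prior only]" else ""))
    d <- x$diagnostics
    cat(sprintf("  max split-Rhat %.3f, divergence fraction %.3f%s\n",
                max(d$rhat), d$divergence_frac,
                if (d$ok) "" else "  ** DIAGNOSTICS FAILED **"))
  }
  print(summary(x)$hyper, digits = 3)
  invisible(x)
}

# Gauss-Hermite nodes for the population mean E[ub * pnorm(mu + sigma*Z)],
# via Golub-Welsch on the Hermite Jacobi matrix; weights sum to 1 so the
# rule integrates directly against the standard normal.
gh_rule <- function(n = 21) {
  off <- sqrt(seq_len(n - 1) / 2)
  Jm <- matrix(0, n, n)
  Jm[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  Jm[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  E <- eigen(Jm, symmetric = TRUE)
  list(nodes = E$values * sqrt(2), weights = E$vectors[1, ]^2)
}

.gh_env <- new.env(parent = emptyenv())
get_gh <- function() {
  if (is.null(.gh_env$rule)) .gh_env$rule <- gh_rule(21)
  .gh_env$rule
}

#' Extract posterior draws of group-level quantities
#'
#' @param fit A `bandit_fit` (HMC method).
#' @param parameter One of the model's parameters (`"R"`, `"P"`, `"lr_r"`,
#'   `"lr_p"`, `"d"`, `"xi"`) or, for coupled models, the derived
#'   `"alpha"`/`"beta"`.
#' @param scale `"hypermean"` (constrained-scale transform of the group
#'   location, Table-style), `"popmean"` (model-implied population mean,
#'   integrating over subject variability), `"unconstrained"` (raw
#'   hypermean), or `"sigma"` (hyper-SD on the unconstrained scale).
#' @return Numeric vector of posterior draws.
#' @export
hyper_draws <- function(fit, parameter,
                        scale = c("hypermean", "popmean", "unconstrained",
                                  "sigma")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "bandit_fit"))
  if (fit$method != "hmc") stop("draws are only available for HMC fits")
  if (parameter %in% c("alpha", "beta")) {
    if (!fit$model$coupled_learning_rates)
      stop("alpha/beta are defined only for coupled models (1-2)")
    lr_r <- hyper_draws(fit, "lr_r", scale = if (scale == "sigma") "hypermean" else scale)
    lr_p <- hyper_draws(fit, "lr_p", scale = if (scale == "sigma") "hypermean" else scale)
    return(if (parameter == "alpha") (lr_r + lr_p) / 2 else (lr_r - lr_p) / 2)
  }
  parameter <- canonical_param(parameter)
  if (!parameter %in% fit$param_names)
    stop("parameter '", parameter, "' is not active in model ",
         fit$model$model_id)
  mu <- fit$draws$mu[, parameter]
  ub <- param_upper_bounds(fit$prior)[parameter]
  switch(scale,
    unconstrained = mu,
    sigma = fit$draws$sigma[, parameter],
    hypermean = pnorm(mu) * ub,
    popmean = {
      gh <- get_gh()
      sigma <- fit$draws$sigma[, parameter]
      out <- numeric(length(mu))
      for (q in seq_along(gh$nodes))
        out <- out + gh$weights[q] * pnorm(mu + sigma * gh$nodes[q])
      out * ub
    })
}

#' Posterior means of subject-level parameters
#'
#' @param fit A `bandit_fit`.
#' @return Matrix subjects x parameters on the constrained scale.
#' @export
subject_means <- function(fit) {
  stopifnot(inherits(fit, "bandit_fit"))
  if (fit$method == "map") return(fit$estimates$subject)
  J <- fit$data$n_subjects
  out <- matrix(0, J, length(fit$param_names),
                dimnames = list(names(fit$data$subjects), fit$param_names))
  for (j in seq_len(J))
    out[j, ] <- colMeans(fit$draws$theta[, 6 * (j - 1) + fit$active,
                                         drop = FALSE])
  out
}

#' Summarize a hierarchical bandit fit
#'
#' Group-level posterior means, SDs and 95% HDIs for each active parameter
#' on the constrained hypermean scale, with derived `alpha`, `beta`,
#' reward-LR and punishment-LR composites for coupled models (computed per
#' draw).
#'
#' @param object A `bandit_fit`.
#' @param ... Unused.
#' @return A `summary.bandit_fit` list with elements `hyper` (data frame)
#'   and `subjects` (posterior-mean matrix).
#' @export
summary.bandit_fit <- function(object, ...) {
  pn <- object$param_names
  if (object$method == "map") {
    ub <- param_upper_bounds(object$prior)[pn]
    hyper <- data.frame(
      parameter = pn,
      mean = unname(pnorm(object$estimates$mu) * ub),
      sd = NA_real_, hdi_lower = NA_real_, hdi_upper = NA_real_)
  } else {
    rows <- pn
    if (object$model$coupled_learning_rates) rows <- c(rows, "alpha", "beta")
    hyper <- do.call(rbind, lapply(rows, function(p) {
      dr <- hyper_draws(object, p, scale = "hypermean")
      ci <- hdi(dr)
      data.frame(parameter = p, mean = mean(dr), sd = sd(dr),
                 hdi_lower = ci[1], hdi_upper = ci[2])
    }))
  }
  rownames(hyper) <- NULL
  structure(list(hyper = hyper, subjects = subject_means(object),
                 model_id = object$model$model_id, group = object$data$group),
            class = "summary.bandit_fit")
}

#' @export
print.summary.bandit_fit <- function(x, ...) {
  cat(sprintf("Model %d, group '%s' - group-level estimates:\n",
              x$model_id, x$group))
  print(x$hyper, digits = 3)
  invisible(x)
}

#' @export
coef.bandit_fit <- function(object, level = c("group", "subject"), ...) {
  level <- match.arg(level)
  if (level == "subject") return(subject_means(object))
  s <- summary(object)$hyper
  setNames(s$mean, s$parameter)
}

#' @export
logLik.bandit_fit <- function(object, ...) {
  if (object$method == "map") {
    ll <- sum(vapply(seq_len(object$data$n_subjects), function(j) {
      th <- setNames(rep(0, 6), .param_names)
      th[object$param_names] <- object$estimates$subject[j, ]
      attr(run_trials(object$model, th, object$data$subjects[[j]],
                      reset_runs = object$reset_runs), "loglik")
    }, 0))
  } else {
    if (is.null(object$pointwise)) stop("fit has no pointwise log-likelihood")
    ll <- mean(rowSums(object$pointwise))
  }
  structure(ll, df = length(object$param_names) *
              (object$data$n_subjects + 2), class = "logLik")
}

#' Per-trial predicted choice probabilities
#'
#' Runs each subject's posterior-mean (or MAP) parameters through the
#' model and returns the policy probabilities for every trial.
#'
#' @param object A `bandit_fit`.
#' @param newdata Optional `bandit_data` to score instead of the training
#'   cohort (matched by position; must have the same number of subjects).
#' @param ... Unused.
#' @return Data frame with subject, trial, observed choice and `p1..p4`.
#' @export
predict.bandit_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else bandit_data(newdata)
  theta <- subject_means(object)
  out <- lapply(seq_len(data$n_subjects), function(j) {
    th <- setNames(rep(0, 6), .param_names)
    th[object$param_names] <- theta[min(j, nrow(theta)), ]
    tr <- run_trials(object$model, th, data$subjects[[j]],
                     reset_runs = object$reset_runs)
    cbind(subject = data$subjects[[j]]$subject_id,
          tr[c("trial", "choice", "p1", "p2", "p3", "p4")])
  })
  do.call(rbind, out)
}

#' @export
residuals.bandit_fit <- function(object, ...) {
  pr <- predict(object)
  pmat <- as.matrix(pr[c("p1", "p2", "p3", "p4")])
  1 - pmat[cbind(seq_len(nrow(pr)), pr$choice)]
}

#' Simulate datasets from a fitted model
#'
#' Forward-simulates one cohort per replicate using each subject's
#' posterior-mean parameters on a fresh task schedule.
#'
#' @param object A `bandit_fit`.
#' @param nsim Number of replicate cohorts.
#' @param seed Integer seed.
#' @param schedule Optional [generate_schedule()] output reused for all
#'   subjects; by default a new schedule per subject.
#' @param ... Unused.
#' @return List of `bandit_data` cohorts (length `nsim`).
#' @export
simulate.bandit_fit <- function(object, nsim = 1, seed = 1, schedule = NULL,
                                ...) {
  theta <- subject_means(object)
  lapply(seq_len(nsim), function(r) {
    dfs <- lapply(seq_len(nrow(theta)), function(j) {
      th <- setNames(rep(0, 6), .param_names)
      th[object$param_names] <- theta[j, ]
      sch <- schedule %||% generate_schedule(
        walk_config(seed = seed * 1000L + r * 100L + j))
      agent <- simulate_agent(object$model, th, sch,
                              seed = seed * 1000L + r * 100L + j + 50L)
      agent$subject <- sprintf("sim%02d", j)
      agent
    })
    bandit_data(do.call(rbind, dfs), group = paste0("sim", r))
  })
}

#' @export
plot.bandit_fit <- function(x, parameters = NULL, ...) {
  if (x$method != "hmc") stop("plotting requires an HMC fit")
  pars <- parameters %||% x$param_names
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    dr <- hyper_draws(x, p, scale = "hypermean")
    graphics::plot(stats::density(dr), main = p, xlab = "hypermean",
                   ...)
    ci <- hdi(dr)
    graphics::abline(v = ci, lty = 2)
  }
  invisible(x)
}
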