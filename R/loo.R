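# Pareto-smoothed importance-sampling leave-one-out cross-validation.
#
# The importance ratio for point i at draw s is 1/p(y_i | theta_s); the
# largest 20% of ratios are replaced by expected order statistics of a
# generalized Pareto distribution fitted to them (Zhang-Stephens
# estimator), and the pointwise ELPD is the log smoothed-weighted mean of
# the predictive density.

# Zhang & Stephens (2009) profile-posterior GPD fit to exceedances x > 0.
# Returns shape k (heavy tail when k > 0) and scale sigma, with the weak
# shape prior used by standard PSIS implementations.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  profile_lp <- vapply(b, function(bj) {
    k <- mean(log1p(-bj * x))
    n * (log(-bj / k) - k - 1)
  }, 0)
  profile_lp[!is.finite(profile_lp)] <- -Inf
  w <- exp(profile_lp - max(profile_lp))
  w <- w / sum(w)
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat
  # weakly informative shape prior towards 0.5 (stabilizes small tails)
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

# GPD quantile with the usual shape convention (k > 0: heavy tail).
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Smooth one point's log importance ratios; returns normalized log weights
# and the Pareto k diagnostic.
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lr <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k_hat <- Inf
  if (M >= 5 && S - M >= 1) {
    ord <- order(lr)
    tail_idx <- ord[(S - M + 1L):S]
    cut_log <- lr[ord[S - M]]
    exceed <- exp(lr[tail_idx]) - exp(cut_log)
    if (all(exceed >= 0) && max(exceed) > 0) {
      fit <- gpd_fit(exceed[exceed > 0])
      k_hat <- fit$k
      if (is.finite(fit$k) && fit$sigma > 0) {
        pq <- (seq_len(M) - 0.5) / M
        smoothed <- log(exp(cut_log) + qgpd(pq, fit$k, fit$sigma))
        smoothed <- pmin(smoothed, 0)  # truncate at max raw weight
        lr[tail_idx[order(lr[tail_idx])]] <- smoothed
      }
    } else k_hat <- -Inf
  }
  list(log_weights = lr - log_sum_exp(lr), k = k_hat)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' @param loglik Matrix of pointwise log-likelihood, draws x points (the
#'   point unit here is the trial).
#' @return A `bandit_loo` object: `elpd_loo`, `looic = -2 * elpd_loo`,
#'   `pointwise` per-point ELPD, `pareto_k` diagnostics and a
#'   `high_k_warning` flag (> 10% of points with k > 0.7).
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 100L) stop("need >= 100 posterior draws for PSIS-LOO")
  if (any(!is.finite(loglik))) stop("non-finite pointwise log-likelihood")
  N <- ncol(loglik)
  pointwise <- numeric(N)
  ks <- numeric(N)
  for (i in seq_len(N)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    pointwise[i] <- log_sum_exp(sm$log_weights + ll)
    ks[i] <- sm$k
  }
  elpd <- sum(pointwise)
  high <- mean(ks > 0.7, na.rm = TRUE)
  structure(list(elpd_loo = elpd, looic = -2 * elpd,
                 pointwise = pointwise, pareto_k = ks,
                 high_k_warning = high > 0.1, n_points = N,
                 n_draws = nrow(loglik)),
            class = "bandit_loo")
}

#' @export
print.bandit_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo %.1f, LOOIC %.1f (%d points, %d draws)\n",
              x$elpd_loo, x$looic, x$n_points, x$n_draws))
  if (x$high_k_warning)
    cat("  warning: >10% of points have Pareto k > 0.7\n")
  invisible(x)
}

#' PSIS-LOO for a fitted bandit model
#'
#' @param fit A `bandit_fit` with stored pointwise log-likelihood.
#' @return A `bandit_loo`; the pointwise matrix is attached as
#'   `attr(, "loglik")` for use by [compare_models()].
#' @export
bandit_loo <- function(fit) {
  stopifnot(inherits(fit, "bandit_fit"))
  if (is.null(fit$pointwise))
    stop("fit carries no pointwise log-likelihood (pointwise = FALSE?)")
  out <- psis_loo(fit$pointwise)
  attr(out, "loglik") <- fit$pointwise
  attr(out, "model_id") <- fit$model$model_id
  out
}

#' Sigma effect of an ELPD difference
#'
#' The ratio between an ELPD difference and the standard error of the
#' difference, a heuristic for the significance of model differences. The
#' best model (difference 0) has no sigma effect (NA, printed as "-").
#'
#' @param elpd_diff ELPD difference versus the best model (<= 0).
#' @param se_diff Standard error of the difference.
#' @return `elpd_diff / se_diff` (NA where `elpd_diff == 0`).
#' @export
sigma_effect <- function(elpd_diff, se_diff) {
  ifelse(elpd_diff == 0, NA_real_, elpd_diff / se_diff)
}

#' Compare models by out-of-sample predictive density
#'
#' Ranks models by LOOIC and reports, for each model, the ELPD difference
#' to the best model, the SE of that difference (computed from the
#' pointwise-difference vector: `sqrt(n * var(diff_i))`), and the sigma
#' effect.
#'
#' @param ... `bandit_loo` objects (or a single list of them), all scored
#'   on identical points in identical order.
#' @param model_ids Optional labels; defaults to attached model ids or
#'   positions.
#' @return Data frame of class `bandit_compare` with columns `model`,
#'   `elpd_diff`, `se_diff`, `sigma_effect`, `looic`, sorted by LOOIC.
#' @export
compare_models <- function(..., model_ids = NULL) {
  loos <- list(...)
  if (length(loos) == 1L && !inherits(loos[[1]], "bandit_loo"))
    loos <- loos[[1]]
  if (length(loos) < 2L) stop("need at least two models to compare")
  n_pts <- vapply(loos, function(l) l$n_points, 0L)
  if (length(unique(n_pts)) != 1L)
    stop("models were scored on different numbers of points")
  if (is.null(model_ids))
    model_ids <- vapply(seq_along(loos), function(i)
      attr(loos[[i]], "model_id") %||% i, 0)
  elpd <- vapply(loos, function(l) l$elpd_loo, 0)
  best <- which.max(elpd)
  rows <- lapply(seq_along(loos), function(i) {
    diff_i <- loos[[i]]$pointwise - loos[[best]]$pointwise
    ed <- elpd[i] - elpd[best]
    se <- if (i == best) 0 else sqrt(length(diff_i) * var(diff_i))
    data.frame(model = model_ids[i], elpd_diff = ed, se_diff = se,
               sigma_effect = sigma_effect(ed, se),
               looic = loos[[i]]$looic)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$looic), ]
  rownames(out) <- NULL
  class(out) <- c("bandit_compare", "data.frame")
  out
}

#' @export
print.bandit_compare <- function(x, ...) {
  y <- as.data.frame(x)
  y$sigma_effect <- ifelse(is.na(y$sigma_effect), "-",
                           format(y$sigma_effect, digits = 5))
  print(y, ...)
  invisible(x)
}
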