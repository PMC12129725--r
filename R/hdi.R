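#' Highest-density interval of a sample of draws
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' found by scanning sorted draws.
#'
#' @param draws Numeric vector of posterior draws (>= some minimum to
#'   resolve the mass; all-equal draws give a degenerate interval).
#' @param mass Probability mass (default 0.95).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e4))
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  k <- ceiling(mass * n)
  if (n < 2L || k < 2L)
    stop("too few draws (", n, ") to resolve mass ", mass)
  x <- sort(draws)
  widths <- x[k:n] - x[1:(n - k + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1L])
}

# Seeded random involution of 1..n: a self-inverse pairing used to align
# draws from two independently fitted posteriors. Involutivity makes
# group_difference(A, B) exactly antisymmetric in its arguments.
random_involution <- function(n, seed) {
  set.seed(seed)
  p <- sample.int(n)
  inv <- integer(n)
  half <- floor(n / 2)
  a <- p[seq_len(half)]
  b <- p[half + seq_len(half)]
  inv[a] <- b
  inv[b] <- a
  if (n %% 2 == 1L) inv[p[n]] <- p[n]
  inv
}

#' Posterior group difference with 95% HDI
#'
#' Groups are fitted independently, so their draws are exchangeable; the
#' difference distribution is formed by pairing draws through a seeded
#' random involution (self-inverse index pairing, making the operation
#' exactly antisymmetric in its arguments). If draw counts differ, the
#' larger set is subsampled with the same seed. A difference is flagged
#' significant when the HDI excludes zero.
#'
#' @param fit_a,fit_b `bandit_fit` objects (or plain numeric draw vectors).
#' @param parameter Parameter name passed to [hyper_draws()]; ignored for
#'   plain vectors.
#' @param scale Scale passed to [hyper_draws()] (default `"hypermean"`).
#' @param mass HDI mass (default 0.95).
#' @param seed Seed for pairing/subsampling.
#' @return A `bandit_hdi` list: `parameter`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `lower`, `upper`, `significant`, `mass`.
#' @export
group_difference <- function(fit_a, fit_b, parameter = "P",
                             scale = "hypermean", mass = 0.95, seed = 1) {
  da <- if (is.numeric(fit_a)) fit_a else hyper_draws(fit_a, parameter, scale)
  db <- if (is.numeric(fit_b)) fit_b else hyper_draws(fit_b, parameter, scale)
  n <- min(length(da), length(db))
  if (length(da) > n) { set.seed(seed + 1L); da <- da[sample.int(length(da), n)] }
  if (length(db) > n) { set.seed(seed + 1L); db <- db[sample.int(length(db), n)] }
  pair <- random_involution(n, seed)
  diff <- da - db[pair]
  ci <- hdi(diff, mass)
  structure(list(parameter = parameter,
                 mean_a = mean(da), sd_a = sd(da),
                 mean_b = mean(db), sd_b = sd(db),
                 lower = unname(ci[1]), upper = unname(ci[2]),
                 significant = ci[1] > 0 || ci[2] < 0,
                 mass = mass, n_draws = n),
            class = "bandit_hdi")
}

#' @export
print.bandit_hdi <- function(x, ...) {
  cat(sprintf("%s: A %.3f (%.3f) vs B %.3f (%.3f); %.0f%% HDI of difference [%.3f, %.3f]%s\n",
              x$parameter, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
              100 * x$mass, x$lower, x$upper,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Full group contrast table
#'
#' [group_difference()] applied to every active parameter of two fits of
#' the same model (plus derived `alpha`/`beta` for coupled models),
#' mirroring a group-comparison table: group means and SDs, lower/upper
#' 95% HDI of the difference and a significance marker.
#'
#' @inheritParams group_difference
#' @return Data frame with one row per parameter.
#' @export
group_contrast <- function(fit_a, fit_b, scale = "hypermean", mass = 0.95,
                           seed = 1) {
  stopifnot(fit_a$model$model_id == fit_b$model$model_id)
  pars <- fit_a$param_names
  if (fit_a$model$coupled_learning_rates) pars <- c(pars, "alpha", "beta")
  rows <- lapply(pars, function(p) {
    g <- group_difference(fit_a, fit_b, p, scale, mass, seed)
    data.frame(parameter = p, mean_a = g$mean_a, sd_a = g$sd_a,
               mean_b = g$mean_b, sd_b = g$sd_b,
               hdi_lower = g$lower, hdi_upper = g$upper,
               significant = g$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
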