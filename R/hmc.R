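# No-U-Turn sampler driver used by fit_bandit().
#
# NUTS (slice variant) with dual-averaging step-size adaptation towards a
# target acceptance rate and a diagonal mass matrix, optionally seeded from
# curvature and re-estimated from a mid-warmup window. Densities are
# supplied as a function returning list(lp, grad) on the unconstrained
# scale. The RL likelihood surface is ridged and near-deterministic in
# places, so dynamic trajectory lengths matter: fixed-length HMC stalls.

leapfrog <- function(lp_grad, q, p, grad, eps, inv_mass) {
  p <- p + 0.5 * eps * grad
  q <- q + eps * (p * inv_mass)
  st <- lp_grad(q)
  if (!is.finite(st$lp) || any(!is.finite(st$grad)))
    return(list(ok = FALSE))
  p <- p + 0.5 * eps * st$grad
  list(ok = TRUE, q = q, p = p, lp = st$lp, grad = st$grad)
}

kinetic <- function(p, inv_mass) 0.5 * sum(p^2 * inv_mass)

# Recursive tree doubling (Hoffman & Gelman slice formulation). `joint0`
# is lp - kinetic at trajectory start; divergences are joint drops > 1000.
build_tree <- function(lp_grad, q, p, grad, log_u, v, depth, eps, inv_mass,
                       joint0) {
  if (depth == 0L) {
    st <- leapfrog(lp_grad, q, p, grad, v * eps, inv_mass)
    if (!st$ok)
      # endpoints kept well-defined even on a failed step
      return(list(q_minus = q, p_minus = p, grad_minus = grad,
                  q_plus = q, p_plus = p, grad_plus = grad,
                  q_prop = q, lp_prop = -Inf,
                  s = FALSE, n = 0L, divergent = TRUE, alpha = 0,
                  n_alpha = 1L))
    joint <- st$lp - kinetic(st$p, inv_mass)
    divergent <- (joint0 - joint) > 1000
    list(q_minus = st$q, p_minus = st$p, grad_minus = st$grad,
         q_plus = st$q, p_plus = st$p, grad_plus = st$grad,
         q_prop = st$q, lp_prop = st$lp,
         n = as.integer(log_u <= joint),
         s = !divergent && (log_u < joint + 1000),
         divergent = divergent,
         alpha = min(1, exp(joint - joint0)), n_alpha = 1L)
  } else {
    t1 <- build_tree(lp_grad, q, p, grad, log_u, v, depth - 1L, eps,
                     inv_mass, joint0)
    if (!t1$s) return(t1)
    if (v == -1) {
      t2 <- build_tree(lp_grad, t1$q_minus, t1$p_minus, t1$grad_minus,
                       log_u, v, depth - 1L, eps, inv_mass, joint0)
      if (isTRUE(t2$s)) {
        t1$q_minus <- t2$q_minus; t1$p_minus <- t2$p_minus
        t1$grad_minus <- t2$grad_minus
      }
    } else {
      t2 <- build_tree(lp_grad, t1$q_plus, t1$p_plus, t1$grad_plus,
                       log_u, v, depth - 1L, eps, inv_mass, joint0)
      if (isTRUE(t2$s)) {
        t1$q_plus <- t2$q_plus; t1$p_plus <- t2$p_plus
        t1$grad_plus <- t2$grad_plus
      }
    }
    if (isTRUE(t2$s) && t2$n > 0L &&
        runif(1) < t2$n / max(t1$n + t2$n, 1L)) {
      t1$q_prop <- t2$q_prop
      t1$lp_prop <- t2$lp_prop
    }
    t1$n <- t1$n + t2$n
    t1$alpha <- t1$alpha + t2$alpha
    t1$n_alpha <- t1$n_alpha + t2$n_alpha
    t1$divergent <- t1$divergent || isTRUE(t2$divergent)
    dq <- t1$q_plus - t1$q_minus
    t1$s <- isTRUE(t2$s) &&
      sum(dq * (t1$p_minus * inv_mass)) >= 0 &&
      sum(dq * (t1$p_plus * inv_mass)) >= 0
    t1
  }
}

hmc_chain <- function(lp_grad, init, warmup, iter, control = list()) {
  ctl <- modifyList(list(target_accept = 0.8, max_depth = 9L,
                         init_step = 0.1, inv_mass = NULL), control)
  d <- length(init)
  q <- init
  cur <- lp_grad(q)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initial value")

  inv_mass <- ctl$inv_mass %||% rep(1, d)
  eps <- find_initial_step(lp_grad, q, cur, ctl$init_step, inv_mass)
  da <- da_init(eps)
  # Stan-style adaptation schedule: initial step-size-only buffer, then
  # doubling covariance windows, then a terminal step-size-only buffer.
  win_ends <- adapt_windows(warmup)
  win_buf <- NULL

  total <- warmup + iter
  draws <- matrix(0, nrow = iter, ncol = d)
  lps <- numeric(iter)
  div_sampling <- 0L
  accept_sum <- 0
  depth_sum <- 0L

  for (m in seq_len(total)) {
    p0 <- rnorm(d) / sqrt(inv_mass)
    joint0 <- cur$lp - kinetic(p0, inv_mass)
    log_u <- joint0 - stats::rexp(1)
    tree <- list(q_minus = q, p_minus = p0, grad_minus = cur$grad,
                 q_plus = q, p_plus = p0, grad_plus = cur$grad)
    q_new <- q; lp_new <- cur$lp
    n <- 1L; s <- TRUE; depth <- 0L
    alpha <- 0; n_alpha <- 0L; divergent <- FALSE
    while (s && depth < ctl$max_depth) {
      v <- if (runif(1) < 0.5) -1 else 1
      sub <- if (v == -1)
        build_tree(lp_grad, tree$q_minus, tree$p_minus, tree$grad_minus,
                   log_u, v, depth, eps, inv_mass, joint0)
      else
        build_tree(lp_grad, tree$q_plus, tree$p_plus, tree$grad_plus,
                   log_u, v, depth, eps, inv_mass, joint0)
      alpha <- alpha + sub$alpha
      n_alpha <- n_alpha + sub$n_alpha
      divergent <- divergent || isTRUE(sub$divergent)
      if (isTRUE(sub$s)) {
        if (v == -1) {
          tree$q_minus <- sub$q_minus; tree$p_minus <- sub$p_minus
          tree$grad_minus <- sub$grad_minus
        } else {
          tree$q_plus <- sub$q_plus; tree$p_plus <- sub$p_plus
          tree$grad_plus <- sub$grad_plus
        }
        if (sub$n > 0L && runif(1) < sub$n / n) {
          q_new <- sub$q_prop
          lp_new <- sub$lp_prop
        }
        n <- n + sub$n
        dq <- tree$q_plus - tree$q_minus
        s <- sum(dq * (tree$p_minus * inv_mass)) >= 0 &&
             sum(dq * (tree$p_plus * inv_mass)) >= 0
      } else s <- FALSE
      depth <- depth + 1L
    }
    if (lp_new != cur$lp || any(q_new != q)) {
      q <- q_new
      cur <- lp_grad(q)
    }
    a_stat <- if (n_alpha > 0L) alpha / n_alpha else 0

    if (m <= warmup) {
      da <- da_update(da, ctl$target_accept - a_stat)
      eps <- da$eps
      if (length(win_ends)) {
        win_buf <- rbind(win_buf, q)
        if (m == win_ends[1]) {
          if (nrow(win_buf) >= 10L) {
            v_est <- apply(win_buf, 2, var)
            nw <- nrow(win_buf)
            # regularized, blended with the current mass so a barely-
            # moving window cannot zero out a coordinate
            inv_mass <- pmax((v_est * nw + 1e-3 * 5) / (nw + 5),
                             0.05 * inv_mass)
            da <- da_init(eps)
          }
          win_buf <- NULL
          win_ends <- win_ends[-1]
        }
      }
      if (m == warmup) eps <- da$eps_bar
    } else {
      draws[m - warmup, ] <- q
      lps[m - warmup] <- cur$lp
      if (divergent) div_sampling <- div_sampling + 1L
      accept_sum <- accept_sum + a_stat
      depth_sum <- depth_sum + depth
    }
  }
  list(draws = draws, lp = lps, divergences = div_sampling,
       accept_rate = accept_sum / iter, step_size = eps,
       mean_tree_depth = depth_sum / iter)
}

# End indices of doubling covariance-adaptation windows within warmup
# (init buffer 15%, terminal buffer 10%, base window 25 iterations).
adapt_windows <- function(warmup) {
  init_buf <- max(10L, floor(0.15 * warmup))
  term_buf <- max(10L, floor(0.10 * warmup))
  if (warmup < init_buf + term_buf + 20L)
    return(floor(warmup / 2))
  ends <- integer(0)
  start <- init_buf
  size <- 25L
  while (start + size < warmup - term_buf) {
    nxt <- start + size
    # absorb the remainder if the next doubling would overshoot
    if (nxt + 2L * size >= warmup - term_buf) nxt <- warmup - term_buf
    ends <- c(ends, nxt)
    start <- nxt
    size <- size * 2L
  }
  if (!length(ends)) ends <- warmup - term_buf
  ends
}

# Nesterov dual averaging (standard constants gamma .05, t0 10, kappa .75).
da_init <- function(eps) {
  list(mu = log(10 * eps), log_eps_bar = log(eps), H_bar = 0, m = 0,
       eps = eps, eps_bar = eps)
}

da_update <- function(da, h) {
  da$m <- da$m + 1
  frac <- 1 / (da$m + 10)
  da$H_bar <- (1 - frac) * da$H_bar + frac * h
  log_eps <- da$mu - sqrt(da$m) / 0.05 * da$H_bar
  w <- da$m^(-0.75)
  da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
  da$eps <- exp(log_eps)
  da$eps_bar <- exp(da$log_eps_bar)
  da
}

find_initial_step <- function(lp_grad, q, cur, eps, inv_mass) {
  d <- length(q)
  p0 <- rnorm(d) / sqrt(inv_mass)
  H0 <- -cur$lp + kinetic(p0, inv_mass)
  try_eps <- function(eps) {
    st <- leapfrog(lp_grad, q, p0, cur$grad, eps, inv_mass)
    if (!st$ok) return(-Inf)
    -(-st$lp + kinetic(st$p, inv_mass)) + H0
  }
  a <- try_eps(eps)
  dir <- if (is.finite(a) && a > log(0.5)) 1 else -1
  for (i in 1:20) {
    eps2 <- eps * 2^dir
    a2 <- try_eps(eps2)
    ok <- is.finite(a2) && a2 > log(0.5)
    if ((dir == 1 && !ok) || (dir == -1 && ok)) break
    eps <- eps2
  }
  eps
}

# Split-half potential scale reduction factor over a draws x chains matrix.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(sub)
  if (half < 2L || m < 2L) return(NA_real_)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  B <- half * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size from combined-chain autocovariance (Geyer initial
# monotone positive sequence).
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acov <- sapply(seq_len(m), function(j) {
    v <- x[, j] - mean(x[, j])
    stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE,
               type = "covariance")$acf[, 1, 1]
  })
  acov <- as.matrix(acov)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n +
    (if (m > 1) var(colMeans(x)) else 0)
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  rho[1] <- 1
  tau <- 0
  t <- 1
  prev <- Inf
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
    t <- t + 2
  }
  tau <- max(tau * 2 - 1, 1 / n)
  n * m / tau
}
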