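# Independent oracles and small fixture builders used across the suite.

# Naive unvectorized R reference for the trial loop: decay -> policy ->
# prediction errors -> update, written directly from the model equations,
# deliberately separate from the package's C++ path.
oracle_trace_loglik <- function(model, params, trials, reset_runs = FALSE) {
  th <- c(R = 0, P = 0, lr_r = 0, lr_p = 0, d = 0, xi = 0)
  th[names(params)] <- params
  qr <- qp <- rep(0, 4)
  total <- 0
  for (t in seq_len(nrow(trials))) {
    if (t == 1 || (reset_runs && !is.null(trials$run) &&
                   trials$run[t] != trials$run[t - 1])) {
      qr <- qp <- rep(0, 4)
    }
    if (model$has_decay) {
      qr <- (1 - th[["d"]]) * qr
      qp <- (1 - th[["d"]]) * qp
    }
    v <- qr + qp
    p <- exp(v - max(v))
    p <- p / sum(p)
    if (model$has_lapse) p <- p * (1 - th[["xi"]]) + th[["xi"]] / 4
    c_t <- trials$choice[t]
    total <- total + log(max(p[c_t], 1e-12))
    dr <- th[["R"]] * trials$win[t] - qr[c_t]
    dp <- th[["P"]] * trials$loss[t] - qp[c_t]
    qr[c_t] <- qr[c_t] + th[["lr_r"]] * dr
    qp[c_t] <- qp[c_t] + th[["lr_p"]] * dp
  }
  total
}

random_trials <- function(n, seed) {
  set.seed(seed)
  data.frame(choice = sample(1:4, n, replace = TRUE),
             win = sample(0:1, n, replace = TRUE),
             loss = -sample(0:1, n, replace = TRUE),
             run = sort(rep_len(1:2, n)))
}

random_params <- function(model, seed) {
  set.seed(seed)
  th <- c(R = runif(1, 0, 20), P = runif(1, 0, 20),
          lr_r = runif(1), lr_p = runif(1),
          d = if (model$has_decay) runif(1) else 0,
          xi = if (model$has_lapse) runif(1) else 0)
  th
}

tiny_cohort <- function(model_id = 5, n_subjects = 3, n_trials = 40,
                        seed = 1) {
  simulate_cohort(model = model_id, n_subjects = n_subjects, seed = seed,
                  group = "arthritis",
                  walk = list(n_trials = n_trials, n_runs = 2))
}

# ---- exhaustive graph oracles (n <= 8) ----

oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (w in which(adj[u, ] > 0))
      if (d[w] == Inf) { d[w] <- d[u] + 1; nxt <- c(nxt, w) }
    frontier <- unique(nxt)
  }
  d
}

# all shortest paths s -> t by recursive descent on distance-to-t
oracle_all_shortest_paths <- function(adj, s, t) {
  dt <- oracle_bfs_dist(adj, t)
  if (!is.finite(dt[s])) return(list())
  recur <- function(u) {
    if (u == t) return(list(t))
    succ <- which(adj[u, ] > 0 & dt == dt[u] - 1)
    out <- list()
    for (w in succ) for (pp in recur(w)) out <- c(out, list(c(u, pp)))
    out
  }
  recur(s)
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_shortest_paths(adj, s, t)
    if (!length(paths)) next
    for (pp in paths) {
      mid <- setdiff(pp, c(s, t))
      btw[mid] <- btw[mid] + 1 / length(paths)
    }
  }
  btw
}

# equal-split packet flow (one unit s -> t, split among onward shortest-
# path successors at each junction), summed over ordered pairs, halved
oracle_load <- function(adj) {
  n <- nrow(adj)
  load <- numeric(n)
  for (s in 1:n) for (t in 1:n) {
    if (s == t) next
    dt <- oracle_bfs_dist(adj, t)
    if (!is.finite(dt[s])) next
    flow_through <- numeric(n)
    recur <- function(u, amount) {
      if (u != s) flow_through[u] <<- flow_through[u] + amount
      if (u == t) return(invisible())
      succ <- which(adj[u, ] > 0 & dt == dt[u] - 1)
      for (w in succ) recur(w, amount / length(succ))
    }
    recur(s, 1)
    mid <- setdiff(seq_len(n), c(s, t))
    load[mid] <- load[mid] + flow_through[mid]
  }
  load / 2
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    d <- oracle_bfs_dist(adj, i)[-i]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d[reach]))
  }, 0)
}

oracle_eigenvector <- function(adj) {
  ev <- abs(eigen(adj, symmetric = TRUE)$vectors[, 1])
  ev / max(ev)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# ---- conjugate toy for exact leave-one-out ----
# y_i ~ N(mu, 1), mu ~ N(0, 1): exact posterior and exact LOO predictive.
conjugate_posterior <- function(y) {
  n <- length(y)
  v <- 1 / (n + 1)
  list(mean = sum(y) * v, var = v)
}
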