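# Connectivity stage: parcel time series -> Pearson correlation network ->
# fixed-link-density binary graph -> nodal centralities -> Bayes-factor
# correlation screen with Bayesian FDR control.

#' Elementwise sum of task-run time series
#'
#' Task runs are summed elementwise (parcels x volumes), making the summed
#' task series comparable with a single resting-state series.
#'
#' @param runs List of numeric matrices (parcels x volumes) with identical
#'   dimensions and parcel order.
#' @return One matrix of the same shape.
#' @export
sum_task_runs <- function(runs) {
  if (!length(runs)) stop("no runs supplied")
  dims <- lapply(runs, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("runs differ in shape")
  Reduce(`+`, runs)
}

#' Pearson correlation matrix of parcel time series
#'
#' @param ts Numeric matrix, parcels x volumes; row names are parcel
#'   labels.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need >= 3 volumes")
  v <- apply(ts, 1, var)
  if (any(v == 0)) {
    bad <- rownames(ts)[v == 0] %||% which(v == 0)
    stop("zero-variance parcel(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(ts) > ncol(ts))
    warning("fewer volumes than parcels; correlation matrix is rank deficient")
  cc <- cor(t(ts))
  diag(cc) <- 1
  cc
}

#' Threshold a correlation matrix to a fixed link density
#'
#' Keeps the strongest edges by signed correlation (most positive; set
#' `absolute = TRUE` to rank by magnitude) until the nearest integer to
#' `density * n * (n - 1) / 2` edges are retained. Ties at the cutoff are
#' broken by lexicographic (i, j) order, making the graph deterministic.
#'
#' @param corr Symmetric matrix (e.g. from [correlation_matrix()]).
#' @param density Target link density in (0, 1].
#' @param absolute Rank edges by `|r|` instead of signed `r`.
#' @return A `bandit_graph`: list with `adjacency` (symmetric 0/1 matrix,
#'   zero diagonal), `n_edges`, `link_density` (realized).
#' @export
threshold_to_density <- function(corr, density = 0.10, absolute = FALSE) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n != ncol(corr) || any(abs(corr - t(corr)) > 1e-8))
    stop("corr must be a symmetric matrix")
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  m_max <- n * (n - 1) / 2
  m <- round(density * m_max)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- corr[upper.tri(corr)]
  if (absolute) vals <- abs(vals)
  # order by value descending, then (i, j) lexicographic for ties
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(m, m_max))]
  adj <- matrix(0L, n, n, dimnames = dimnames(corr))
  adj[cbind(ut[keep, 1], ut[keep, 2])] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, n_edges = length(keep),
                 link_density = length(keep) / m_max),
            class = "bandit_graph")
}

#' @export
print.bandit_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges (density %.3f)\n",
              nrow(x$adjacency), x$n_edges, x$link_density))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Five nodal centrality measures of a binary graph
#'
#' Degree (edge count), eigenvector (principal eigenvector by power
#' iteration, normalized to unit maximum), betweenness (shortest-path pair
#' fractions), closeness (classic definition per connected component,
#' scaled by the reachable fraction of the network), and Goh-style load
#' (unit packets routed along shortest paths, split equally at each
#' junction).
#'
#' @param g A `bandit_graph` (or plain adjacency matrix).
#' @param measures Subset of `c("degree", "eigenvector", "betweenness",
#'   "closeness", "load")` to compute (default: all five).
#' @return Data frame: `node` plus one column per requested measure.
#' @export
centralities <- function(g, measures = c("degree", "eigenvector",
                                         "betweenness", "closeness",
                                         "load")) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.matrix(g)) g <- structure(list(adjacency = g,
                                        n_edges = sum(g) / 2,
                                        link_density = NA),
                                   class = "bandit_graph")
  adj <- g$adjacency
  n <- nrow(adj)
  nodes <- rownames(adj) %||% as.character(seq_len(n))
  out <- data.frame(node = nodes, row.names = NULL)
  if (g$n_edges == 0) {
    warning("empty graph; all centralities are zero")
    for (m in measures) out[[m]] <- 0
    return(out)
  }
  ig <- as_igraph(g)
  for (m in measures)
    out[[m]] <- switch(m,
      degree = as.numeric(rowSums(adj)),
      eigenvector = power_iteration_centrality(adj),
      betweenness = as.numeric(igraph::betweenness(ig, directed = FALSE,
                                                   normalized = FALSE)),
      closeness = closeness_wf(igraph::distances(ig)),
      load = load_centrality(adj))
  out
}

# Principal-eigenvector centrality by power iteration (tolerance 1e-10),
# normalized so the maximum score is 1. Iterates on A + I: the unit shift
# keeps the eigenvectors, makes the dominant eigenvalue strictly largest
# in modulus, and so prevents oscillation on bipartite components.
power_iteration_centrality <- function(adj, tol = 1e-10, max_iter = 10000) {
  n <- nrow(adj)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(adj %*% v) + v
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(rep(0, n))
    w <- w / nrm
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v <- abs(v)
  v / max(v)
}

# Wasserman-Faust closeness: within-component closeness scaled by the
# fraction of the network the node can reach.
closeness_wf <- function(dmat) {
  n <- nrow(dmat)
  vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    reach <- is.finite(d) & d > 0
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d[reach]))
  }, 0)
}

# Goh-style load centrality: for every ordered source-target pair a unit
# packet travels along shortest paths, splitting equally among onward
# shortest-path successors at each junction; a node's load is the total
# flow through it (endpoints excluded), halved for undirected graphs.
load_centrality <- function(adj) {
  n <- nrow(adj)
  load <- numeric(n)
  nbrs <- apply(adj > 0, 1, which, simplify = FALSE)
  for (s in seq_len(n)) {
    dist <- bfs_dist(nbrs, s, n)
    reach <- which(is.finite(dist) & dist > 0)
    for (t in reach) {
      # forward pass over the s->t shortest-path DAG
      onpath <- nodes_on_paths(nbrs, dist, s, t)
      flow <- numeric(n)
      flow[s] <- 1
      for (v in onpath$order) {
        succ <- onpath$succ[[v]]
        if (length(succ))
          flow[succ] <- flow[succ] + flow[v] / length(succ)
      }
      mid <- setdiff(which(flow > 0), c(s, t))
      load[mid] <- load[mid] + flow[mid]
    }
  }
  load / 2
}

bfs_dist <- function(nbrs, s, n) {
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Restrict the BFS DAG from s to shortest paths reaching t; returns
# processing order (by distance) and successor lists.
nodes_on_paths <- function(nbrs, dist, s, t) {
  n <- length(dist)
  on <- logical(n)
  on[t] <- TRUE
  ord <- order(dist)
  ord <- ord[is.finite(dist[ord]) & dist[ord] <= dist[t]]
  for (v in rev(ord)) {
    if (on[v] || v == t) next
    nb <- nbrs[[v]]
    on[v] <- any(on[nb] & dist[nb] == dist[v] + 1)
  }
  on[s] <- TRUE
  succ <- vector("list", n)
  active <- which(on)
  for (v in active)
    succ[[v]] <- nbrs[[v]][on[nbrs[[v]]] & dist[nbrs[[v]]] == dist[v] + 1]
  list(order = active[order(dist[active])], succ = succ)
}

#' Default Bayes factor for a Pearson correlation
#'
#' Sample correlation plus the two-sided Bayes factor BF10 under a
#' symmetric stretched-beta prior on the population correlation
#' (width `prior_width`; width 1 is the flat default of standard
#' Bayesian-correlation software). The marginal likelihood uses the exact
#' sampling distribution of r (Gaussian-hypergeometric form) integrated
#' numerically over the prior.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @param prior_width Stretched-beta prior width kappa (> 0).
#' @param log_base Base for the returned log Bayes factor (default natural
#'   log; use 10 for log10 BF).
#' @return List with `r`, `bf10`, `log_bf`, `n`.
#' @export
bayes_pearson <- function(x, y, prior_width = 1, log_base = exp(1)) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  r <- cor(x, y)
  bf <- if (abs(r) >= 1 - 1e-12) Inf
        else correlation_bf10(n, r, kappa = prior_width)
  list(r = r, bf10 = bf, log_bf = log(bf) / log(log_base), n = n)
}

# Gauss hypergeometric 2F1(a, b; c; z) by power series; converges for
# z in [0, 1) with the large c (= n - 1/2) used here.
hyp2f1 <- function(a, b, cc, z, tol = 1e-14, max_terms = 100000) {
  term <- 1
  total <- 1
  for (k in seq_len(max_terms)) {
    term <- term * (a + k - 1) * (b + k - 1) / ((cc + k - 1) * k) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) break
  }
  total
}

# Likelihood ratio f(r | rho, n) / f(r | 0, n) from the exact density of
# the sample correlation (Fisher), r-independent factors cancelled.
corr_lik_ratio <- function(rho, n, r) {
  h0 <- hyp2f1(0.5, 0.5, n - 0.5, (1 + 0) / 2)
  vapply(rho, function(p) {
    (1 - p^2)^((n - 1) / 2) * (1 - p * r)^(-(n - 1.5)) *
      hyp2f1(0.5, 0.5, n - 0.5, (1 + p * r) / 2) / h0
  }, 0)
}

correlation_bf10 <- function(n, r, kappa = 1) {
  # stretched beta prior: rho = 2B - 1, B ~ Beta(1/kappa, 1/kappa)
  a <- 1 / kappa
  log_norm <- lbeta(a, a) + (2 * a - 1) * log(2)
  integrand <- function(rho)
    corr_lik_ratio(rho, n, r) *
      exp((a - 1) * (log1p(rho) + log1p(-rho)) - log_norm)
  stats::integrate(integrand, -1, 1, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

#' Convert a Bayes factor to posterior probability and PEP
#'
#' Under equal prior odds, `P(H1 | data) = BF10 / (1 + BF10)`; the
#' posterior error probability is its complement.
#'
#' @param bf Positive Bayes factor BF10.
#' @return List with `posterior_h1` and `pep`.
#' @export
bf_to_pep <- function(bf) {
  if (any(!is.finite(bf) & !is.infinite(bf)) || any(bf <= 0))
    stop("Bayes factor must be positive")
  p1 <- ifelse(is.infinite(bf), 1, bf / (1 + bf))
  list(posterior_h1 = p1, pep = 1 - p1)
}

#' Bayesian false-discovery-rate control from posterior error probabilities
#'
#' Tests are ranked by posterior probability of H1 descending (PEP
#' ascending); the q-value of the i-th ranked test is the cumulative mean
#' of the first i PEPs, and tests with q below the threshold are retained.
#'
#' @param peps Numeric vector of posterior error probabilities in `[0, 1]`.
#' @param threshold FDR threshold (default 0.01).
#' @return Data frame in the original order with `pep`, `rank`, `q_value`,
#'   `retained`.
#' @export
bayes_fdr <- function(peps, threshold = 0.01) {
  if (!length(peps))
    return(data.frame(pep = numeric(0), rank = integer(0),
                      q_value = numeric(0), retained = logical(0)))
  if (any(peps < 0 | peps > 1)) stop("PEPs must lie in [0, 1]")
  ord <- order(peps)
  q_sorted <- cumsum(peps[ord]) / seq_along(peps)
  q <- numeric(length(peps))
  q[ord] <- q_sorted
  rank <- integer(length(peps))
  rank[ord] <- seq_along(peps)
  data.frame(pep = peps, rank = rank, q_value = q,
             retained = q < threshold)
}

#' Screen nodal centrality against clinical scores
#'
#' One Bayesian Pearson correlation per (node of interest x clinical
#' score), with missing values dropped pairwise, cells with fewer than 4
#' complete pairs marked untestable, and Bayesian FDR applied across the
#' whole screen.
#'
#' @param centrality Data frame or matrix, subjects x nodes (columns named
#'   by node), e.g. one [centralities()] measure gathered across subjects.
#' @param clinical Data frame, subjects x named scores (same row order as
#'   `centrality`).
#' @param nodes Node columns to screen (default: all).
#' @param scores Score columns to screen (default: all).
#' @param threshold Bayesian FDR threshold (default 0.01).
#' @param prior_width,log_base Passed to [bayes_pearson()].
#' @return Data frame of class `bandit_screen`: one row per node x score
#'   with `r`, `log_bf`, `posterior_h1`, `pep`, `q_value`, `retained`,
#'   `n`, `testable`.
#' @export
centrality_screen <- function(centrality, clinical, nodes = NULL,
                              scores = NULL, threshold = 0.01,
                              prior_width = 1, log_base = exp(1)) {
  centrality <- as.data.frame(centrality)
  clinical <- as.data.frame(clinical)
  if (nrow(centrality) != nrow(clinical))
    stop("centrality and clinical tables must align by subject")
  nodes <- nodes %||% names(centrality)
  scores <- scores %||% names(clinical)
  rows <- list()
  for (nd in nodes) for (sc in scores) {
    xv <- centrality[[nd]]; yv <- clinical[[sc]]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 4L || sd(xv[ok]) == 0 || sd(yv[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, score = sc, r = NA_real_, log_bf = NA_real_,
        posterior_h1 = NA_real_, pep = NA_real_, n = sum(ok),
        testable = FALSE)
      next
    }
    bp <- bayes_pearson(xv[ok], yv[ok], prior_width, log_base)
    pp <- bf_to_pep(bp$bf10)
    rows[[length(rows) + 1L]] <- data.frame(
      node = nd, score = sc, r = bp$r, log_bf = bp$log_bf,
      posterior_h1 = pp$posterior_h1, pep = pp$pep, n = bp$n,
      testable = TRUE)
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$retained <- FALSE
  idx <- which(out$testable)
  if (length(idx)) {
    fdr <- bayes_fdr(out$pep[idx], threshold)
    out$q_value[idx] <- fdr$q_value
    out$retained[idx] <- fdr$retained
  }
  class(out) <- c("bandit_screen", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.bandit_screen <- function(x, ...) {
  cat(sprintf("Centrality screen: %d cells (%d testable), %d retained at FDR %.2g\n",
              nrow(x), sum(x$testable), sum(x$retained),
              attr(x, "threshold")))
  print(as.data.frame(x)[x$retained, ], digits = 3)
  invisible(x)
}
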