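test_that("task runs are summed elementwise", {
  set.seed(1)
  runs <- lapply(1:4, function(i) matrix(rnorm(20), 4, 5))
  expect_equal(sum_task_runs(runs[1]), runs[[1]])
  expect_equal(sum_task_runs(list(runs[[1]], runs[[1]], runs[[1]],
                                  runs[[1]])), 4 * runs[[1]])
  expect_equal(sum_task_runs(runs), sum_task_runs(rev(runs)))
  expect_error(sum_task_runs(list(runs[[1]], matrix(0, 3, 5))), "shape")
})

test_that("correlation matrices match the pairwise scalar formula", {
  set.seed(2)
  ts <- matrix(rnorm(5 * 200), 5, 200)
  ts[2, ] <- -ts[1, ] + rnorm(200, 0, 1e-8)
  cc <- correlation_matrix(ts)
  expect_equal(diag(cc), rep(1, 5))
  expect_equal(cc, t(cc))
  expect_equal(cc[1, 2], -1, tolerance = 1e-6)
  # definitional oracle per pair
  for (i in 1:4) for (j in (i + 1):5) {
    x <- ts[i, ]; y <- ts[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cc[i, j], r, tolerance = 1e-12)
  }
  bad <- ts; bad[3, ] <- 2
  rownames(bad) <- paste0("p", 1:5)
  expect_error(correlation_matrix(bad), "p3")
  expect_error(correlation_matrix(ts[, 1:2]), "volumes")
})

test_that("density thresholding keeps the strongest edges deterministically", {
  set.seed(3)
  n <- 180
  ts <- matrix(rnorm(n * 60), n, 60)
  expect_warning(cc180 <- correlation_matrix(ts), "rank")
  g <- threshold_to_density(cc180, 0.10)
  expect_equal(g$n_edges, 1611)            # round(0.10 * 180 * 179 / 2)
  expect_equal(g$adjacency, t(g$adjacency))
  expect_equal(diag(g$adjacency), rep(0L, n))
  full <- threshold_to_density(cc180, 1)
  expect_equal(full$n_edges, n * (n - 1) / 2)
  # tie-break contract: all-equal off-diagonal values retain the first
  # edges in (i, j) lexicographic order
  m <- matrix(0.5, 6, 6); diag(m) <- 1
  gt <- threshold_to_density(m, 0.2)       # round(0.2 * 15) = 3 edges
  idx <- which(upper.tri(m) & gt$adjacency == 1, arr.ind = TRUE)
  expect_equal(idx[order(idx[, 1], idx[, 2]), , drop = FALSE],
               cbind(row = c(1, 1, 1), col = c(2, 3, 4)),
               ignore_attr = TRUE)
  expect_error(threshold_to_density(m, 0), "density")
  # absolute-value ranking is available
  m2 <- diag(4); m2[1, 2] <- m2[2, 1] <- -0.9; m2[3, 4] <- m2[4, 3] <- 0.5
  g_abs <- threshold_to_density(m2, 1 / 6, absolute = TRUE)
  expect_equal(g_abs$adjacency[1, 2], 1L)
  g_sgn <- threshold_to_density(m2, 1 / 6)
  expect_equal(g_sgn$adjacency[1, 2], 0L)
})

test_that("centralities reproduce closed forms on canonical graphs", {
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- 1L; star[2:5, 1] <- 1L
  ct <- centralities(star)
  expect_equal(ct$degree, c(4, 1, 1, 1, 1))
  expect_equal(ct$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(ct$load, c(6, 0, 0, 0, 0))
  expect_equal(ct$eigenvector[1], 1)
  complete <- matrix(1L, 6, 6); diag(complete) <- 0L
  cc <- centralities(complete)
  expect_equal(cc$degree, rep(5, 6))
  expect_equal(cc$betweenness, rep(0, 6))
  expect_equal(cc$eigenvector, rep(1, 6))
  expect_equal(cc$closeness, rep(1, 6))
  empty <- matrix(0L, 3, 3)
  expect_warning(ce <- centralities(empty), "empty")
  expect_equal(ce$degree, rep(0, 3))
})

test_that("all five measures match exhaustive path oracles on small graphs", {
  cases <- list(c(4, 0.5, 11), c(5, 0.4, 12), c(6, 0.35, 13), c(6, 0.6, 14),
                c(7, 0.3, 15), c(7, 0.5, 16), c(8, 0.25, 17), c(8, 0.45, 18))
  for (cs in cases) {
    adj <- random_graph(cs[1], cs[2], cs[3])
    if (sum(adj) == 0) next
    ct <- centralities(adj)
    expect_equal(ct$degree, rowSums(adj))
    expect_equal(ct$betweenness, oracle_betweenness(adj), tolerance = 1e-9)
    expect_equal(ct$load, oracle_load(adj), tolerance = 1e-9)
    expect_equal(ct$closeness, oracle_closeness(adj), tolerance = 1e-12)
    ev <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] - ev[2] > 1e-8)  # comparison well-posed only off ties
      expect_equal(ct$eigenvector, oracle_eigenvector(adj),
                   tolerance = 1e-6)
  }
})

test_that("load centrality agrees with an external graph-theory reference", {
  # frozen reference values (ordered-pair convention halved)
  adj <- matrix(c(0, 0, 0, 1, 1, 0, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0,
                  0, 1, 1, 1, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 1, 0, 0, 1, 0,
                  0, 1, 0, 0, 1, 0, 1, 0, 0, 0, 0), 7, byrow = TRUE)
  expect_equal(banditrl:::load_centrality(adj),
               c(17, 3, 0, 3, 9, 0, 10) / 2)
})

test_that("default correlation Bayes factors match the exact reference", {
  # frozen oracle values from an independent implementation of the
  # two-sided default Bayes factor (stretched prior, kappa = 1)
  ref <- list(list(29, 0.5, 8.73168329449498),
              list(29, 0.566, 30.241609428820095),
              list(20, 0.0, 0.2767696820767577),
              list(20, 0.3, 0.5996515690280951),
              list(50, -0.4, 9.864260804115133),
              list(15, 0.8, 106.81579337217329))
  for (cs in ref) {
    bf <- banditrl:::correlation_bf10(cs[[1]], cs[[2]])
    expect_equal(bf, cs[[3]], tolerance = 1e-6)
  }
  # quadrature refinement oracle: fine trapezoid grid
  n <- 29; r <- 0.5
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = 40001)
  f <- banditrl:::corr_lik_ratio(rho, n, r) * 0.5
  bf_grid <- sum((f[-1] + f[-length(f)]) / 2 * diff(rho))
  expect_equal(banditrl:::correlation_bf10(n, r), bf_grid,
               tolerance = 1e-6)
  # interface behaviour
  set.seed(5)
  x <- rnorm(20); y <- x
  expect_equal(bayes_pearson(x, y)$r, 1)
  expect_error(bayes_pearson(rep(1, 10), rnorm(10)), "constant")
  expect_error(bayes_pearson(x[1:3], y[1:3]), "4")
  b10 <- bayes_pearson(rnorm(30), rnorm(30), log_base = 10)
  expect_equal(b10$log_bf, log10(b10$bf10))
})

test_that("null data yields mostly evidence for H0", {
  set.seed(6)
  bfs <- vapply(1:200, function(i) {
    bayes_pearson(rnorm(20), rnorm(20))$bf10
  }, 0)
  expect_lt(median(bfs), 1)
})

test_that("Bayes factor to posterior-probability conversion follows Bayes rule", {
  expect_equal(bf_to_pep(1), list(posterior_h1 = 0.5, pep = 0.5))
  expect_equal(bf_to_pep(3), list(posterior_h1 = 0.75, pep = 0.25))
  expect_equal(bf_to_pep(Inf)$pep, 0)
  expect_error(bf_to_pep(0))
  expect_error(bf_to_pep(-2))
})

test_that("Bayesian FDR ranks PEPs and thresholds cumulative means", {
  fdr <- bayes_fdr(c(0.02, 0.04, 0.30), threshold = 0.05)
  expect_equal(fdr$q_value, c(0.02, 0.03, 0.12))
  expect_equal(fdr$retained, c(TRUE, TRUE, FALSE))
  # order independence of the input
  fdr2 <- bayes_fdr(c(0.30, 0.02, 0.04), threshold = 0.05)
  expect_equal(fdr2$q_value, c(0.12, 0.02, 0.03))
  expect_equal(bayes_fdr(rep(0, 5), threshold = 1e-6)$retained,
               rep(TRUE, 5))
  expect_equal(nrow(bayes_fdr(numeric(0))), 0)
  # q non-decreasing in rank; retained set shrinks with the threshold
  set.seed(8)
  peps <- runif(50)
  fdr3 <- bayes_fdr(peps, 0.5)
  expect_true(all(diff(fdr3$q_value[order(fdr3$rank)]) >= 0))
  for (th in c(0.5, 0.2, 0.1, 0.01)) {
    kept <- sum(bayes_fdr(peps, th)$retained)
    if (exists("prev_kept")) expect_lte(kept, prev_kept)
    prev_kept <- kept
  }
})

test_that("the centrality screen recovers a planted clinical correlation", {
  set.seed(9)
  n_sub <- 30
  cent <- matrix(rnorm(n_sub * 4), n_sub,
                 dimnames = list(NULL, paste0("node", 1:4)))
  clinical <- data.frame(
    pain = generate_clinical_scores(cent[, "node1"], 0.8, seed = 10),
    mood = rnorm(n_sub))
  sc <- centrality_screen(cent, clinical, threshold = 0.05)
  expect_equal(nrow(sc), 8)
  planted <- sc$node == "node1" & sc$score == "pain"
  expect_true(sc$retained[planted])
  expect_lte(sum(sc$retained), 2)
  # exact correlation reports r = 1
  clinical2 <- data.frame(self = cent[, "node2"])
  sc2 <- centrality_screen(cent, clinical2)
  expect_equal(sc2$r[sc2$node == "node2"], 1)
  # joint permutation of subjects leaves every row unchanged
  perm <- sample(n_sub)
  sc_perm <- centrality_screen(cent[perm, ], clinical[perm, , drop = FALSE],
                               threshold = 0.05)
  expect_equal(sc_perm$r, sc$r)
  expect_equal(sc_perm$q_value, sc$q_value)
  # incomplete cells are untestable and excluded from ranking
  clinical3 <- clinical
  clinical3$pain[4:n_sub] <- NA
  sc3 <- centrality_screen(cent, clinical3)
  expect_false(any(sc3$testable[sc3$score == "pain"]))
  expect_true(all(is.na(sc3$q_value[sc3$score == "pain"])))
})
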