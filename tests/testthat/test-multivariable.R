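classical_hotelling_p <- function(X1, X2) {
  k <- nrow(X1); n1 <- ncol(X1); n2 <- ncol(X2); n <- n1 + n2
  d <- rowMeans(X1) - rowMeans(X2)
  S <- ((n1 - 1) * stats::cov(t(X1)) + (n2 - 1) * stats::cov(t(X2))) / (n - 2)
  T2 <- (n1 * n2 / n) * drop(t(d) %*% solve(S) %*% d)
  stats::pf(T2 * (n - k - 1) / (k * (n - 2)), k, n - k - 1,
            lower.tail = FALSE)
}

test_that("degraph with k = p equals the classical Hotelling T2 test", {
  for (seed in 1:5) {
    set.seed(seed)
    genes <- c("A", "B", "C")
    x <- matrix(rnorm(3 * 20), 3, 20,
                dimnames = list(genes, sprintf("s%02d", 1:20)))
    x[, 11:20] <- x[, 11:20] + 0.3
    gr <- group_labels(colnames(x), rep(c("ctrl", "case"), each = 10))
    r <- degraph(triangle_pathway(), expression_matrix(x, "normalized"),
                 gr, k = 3)
    expect_equal(r$stats$p, classical_hotelling_p(x[, 1:10], x[, 11:20]),
                 tolerance = 1e-8)
  }
})

test_that("degraph is invariant to gene and within-group sample order", {
  sim <- simulate_preset("null", seed = 13)
  pw <- sim$collection[[3]]
  r1 <- degraph(pw, sim$em, sim$groups)
  x <- sim$em$values
  set.seed(1)
  x2 <- x[sample(nrow(x)), c(sample(1:4), sample(5:8))]
  r2 <- degraph(pw, expression_matrix(x2, "normalized"), sim$groups)
  expect_equal(r1$stats$p, r2$stats$p, tolerance = 1e-9)
})

test_that("degraph smoothing gains power for smooth shifts", {
  # mean shift aligned with the smallest-eigenvalue eigenvector (constant
  # on the connected graph): p at k=1 should usually beat full k
  pw <- build_pathway("line", LETTERS[1:6],
                      data.frame(source = LETTERS[1:5], target = LETTERS[2:6],
                                 sign = 1))
  wins <- 0
  for (seed in 1:60) {
    set.seed(seed)
    x <- matrix(rnorm(6 * 12), 6, 12,
                dimnames = list(LETTERS[1:6], sprintf("s%02d", 1:12)))
    x[, 7:12] <- x[, 7:12] + 0.8   # constant shift = smoothest signal
    gr <- group_labels(colnames(x), rep(c("ctrl", "case"), each = 6))
    em <- expression_matrix(x, "normalized")
    p1 <- degraph(pw, em, gr, k = 1)$stats$p
    pf <- degraph(pw, em, gr, k = 6)$stats$p
    if (p1 <= pf) wins <- wins + 1
  }
  expect_gte(wins / 60, 0.9)
})

test_that("decomposable concentration matches constrained numeric MLE", {
  fixtures <- 0
  seed <- 0
  while (fixtures < 10) {
    seed <- seed + 1
    pw <- make_random_pathway(sample(4:6, 1), 0.45, dag = TRUE,
                              seed = 300 + seed)
    if (nrow(pw$edges) < 2) next
    scaf <- pathtopo:::.jt_scaffold(pw, pw$nodes)
    genes <- sort(pw$nodes)
    A <- scaf$adjacency[genes, genes]
    set.seed(seed)
    n <- 40
    X <- matrix(rnorm(length(genes) * n), length(genes), n,
                dimnames = list(genes, NULL))
    Xc <- X - rowMeans(X)
    S <- tcrossprod(Xc) / n
    K <- pathtopo:::.decomposable_concentration(S, genes, scaf$jt)
    # off-graph entries are exactly zero
    off <- which(!A & upper.tri(A), arr.ind = TRUE)
    if (nrow(off)) expect_lt(max(abs(K[off])), 1e-10)
    # numeric maximization of the constrained Gaussian likelihood
    p <- length(genes)
    free <- which(upper.tri(A) & A, arr.ind = TRUE)
    nll <- function(par) {
      Km <- diag(par[1:p], p)
      for (r in seq_len(nrow(free))) {
        Km[free[r, 1], free[r, 2]] <- Km[free[r, 2], free[r, 1]] <-
          par[p + r]
      }
      ev <- eigen(Km, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev <= 1e-9)) return(1e10)
      -(sum(log(ev)) - sum(S * Km))
    }
    opt <- stats::optim(c(rep(1, p), rep(0, nrow(free))), nll,
                        method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))
    Kopt <- diag(opt$par[1:p], p)
    for (r in seq_len(nrow(free))) {
      Kopt[free[r, 1], free[r, 2]] <- Kopt[free[r, 2], free[r, 1]] <-
        opt$par[p + r]
    }
    expect_lt(max(abs(K - unname(Kopt))), 1e-4)
    fixtures <- fixtures + 1
  }
})

test_that("complete-graph concentration is the inverse sample covariance", {
  pw <- build_pathway("k4", LETTERS[1:4],
                      data.frame(source = c("A", "A", "A", "B", "B", "C"),
                                 target = c("B", "C", "D", "C", "D", "D"),
                                 sign = 1))
  scaf <- pathtopo:::.jt_scaffold(pw, pw$nodes)
  expect_equal(length(scaf$jt$cliques), 1)
  set.seed(5)
  X <- matrix(rnorm(4 * 25), 4, 25, dimnames = list(LETTERS[1:4], NULL))
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / 25
  dimnames(S) <- list(LETTERS[1:4], LETTERS[1:4])
  K <- pathtopo:::.decomposable_concentration(S, LETTERS[1:4], scaf$jt)
  expect_equal(K, solve(S), tolerance = 1e-10)
})

test_that("topology_gsa returns calibrated-looking permutation p-values", {
  pw <- two_clique_pathway()
  em <- gaussian_em(pw$nodes, n = 12, seed = 31)
  gr <- toy_groups(colnames(em$values))
  r <- topology_gsa(pw, em, gr, nperm = 200, seed = 4)
  expect_equal(r$status, "ok")
  expect_gte(r$stats$p, 1 / 201)
  expect_lte(r$stats$p, 1)
  expect_equal(length(r$cliques), 3)
  expect_true(all(vapply(r$cliques, function(cl) cl$score >= 0, logical(1))))
  # reproducible under seed
  r2 <- topology_gsa(pw, em, gr, nperm = 200, seed = 4)
  expect_identical(r2$stats$p, r$stats$p)
  # var test needs more samples than the largest clique
  small <- gaussian_em(pw$nodes, n = 6, seed = 32)
  rv <- topology_gsa(pw, small, toy_groups(colnames(small$values)),
                     test = "var", nperm = 100, seed = 1)
  expect_equal(rv$status, "insufficient-samples")
})

test_that("topology_gsa enforces a DAG by logged feedback-edge removal", {
  cyc <- build_pathway("cyc", c("A", "B", "C"),
                       data.frame(source = c("A", "B", "C"),
                                  target = c("B", "C", "A"), sign = 1))
  em <- gaussian_em(cyc$nodes, n = 10, seed = 33)
  r <- topology_gsa(cyc, em, toy_groups(colnames(em$values)),
                    nperm = 100, seed = 2)
  expect_equal(r$status, "ok")
  expect_gte(nrow(r$removed_edges), 1)
})

test_that("clipper with zero shrinkage reproduces topology_gsa exactly", {
  pw <- two_clique_pathway()
  em <- gaussian_em(pw$nodes, n = 16, seed = 41)
  gr <- toy_groups(colnames(em$values))
  rt <- topology_gsa(pw, em, gr, nperm = 300, seed = 7)
  rc <- clipper(pw, em, gr, nperm = 300, seed = 7, lambda = 0)
  expect_equal(rc$stats$mean_p, rt$stats$mean_p, tolerance = 1e-12)
  expect_equal(rc$stats$var_p, rt$stats$var_p, tolerance = 1e-12)
})

test_that("clipper handles n < p via shrinkage and single-clique paths", {
  pw <- build_pathway("k5", LETTERS[1:5],
                      data.frame(source = rep(LETTERS[1:4], times = 4:1),
                                 target = unlist(lapply(2:5, function(i)
                                   LETTERS[i:5])),
                                 sign = 1))
  # complete graph on 5 nodes, only 3+3 samples: one clique of size 5
  em <- gaussian_em(pw$nodes, n = 6, seed = 51)
  gr <- toy_groups(colnames(em$values))
  r <- clipper(pw, em, gr, nperm = 100, seed = 1)
  expect_equal(r$status, "ok")
  expect_equal(length(r$cliques), 1)
  expect_equal(r$best_path, 1L)
  expect_equal(sort(r$best_path_cliques[[1]]), sort(pw$nodes))
})

test_that("clipper localizes a planted clique on the best path", {
  pw <- two_clique_pathway()
  hits_min <- 0; hits_path <- 0; nrun <- 25
  for (rep in 1:nrun) {
    set.seed(700 + rep)
    x <- matrix(rnorm(5 * 8), 5, 8,
                dimnames = list(pw$nodes, sprintf("s%d", 1:8)))
    # only A and B shift, so {A,B,C} is the unique clique carrying signal
    x[c("A", "B"), 5:8] <- x[c("A", "B"), 5:8] + 2
    gr <- group_labels(colnames(x), rep(c("ctrl", "case"), each = 4))
    r <- clipper(pw, expression_matrix(x, "normalized"), gr,
                 nperm = 200, seed = rep)
    keys <- vapply(r$cliques, function(cl) paste(sort(cl$clique),
                                                 collapse = "+"),
                   character(1))
    planted <- which(keys == "A+B+C")
    ps <- vapply(r$cliques, function(cl) cl$mean_p, numeric(1))
    if (which.min(ps) == planted) hits_min <- hits_min + 1
    if (planted %in% r$best_path) hits_path <- hits_path + 1
  }
  expect_gte(hits_min / nrun, 0.85)
  expect_gte(hits_path / nrun, 0.9)
})

test_that("junction trees pass the running-intersection check in both methods", {
  for (seed in 1:8) {
    pw <- make_random_pathway(8, 0.3, dag = TRUE, seed = 600 + seed)
    em <- gaussian_em(pw$nodes, n = 12, seed = seed)
    gr <- toy_groups(colnames(em$values))
    rt <- topology_gsa(pw, em, gr, nperm = 50, seed = seed)
    if (rt$status == "ok") {
      expect_true(check_running_intersection(rt$junction_tree))
    }
    rc <- clipper(pw, em, gr, nperm = 50, seed = seed)
    expect_true(check_running_intersection(rc$junction_tree))
  }
})
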