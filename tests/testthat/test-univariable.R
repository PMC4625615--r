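de_table_for <- function(genes, logfc, p = NULL) {
  if (is.null(p)) p <- ifelse(abs(logfc) > 0, 0.01, 0.9)
  data.frame(gene = genes, logFC = logfc, t = logfc * 3, p = p,
             p_adjusted = p, row.names = genes)
}

test_that("SPIA reproduces the hand-solved chain and degenerate cases", {
  p <- build_pathway("ch", c("A", "B"),
                     data.frame(source = "A", target = "B", sign = 1))
  de <- de_table_for(c("A", "B"), c(1, 0))
  r <- spia(p, de, "A", c("A", "B"), nboot = 100, seed = 1)
  expect_equal(r$stats$t_A, 1)
  expect_equal(unname(r$scores), c(0, 1))
  # no-edge pathway: no propagation, p_PERT = 1
  p0 <- build_pathway("iso", c("A", "B"))
  r0 <- spia(p0, de, "A", c("A", "B"), nboot = 100, seed = 1)
  expect_equal(r0$stats$t_A, 0)
  expect_true(all(r0$scores == 0))
  expect_equal(r0$stats$p_PERT, 1)
  # unmeasured pathway is skipped
  rs <- spia(p, de, "A", c("X", "Y"), nboot = 100, seed = 1)
  expect_equal(rs$status, "skipped")
})

test_that("p_G combination follows the closed form", {
  expect_equal(spia_combine_p(1, 1), 1)
  cc <- 0.0025
  expect_equal(spia_combine_p(0.05, 0.05), cc - cc * log(cc),
               tolerance = 1e-12)
  expect_equal(spia_combine_p(0.05, 0.05), 0.01747866, tolerance = 1e-6)
})

test_that("SPIA linear system residual is tiny on random fixtures", {
  for (seed in 1:10) {
    pw <- make_random_pathway(sample(5:15, 1), 0.3, inhibition_frac = 0.3,
                              dag = FALSE, seed = seed)
    pw <- orient_undirected(pw, "both")
    genes <- pw$nodes
    set.seed(seed)
    lfc <- rnorm(length(genes), 0, 2)
    de <- de_table_for(genes, lfc)
    deg <- genes[abs(lfc) > 2]
    r <- spia(pw, de, deg, genes, nboot = 100, seed = seed)
    if (r$status != "ok") next
    sa <- signed_adjacency(pw)
    dE <- setNames(numeric(length(genes)), sa$nodes)
    dE[intersect(deg, genes)] <- de[intersect(deg, genes), "logFC"]
    PF <- r$scores + dE[names(r$scores)]
    resid <- (diag(length(genes)) - sa$B) %*% PF - dE
    expect_lt(max(abs(resid)), 1e-9)
    # Acc is exactly zero when nothing is differentially expressed
    rnull <- spia(pw, de, character(), genes, nboot = 100, seed = seed)
    expect_true(all(rnull$scores == 0))
  }
})

test_that("hypergeometric enrichment p matches exhaustive enumeration", {
  enum_p <- function(k, K, N, n) {
    # P(X >= k) by direct enumeration over all draw compositions
    sum(sapply(k:min(K, n), function(i) {
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
    }))
  }
  for (trial in 1:30) {
    set.seed(trial)
    N <- sample(8:30, 1)
    K <- sample(1:(N - 2), 1)
    n <- sample(2:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 enum_p(k, K, N, n), tolerance = 1e-12)
  }
  # and through the spia interface on a tiny universe
  pw <- orient_undirected(chain_pathway(c("A", "B", "C")), "both")
  genes <- c(LETTERS[1:10])
  de <- de_table_for(genes, c(3, 3, 0, 0, 0, 0, 0, 0, 0, 3))
  r <- spia(pw, de, c("A", "B", "J"), genes, nboot = 100, seed = 1)
  expect_equal(r$stats$p_NDE, enum_p(2, 3, 10, 3), tolerance = 1e-12)
})

test_that("PRS reproduces the hand-evaluated chain score", {
  p <- chain_pathway(c("A", "B", "C"))
  de <- de_table_for(c("A", "B", "C"), c(1, 0, 1))
  r <- prs(p, de, c("A", "C"), c("A", "B", "C"), nperm = 100, seed = 1)
  # w_A = 1 + |{C}| = 2, w_C = 1; raw = (1*2 + 1*1)/2
  expect_equal(r$stats$raw, 1.5)
  expect_equal(unname(r$scores), c(2, 0, 1))
  # no DEG on the pathway: raw = 0
  r0 <- prs(p, de, "Z", c("A", "B", "C", "Z"), nperm = 100, seed = 1)
  expect_equal(r0$stats$raw, 0)
  # no DEG genome-wide: flagged degenerate
  rn <- prs(p, de, character(), c("A", "B", "C"), nperm = 100, seed = 1)
  expect_equal(rn$status, "no-deg")
  expect_equal(rn$stats$p, 1)
  expect_equal(rn$stats$z, 0)
})

test_that("PWEA TIFs and ES reduce to the unweighted running sum", {
  # uncorrelated pair at distance 1: TIF = exp(0/1) = 1
  p2 <- build_pathway("ab", c("A", "B"),
                      data.frame(source = "A", target = "B",
                                 directed = FALSE, sign = 0))
  x <- rbind(A = c(1, -1, 1, -1, 2, -2, 1, -1),
             B = c(1, 1, -1, -1, -2, 2, -1, 1))
  x <- x - rowMeans(x)
  tif <- pathtopo:::.pwea_tif(p2, x, c("A", "B"))
  rho <- cor(x["A", ], x["B", ])
  expect_equal(unname(tif), rep(exp(rho / 1), 2), tolerance = 1e-12)
  # with all TIF = 1 and uniform |t|, ES equals the unweighted running sum
  genes <- sprintf("g%02d", 1:20)
  tstat <- setNames(seq(2, -2, length.out = 20), genes)
  tstat[] <- sign(tstat) * 1        # uniform magnitude, ranking preserved
  path_genes <- genes[c(2, 5, 9)]
  tif1 <- setNames(rep(1, 3), path_genes)
  es <- pathtopo:::.pwea_es(tstat, path_genes, tif1)
  direct <- {
    ord <- order(-tstat, genes)
    inc <- ifelse(genes[ord] %in% path_genes, 1 / 3, -1 / 17)
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  expect_equal(es, direct, tolerance = 1e-12)
})

test_that("PWEA end-to-end returns valid permutation p-values", {
  sim <- simulate_preset("null", seed = 6)
  coll <- sim$collection[1:4]
  pstats <- pwea_permutation_stats(sim$em, sim$groups, 120, seed = 3)
  for (nm in names(coll)) {
    r <- pwea(coll[[nm]], sim$em, sim$groups, nperm = 120, seed = 3,
              perm_stats = pstats)
    expect_gte(r$stats$p, 1 / 121)
    expect_lte(r$stats$p, 1)
    expect_gte(abs(r$stats$ES), 0)
    expect_lte(abs(r$stats$ES), 1)
    expect_true(all(r$scores > 0))
    # reproducible under the same seed
    r2 <- pwea(coll[[nm]], sim$em, sim$groups, nperm = 120, seed = 3,
               perm_stats = pstats)
    expect_identical(r$stats$p, r2$stats$p)
  }
})

test_that("TAPPA PCI follows the committed formula", {
  # single gene with self-loop term only: PCI keeps the sign of z
  z <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("s1", "s2")))
  A <- matrix(0, 1, 1, dimnames = list("A", "A"))
  expect_equal(unname(pathtopo:::.tappa_pci(z, A)), c(1, -1))
  # two connected genes: off-diagonal term plus signed self-terms
  z2 <- matrix(c(1, 4, -1, -4), 2, 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  A2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  pci <- pathtopo:::.tappa_pci(z2, A2)
  expect_equal(unname(pci[1]), (sqrt(4) + 1 + 4) / 3)
  expect_equal(unname(pci[2]), (sqrt(4) - 1 - 4) / 3)
})

test_that("TAPPA is invariant to sample and gene order; ties give p = 1", {
  sim <- simulate_preset("null", seed = 9)
  pw <- sim$collection[[2]]
  r1 <- tappa(pw, sim$em, sim$groups)
  # permute genes and samples
  x <- sim$em$values
  x <- x[sample(nrow(x)), sample(ncol(x))]
  em2 <- expression_matrix(x, "normalized")
  r2 <- tappa(pw, em2, sim$groups)
  expect_equal(sort(r1$scores), sort(r2$scores), tolerance = 1e-12)
  expect_equal(r1$stats$p, r2$stats$p, tolerance = 1e-12)
  # identical groups: all PCI tied, two-sided p = 1
  xx <- matrix(rep(c(1, 2, 3, 4), 8), 4, 8,
               dimnames = list(c("A", "B", "C", "D"), sprintf("s%d", 1:8)))
  emx <- expression_matrix(xx, "normalized")
  pw2 <- build_pathway("t", c("A", "B"),
                       data.frame(source = "A", target = "B", sign = 1))
  gr <- toy_groups(colnames(emx$values))
  expect_warning(rt <- tappa(pw2, emx, gr), "constant")
  expect_equal(rt$stats$p, 1)
})

test_that("permutation p-values live on the (1+k)/(n+1) lattice and reproduce", {
  p <- chain_pathway(c("A", "B", "C"))
  genes <- sprintf("g%02d", 1:30)
  genes[1:3] <- c("A", "B", "C")
  set.seed(10)
  lfc <- rnorm(30, 0, 2)
  de <- de_table_for(genes, lfc)
  deg <- genes[abs(lfc) > 1.5]
  for (seed in c(1, 2)) {
    r1 <- prs(p, de, deg, genes, nperm = 100, seed = seed)
    r2 <- prs(p, de, deg, genes, nperm = 100, seed = seed)
    expect_identical(r1$stats$p, r2$stats$p)
    expect_gte(r1$stats$p, 1 / 101)
    expect_lte(r1$stats$p, 1)
    expect_equal(r1$stats$p * 101, round(r1$stats$p * 101))
  }
})
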