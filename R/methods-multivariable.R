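# Multivariable methods: the joint multivariate distribution of pathway
# genes is compared between groups, either in a Laplacian eigenbasis
# (DEGraph) or under a decomposable Gaussian graphical model on the
# moralized, triangulated topology (TopologyGSA, clipper).

.split_groups <- function(x, groups) {
  x <- x[, groups$samples, drop = FALSE]
  is_ref <- groups$groups == groups$reference
  list(X1 = x[, is_ref, drop = FALSE], X2 = x[, !is_ref, drop = FALSE])
}

# Classical two-sample Hotelling T2 with F transform; optional ridge when
# the pooled covariance is singular. X1, X2: variables x samples.
.hotelling <- function(X1, X2, ridge = TRUE) {
  k <- nrow(X1)
  n1 <- ncol(X1); n2 <- ncol(X2); n <- n1 + n2
  d <- rowMeans(X1) - rowMeans(X2)
  C1 <- X1 - rowMeans(X1); C2 <- X2 - rowMeans(X2)
  Sp <- (tcrossprod(C1) + tcrossprod(C2)) / (n - 2)
  flag <- NULL
  Si <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(Si) || !all(is.finite(Si))) {
    if (!ridge) stop("singular pooled covariance")
    Sp <- Sp + diag(1e-8 * sum(diag(Sp)) / k, k)
    Si <- solve(Sp)
    flag <- "ridged"
  }
  T2 <- (n1 * n2 / n) * drop(crossprod(d, Si %*% d))
  fstat <- T2 * (n - k - 1) / (k * (n - 2))
  p <- stats::pf(fstat, k, n - k - 1, lower.tail = FALSE)
  list(T2 = T2, F = fstat, p = p, flag = flag)
}

#' Laplacian-smoothed multivariate test of differential expression
#'
#' For each connected component of the pathway (restricted to measured
#' genes, at least 2), expression is projected onto the eigenvectors of the
#' (optionally signed) graph Laplacian belonging to the k smallest
#' eigenvalues -- the smoothest functions on the graph -- and the two groups
#' are compared with a Hotelling T-squared test in that k-dimensional
#' subspace (F transform: `T2 * (n-k-1) / (k*(n-2)) ~ F(k, n-k-1)`). The
#' pathway p-value is the smallest component p-value, Bonferroni-corrected
#' by the number of components tested.
#'
#' @param pathway A `Pathway`.
#' @param em Normalized `ExpressionMatrix`.
#' @param groups A [group_labels()].
#' @param k Subspace dimension; `NULL` uses
#'   `min(ceiling(p_genes/4), n - 3, 5)` (at least 1), clipped per
#'   component to the component size and to `n - 2 - 1`.
#' @param signed Use the signed Laplacian (inhibition edges enter with
#'   weight -1)? Default `FALSE`.
#' @return A list with `name`, `status`, `stats` (p, k, n_components) and
#'   `components` (per-component data.frame of size, k and p).
#' @export
degraph <- function(pathway, em, groups, k = NULL, signed = FALSE) {
  stopifnot(inherits(pathway, "Pathway"), inherits(groups, "GroupLabels"))
  x <- .values_of(em)
  measured <- intersect(pathway$nodes, rownames(x))
  if (length(measured) < 2L) {
    return(list(name = pathway$id, status = "skipped", stats = NULL))
  }
  sub <- induced_subgraph(pathway, measured)
  n <- length(groups$samples)
  k_req <- if (is.null(k)) {
    max(1L, min(ceiling(length(measured) / 4), n - 3L, 5L))
  } else as.integer(k)
  g <- .skeleton_igraph(sub)
  comp <- igraph::components(g)
  lap <- graph_laplacian(sub, signed = signed)
  sp <- .split_groups(x, groups)
  rows <- list()
  flags <- character()
  for (ci in seq_len(comp$no)) {
    genes <- names(comp$membership)[comp$membership == ci]
    if (length(genes) < 2L) next
    kc <- min(k_req, length(genes), n - 3L)
    kc <- max(1L, kc)
    if (kc < k_req) flags <- c(flags, sprintf("component %d: k clipped to %d",
                                              ci, kc))
    Lc <- lap$L[genes, genes, drop = FALSE]
    ev <- eigen(Lc, symmetric = TRUE)
    U <- ev$vectors[, ncol(ev$vectors) - seq_len(kc) + 1L, drop = FALSE]
    Y1 <- crossprod(U, sp$X1[genes, , drop = FALSE])
    Y2 <- crossprod(U, sp$X2[genes, , drop = FALSE])
    ht <- .hotelling(Y1, Y2)
    if (!is.null(ht$flag)) flags <- c(flags, sprintf("component %d: %s", ci,
                                                     ht$flag))
    rows[[length(rows) + 1L]] <- data.frame(component = ci,
                                            size = length(genes), k = kc,
                                            p = ht$p)
  }
  if (!length(rows)) {
    return(list(name = pathway$id, status = "skipped", stats = NULL))
  }
  tab <- do.call(rbind, rows)
  p <- min(1, min(tab$p) * nrow(tab))
  list(name = pathway$id, status = "ok",
       stats = list(p = p, k = k_req, n_components = nrow(tab)),
       components = tab, notes = flags)
}

# Greedy minimal feedback-edge removal: keep each directed edge unless it
# closes a cycle among the edges kept so far. Returns the pathway plus the
# removed edges.
.enforce_dag <- function(p) {
  e <- p$edges
  keep <- logical(nrow(e))
  adj <- list()
  reaches <- function(from, to) {
    seen <- character(); frontier <- from
    while (length(frontier)) {
      if (to %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      frontier <- setdiff(nxt, seen)
    }
    FALSE
  }
  for (i in seq_len(nrow(e))) {
    u <- e$source[i]; v <- e$target[i]
    if (u == v) next
    if (!reaches(v, u)) {
      keep[i] <- TRUE
      adj[[u]] <- c(adj[[u]], v)
    }
  }
  out <- p
  out$edges <- e[keep, , drop = FALSE]
  list(pathway = out, removed = e[!keep & e$source != e$target, ,
                                  drop = FALSE])
}

# Junction-tree scaffold over the measured subgraph: orient undirected
# edges both ways, enforce a DAG, moralize, triangulate, build the tree.
.jt_scaffold <- function(pathway, measured, orient_mode = "both") {
  sub <- induced_subgraph(pathway, measured)
  sub <- orient_undirected(sub, orient_mode)
  dag <- .enforce_dag(sub)
  A <- moralize(dag$pathway)
  tri <- triangulate(A)
  jt <- build_junction_tree(tri$adjacency)
  list(jt = jt, removed = dag$removed, adjacency = tri$adjacency)
}

# Decomposable Gaussian MLE of the concentration matrix: clique-padded
# inverses minus separator-padded inverses. S is an MLE covariance over
# `genes` (divisor n); cliques/separators index into genes.
.decomposable_concentration <- function(S, genes, jt) {
  K <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (cl in jt$cliques) {
    K[cl, cl] <- K[cl, cl] + solve(S[cl, cl, drop = FALSE])
  }
  for (sep in jt$separators) {
    if (length(sep)) {
      K[sep, sep] <- K[sep, sep] - solve(S[sep, sep, drop = FALSE])
    }
  }
  K
}

.gauss_deviance <- function(K, S, n) {
  n * (-as.numeric(determinant(K, logarithm = TRUE)$modulus) + sum(S * K))
}

# Ledoit-Wolf shrinkage toward (tr(S)/p) I with analytic intensity.
# X: variables x samples, columns already centered; lambda NULL = analytic.
.lw_covariance <- function(X, lambda = NULL) {
  p <- nrow(X); n <- ncol(X)
  S <- tcrossprod(X) / n
  mu <- sum(diag(S)) / p
  if (is.null(lambda)) {
    d2 <- sum((S - diag(mu, p))^2)
    if (d2 <= 0) {
      lambda <- 0
    } else {
      b2 <- 0
      for (kk in seq_len(n)) {
        b2 <- b2 + sum((tcrossprod(X[, kk]) - S)^2)
      }
      b2 <- b2 / n^2
      lambda <- min(1, b2 / d2)
    }
  }
  list(S = lambda * diag(mu, p) + (1 - lambda) * S, lambda = lambda)
}

# Observed + permutation statistics for the junction-tree tests. Returns
# pathway-level mean/var statistics and per-clique statistics for a given
# label assignment.
.jt_statistics <- function(x, is_ref, genes, jt, shrink, lambda,
                           want_var = TRUE) {
  X1 <- x[genes, is_ref, drop = FALSE]
  X2 <- x[genes, !is_ref, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2); n <- n1 + n2
  C1 <- X1 - rowMeans(X1); C2 <- X2 - rowMeans(X2)
  cov_of <- function(C) {
    if (shrink) .lw_covariance(C, lambda)$S else tcrossprod(C) / ncol(C)
  }
  Spool <- if (shrink) .lw_covariance(cbind(C1, C2), lambda)$S else {
    (tcrossprod(C1) + tcrossprod(C2)) / n
  }
  dimnames(Spool) <- list(genes, genes)
  Kpool <- .decomposable_concentration(Spool, genes, jt)
  d <- rowMeans(X1) - rowMeans(X2)
  mean_stat <- drop(crossprod(d, Kpool %*% d)) * n1 * n2 / n
  var_stat <- NA_real_
  S1 <- S2 <- NULL
  if (want_var) {
    S1 <- cov_of(C1); S2 <- cov_of(C2)
    dimnames(S1) <- dimnames(S2) <- list(genes, genes)
    K1 <- .decomposable_concentration(S1, genes, jt)
    K2 <- .decomposable_concentration(S2, genes, jt)
    var_stat <- .gauss_deviance(Kpool, S1, n1) +
      .gauss_deviance(Kpool, S2, n2) -
      .gauss_deviance(K1, S1, n1) - .gauss_deviance(K2, S2, n2)
  }
  clique_stats <- t(vapply(jt$cliques, function(cl) {
    dC <- d[cl]
    SpC <- Spool[cl, cl, drop = FALSE]
    m <- drop(crossprod(dC, solve(SpC, dC))) * n1 * n2 / n
    v <- NA_real_
    if (want_var) {
      v <- .gauss_deviance(solve(SpC), S1[cl, cl, drop = FALSE], n1) +
        .gauss_deviance(solve(SpC), S2[cl, cl, drop = FALSE], n2) -
        .gauss_deviance(solve(S1[cl, cl, drop = FALSE]),
                        S1[cl, cl, drop = FALSE], n1) -
        .gauss_deviance(solve(S2[cl, cl, drop = FALSE]),
                        S2[cl, cl, drop = FALSE], n2)
    }
    c(mean = m, var = v)
  }, numeric(2)))
  list(mean = mean_stat, var = var_stat, cliques = clique_stats)
}

.jt_permutation_test <- function(x, groups, genes, jt, nperm, seed, tag,
                                 shrink = FALSE, lambda = NULL,
                                 var_ok = TRUE) {
  is_ref <- groups$groups == groups$reference
  obs <- .jt_statistics(x, is_ref, genes, jt, shrink, lambda, var_ok)
  nc <- length(jt$cliques)
  ge_mean <- 0; ge_var <- 0
  ge_cl_mean <- numeric(nc); ge_cl_var <- numeric(nc)
  set.seed(.derive_seed(seed, tag))
  for (b in seq_len(nperm)) {
    perm <- sample(is_ref)
    st <- .jt_statistics(x, perm, genes, jt, shrink, lambda, var_ok)
    ge_mean <- ge_mean + (st$mean >= obs$mean)
    if (var_ok) ge_var <- ge_var + (st$var >= obs$var)
    ge_cl_mean <- ge_cl_mean + (st$cliques[, "mean"] >= obs$cliques[, "mean"])
    if (var_ok) {
      ge_cl_var <- ge_cl_var + (st$cliques[, "var"] >= obs$cliques[, "var"])
    }
  }
  list(obs = obs,
       mean_p = (1 + ge_mean) / (nperm + 1),
       var_p = if (var_ok) (1 + ge_var) / (nperm + 1) else NA_real_,
       clique_mean_p = (1 + ge_cl_mean) / (nperm + 1),
       clique_var_p = if (var_ok) (1 + ge_cl_var) / (nperm + 1) else
         rep(NA_real_, nc))
}

.clique_results <- function(jt, mean_p, var_p) {
  lapply(seq_along(jt$cliques), function(i) {
    pm <- mean_p[i]; pv <- var_p[i]
    best <- suppressWarnings(min(pm, pv, na.rm = TRUE))
    structure(list(clique = jt$cliques[[i]], mean_p = pm, var_p = pv,
                   score = -log10(best)), class = "CliqueTestResult")
  })
}

#' Junction-tree likelihood test of pathway differential expression
#'
#' The measured pathway topology is oriented, reduced to a DAG by greedy
#' removal of a feedback edge set (removed edges are reported), moralized,
#' triangulated, and decomposed into a junction tree. Under the resulting
#' decomposable Gaussian graphical model the concentration matrix has a
#' closed-form MLE (clique-padded inverses minus separator-padded
#' inverses). The variance test is the deviance difference between
#' separate-group and pooled fits; the mean test is the Mahalanobis
#' distance of the group mean difference under the pooled concentration.
#' Both are calibrated by sample-label permutation; an asymptotic
#' chi-squared p-value is additionally reported for the variance test.
#' Per-clique mean and variance tests are returned as well.
#'
#' @param pathway A `Pathway`.
#' @param em Normalized `ExpressionMatrix`.
#' @param groups A [group_labels()].
#' @param test Which test drives the reported pathway `p`: `"mean"`
#'   (default) or `"var"`.
#' @param nperm Number of label permutations (default 1000).
#' @param seed Integer master seed.
#' @param orient_mode Orientation of undirected input edges before
#'   moralization (default `"both"`).
#' @return A list with `name`, `status`, `stats` (p, mean_p, var_p,
#'   var_p_asymptotic, mean_stat, var_stat), `cliques` (list of
#'   `CliqueTestResult`), `removed_edges` and `junction_tree`.
#' @export
topology_gsa <- function(pathway, em, groups, test = c("mean", "var"),
                         nperm = 1000, seed = NULL,
                         orient_mode = "both") {
  test <- match.arg(test)
  stopifnot(inherits(pathway, "Pathway"), inherits(groups, "GroupLabels"))
  x <- .values_of(em)
  measured <- intersect(pathway$nodes, rownames(x))
  if (length(measured) < 2L) {
    return(list(name = pathway$id, status = "skipped", stats = NULL))
  }
  scaf <- .jt_scaffold(pathway, measured, orient_mode)
  jt <- scaf$jt
  genes <- sort(measured)
  n1 <- sum(groups$groups == groups$reference)
  n2 <- length(groups$groups) - n1
  max_cl <- max(lengths(jt$cliques))
  # pooled centered data have rank n1 + n2 - 2; larger cliques give
  # singular clique covariances
  if (max_cl > n1 + n2 - 2) {
    return(list(name = pathway$id, status = "insufficient-samples",
                stats = NULL, junction_tree = jt))
  }
  var_ok <- max_cl < min(n1, n2)
  pt <- .jt_permutation_test(x, groups, genes, jt, nperm,
                             if (is.null(seed)) 0L else seed,
                             paste0("jt|", pathway$id),
                             shrink = FALSE, var_ok = var_ok)
  df_var <- sum(vapply(jt$cliques, function(cl) length(cl) * (length(cl) + 1) / 2,
                       numeric(1))) -
    sum(vapply(jt$separators, function(sp) length(sp) * (length(sp) + 1) / 2,
               numeric(1)))
  var_p_asy <- if (var_ok) {
    stats::pchisq(pt$obs$var, df = df_var, lower.tail = FALSE)
  } else NA_real_
  p <- if (test == "mean") pt$mean_p else pt$var_p
  status <- if (test == "var" && !var_ok) "insufficient-samples" else "ok"
  list(name = pathway$id, status = status,
       stats = list(p = p, mean_p = pt$mean_p, var_p = pt$var_p,
                    var_p_asymptotic = var_p_asy,
                    mean_stat = pt$obs$mean, var_stat = pt$obs$var),
       cliques = .clique_results(jt, pt$clique_mean_p, pt$clique_var_p),
       removed_edges = scaf$removed, junction_tree = jt)
}

# All root-to-leaf paths in the junction tree component containing `root`.
.tree_paths <- function(jt, root) {
  nc <- length(jt$cliques)
  adj <- lapply(seq_len(nc), function(i) integer())
  if (nrow(jt$edges)) {
    for (r in seq_len(nrow(jt$edges))) {
      a <- jt$edges[r, 1]; b <- jt$edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  paths <- list()
  walk <- function(v, path) {
    nxt <- setdiff(adj[[v]], path)
    if (!length(nxt)) {
      paths[[length(paths) + 1L]] <<- c(path, v)
      return(invisible())
    }
    for (w in nxt) walk(w, c(path, v))
  }
  walk(root, integer())
  paths
}

#' Two-step junction-tree analysis with covariance shrinkage
#'
#' Step one tests the whole pathway as in [topology_gsa()] but with
#' Ledoit-Wolf-shrunk covariance estimates (shrinkage toward
#' `(tr(S)/p) I` with analytic intensity), which keeps every clique
#' estimate invertible even when samples are fewer than genes. Step two
#' tests each junction-tree clique, takes the clique with the smallest
#' p-value as root, and reports the root-to-leaf path of the tree
#' maximizing the mean clique score `-log10(p)` -- the portion of the
#' pathway most associated with the phenotype.
#'
#' @inheritParams topology_gsa
#' @param lambda Force the shrinkage intensity (e.g. 0 to disable); `NULL`
#'   (default) estimates it analytically.
#' @return As [topology_gsa()], plus `best_path` (clique indices),
#'   `best_path_cliques` (their node sets) and `best_path_scores`.
#' @export
clipper <- function(pathway, em, groups, test = c("mean", "var"),
                    nperm = 1000, seed = NULL, orient_mode = "both",
                    lambda = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(pathway, "Pathway"), inherits(groups, "GroupLabels"))
  x <- .values_of(em)
  measured <- intersect(pathway$nodes, rownames(x))
  if (length(measured) < 2L) {
    return(list(name = pathway$id, status = "skipped", stats = NULL))
  }
  scaf <- .jt_scaffold(pathway, measured, orient_mode)
  jt <- scaf$jt
  genes <- sort(measured)
  pt <- .jt_permutation_test(x, groups, genes, jt, nperm,
                             if (is.null(seed)) 0L else seed,
                             paste0("jt|", pathway$id),
                             shrink = TRUE, lambda = lambda, var_ok = TRUE)
  cl_p <- unname(if (test == "mean") pt$clique_mean_p else pt$clique_var_p)
  root <- which.min(cl_p)
  scores <- -log10(cl_p)
  paths <- .tree_paths(jt, root)
  path_score <- vapply(paths, function(pp) mean(scores[pp]), numeric(1))
  best <- paths[[which.max(path_score)]]
  p <- if (test == "mean") pt$mean_p else pt$var_p
  list(name = pathway$id, status = "ok",
       stats = list(p = p, mean_p = pt$mean_p, var_p = pt$var_p,
                    mean_stat = pt$obs$mean, var_stat = pt$obs$var),
       cliques = .clique_results(jt, pt$clique_mean_p, pt$clique_var_p),
       best_path = best,
       best_path_cliques = jt$cliques[best],
       best_path_scores = scores[best],
       removed_edges = scaf$removed, junction_tree = jt)
}
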