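# Univariable methods: pathway scores built from per-gene statistics
# (log fold-changes, t statistics) combined over the topology.

.deg_genes <- function(deg) {
  if (is.data.frame(deg)) rownames(deg) else as.character(deg)
}

.measured_nodes <- function(pathway, all_genes) {
  intersect(pathway$nodes, all_genes)
}

#' Signaling-pathway impact analysis (perturbation accumulation)
#'
#' Propagates log fold-changes of differentially expressed genes through
#' the signed directed topology: with `B[i,j]` the sign of edge j -> i over
#' j's outdegree, the perturbation factors solve `(I - B) PF = dE`, and the
#' net accumulation `Acc = PF - dE` measures signal a gene receives from
#' upstream. The total accumulation `tA = sum(Acc)` is tested against a
#' bootstrap null that re-places the observed number of DEGs (log
#' fold-changes drawn with replacement from the global DEG pool) onto
#' random pathway positions; the enrichment p-value `p_NDE` is an upper-tail
#' hypergeometric test on the DEG count, and the two are combined as
#' `p_G = c - c*log(c)` with `c = p_NDE * p_PERT`.
#'
#' @param pathway A fully directed `Pathway` (see [orient_undirected()]).
#' @param de_table A `DifferentialExpressionTable` covering the measured
#'   genes.
#' @param deg The DEG selection (output of [select_deg()] or a character
#'   vector of gene ids).
#' @param all_genes Character vector of all measured gene ids (the
#'   hypergeometric population).
#' @param nboot Number of bootstrap draws (>= 100; default 2000).
#' @param seed Integer seed for the bootstrap stream.
#' @return A list with `name`, `status`, `stats` (N_pathway_genes,
#'   N_de_on_pathway, t_A, p_NDE, p_PERT, p = p_G) and per-gene `scores`
#'   (the Acc vector).
#' @export
spia <- function(pathway, de_table, deg, all_genes, nboot = 2000,
                 seed = NULL) {
  stopifnot(inherits(pathway, "Pathway"), nboot >= 100)
  if (any(!pathway$edges$directed)) {
    stop("spia() needs a fully directed pathway; orient_undirected() first")
  }
  deg_genes <- .deg_genes(deg)
  measured <- .measured_nodes(pathway, all_genes)
  if (length(measured) == 0L) {
    return(list(name = pathway$id, status = "skipped", stats = NULL,
                scores = NULL))
  }
  sa <- signed_adjacency(pathway)
  n <- length(sa$nodes)
  IB <- diag(n) - sa$B
  if (kappa(IB, exact = FALSE) > 1e12) {
    return(list(name = pathway$id, status = "singular", stats = NULL,
                scores = NULL))
  }
  Cinv <- solve(IB)
  de_on <- intersect(deg_genes, measured)
  dE <- stats::setNames(numeric(n), sa$nodes)
  dE[de_on] <- de_table[de_on, "logFC"]
  PF <- drop(Cinv %*% dE)
  Acc <- stats::setNames(PF - dE, sa$nodes)
  tA <- sum(Acc)
  K <- length(intersect(deg_genes, all_genes))
  p_nde <- stats::phyper(length(de_on) - 1, K, length(all_genes) - K,
                         length(measured), lower.tail = FALSE)
  # bootstrap null for the accumulation; sum(Acc) for a placement is a
  # weighted sum with per-node weight colsum(Cinv) - 1
  wcol <- colSums(Cinv) - 1
  names(wcol) <- sa$nodes
  pool <- de_table[intersect(deg_genes, rownames(de_table)), "logFC"]
  nde <- length(de_on)
  if (nde > 0L && length(pool)) {
    set.seed(.derive_seed(if (is.null(seed)) 0L else seed, "spia",
                          pathway$id))
    wm <- wcol[measured]
    tb <- vapply(seq_len(nboot), function(b) {
      vals <- sample(pool, nde, replace = TRUE)
      slots <- sample.int(length(wm), nde)
      sum(wm[slots] * vals)
    }, numeric(1))
  } else {
    tb <- numeric(nboot)
  }
  med <- stats::median(tb)
  p_pert <- (1 + sum(abs(tb - med) >= abs(tA - med))) / (nboot + 1)
  cc <- p_nde * p_pert
  p_g <- spia_combine_p(p_nde, p_pert)
  list(name = pathway$id, status = "ok",
       stats = list(N_pathway_genes = length(measured),
                    N_de_on_pathway = nde, t_A = tA,
                    p_NDE = p_nde, p_PERT = p_pert, p = p_g),
       scores = Acc)
}

#' Combine enrichment and perturbation p-values
#'
#' `p_G = c - c*log(c)` with `c = p_NDE * p_PERT`, the tail probability of
#' the product of two independent uniforms.
#'
#' @param p_nde,p_pert The two p-values.
#' @return The combined p-value in (0, 1].
#' @export
spia_combine_p <- function(p_nde, p_pert) {
  cc <- p_nde * p_pert
  ifelse(cc <= 0, 0, cc - cc * log(cc))
}

#' Pathway regulation score
#'
#' Each differentially expressed pathway gene contributes its absolute log
#' fold-change weighted by `1 +` the number of differentially expressed
#' genes downstream of it; the raw score is the weighted sum divided by the
#' number of DEGs on the pathway. Significance comes from a competitive
#' permutation null that redraws the pathway's gene slots (DE status and
#' |logFC|) from the genome without replacement.
#'
#' @inheritParams spia
#' @param nperm Number of permutations (>= 100; default 1000).
#' @return A list with `name`, `status`, `stats` (raw score, null mean and
#'   sd, z, p) and per-gene `scores` (contribution `v_i * w_i`), plus
#'   `weights` (the w vector over measured pathway genes).
#' @export
prs <- function(pathway, de_table, deg, all_genes, nperm = 1000,
                seed = NULL) {
  stopifnot(inherits(pathway, "Pathway"), nperm >= 100)
  if (any(!pathway$edges$directed)) {
    stop("prs() needs a fully directed pathway; orient_undirected() first")
  }
  deg_genes <- .deg_genes(deg)
  measured <- .measured_nodes(pathway, all_genes)
  if (length(measured) == 0L) {
    return(list(name = pathway$id, status = "skipped", stats = NULL,
                scores = NULL))
  }
  m <- length(measured)
  ds <- lapply(measured, function(g) {
    match(intersect(reachable_downstream(pathway, g), measured), measured)
  })
  de_flag <- measured %in% deg_genes
  alfc <- stats::setNames(rep(0, m), measured)
  have <- intersect(measured, rownames(de_table))
  alfc[have] <- abs(de_table[have, "logFC"])
  v <- ifelse(de_flag, alfc, 0)
  w <- 1 + vapply(ds, function(js) sum(de_flag[js]), numeric(1))
  nde <- sum(de_flag)
  raw <- sum(v * w) / max(1, nde)
  global_de <- all_genes %in% deg_genes
  if (!any(global_de)) {
    return(list(name = pathway$id, status = "no-deg",
                stats = list(raw = 0, null_mean = 0, null_sd = 0, z = 0,
                             p = 1),
                scores = stats::setNames(v * w, measured), weights = w))
  }
  g_alfc <- stats::setNames(rep(0, length(all_genes)), all_genes)
  have_g <- intersect(all_genes, rownames(de_table))
  g_alfc[have_g] <- abs(de_table[have_g, "logFC"])
  set.seed(.derive_seed(if (is.null(seed)) 0L else seed, "prs", pathway$id))
  raw_perm <- vapply(seq_len(nperm), function(b) {
    idx <- sample.int(length(all_genes), m)
    de_p <- global_de[idx]
    v_p <- ifelse(de_p, g_alfc[idx], 0)
    w_p <- 1 + vapply(ds, function(js) sum(de_p[js]), numeric(1))
    sum(v_p * w_p) / max(1, sum(de_p))
  }, numeric(1))
  mu <- mean(raw_perm); sdev <- stats::sd(raw_perm)
  status <- "ok"
  z <- if (is.na(sdev) || sdev == 0) { status <- "degenerate-null"; 0 }
  else (raw - mu) / sdev
  p <- (1 + sum(raw_perm >= raw)) / (nperm + 1)
  list(name = pathway$id, status = status,
       stats = list(raw = raw, null_mean = mu, null_sd = sdev, z = z,
                    p = p),
       scores = stats::setNames(v * w, measured), weights = w)
}

# Topology influence factors: TIF_i = mean over pathway partners j != i at
# finite hop distance of exp(rho_ij / d_ij); isolated genes get 1.
.pwea_tif <- function(pathway, x, measured) {
  rho <- suppressWarnings(stats::cor(t(x[measured, , drop = FALSE])))
  rho[is.na(rho)] <- 0
  d <- shortest_path_lengths(pathway)[measured, measured, drop = FALSE]
  tif <- vapply(seq_along(measured), function(i) {
    j <- which(is.finite(d[i, ]) & seq_along(measured) != i)
    if (!length(j)) return(1)
    mean(exp(rho[i, j] / d[i, j]))
  }, numeric(1))
  stats::setNames(tif, measured)
}

# Weighted running-sum enrichment score over a genome-wide ranking by
# decreasing t; deterministic tie-break by gene id.
.pwea_es <- function(tstat, path_genes, tif) {
  genes <- names(tstat)
  n <- length(genes)
  in_path <- genes %in% path_genes
  npath <- sum(in_path)
  inc <- rep(-1 / (n - npath), n)
  wts <- abs(tstat[in_path]) * tif[genes[in_path]]
  if (sum(wts) == 0) wts <- rep(1, npath)
  inc[in_path] <- wts / sum(wts)
  ord <- order(-tstat, genes)
  run <- cumsum(inc[ord])
  run[which.max(abs(run))]
}

#' Pathway-weighted enrichment analysis
#'
#' A weighted running-sum enrichment statistic: genes are ranked
#' genome-wide by decreasing moderated-t, pathway genes add
#' `|t| * TIF / sum(|t| * TIF)` and background genes subtract
#' `1/(N - n_path)`; the enrichment score is the maximal absolute running
#' deviation. The topology influence factor `TIF_i` is the mean of
#' `exp(rho_ij / d_ij)` over pathway partners at finite hop distance
#' (expression correlation over graph distance). The null re-permutes the
#' sample labels and recomputes the differential expression genome-wide
#' (TIFs held fixed); per-permutation seeds are derived from the master
#' seed and the permutation index so the loop parallelizes safely.
#'
#' @param pathway A `Pathway` (any edge mix; hop distances use the
#'   undirected skeleton).
#' @param em Normalized `ExpressionMatrix`.
#' @param groups A [group_labels()].
#' @param nperm Number of label permutations (>= 100; default 1000).
#' @param seed Integer master seed.
#' @param de_engine Function `(em, groups) -> DifferentialExpressionTable`
#'   (default [moderated_t()]).
#' @param perm_stats Optional precomputed genes-by-nperm matrix of permuted
#'   t statistics (see [pwea_permutation_stats()]), shared across pathways.
#' @return A list with `name`, `status`, `stats` (ES, p) and per-gene
#'   `scores` (the TIF vector).
#' @export
pwea <- function(pathway, em, groups, nperm = 1000, seed = NULL,
                 de_engine = moderated_t, perm_stats = NULL) {
  stopifnot(inherits(pathway, "Pathway"))
  x <- .values_of(em)
  measured <- intersect(pathway$nodes, rownames(x))
  if (length(measured) < 2L || length(measured) >= nrow(x)) {
    return(list(name = pathway$id, status = "skipped", stats = NULL,
                scores = NULL))
  }
  stopifnot(nperm >= 100)
  tif <- .pwea_tif(pathway, x, measured)
  de_obs <- de_engine(em, groups)
  tstat <- stats::setNames(de_obs$t, rownames(de_obs))
  es <- .pwea_es(tstat, measured, tif)
  if (is.null(perm_stats)) {
    perm_stats <- pwea_permutation_stats(em, groups, nperm, seed,
                                         de_engine = de_engine)
  }
  es_perm <- vapply(seq_len(ncol(perm_stats)), function(b) {
    .pwea_es(stats::setNames(perm_stats[, b], rownames(perm_stats)),
             measured, tif)
  }, numeric(1))
  p <- (1 + sum(abs(es_perm) >= abs(es))) / (ncol(perm_stats) + 1)
  list(name = pathway$id, status = "ok",
       stats = list(ES = es, p = p), scores = tif)
}

#' Permuted genome-wide t statistics for the PWEA null
#'
#' Each permutation shuffles the sample labels (seed derived from the
#' master seed and the permutation index) and recomputes the differential
#' expression statistics; the matrix is shared across all pathways of a
#' run.
#'
#' @inheritParams pwea
#' @return Genes-by-nperm numeric matrix of t statistics.
#' @export
pwea_permutation_stats <- function(em, groups, nperm = 1000, seed = NULL,
                                   de_engine = moderated_t) {
  x <- .values_of(em)
  out <- matrix(NA_real_, nrow(x), nperm,
                dimnames = list(rownames(x), NULL))
  base_seed <- if (is.null(seed)) 0L else seed
  for (b in seq_len(nperm)) {
    set.seed(.derive_seed(base_seed, "pwea-perm", b))
    gp <- groups
    gp$groups <- sample(groups$groups)
    out[, b] <- de_engine(em, gp)$t
  }
  out
}

# Pathway connectivity index per sample. z: z-scored genes x samples; A:
# 0/1 skeleton adjacency without self-loop entries. Terms run over pairs
# i <= j with A_ij = 1 plus every self-pair: the off-diagonal terms are
# sign(z_i) sign(z_j) sqrt(|z_i| |z_j|); a self-term keeps its gene's sign
# (it equals z_i), linking the index to the pathway's net expression.
.tappa_pci <- function(z, A) {
  n <- nrow(z)
  diag(A) <- 0
  n_terms <- sum(A) / 2 + n
  S <- sign(z) * sqrt(abs(z))
  pci <- vapply(seq_len(ncol(S)), function(s) {
    q <- S[, s]
    (drop(crossprod(q, A %*% q)) / 2 + sum(z[, s])) / n_terms
  }, numeric(1))
  stats::setNames(pci, colnames(z))
}

#' Topological analysis of pathway gene expression (connectivity index)
#'
#' Each sample gets a pathway connectivity index: pathway genes are
#' z-scored across samples and, over the undirected skeleton adjacency with
#' self-loops, `PCI_s` averages
#' `sign(z_i) * sign(z_j) * sqrt(|z_i| * |z_j|)` over connected gene pairs
#' `i < j` together with one self-term per gene that keeps the gene's sign
#' (equal to `z_i`), so the index tracks both co-expression agreement along
#' edges and the pathway's net expression shift. Groups are compared by a
#' two-sided Mann-Whitney test (exact
#' when both groups are small and PCI values untied; normal approximation
#' with tie and continuity correction otherwise).
#'
#' @param pathway A `Pathway`.
#' @param em Normalized `ExpressionMatrix`.
#' @param groups A [group_labels()].
#' @return A list with `name`, `status`, `stats` (U, p) and per-sample
#'   `scores` (the PCI values).
#' @export
tappa <- function(pathway, em, groups) {
  stopifnot(inherits(pathway, "Pathway"), inherits(groups, "GroupLabels"))
  x <- .values_of(em)
  measured <- intersect(pathway$nodes, rownames(x))
  if (length(measured) < 2L) {
    return(list(name = pathway$id, status = "skipped", stats = NULL,
                scores = NULL))
  }
  x <- x[measured, groups$samples, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("constant gene(s) on pathway '", pathway$id,
            "' z-scored to 0: ",
            paste(measured[sdv == 0], collapse = ", "))
  }
  z <- (x - mu) / ifelse(sdv == 0, Inf, sdv)
  A <- .skeleton_adjacency(induced_subgraph(pathway, measured))
  A <- A[measured, measured, drop = FALSE] * 1.0
  pci <- .tappa_pci(z, A)
  is_ref <- groups$groups == groups$reference
  x1 <- pci[is_ref]; x2 <- pci[!is_ref]
  if (stats::sd(pci) == 0) {
    # complete ties carry no ordering information
    return(list(name = pathway$id, status = "ok",
                stats = list(U = length(x1) * length(x2) / 2, p = 1),
                scores = pci))
  }
  use_exact <- min(length(x1), length(x2)) <= 8 &&
    !any(duplicated(c(x1, x2)))
  wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = use_exact,
                                            correct = TRUE))
  list(name = pathway$id, status = "ok",
       stats = list(U = unname(wt$statistic), p = wt$p.value),
       scores = pci)
}
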