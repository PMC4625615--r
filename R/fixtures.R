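# Synthetic pathway and expression generators. The defaults mirror a
# small two-condition RNA-Seq knockdown design: 4 + 4 samples, negative
# binomial counts with dispersion 0.1 around log-normal baseline means,
# and a planted differentially expressed pathway with a log2 effect of 2
# on 30 percent of its genes.

#' Random signed pathway
#'
#' Erdos-Renyi-style topology. With `dag = TRUE` edges run only from lower
#' to higher position in a random node order, so the result is acyclic by
#' construction. Each edge is inhibitory (sign -1) with probability
#' `inhibition_frac`, activating (+1) otherwise.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param edge_prob Probability of each ordered (dag) or unordered pair
#'   receiving an edge.
#' @param inhibition_frac Fraction of inhibitory edges.
#' @param dag Generate a DAG (default `TRUE`).
#' @param seed Integer seed (deterministic output); `NULL` uses the current
#'   RNG state.
#' @param genes Optional gene-id pool to draw node ids from (sampled
#'   without replacement); default ids are `g001`, `g002`, ...
#' @param id Pathway id.
#' @return A `Pathway`.
#' @export
make_random_pathway <- function(n_nodes, edge_prob = 0.15,
                                inhibition_frac = 0.2, dag = TRUE,
                                seed = NULL, genes = NULL, id = "random") {
  stopifnot(n_nodes >= 1, edge_prob >= 0, edge_prob <= 1,
            inhibition_frac >= 0, inhibition_frac <= 1)
  if (!is.null(seed)) set.seed(.derive_seed(seed, "pathway", id))
  nodes <- if (is.null(genes)) {
    sprintf("g%03d", seq_len(n_nodes))
  } else {
    sample(genes, n_nodes)
  }
  ord <- sample(nodes)
  src <- character(); tgt <- character()
  if (n_nodes >= 2) {
    for (i in seq_len(n_nodes - 1L)) {
      for (j in (i + 1L):n_nodes) {
        if (stats::runif(1) < edge_prob) {
          src <- c(src, ord[i]); tgt <- c(tgt, ord[j])
        }
        if (!dag && stats::runif(1) < edge_prob) {
          src <- c(src, ord[j]); tgt <- c(tgt, ord[i])
        }
      }
    }
  }
  edges <- if (length(src)) {
    data.frame(source = src, target = tgt, directed = TRUE,
               sign = ifelse(stats::runif(length(src)) < inhibition_frac,
                             -1L, 1L),
               subtype = "", stringsAsFactors = FALSE)
  } else NULL
  build_pathway(id, nodes, edges)
}

#' Random pathway collection over a shared gene universe
#'
#' @param n_pathways Number of pathways.
#' @param size_range Node-count range, inclusive.
#' @param genes Gene universe to draw node ids from.
#' @param edge_prob,inhibition_frac,dag Passed to [make_random_pathway()].
#' @param seed Integer seed.
#' @return A `PathwayCollection` named `P001`, `P002`, ...
#' @export
make_pathway_collection <- function(n_pathways, size_range = c(10, 40),
                                    genes, edge_prob = 0.15,
                                    inhibition_frac = 0.2, dag = TRUE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(.derive_seed(seed, "collection-sizes"))
  sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
  ps <- lapply(seq_len(n_pathways), function(i) {
    make_random_pathway(sizes[i], edge_prob, inhibition_frac, dag,
                        seed = if (is.null(seed)) NULL else
                          .derive_seed(seed, "member", i),
                        genes = genes, id = sprintf("P%03d", i))
  })
  pathway_collection(ps)
}

#' Ground truth of a simulation
#'
#' @param planted Planted pathway name (or `NA` for a null simulation).
#' @param affected Affected gene ids (must lie inside the planted pathway).
#' @param effect Effect size on the log2 scale.
#' @param kind `"nb-counts"`, `"gaussian"` or `"graph-gaussian"`.
#' @param seed The generator seed.
#' @return A `SimulationTruth` list.
#' @export
simulation_truth <- function(planted = NA_character_,
                             affected = character(), effect = 2,
                             kind = c("nb-counts", "gaussian",
                                      "graph-gaussian"),
                             seed = 0L) {
  kind <- match.arg(kind)
  structure(list(planted = planted, affected = as.character(affected),
                 effect = effect, kind = kind, seed = seed),
            class = "SimulationTruth")
}

# covariance block implied by a pathway's adjacency: inverse of
# (I + 0.3 * symmetrized adjacency), eigenvalues floored at 0.1 so the
# precision matrix is positive definite.
.graph_covariance <- function(adj) {
  M <- diag(nrow(adj)) + 0.3 * (adj * 1.0)
  ev <- eigen(M, symmetric = TRUE)
  vals <- pmax(ev$values, 0.1)
  Minv <- ev$vectors %*% diag(1 / vals, length(vals)) %*% t(ev$vectors)
  dimnames(Minv) <- dimnames(adj)
  Minv
}

#' Simulate a two-condition expression experiment
#'
#' Generators: `"nb-counts"` draws negative binomial counts with per-gene
#' baseline means log-normal(log 500, 1) and dispersion `params$phi`
#' (default 0.1); group-2 means of affected genes are multiplied by
#' `2^effect`. `"gaussian"` draws unit-variance normals with the affected
#' genes' group-2 mean shifted by `effect`. `"graph-gaussian"` additionally
#' correlates each pathway's genes with covariance
#' `inv(I + 0.3 * adjacency)` (eigenvalue-floored), the graphical structure
#' the multivariable tests assume; a gene shared by several pathways takes
#' its covariance block from the first pathway containing it.
#'
#' @param collection A `PathwayCollection` (defines the pathway genes).
#' @param truth A [simulation_truth()]; its `seed` drives the draw.
#' @param n1,n2 Samples per group (reference group first).
#' @param params List: `phi` (NB dispersion), `base_log_mean`,
#'   `base_log_sd`, `background` (extra non-pathway gene ids to include).
#' @return A list with `em` (an `ExpressionMatrix`), `groups`
#'   (a `GroupLabels` with reference level `"ctrl"`) and `truth`.
#' @export
simulate_expression <- function(collection, truth, n1 = 4, n2 = 4,
                                params = list()) {
  stopifnot(inherits(collection, "PathwayCollection"),
            inherits(truth, "SimulationTruth"))
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (!is.na(truth$planted)) {
    if (!truth$planted %in% names(collection)) {
      stop("planted pathway '", truth$planted, "' not in the collection")
    }
    if (!all(truth$affected %in% collection[[truth$planted]]$nodes)) {
      stop("affected genes must lie inside the planted pathway")
    }
  }
  phi <- if (is.null(params$phi)) 0.1 else params$phi
  mlog <- if (is.null(params$base_log_mean)) log(500) else params$base_log_mean
  slog <- if (is.null(params$base_log_sd)) 1 else params$base_log_sd
  genes <- unique(c(unlist(lapply(collection, function(p) p$nodes),
                           use.names = FALSE),
                    params$background))
  genes <- sort(genes)
  n <- n1 + n2
  samples <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("ctrl", "case"), c(n1, n2))
  affected <- truth$affected
  set.seed(.derive_seed(truth$seed, "simulate", truth$kind))
  if (truth$kind == "nb-counts") {
    mu <- exp(stats::rnorm(length(genes), mlog, slog))
    names(mu) <- genes
    M <- matrix(rep(mu, n), ncol = n, dimnames = list(genes, samples))
    M[affected, grp == "case"] <- M[affected, grp == "case"] *
      2^truth$effect
    counts <- matrix(stats::rnbinom(length(M), mu = M, size = 1 / phi),
                     nrow = nrow(M), dimnames = dimnames(M))
    em <- expression_matrix(counts, "counts")
  } else {
    X <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                dimnames = list(genes, samples))
    if (truth$kind == "graph-gaussian") {
      owner <- rep(NA_integer_, length(genes))
      names(owner) <- genes
      for (i in seq_along(collection)) {
        nd <- collection[[i]]$nodes
        owner[nd[is.na(owner[nd])]] <- i
      }
      for (i in seq_along(collection)) {
        nd <- names(owner)[!is.na(owner) & owner == i]
        if (length(nd) < 2L) next
        adj <- .skeleton_adjacency(induced_subgraph(collection[[i]], nd))
        Sig <- .graph_covariance(adj[nd, nd, drop = FALSE])
        X[nd, ] <- t(chol(Sig)) %*% X[nd, , drop = FALSE]
      }
    }
    X[affected, grp == "case"] <- X[affected, grp == "case"] + truth$effect
    em <- expression_matrix(X, "normalized")
  }
  list(em = em, groups = group_labels(samples, grp, reference = "ctrl"),
       truth = truth)
}

#' Ready-made simulation presets
#'
#' The `"paper-like"` preset builds 50 DAG pathways of 10-40 nodes over a
#' 2000-gene universe, plants a log2 effect of 2 on 30 percent of the genes
#' of one pathway, and draws negative binomial counts for 4 + 4 samples --
#' the scale of a small knockdown experiment.
#'
#' @param preset Currently `"paper-like"` or `"null"` (same design, no
#'   planted effect, Gaussian values).
#' @param seed Integer seed.
#' @param kind Generator kind override (default `"nb-counts"` for
#'   paper-like, `"gaussian"` for null).
#' @return A list with `collection`, `em`, `groups` and `truth`.
#' @export
simulate_preset <- function(preset = c("paper-like", "null"), seed = 1L,
                            kind = NULL) {
  preset <- match.arg(preset)
  universe <- sprintf("G%04d", seq_len(2000))
  coll <- make_pathway_collection(50, c(10, 40), universe, seed = seed)
  if (preset == "paper-like") {
    kind <- if (is.null(kind)) "nb-counts" else kind
    planted <- names(coll)[1]
    nodes <- coll[[planted]]$nodes
    set.seed(.derive_seed(seed, "affected"))
    affected <- sample(nodes, ceiling(0.3 * length(nodes)))
    truth <- simulation_truth(planted, affected, effect = 2, kind = kind,
                              seed = seed)
  } else {
    kind <- if (is.null(kind)) "gaussian" else kind
    truth <- simulation_truth(kind = kind, seed = seed, effect = 0)
  }
  sim <- simulate_expression(coll, truth,
                             params = list(background = sprintf(
                               "B%04d", seq_len(200))))
  c(list(collection = coll), sim)
}

#' Write a simulation to disk
#'
#' Writes the expression TSV, the groups TSV, one edge-list TSV per
#' pathway, and a truth JSON.
#'
#' @param sim Output of [simulate_preset()] or a compatible list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$em, file.path(dir, "expression.tsv"))
  utils::write.table(data.frame(sample = sim$groups$samples,
                                group = sim$groups$groups),
                     file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pdir <- file.path(dir, "pathways")
  dir.create(pdir, showWarnings = FALSE)
  for (nm in names(sim$collection)) {
    write_edge_list(sim$collection[[nm]], file.path(pdir,
                                                    paste0(nm, ".tsv")))
  }
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
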