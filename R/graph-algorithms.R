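# Graph machinery shared by the seven methods. Simple undirected graphs are
# represented as symmetric logical adjacency matrices with node ids as
# dimnames; pathways are converted on the fly (parallel edges collapsed,
# self-loops ignored).

.adjacency_from_pairs <- function(nodes, src, tgt) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  A[cbind(src, tgt)] <- TRUE
  A[cbind(tgt, src)] <- TRUE
  A
}

# Undirected skeleton of a pathway as a logical adjacency matrix.
.skeleton_adjacency <- function(p) {
  .adjacency_from_pairs(p$nodes, p$edges$source, p$edges$target)
}

.skeleton_igraph <- function(p) {
  A <- .skeleton_adjacency(p)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

.as_undirected_adjacency <- function(x) {
  if (inherits(x, "Pathway")) return(.skeleton_adjacency(x))
  if (is.matrix(x)) {
    storage.mode(x) <- "logical"
    if (is.null(dimnames(x))) {
      dimnames(x) <- list(as.character(seq_len(nrow(x))),
                          as.character(seq_len(nrow(x))))
    }
    if (!isSymmetric(unname(x * 1L))) stop("adjacency matrix must be symmetric")
    diag(x) <- FALSE
    return(x)
  }
  stop("expected a Pathway or a symmetric adjacency matrix")
}

#' Enumerate all maximal cliques (Bron--Kerbosch)
#'
#' Bron--Kerbosch enumeration with pivoting on a degeneracy-ordered outer
#' loop, which keeps clique detection tractable on dense pathway topologies.
#'
#' @param x A `Pathway` (its undirected skeleton is used; parallel edges
#'   collapsed, self-loops ignored) or a symmetric logical/0-1 adjacency
#'   matrix with node names as dimnames.
#' @return List of character vectors, each sorted; the list itself sorted
#'   lexicographically. Empty graph gives an empty list; isolated nodes are
#'   cliques of size 1.
#' @export
maximal_cliques <- function(x) {
  A <- .as_undirected_adjacency(x)
  nodes <- rownames(A)
  n <- length(nodes)
  if (n == 0L) return(list())
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  deg <- lengths(nbrs)
  # degeneracy order: repeatedly remove the minimum-degree vertex
  order_ <- integer(n); alive <- rep(TRUE, n); d <- deg
  for (k in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(d[cand])]
    order_[k] <- v; alive[v] <- FALSE
    d[nbrs[[v]]] <- d[nbrs[[v]]] - 1L
  }
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    PX <- c(P, X)
    u <- PX[which.max(vapply(PX, function(w) sum(P %in% nbrs[[w]]),
                             integer(1)))]
    for (v in setdiff(P, nbrs[[u]])) {
      bk(c(R, v), intersect(P, nbrs[[v]]), intersect(X, nbrs[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  pos <- integer(n); pos[order_] <- seq_len(n)
  for (v in order_) {
    later <- nbrs[[v]][pos[nbrs[[v]]] > pos[v]]
    earlier <- nbrs[[v]][pos[nbrs[[v]]] < pos[v]]
    bk(v, later, earlier)
  }
  cliques <- lapply(out, function(idx) sort(nodes[idx]))
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(keys)]
}

# Kahn topological sort on directed edges; NULL if cyclic.
.topo_order <- function(nodes, src, tgt) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(tgt, levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  adj <- split(tgt, factor(src, levels = nodes))
  queue <- nodes[indeg == 0L]
  out <- character()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

.find_cycle <- function(nodes, src, tgt) {
  adj <- split(tgt, factor(src, levels = nodes))
  color <- stats::setNames(integer(length(nodes)), nodes)
  stack <- character()
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return(invisible())
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (!is.null(cyc)) break
      if (color[w] == 1L) {
        i <- match(w, stack)
        cyc <<- c(stack[i:length(stack)], w)
      } else if (color[w] == 0L) visit(w)
    }
    color[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in nodes) if (color[v] == 0L) visit(v)
  cyc
}

#' Test whether a pathway's directed edges form a DAG
#' @param p A `Pathway` (undirected edges are ignored).
#' @return `TRUE`/`FALSE`.
#' @export
is_dag <- function(p) {
  stopifnot(inherits(p, "Pathway"))
  e <- p$edges[p$edges$directed, , drop = FALSE]
  !is.null(.topo_order(p$nodes, e$source, e$target))
}

#' Moralize a directed acyclic graph
#'
#' Connects the parents of every node pairwise and drops edge directions,
#' producing the undirected Markov structure used by the junction-tree
#' methods.
#'
#' @param p A `Pathway` whose edges are all directed and acyclic.
#' @return Symmetric logical adjacency matrix.
#' @export
moralize <- function(p) {
  stopifnot(inherits(p, "Pathway"))
  if (any(!p$edges$directed)) {
    stop("moralize() needs a fully directed pathway; run orient_undirected() first")
  }
  e <- p$edges[p$edges$source != p$edges$target, , drop = FALSE]
  if (is.null(.topo_order(p$nodes, e$source, e$target))) {
    cyc <- .find_cycle(p$nodes, e$source, e$target)
    stop("input graph is cyclic: ", paste(cyc, collapse = " -> "))
  }
  A <- .adjacency_from_pairs(p$nodes, e$source, e$target)
  for (v in p$nodes) {
    parents <- unique(e$source[e$target == v])
    if (length(parents) > 1L) {
      for (i in seq_len(length(parents) - 1L)) {
        for (j in (i + 1L):length(parents)) {
          A[parents[i], parents[j]] <- TRUE
          A[parents[j], parents[i]] <- TRUE
        }
      }
    }
  }
  A
}

# Maximum cardinality search; returns a node order (reverse of elimination).
.mcs_order <- function(A) {
  n <- nrow(A)
  wt <- stats::setNames(integer(n), rownames(A))
  alive <- rep(TRUE, n)
  ord <- character(n)
  for (k in seq_len(n)) {
    cand <- which(alive)
    # tie-break by node id for determinism
    v <- cand[order(-wt[cand], rownames(A)[cand])][1]
    ord[k] <- rownames(A)[v]
    alive[v] <- FALSE
    nb <- which(A[v, ] & alive)
    wt[nb] <- wt[nb] + 1L
  }
  ord
}

#' Test chordality
#' @param x A `Pathway` or adjacency matrix (see [maximal_cliques()]).
#' @return `TRUE` when the graph is chordal (every cycle of length >= 4 has
#'   a chord), checked by zero fill-in under a maximum-cardinality-search
#'   elimination order.
#' @export
is_chordal <- function(x) {
  A <- .as_undirected_adjacency(x)
  ord <- rev(.mcs_order(A))   # elimination order
  pos <- stats::setNames(seq_along(ord), ord)
  for (v in ord) {
    later <- rownames(A)[A[v, ] & pos[rownames(A)] > pos[v]]
    if (length(later) > 1L) {
      for (i in seq_len(length(later) - 1L)) {
        for (j in (i + 1L):length(later)) {
          if (!A[later[i], later[j]]) return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Triangulate an undirected graph (min-fill heuristic)
#'
#' Greedy elimination choosing at each step the node whose elimination adds
#' the fewest fill edges, ties broken by node id, so the returned chordal
#' supergraph is deterministic.
#'
#' @param x A `Pathway` or adjacency matrix.
#' @return A list with `adjacency` (chordal supergraph) and `order` (the
#'   elimination order used; it is a perfect elimination order of the
#'   output).
#' @export
triangulate <- function(x) {
  A0 <- .as_undirected_adjacency(x)
  A <- A0
  W <- A0             # working copy, nodes removed as eliminated
  nodes <- rownames(A0)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  ord <- character()
  fill_count <- function(v) {
    nb <- nodes[W[v, ] & alive]
    if (length(nb) < 2L) return(0L)
    m <- 0L
    for (i in seq_len(length(nb) - 1L)) {
      for (j in (i + 1L):length(nb)) {
        if (!W[nb[i], nb[j]]) m <- m + 1L
      }
    }
    m
  }
  while (any(alive)) {
    cand <- nodes[alive]
    fills <- vapply(cand, fill_count, integer(1))
    v <- cand[order(fills, cand)][1]
    nb <- nodes[W[v, ] & alive]
    if (length(nb) > 1L) {
      for (i in seq_len(length(nb) - 1L)) {
        for (j in (i + 1L):length(nb)) {
          A[nb[i], nb[j]] <- A[nb[j], nb[i]] <- TRUE
          W[nb[i], nb[j]] <- W[nb[j], nb[i]] <- TRUE
        }
      }
    }
    alive[v] <- FALSE
    ord <- c(ord, v)
  }
  list(adjacency = A, order = ord)
}

# running intersection: for every node, the cliques containing it induce a
# connected subtree of the junction tree/forest.
.check_running_intersection <- function(jt) {
  nodes <- unique(unlist(jt$cliques))
  nc <- length(jt$cliques)
  for (v in nodes) {
    has <- which(vapply(jt$cliques, function(cl) v %in% cl, logical(1)))
    if (length(has) <= 1L) next
    # BFS over tree edges restricted to `has`
    if (nrow(jt$edges)) {
      sub <- jt$edges[jt$edges[, 1] %in% has & jt$edges[, 2] %in% has, ,
                      drop = FALSE]
    } else sub <- jt$edges
    seen <- has[1]; frontier <- has[1]
    while (length(frontier)) {
      nxt <- unique(c(sub[sub[, 1] %in% frontier, 2],
                      sub[sub[, 2] %in% frontier, 1]))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    if (length(seen) != length(has)) return(FALSE)
  }
  TRUE
}

#' Build a junction tree of a chordal graph
#'
#' Maximal cliques become tree nodes; tree edges are a maximum-weight
#' spanning forest of the clique graph weighted by separator size, which
#' guarantees the running intersection property for chordal input.
#'
#' @param x A chordal `Pathway` skeleton or adjacency matrix; non-chordal
#'   input is an error.
#' @return A `JunctionTree`: list with `cliques` (list of sorted character
#'   vectors), `edges` (2-column matrix of clique indices) and `separators`
#'   (list, one per tree edge, the intersection of its endpoint cliques).
#' @export
build_junction_tree <- function(x) {
  A <- .as_undirected_adjacency(x)
  if (!is_chordal(A)) stop("graph is not chordal; triangulate() it first")
  cliques <- maximal_cliques(A)
  nc <- length(cliques)
  edges <- matrix(integer(), 0, 2)
  seps <- list()
  if (nc > 1L) {
    cand <- list()
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        w <- length(intersect(cliques[[i]], cliques[[j]]))
        if (w > 0L) cand[[length(cand) + 1L]] <- c(i, j, w)
      }
    }
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(-cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
      parent <- seq_len(nc)
      find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
      for (r in seq_len(nrow(cm))) {
        ra <- find(cm[r, 1]); rb <- find(cm[r, 2])
        if (ra != rb) {
          parent[ra] <- rb
          edges <- rbind(edges, cm[r, 1:2])
          seps[[nrow(edges)]] <- intersect(cliques[[cm[r, 1]]],
                                           cliques[[cm[r, 2]]])
        }
      }
    }
  }
  jt <- structure(list(cliques = cliques, edges = edges, separators = seps),
                  class = "JunctionTree")
  stopifnot(.check_running_intersection(jt))
  jt
}

#' @export
print.JunctionTree <- function(x, ...) {
  cat(sprintf("JunctionTree: %d clique(s), %d edge(s)\n",
              length(x$cliques), nrow(x$edges)))
  invisible(x)
}

#' Nodes reachable downstream of a node
#'
#' Follows directed edges only. The start node itself is included only when
#' it lies on a directed cycle through itself.
#'
#' @param p A `Pathway`.
#' @param node Start node id.
#' @return Character vector of reachable node ids.
#' @export
reachable_downstream <- function(p, node) {
  stopifnot(inherits(p, "Pathway"))
  if (!node %in% p$nodes) stop("unknown node: ", node)
  e <- p$edges[p$edges$directed, , drop = FALSE]
  adj <- split(e$target, factor(e$source, levels = p$nodes))
  seen <- character()
  frontier <- unique(adj[[node]])
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

#' Pairwise hop distances on the undirected skeleton
#' @param p A `Pathway`.
#' @return Symmetric numeric matrix of shortest-path hop counts, `Inf` where
#'   disconnected, 0 on the diagonal.
#' @export
shortest_path_lengths <- function(p) {
  stopifnot(inherits(p, "Pathway"))
  g <- .skeleton_igraph(p)
  D <- igraph::distances(g)
  D[p$nodes, p$nodes, drop = FALSE]
}

# Collapsed sign between ordered node pairs: majority of nonzero signs of
# parallel edges, ties -> 0. directed_only: use j->i directed edges only.
.collapsed_sign <- function(p, directed_only = TRUE) {
  n <- length(p$nodes)
  pos <- stats::setNames(seq_len(n), p$nodes)
  plus <- matrix(0L, n, n, dimnames = list(p$nodes, p$nodes))
  minus <- plus
  e <- p$edges
  for (k in seq_len(nrow(e))) {
    s <- e$sign[k]
    if (s == 0L) next
    i <- pos[e$target[k]]; j <- pos[e$source[k]]
    if (e$directed[k]) {
      if (s > 0) plus[i, j] <- plus[i, j] + 1L else minus[i, j] <- minus[i, j] + 1L
    } else if (!directed_only) {
      if (s > 0) { plus[i, j] <- plus[i, j] + 1L; plus[j, i] <- plus[j, i] + 1L }
      else { minus[i, j] <- minus[i, j] + 1L; minus[j, i] <- minus[j, i] + 1L }
    }
  }
  sign(plus - minus)
}

#' Signed adjacency and outdegrees for perturbation propagation
#'
#' Builds the matrix `B` with `B[i, j]` the sign of the (collapsed) directed
#' edge j -> i divided by j's signed outdegree `N_ds(j)`, the propagation
#' operator of the perturbation-accumulation model.
#'
#' @param p A fully directed `Pathway` (see [orient_undirected()]).
#' @return List with `B` (numeric matrix), `nodes`, and `outdegree` (named
#'   integer, number of distinct targets with nonzero collapsed sign).
#' @export
signed_adjacency <- function(p) {
  stopifnot(inherits(p, "Pathway"))
  if (any(!p$edges$directed)) {
    stop("signed_adjacency() needs directed edges only; orient_undirected() first")
  }
  S <- .collapsed_sign(p, directed_only = TRUE)
  nds <- colSums(S != 0L)
  B <- S * 0
  nz <- nds > 0
  if (any(nz)) B[, nz] <- sweep(S[, nz, drop = FALSE] * 1.0, 2, nds[nz], "/")
  list(B = B, nodes = p$nodes, outdegree = nds)
}

#' Graph Laplacian of a pathway
#'
#' Unsigned: `L = D - A` with `A` the symmetrized 0/1 adjacency and `D` the
#' degree diagonal (positive semidefinite). Signed: `A` carries interaction
#' signs (+1 activation or neutral, -1 inhibition; conflicting parallel
#' signs cancel to 0) and `D` is the diagonal of row sums of `|A|`, so that
#' inhibition contributes structure without being treated as activation.
#'
#' @param p A `Pathway`.
#' @param signed Use interaction signs (default `FALSE`).
#' @return List with `L` (numeric matrix) and `nodes` (the row/column order).
#' @export
graph_laplacian <- function(p, signed = FALSE) {
  stopifnot(inherits(p, "Pathway"))
  n <- length(p$nodes)
  if (!signed) {
    A <- .skeleton_adjacency(p) * 1.0
  } else {
    e <- p$edges
    e$sign[e$sign == 0L] <- 1L   # neutral edges connect without inhibiting
    p2 <- p; p2$edges <- e
    S <- .collapsed_sign(p2, directed_only = FALSE)
    Sd <- .collapsed_sign(p2, directed_only = TRUE)
    # symmetrize: any direction counts; conflicts cancel
    A <- sign(sign(S + t(S) + Sd + t(Sd)))
    conflict <- (S + t(S) + Sd + t(Sd)) == 0 &
      ((S != 0) | (t(S) != 0) | (Sd != 0) | (t(Sd) != 0))
    A[conflict] <- 0
    diag(A) <- 0
    A <- A * 1.0
  }
  D <- diag(rowSums(abs(A)), n)
  L <- D - A
  dimnames(L) <- list(p$nodes, p$nodes)
  list(L = L, nodes = p$nodes)
}
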