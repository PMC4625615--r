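# Shared fixture builders and independent oracles used across test files.

chain_pathway <- function(nodes = c("A", "B", "C"), sign = 1) {
  n <- length(nodes)
  build_pathway(paste(nodes, collapse = ""), nodes,
                data.frame(source = nodes[-n], target = nodes[-1],
                           sign = sign))
}

triangle_pathway <- function() {
  build_pathway("tri", c("A", "B", "C"),
                data.frame(source = c("A", "B", "C"),
                           target = c("B", "C", "A"), sign = 1))
}

random_adjacency <- function(n, p_edge, seed) {
  set.seed(seed)
  A <- matrix(FALSE, n, n,
              dimnames = list(LETTERS[seq_len(n)], LETTERS[seq_len(n)]))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) A[i, j] <- A[j, i] <- TRUE
    }
  }
  A
}

# brute-force maximal clique enumeration over all vertex subsets
brute_force_cliques <- function(A) {
  nodes <- rownames(A)
  n <- length(nodes)
  is_clique <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    all(A[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
  }
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(idx)) next
    # maximal: no vertex outside connected to all members
    ext <- setdiff(seq_len(n), idx)
    if (!any(vapply(ext, function(v) all(A[v, idx]), logical(1)))) {
      cliques[[length(cliques) + 1]] <- sort(nodes[idx])
    }
  }
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(keys)]
}

# independent running-intersection check (BFS over the clique tree)
check_running_intersection <- function(jt) {
  for (v in unique(unlist(jt$cliques))) {
    has <- which(vapply(jt$cliques, function(cl) v %in% cl, logical(1)))
    if (length(has) <= 1) next
    sub <- jt$edges[jt$edges[, 1] %in% has & jt$edges[, 2] %in% has, ,
                    drop = FALSE]
    seen <- has[1]
    repeat {
      nxt <- unique(c(sub[sub[, 1] %in% seen, 2], sub[sub[, 2] %in% seen, 1]))
      new <- setdiff(nxt, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    if (length(seen) != length(has)) return(FALSE)
  }
  TRUE
}

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  D[A] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# small reproducible NB count matrix
toy_counts <- function(genes = 60, samples = 6, seed = 1, mu = 300,
                       size = 8) {
  set.seed(seed)
  m <- matrix(rnbinom(genes * samples, mu = mu, size = size), genes, samples,
              dimnames = list(sprintf("g%03d", seq_len(genes)),
                              sprintf("s%d", seq_len(samples))))
  m
}

toy_groups <- function(samples, n1 = length(samples) %/% 2) {
  group_labels(samples, rep(c("ctrl", "case"),
                            c(n1, length(samples) - n1)))
}

# two-clique fixture for the junction-tree methods: collider A,B -> C plus
# chain C -> D -> E; moralization yields cliques {A,B,C}, {C,D}, {D,E}
two_clique_pathway <- function() {
  build_pathway("twoclique", LETTERS[1:5],
                data.frame(source = c("A", "B", "C", "D"),
                           target = c("C", "C", "D", "E"), sign = 1))
}

gaussian_em <- function(genes, n = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, sprintf("s%02d", seq_len(n))))
  expression_matrix(x, "normalized")
}
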