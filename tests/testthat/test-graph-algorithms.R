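test_that("maximal cliques match hand-enumerable cases", {
  expect_equal(maximal_cliques(triangle_pathway()),
               list(c("A", "B", "C")))
  path <- build_pathway("p", c("A", "B", "C"),
                        data.frame(source = c("A", "B"),
                                   target = c("B", "C"),
                                   directed = FALSE, sign = 0))
  expect_equal(maximal_cliques(path), list(c("A", "B"), c("B", "C")))
  expect_equal(maximal_cliques(matrix(FALSE, 0, 0)), list())
})

test_that("maximal cliques equal brute-force enumeration on random graphs", {
  for (seed in 1:50) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, runif(1, 0.2, 0.7), seed = 1000 + seed)
    expect_identical(maximal_cliques(A), brute_force_cliques(A))
  }
})

test_that("moralize marries parents and rejects cycles", {
  collider <- build_pathway("c", c("A", "B", "C"),
                            data.frame(source = c("A", "B"),
                                       target = c("C", "C"), sign = 1))
  A <- moralize(collider)
  expect_true(A["A", "B"] && A["A", "C"] && A["B", "C"])
  chain <- chain_pathway(c("A", "B", "C"))
  Ac <- moralize(chain)
  expect_true(Ac["A", "B"] && Ac["B", "C"] && !Ac["A", "C"])
  cyc <- build_pathway("y", c("A", "B"),
                       data.frame(source = c("A", "B"), target = c("B", "A"),
                                  sign = 1))
  expect_error(moralize(cyc), "cyclic")
  expect_false(is_dag(cyc))
  expect_true(is_dag(chain))
})

test_that("triangulate returns a chordal supergraph; 4-cycle gets one chord", {
  sq <- build_pathway("sq", LETTERS[1:4],
                      data.frame(source = c("A", "B", "C", "D"),
                                 target = c("B", "C", "D", "A"),
                                 directed = FALSE, sign = 0))
  A <- pathtopo:::.skeleton_adjacency(sq)
  tri <- triangulate(A)
  expect_true(is_chordal(tri$adjacency))
  expect_equal(sum(tri$adjacency) / 2, 5)        # 4 + 1 chord
  expect_true(all(tri$adjacency[A]))             # supergraph
  # trees and complete graphs are already chordal
  tree <- pathtopo:::.skeleton_adjacency(chain_pathway(LETTERS[1:5]))
  expect_identical(triangulate(tree)$adjacency, tree)
  K <- matrix(TRUE, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(K) <- FALSE
  expect_identical(triangulate(K)$adjacency, K)
})

test_that("junction tree has correct cliques/separators and rejects chordless input", {
  path <- build_pathway("p", c("A", "B", "C"),
                        data.frame(source = c("A", "B"),
                                   target = c("B", "C"),
                                   directed = FALSE, sign = 0))
  jt <- build_junction_tree(pathtopo:::.skeleton_adjacency(path))
  expect_equal(jt$cliques, list(c("A", "B"), c("B", "C")))
  expect_equal(jt$separators[[1]], "B")
  K <- matrix(TRUE, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(K) <- FALSE
  jtK <- build_junction_tree(K)
  expect_equal(length(jtK$cliques), 1)
  expect_equal(nrow(jtK$edges), 0)
  sq <- random_adjacency(4, 0, seed = 1)
  sq["A", "B"] <- sq["B", "A"] <- TRUE; sq["B", "C"] <- sq["C", "B"] <- TRUE
  sq["C", "D"] <- sq["D", "C"] <- TRUE; sq["D", "A"] <- sq["A", "D"] <- TRUE
  expect_error(build_junction_tree(sq), "chordal")
})

test_that("running intersection holds on 100 random chordal graphs", {
  for (seed in 1:100) {
    n <- sample(4:10, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.6), seed = 4000 + seed)
    tri <- triangulate(A)
    jt <- build_junction_tree(tri$adjacency)
    expect_true(check_running_intersection(jt))
    # separators are exactly pairwise clique intersections
    if (nrow(jt$edges)) {
      for (r in seq_len(nrow(jt$edges))) {
        expect_equal(sort(jt$separators[[r]]),
                     sort(intersect(jt$cliques[[jt$edges[r, 1]]],
                                    jt$cliques[[jt$edges[r, 2]]])))
      }
    }
  }
})

test_that("junction-tree pipeline succeeds for random DAGs", {
  for (seed in 1:20) {
    p <- make_random_pathway(sample(4:10, 1), 0.3, dag = TRUE, seed = seed)
    jt <- build_junction_tree(triangulate(moralize(p))$adjacency)
    expect_true(check_running_intersection(jt))
  }
})

test_that("downstream reachability follows directed walks only", {
  chain <- chain_pathway(c("A", "B", "C"))
  expect_equal(reachable_downstream(chain, "A"), c("B", "C"))
  expect_equal(reachable_downstream(chain, "C"), character())
  cyc <- build_pathway("y", c("A", "B"),
                       data.frame(source = c("A", "B"), target = c("B", "A"),
                                  sign = 1))
  expect_setequal(reachable_downstream(cyc, "A"), c("A", "B"))
  expect_error(reachable_downstream(chain, "Z"), "unknown")
  # undirected edges do not propagate
  und <- build_pathway("u", c("A", "B"),
                       data.frame(source = "A", target = "B",
                                  directed = FALSE, sign = 0))
  expect_equal(reachable_downstream(und, "A"), character())
})

test_that("hop distances match a Floyd-Warshall oracle", {
  chain <- chain_pathway(c("A", "B", "C"))
  D <- shortest_path_lengths(chain)
  expect_equal(D["A", "C"], 2)
  iso <- build_pathway("i", c("A", "B", "C"),
                       data.frame(source = "A", target = "B", sign = 1))
  expect_equal(shortest_path_lengths(iso)["A", "C"], Inf)
  for (seed in 1:12) {
    p <- make_random_pathway(sample(4:10, 1), 0.3, dag = FALSE, seed = seed)
    A <- pathtopo:::.skeleton_adjacency(p)
    expect_equal(shortest_path_lengths(p), floyd_warshall(A))
  }
})

test_that("Laplacians follow the stated formulas and are PSD when unsigned", {
  und <- build_pathway("u", c("A", "B"),
                       data.frame(source = "A", target = "B",
                                  directed = FALSE, sign = 0))
  L <- graph_laplacian(und)$L
  expect_equal(unname(L), matrix(c(1, -1, -1, 1), 2))
  inh <- build_pathway("i", c("A", "B"),
                       data.frame(source = "A", target = "B",
                                  directed = FALSE, sign = -1))
  Ls <- graph_laplacian(inh, signed = TRUE)$L
  expect_equal(unname(Ls), matrix(c(1, 1, 1, 1), 2))
  for (seed in 1:10) {
    p <- make_random_pathway(sample(3:9, 1), 0.35, dag = FALSE, seed = seed)
    ev <- eigen(graph_laplacian(p)$L, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-12))
    # zero eigenvalue multiplicity = number of connected components
    ncomp <- topology_stats(p)$n_components
    expect_equal(sum(abs(ev) < 1e-9), ncomp)
  }
})

test_that("signed adjacency divides by outdegree and collapses conflicts", {
  p <- build_pathway("s", c("A", "B", "C"),
                     data.frame(source = c("A", "A"), target = c("B", "C"),
                                sign = c(1, -1)))
  sa <- signed_adjacency(p)
  expect_equal(unname(sa$outdegree["A"]), 2)
  expect_equal(sa$B["B", "A"], 0.5)
  expect_equal(sa$B["C", "A"], -0.5)
  # conflicting parallel signs cancel
  conf <- build_pathway("c", c("A", "B"),
                        data.frame(source = c("A", "A"), target = c("B", "B"),
                                   sign = c(1, -1)))
  expect_equal(signed_adjacency(conf)$B["B", "A"], 0)
})
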