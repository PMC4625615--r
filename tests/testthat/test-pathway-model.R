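test_that("build_pathway validates nodes and edges", {
  p <- build_pathway("p", c("A", "B"),
                     data.frame(source = "A", target = "B", sign = 1))
  expect_s3_class(p, "Pathway")
  expect_equal(length(p$nodes), 2)
  expect_equal(nrow(p$edges), 1)
  expect_error(build_pathway("p", c("A", "B"),
                             data.frame(source = "A", target = "C",
                                        sign = 1)),
               "C")
  expect_error(build_pathway("p", c("A", "A")), "duplicate")
  expect_error(build_pathway("p", c("A", "B"),
                             data.frame(source = "A", target = "B",
                                        sign = 2)),
               "sign")
  # parallel edges with opposite signs are both retained
  pp <- build_pathway("p", c("A", "B"),
                      data.frame(source = c("A", "A"), target = c("B", "B"),
                                 sign = c(1, -1)))
  expect_equal(nrow(pp$edges), 2)
})

test_that("edit_nodes removes incident edges and never mutates input", {
  p <- chain_pathway(c("A", "B", "C"))
  q <- edit_nodes(p, remove = "B")
  expect_setequal(q$nodes, c("A", "C"))
  expect_equal(nrow(q$edges), 0)
  # original untouched
  expect_equal(nrow(p$edges), 2)
  q2 <- edit_nodes(p, add = "D")
  expect_equal(length(q2$nodes), 4)
  expect_equal(nrow(q2$edges), 2)
  expect_error(edit_nodes(p, remove = "Z"), "unknown")
  expect_error(node_degree(edit_nodes(p, remove = "A"), "A"), "unknown")
})

test_that("edit_edges retypes, removes by selector, and adds mixed edges", {
  p <- build_pathway("p", c("A", "B"),
                     data.frame(source = c("A", "A"), target = c("B", "B"),
                                sign = c(1, -1)))
  q <- edit_edges(p, retype = list(select = list(source = "A", sign = 1),
                                   sign = -1))
  expect_equal(q$edges$sign, c(-1L, -1L))
  expect_equal(nrow(q$edges), 2)
  r <- edit_edges(p, remove = list(source = "A", target = "B", sign = -1))
  expect_equal(nrow(r$edges), 1)
  expect_equal(r$edges$sign, 1L)
  expect_error(edit_edges(p, remove = list(source = "B", target = "A")),
               "matched no")
  # adding an undirected edge to a directed-only pathway is valid
  s <- edit_edges(p, add = data.frame(source = "A", target = "B",
                                      directed = FALSE, sign = 0))
  expect_equal(sum(!s$edges$directed), 1)
})

test_that("merge_pathways unions nodes, concatenates edges, checks namespace", {
  p <- chain_pathway(c("A", "B"))
  q <- chain_pathway(c("C", "D", "E"))
  m <- merge_pathways(p, q)
  expect_equal(length(m$nodes), 5)
  expect_equal(nrow(m$edges), 3)
  self <- merge_pathways(p, p)
  expect_equal(length(self$nodes), 2)
  expect_equal(nrow(self$edges), 2)
  ent <- build_pathway("e", c("1", "2"),
                       data.frame(source = "1", target = "2", sign = 1),
                       id_namespace = "entrez")
  expect_error(merge_pathways(p, ent), "namespace")
})

test_that("induced_subgraph keeps exactly the internal edges", {
  tri <- triangle_pathway()
  expect_equal(nrow(induced_subgraph(tri, c("A", "B"))$edges), 1)
  expect_equal(induced_subgraph(tri, tri$nodes)$edges, tri$edges)
  one <- induced_subgraph(tri, "A")
  expect_equal(length(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)
  # self-loops on kept nodes are retained
  loop <- build_pathway("l", c("A", "B"),
                        data.frame(source = c("A", "A"),
                                   target = c("A", "B"), sign = 1))
  expect_equal(nrow(induced_subgraph(loop, "A")$edges), 1)
  expect_error(induced_subgraph(tri, c("A", "Z")), "unknown")
})

test_that("orient_undirected doubles or keeps undirected edges", {
  p <- build_pathway("u", c("A", "B"),
                     data.frame(source = "A", target = "B",
                                directed = FALSE, sign = -1))
  both <- orient_undirected(p, "both")
  expect_equal(nrow(both$edges), 2)
  expect_true(all(both$edges$directed))
  expect_equal(sort(both$edges$source), c("A", "B"))
  expect_equal(both$edges$sign, c(-1L, -1L))
  one <- orient_undirected(p, "as-listed")
  expect_equal(nrow(one$edges), 1)
  expect_equal(one$edges$source, "A")
  d <- chain_pathway(c("A", "B"))
  expect_identical(orient_undirected(d, "both")$edges, d$edges)
})

test_that("topology_stats counts nodes, parallel edges and components", {
  tri <- triangle_pathway()
  st <- topology_stats(tri)
  expect_equal(st$n_nodes, 3)
  expect_equal(st$n_edges, 3)
  expect_equal(st$n_components, 1)
  two <- build_pathway("two", c("A", "B", "C", "D"),
                       data.frame(source = c("A", "C"), target = c("B", "D"),
                                  sign = 1))
  expect_equal(topology_stats(two)$n_components, 2)
  par <- build_pathway("par", c("A", "B"),
                       data.frame(source = c("A", "A"), target = c("B", "B"),
                                  sign = c(1, -1)))
  stp <- topology_stats(par)
  expect_equal(stp$n_edges, 2)
  expect_equal(unname(stp$out_degree["A"]), 2)
})

test_that("filter_pathways is an order-preserving subset", {
  coll <- pathway_collection(list(chain_pathway(c("A", "B")),
                                  chain_pathway(c("C", "D", "E", "F", "G"))),
                             c("small", "big"))
  kept <- filter_pathways(coll, function(st) st$n_nodes >= 3)
  expect_equal(names(kept), "big")
  expect_equal(names(filter_pathways(coll, function(st) TRUE)),
               c("small", "big"))
  empty <- filter_pathways(coll, function(st) FALSE)
  expect_equal(length(empty), 0)
  expect_s3_class(empty, "PathwayCollection")
})

test_that("random edit sequences always yield valid pathways", {
  set.seed(11)
  for (rep in 1:20) {
    p <- make_random_pathway(8, 0.3, dag = FALSE, seed = rep)
    for (step in 1:6) {
      op <- sample(3, 1)
      if (op == 1 && length(p$nodes) > 2) {
        p <- edit_nodes(p, remove = sample(p$nodes, 1))
      } else if (op == 2) {
        p <- edit_nodes(p, add = paste0("new", rep, "_", step))
      } else if (nrow(p$edges) < 30) {
        ends <- sample(p$nodes, 2)
        p <- edit_edges(p, add = data.frame(source = ends[1],
                                            target = ends[2],
                                            directed = sample(c(TRUE, FALSE), 1),
                                            sign = sample(c(-1L, 0L, 1L), 1)))
      }
      # re-validates from scratch; errors would fail the test
      q <- build_pathway(p$id, p$nodes, p$edges, p$id_namespace)
      expect_s3_class(q, "Pathway")
    }
  }
})
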