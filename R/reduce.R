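# Node merging: gene families (identical signed neighborhoods, no internal
# edges) and protein complexes (all-to-all undirected binding, identical
# external neighborhoods) can be collapsed to single nodes without losing
# topological information.

# Signature of a node's signed neighborhood as a character set. `exclude`
# drops edges whose other endpoint is in that set (external view).
.node_signature <- function(edges, v, exclude = character()) {
  sig <- character()
  for (k in seq_len(nrow(edges))) {
    s <- edges$source[k]; t <- edges$target[k]
    if (s != v && t != v) next
    other <- if (s == v) t else s
    if (other %in% exclude) next
    dir <- if (!edges$directed[k]) "un" else if (s == v) "out" else "in"
    sig <- c(sig, paste(dir, edges$sign[k], other, sep = "|"))
  }
  sort(unique(sig))
}

.edges_between <- function(edges, members) {
  which(edges$source %in% members & edges$target %in% members)
}

# TRUE if `members` forms a gene family (rule "family") or a protein complex
# (rule "complex") in pathway p; returns the rule name or FALSE.
.group_rule <- function(p, members) {
  e <- p$edges
  internal <- .edges_between(e, members)
  sigs_full <- lapply(members, .node_signature, edges = e)
  if (length(internal) == 0L) {
    if (length(unique(vapply(sigs_full, paste, character(1),
                             collapse = ";"))) == 1L) {
      return("family")
    }
  }
  # complex: internal edges all undirected, covering every member pair
  if (length(internal)) {
    int <- e[internal, , drop = FALSE]
    if (all(!int$directed)) {
      pairs <- unique(apply(cbind(pmin(int$source, int$target),
                                  pmax(int$source, int$target)), 1,
                            paste, collapse = "|"))
      need <- utils::combn(sort(members), 2,
                           function(x) paste(x, collapse = "|"))
      if (all(need %in% pairs)) {
        sigs_ext <- lapply(members, .node_signature, edges = e,
                           exclude = members)
        if (length(unique(vapply(sigs_ext, paste, character(1),
                                 collapse = ";"))) == 1L) {
          return("complex")
        }
      }
    }
  }
  FALSE
}

#' Estimate mergeable gene families and protein complexes
#'
#' Scans a pathway for maximal sets of nodes that can be collapsed by
#' [reduce_graph()] without losing topological information. Two rules apply:
#' a *gene family* is a set of nodes with identical signed in/out
#' neighborhoods and no edges among its members; a *protein complex* is a set
#' whose members are pairwise connected by undirected (binding) edges and
#' share identical external signed neighborhoods. Groups are maximal under
#' set inclusion and pairwise disjoint; when candidates overlap, larger
#' groups win, ties broken by the lexicographically smallest member.
#'
#' @param p A `Pathway`.
#' @return A named list mapping group name (members joined by `/`) to the
#'   member node ids; empty list when nothing is mergeable.
#' @export
estimate_cf <- function(p) {
  stopifnot(inherits(p, "Pathway"))
  e <- p$edges
  cand <- list()
  # families: partition nodes by full-neighborhood signature
  sigs <- vapply(p$nodes, function(v) {
    paste(.node_signature(e, v), collapse = ";")
  }, character(1))
  for (cls in split(p$nodes, sigs)) {
    if (length(cls) < 2L) next
    # signatures equal implies no internal edges (an internal edge would put
    # a member id into its partner's signature); guard anyway
    while (length(cls) >= 2L && length(.edges_between(e, cls))) {
      counts <- vapply(cls, function(v) {
        sum(e$source[.edges_between(e, cls)] == v |
              e$target[.edges_between(e, cls)] == v)
      }, integer(1))
      cls <- cls[-which.max(counts)]
    }
    if (length(cls) >= 2L) cand <- c(cand, list(sort(cls)))
  }
  # complexes: maximal cliques of the undirected-edge subgraph
  und <- e[!e$directed & e$source != e$target, , drop = FALSE]
  if (nrow(und)) {
    adj <- .adjacency_from_pairs(p$nodes, und$source, und$target)
    for (cl in maximal_cliques(adj)) {
      if (length(cl) >= 2L && identical(.group_rule(p, cl), "complex")) {
        cand <- c(cand, list(sort(cl)))
      }
    }
  }
  if (!length(cand)) return(stats::setNames(list(), character()))
  cand <- unique(cand)
  # drop candidates strictly contained in another
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      i != j && all(cand[[i]] %in% cand[[j]]) &&
        length(cand[[j]]) > length(cand[[i]])
    }, logical(1)))
  }, logical(1))
  cand <- cand[keep]
  ord <- order(-lengths(cand), vapply(cand, `[`, character(1), 1))
  cand <- cand[ord]
  out <- list(); used <- character()
  for (g in cand) {
    if (!any(g %in% used)) {
      out[[paste(g, collapse = "/")]] <- g
      used <- c(used, g)
    }
  }
  out
}

.check_grouping <- function(p, grouping) {
  if (!length(grouping)) return(invisible(TRUE))
  if (is.null(names(grouping)) || any(!nzchar(names(grouping)))) {
    stop("every group must be named")
  }
  all_members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("groups overlap on node(s): ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  for (nm in names(grouping)) {
    g <- grouping[[nm]]
    if (length(g) < 2L) stop("group '", nm, "' has fewer than 2 members")
    missing <- setdiff(g, p$nodes)
    if (length(missing)) {
      stop("group '", nm, "' contains unknown node(s): ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Collapse node groups into single nodes
#'
#' Each group (a gene family or a protein complex, see [estimate_cf()]) is
#' replaced by one node named after the group. Edges internal to a group are
#' dropped (they are redundant under the family/complex rules); external
#' edges are re-attached to the merged node, and re-attached parallel edges
#' identical in endpoint, direction and sign collapse to one. Parallel edges
#' with conflicting signs are kept.
#'
#' @param p A `Pathway`.
#' @param grouping Named list mapping group name to >= 2 member node ids;
#'   groups must be disjoint and each must satisfy the family or complex rule.
#' @param check_rules Enforce the family/complex membership rule (default
#'   `TRUE`); with `FALSE` arbitrary disjoint groups are collapsed with the
#'   same re-attachment semantics.
#' @return A new `Pathway`; attribute `"members"` maps each merged node to
#'   its original members.
#' @export
reduce_graph <- function(p, grouping, check_rules = TRUE) {
  stopifnot(inherits(p, "Pathway"))
  .check_grouping(p, grouping)
  if (check_rules) {
    for (nm in names(grouping)) {
      if (isFALSE(.group_rule(p, grouping[[nm]]))) {
        stop("group '", nm, "' satisfies neither the gene-family rule ",
             "(identical signed neighborhoods, no internal edges) nor the ",
             "protein-complex rule (all-to-all undirected binding, identical ",
             "external neighborhoods)")
      }
    }
  }
  rename <- stats::setNames(p$nodes, p$nodes)
  for (nm in names(grouping)) rename[grouping[[nm]]] <- nm
  e <- p$edges
  old_src <- e$source; old_tgt <- e$target
  e$source <- unname(rename[e$source])
  e$target <- unname(rename[e$target])
  # drop edges internal to a group (both endpoints collapsed to same node,
  # but keep original self-loops)
  drop <- e$source == e$target & old_src != old_tgt
  # also drop self-loops on merged members? a loop on a member re-attaches
  # to the merged node as a loop
  e <- e[!drop, , drop = FALSE]
  merged_names <- names(grouping)
  touched <- e$source %in% merged_names | e$target %in% merged_names
  if (any(touched)) {
    key <- paste(e$source, e$target, e$directed, e$sign, sep = "\r")
    dup <- duplicated(key) & touched
    e <- e[!dup, , drop = FALSE]
  }
  nodes <- unique(unname(rename[p$nodes]))
  out <- build_pathway(p$id, nodes, e, p$id_namespace, p$title, p$species)
  attr(out, "members") <- grouping
  out
}

#' Rename node identifiers via a user-supplied mapping
#'
#' Maps node ids into a new namespace. A node with exactly one image is
#' renamed; a node with k > 1 images is expanded into k nodes, each
#' inheriting all incident edges; unmapped nodes are kept under their old id
#' (a warning reports the count). When two distinct old nodes collide onto
#' one new id they are merged (external edges re-attached, edges between
#' them dropped, identical re-attached parallels collapsed), with a warning.
#'
#' @param p A `Pathway`.
#' @param mapping Named list/character vector: old id -> character vector of
#'   new ids. An empty mapping leaves the pathway unchanged.
#' @param id_namespace Namespace tag for the result; `NULL` (default) keeps
#'   the input namespace.
#' @return A new `Pathway`; attribute `"n_unmapped"` counts kept old ids.
#' @export
convert_identifiers <- function(p, mapping, id_namespace = NULL) {
  stopifnot(inherits(p, "Pathway"))
  if (is.null(id_namespace)) id_namespace <- p$id_namespace
  mapping <- as.list(mapping)
  images <- lapply(p$nodes, function(v) {
    if (!is.null(mapping[[v]]) && length(mapping[[v]])) {
      as.character(mapping[[v]])
    } else NA_character_
  })
  names(images) <- p$nodes
  unmapped <- vapply(images, function(x) all(is.na(x)), logical(1))
  n_unmapped <- sum(unmapped)
  if (n_unmapped) {
    warning(n_unmapped, " node(s) had no mapping and keep their old id")
    images[unmapped] <- as.list(names(images)[unmapped])
  }
  new_nodes <- unique(unlist(images, use.names = FALSE))
  # detect collisions: a new id produced by >1 old node
  owners <- table(unlist(lapply(names(images), function(v) unique(images[[v]]))))
  collided <- names(owners)[owners > 1]
  if (length(collided)) {
    warning(length(collided), " new id(s) received multiple old nodes; ",
            "merged: ", paste(utils::head(collided, 5), collapse = ", "))
  }
  e <- p$edges
  rows <- vector("list", nrow(e))
  for (k in seq_len(nrow(e))) {
    srcs <- images[[e$source[k]]]
    tgts <- images[[e$target[k]]]
    grid <- expand.grid(source = srcs, target = tgts,
                        stringsAsFactors = FALSE)
    if (e$source[k] != e$target[k]) {
      # edges between two old nodes that collapse together are internal
      grid <- grid[grid$source != grid$target, , drop = FALSE]
    }
    if (nrow(grid)) {
      rows[[k]] <- data.frame(grid, directed = e$directed[k],
                              sign = e$sign[k], subtype = e$subtype[k],
                              stringsAsFactors = FALSE)
    }
  }
  ee <- do.call(rbind, c(list(.empty_edges()), rows))
  if (length(collided) && nrow(ee)) {
    touched <- ee$source %in% collided | ee$target %in% collided
    key <- paste(ee$source, ee$target, ee$directed, ee$sign, sep = "\r")
    ee <- ee[!(duplicated(key) & touched), , drop = FALSE]
  }
  out <- build_pathway(p$id, new_nodes, ee, id_namespace, p$title, p$species)
  attr(out, "n_unmapped") <- n_unmapped
  out
}
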