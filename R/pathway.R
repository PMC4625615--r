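# Signed pathway graphs: nodes are opaque, case-sensitive identifier strings;
# edges carry a direction flag, a sign (+1 activation, -1 inhibition, 0
# neutral/unknown) and a free-text subtype. Directed and undirected edges may
# coexist and parallel edges between the same pair are retained.

.empty_edges <- function() {
  data.frame(source = character(), target = character(),
             directed = logical(), sign = integer(),
             subtype = character(), stringsAsFactors = FALSE)
}

.as_edge_frame <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L)) {
    return(.empty_edges())
  }
  if (!is.data.frame(edges)) {
    stop("edges must be a data.frame with columns source and target")
  }
  for (col in c("source", "target")) {
    if (!col %in% names(edges)) stop("edges is missing column '", col, "'")
  }
  out <- data.frame(source = as.character(edges$source),
                    target = as.character(edges$target),
                    stringsAsFactors = FALSE)
  out$directed <- if ("directed" %in% names(edges)) {
    as.logical(edges$directed)
  } else TRUE
  out$sign <- if ("sign" %in% names(edges)) as.integer(edges$sign) else 0L
  out$subtype <- if ("subtype" %in% names(edges)) {
    as.character(edges$subtype)
  } else ""
  rownames(out) <- NULL
  out
}

.validate_pathway <- function(p) {
  stopifnot(is.list(p))
  nodes <- p$nodes
  edges <- p$edges
  if (anyDuplicated(nodes)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (any(is.na(nodes)) || any(!nzchar(nodes))) stop("empty node id")
  bad_sign <- !edges$sign %in% c(-1L, 0L, 1L)
  if (any(bad_sign)) {
    stop("edge sign must be -1, 0 or +1 (offending row ",
         which(bad_sign)[1], ")")
  }
  dangling <- setdiff(c(edges$source, edges$target), nodes)
  if (length(dangling)) {
    stop("edge endpoint(s) not in node set: ",
         paste(unique(dangling), collapse = ", "))
  }
  if (any(is.na(edges$directed))) stop("edge 'directed' flag must be TRUE/FALSE")
  invisible(p)
}

#' Construct a signed pathway graph
#'
#' A `Pathway` is a multigraph over gene/protein identifiers: directed and
#' undirected edges may coexist, parallel edges between the same node pair
#' are retained, and each edge carries a sign (+1 activation, -1 inhibition,
#' 0 neutral) plus a free-text interaction subtype.
#'
#' @param id Pathway identifier.
#' @param nodes Character vector of unique node ids.
#' @param edges A data.frame with columns `source`, `target` and optionally
#'   `directed` (logical, default `TRUE`), `sign` (-1/0/1, default 0) and
#'   `subtype` (character, default `""`).
#' @param id_namespace Identifier namespace tag, e.g. `"symbol"` or
#'   `"entrez"`. Node ids are opaque strings; no namespace inference is
#'   performed.
#' @param title,species Optional descriptive fields.
#' @return An object of class `Pathway`.
#' @examples
#' p <- build_pathway("toy", c("A", "B"),
#'                    data.frame(source = "A", target = "B", sign = 1))
#' topology_stats(p)$n_edges
#' @export
build_pathway <- function(id, nodes, edges = NULL, id_namespace = "symbol",
                          title = id, species = NA_character_) {
  p <- structure(list(id = as.character(id), title = as.character(title),
                      species = as.character(species),
                      id_namespace = as.character(id_namespace),
                      nodes = as.character(nodes),
                      edges = .as_edge_frame(edges)),
                 class = "Pathway")
  .validate_pathway(p)
  p
}

#' @export
print.Pathway <- function(x, ...) {
  st <- topology_stats(x)
  cat(sprintf("Pathway '%s' (%s): %d nodes, %d edges, %d component(s)\n",
              x$id, x$id_namespace, st$n_nodes, st$n_edges, st$n_components))
  invisible(x)
}

#' Add and remove nodes
#'
#' Removing a node removes all incident edges. All editing operations return
#' a new `Pathway`; the input is never modified.
#'
#' @param p A `Pathway`.
#' @param add Node ids to add (must be new).
#' @param remove Node ids to remove (must exist).
#' @return A new `Pathway`.
#' @export
edit_nodes <- function(p, add = character(), remove = character()) {
  stopifnot(inherits(p, "Pathway"))
  add <- as.character(add); remove <- as.character(remove)
  unknown <- setdiff(remove, p$nodes)
  if (length(unknown)) {
    stop("cannot remove unknown node(s): ", paste(unknown, collapse = ", "))
  }
  clash <- intersect(add, setdiff(p$nodes, remove))
  if (length(clash)) {
    stop("node(s) already present: ", paste(clash, collapse = ", "))
  }
  nodes <- c(setdiff(p$nodes, remove), add)
  keep <- !(p$edges$source %in% remove | p$edges$target %in% remove)
  build_pathway(p$id, nodes, p$edges[keep, , drop = FALSE],
                p$id_namespace, p$title, p$species)
}

# Match edges against a selector (list or one-row data.frame with any of
# source, target, directed, sign, subtype). Returns a logical index.
.match_edges <- function(edges, sel) {
  sel <- as.list(sel)
  idx <- rep(TRUE, nrow(edges))
  for (f in intersect(names(sel), c("source", "target", "subtype"))) {
    idx <- idx & edges[[f]] == as.character(sel[[f]])
  }
  if (!is.null(sel$directed)) idx <- idx & edges$directed == as.logical(sel$directed)
  if (!is.null(sel$sign)) idx <- idx & edges$sign == as.integer(sel$sign)
  idx
}

#' Add, remove and retype edges
#'
#' @param p A `Pathway`.
#' @param add Edges to add, as a data.frame (see [build_pathway()]); endpoints
#'   must already exist in `p`.
#' @param remove A list of edge selectors. Each selector is a list naming any
#'   of `source`, `target`, `directed`, `sign`, `subtype`; every matching edge
#'   is removed. A selector matching nothing is an error.
#' @param retype A list of `list(select = <selector>, sign =, directed =,
#'   subtype =)` entries; only the supplied attributes of matched edges change.
#' @return A new `Pathway`.
#' @export
edit_edges <- function(p, add = NULL, remove = NULL, retype = NULL) {
  stopifnot(inherits(p, "Pathway"))
  edges <- p$edges
  if (!is.null(retype)) {
    if (!is.null(retype$select)) retype <- list(retype)
    for (r in retype) {
      idx <- .match_edges(edges, r$select)
      if (!any(idx)) stop("retype selector matched no edges")
      if (!is.null(r$sign)) edges$sign[idx] <- as.integer(r$sign)
      if (!is.null(r$directed)) edges$directed[idx] <- as.logical(r$directed)
      if (!is.null(r$subtype)) edges$subtype[idx] <- as.character(r$subtype)
    }
  }
  if (!is.null(remove)) {
    if (!is.null(names(remove)) && any(names(remove) %in%
        c("source", "target", "directed", "sign", "subtype"))) {
      remove <- list(remove)
    }
    drop <- rep(FALSE, nrow(edges))
    for (sel in remove) {
      idx <- .match_edges(edges, sel)
      if (!any(idx)) stop("remove selector matched no edges")
      drop <- drop | idx
    }
    edges <- edges[!drop, , drop = FALSE]
  }
  if (!is.null(add)) {
    add <- .as_edge_frame(add)
    edges <- rbind(edges, add)
  }
  build_pathway(p$id, p$nodes, edges, p$id_namespace, p$title, p$species)
}

#' Merge two pathways
#'
#' Node sets are unioned and edge lists concatenated; duplicated edges are
#' retained as parallel edges. Both pathways must share an identifier
#' namespace -- convert with [convert_identifiers()] first otherwise.
#'
#' @param p1,p2 `Pathway` objects with the same `id_namespace`.
#' @return A new `Pathway` named `<id1>+<id2>`.
#' @export
merge_pathways <- function(p1, p2) {
  stopifnot(inherits(p1, "Pathway"), inherits(p2, "Pathway"))
  if (!identical(p1$id_namespace, p2$id_namespace)) {
    stop("identifier namespace mismatch ('", p1$id_namespace, "' vs '",
         p2$id_namespace, "'); run convert_identifiers() first")
  }
  build_pathway(paste0(p1$id, "+", p2$id), union(p1$nodes, p2$nodes),
                rbind(p1$edges, p2$edges), p1$id_namespace)
}

#' Induced subgraph on a node subset
#'
#' Retains exactly the edges with both endpoints in `keep` (self-loops on a
#' kept node are retained).
#'
#' @param p A `Pathway`.
#' @param keep Node ids to keep (must all exist).
#' @return A new `Pathway`.
#' @export
induced_subgraph <- function(p, keep) {
  stopifnot(inherits(p, "Pathway"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, p$nodes)
  if (length(unknown)) {
    stop("unknown node(s) in keep: ", paste(unknown, collapse = ", "))
  }
  idx <- p$edges$source %in% keep & p$edges$target %in% keep
  build_pathway(p$id, p$nodes[p$nodes %in% keep],
                p$edges[idx, , drop = FALSE],
                p$id_namespace, p$title, p$species)
}

#' Orient undirected edges
#'
#' Methods that need a fully directed topology (SPIA, PRS) require undirected
#' interactions to be oriented first. Mode `"both"` replaces each undirected
#' edge by two directed edges of the same sign; `"as-listed"` keeps a single
#' directed edge from the stored source to the stored target.
#'
#' @param p A `Pathway`.
#' @param mode `"both"` or `"as-listed"`.
#' @return A new `Pathway` with only directed edges.
#' @export
orient_undirected <- function(p, mode = c("both", "as-listed")) {
  stopifnot(inherits(p, "Pathway"))
  mode <- match.arg(mode)
  e <- p$edges
  und <- which(!e$directed)
  if (!length(und)) return(p)
  e$directed <- TRUE
  if (mode == "both") {
    back <- e[und, , drop = FALSE]
    tmp <- back$source; back$source <- back$target; back$target <- tmp
    # a self-loop oriented "both" stays a single directed loop
    back <- back[back$source != back$target, , drop = FALSE]
    e <- rbind(e, back)
  }
  build_pathway(p$id, p$nodes, e, p$id_namespace, p$title, p$species)
}

#' Topological summary of a pathway
#'
#' @param p A `Pathway`.
#' @return A list with `n_nodes`, `n_edges`, `n_components` (connected
#'   components of the undirected skeleton), per-node `in_degree`,
#'   `out_degree`, `degree` (named integer vectors; parallel edges each
#'   counted, undirected edges counted on both endpoints) and `max_degree`.
#' @export
topology_stats <- function(p) {
  stopifnot(inherits(p, "Pathway"))
  n <- p$nodes
  e <- p$edges
  z <- stats::setNames(integer(length(n)), n)
  outd <- z; ind <- z
  if (nrow(e)) {
    dtab <- table(factor(e$source[e$directed], levels = n))
    outd <- outd + as.integer(dtab)
    itab <- table(factor(e$target[e$directed], levels = n))
    ind <- ind + as.integer(itab)
    for (col in c("source", "target")) {
      utab <- table(factor(e[[col]][!e$directed], levels = n))
      outd <- outd + as.integer(utab)
      ind <- ind + as.integer(utab)
    }
    names(outd) <- names(ind) <- n
  }
  deg <- outd + ind
  # self-loops contribute to both in and out; total degree counts both ends
  ncomp <- if (length(n)) {
    g <- .skeleton_igraph(p)
    igraph::count_components(g)
  } else 0L
  list(n_nodes = length(n), n_edges = nrow(e), n_components = ncomp,
       in_degree = ind, out_degree = outd, degree = deg,
       max_degree = if (length(deg)) max(deg) else 0L)
}

#' Degree of a single node
#' @param p A `Pathway`.
#' @param node A node id; unknown ids are an error.
#' @return Total degree (in + out, undirected edges counted once per endpoint).
#' @export
node_degree <- function(p, node) {
  stopifnot(inherits(p, "Pathway"))
  if (!node %in% p$nodes) stop("unknown node: ", node)
  topology_stats(p)$degree[[node]]
}

#' Ordered collection of named pathways
#'
#' @param pathways A list of `Pathway` objects.
#' @param names Optional unique, non-empty names; defaults to each pathway's
#'   `id`.
#' @return A `PathwayCollection` (named list).
#' @export
pathway_collection <- function(pathways, names = NULL) {
  stopifnot(is.list(pathways))
  lapply(pathways, function(p) stopifnot(inherits(p, "Pathway")))
  if (is.null(names)) names <- vapply(pathways, function(p) p$id, character(1))
  names <- as.character(names)
  if (any(!nzchar(names)) || anyDuplicated(names)) {
    stop("pathway names must be unique and non-empty")
  }
  structure(stats::setNames(pathways, names), class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection of %d pathway(s)\n", length(x)))
  for (nm in utils::head(names(x), 10)) {
    st <- topology_stats(x[[nm]])
    cat(sprintf("  %s: %d nodes, %d edges\n", nm, st$n_nodes, st$n_edges))
  }
  if (length(x) > 10) cat(sprintf("  ... and %d more\n", length(x) - 10))
  invisible(x)
}

#' @export
`[.PathwayCollection` <- function(x, i) {
  structure(NextMethod(), class = "PathwayCollection")
}

#' Filter a collection by topological properties
#'
#' @param collection A `PathwayCollection`.
#' @param predicate A function taking the [topology_stats()] record of a
#'   pathway and returning `TRUE` to keep it.
#' @return An order-preserving `PathwayCollection` subset (possibly empty).
#' @examples
#' \dontrun{filter_pathways(coll, function(st) st$n_nodes >= 3)}
#' @export
filter_pathways <- function(collection, predicate) {
  stopifnot(inherits(collection, "PathwayCollection"), is.function(predicate))
  keep <- vapply(collection, function(p) isTRUE(predicate(topology_stats(p))),
                 logical(1))
  collection[keep]
}
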