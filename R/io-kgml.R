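# KGML (KEGG XML) import. One node represents one gene: entries listing
# several gene ids are expanded, each expanded node inheriting every
# relation of its entry. Compounds and map links are skipped (counted).

#' Default KGML relation-subtype dialect
#'
#' Maps KGML relation subtypes to an edge sign and direction:
#' activation/expression (+1, directed); inhibition/repression (-1,
#' directed); binding/association and dissociation (0, undirected);
#' phosphorylation, dephosphorylation, ubiquitination, methylation,
#' glycosylation alone (0, directed); "indirect effect" inherits the sign of
#' a co-occurring activation/inhibition subtype, else (0, directed);
#' compound-mediated relations are skipped. Unknown subtypes become sign-0
#' directed edges with a warning.
#'
#' @param expand_entries Expand multi-gene entries into one node per gene
#'   (default `TRUE`); otherwise only the first gene id of an entry is used.
#' @return A `KgmlDialect` list with elements `map` (data.frame
#'   subtype/sign/directed), `skip` (subtypes aborting a relation) and
#'   `expand_entries`.
#' @export
kgml_dialect <- function(expand_entries = TRUE) {
  map <- data.frame(
    subtype = c("activation", "expression", "inhibition", "repression",
                "binding/association", "dissociation",
                "phosphorylation", "dephosphorylation", "ubiquitination",
                "methylation", "glycosylation", "state change"),
    sign = c(1L, 1L, -1L, -1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    directed = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  structure(list(map = map, skip = c("compound", "hidden compound"),
                 expand_entries = isTRUE(expand_entries)),
            class = "KgmlDialect")
}

# Decide (sign, directed, label) for a relation's subtype names under a
# dialect; NULL means skip, NA sign means unknown subtype.
.relation_type <- function(subtypes, dialect) {
  if (any(subtypes %in% dialect$skip)) return(NULL)
  label <- paste(subtypes, collapse = ",")
  known <- subtypes[subtypes %in% dialect$map$subtype]
  signs <- dialect$map$sign[match(known, dialect$map$subtype)]
  dirs <- dialect$map$directed[match(known, dialect$map$subtype)]
  if ("indirect effect" %in% subtypes) {
    s <- if (any(signs != 0L)) signs[signs != 0L][1] else 0L
    return(list(sign = s, directed = TRUE, label = label, unknown = FALSE))
  }
  if (length(known) == 0L) {
    return(list(sign = 0L, directed = TRUE, label = label,
                unknown = length(subtypes) > 0L))
  }
  if (any(signs != 0L)) {
    k <- which(signs != 0L)[1]
    return(list(sign = signs[k], directed = dirs[k], label = label,
                unknown = FALSE))
  }
  list(sign = 0L, directed = dirs[1], label = label, unknown = FALSE)
}

#' Parse a KGML pathway file
#'
#' @param x Path to a KGML file, or the XML text itself.
#' @param dialect A [kgml_dialect()].
#' @return A `Pathway` in namespace `"kegg"`. Node and edge order are
#'   canonicalized (sorted), so identical bytes give identical objects.
#'   Attribute `"skipped"` records counts of skipped compounds, maps and
#'   compound-mediated relations.
#' @examples
#' kgml <- system.file("extdata", "example.kgml.xml", package = "pathtopo")
#' p <- parse_kgml(kgml)
#' topology_stats(p)$n_nodes
#' @export
parse_kgml <- function(x, dialect = kgml_dialect()) {
  doc <- xml2::read_xml(x)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(xml2::xml_name(doc)) || xml2::xml_name(doc) != "pathway") {
    stop("not a KGML document (root element is not <pathway>)")
  }
  pid <- xml2::xml_attr(doc, "name")
  title <- xml2::xml_attr(doc, "title")
  org <- xml2::xml_attr(doc, "org")
  entries <- xml2::xml_find_all(doc, "entry")
  entry_genes <- list()   # entry id -> character vector of gene ids
  skipped <- c(compound = 0L, map = 0L, relation_compound = 0L,
               unknown_subtype = 0L)
  groups <- list()
  for (en in entries) {
    eid <- xml2::xml_attr(en, "id")
    etype <- xml2::xml_attr(en, "type")
    if (identical(etype, "gene") || identical(etype, "ortholog")) {
      ids <- strsplit(trimws(xml2::xml_attr(en, "name")), "\\s+")[[1]]
      ids <- ids[nzchar(ids)]
      if (!dialect$expand_entries && length(ids) > 1L) ids <- ids[1]
      entry_genes[[eid]] <- ids
    } else if (identical(etype, "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(en, "component"), "id")
      groups[[eid]] <- comp
    } else if (identical(etype, "compound")) {
      skipped["compound"] <- skipped["compound"] + 1L
    } else if (identical(etype, "map")) {
      skipped["map"] <- skipped["map"] + 1L
    }
  }
  # group entries refer to member entries; resolve to genes
  for (gid in names(groups)) {
    entry_genes[[gid]] <- unique(unlist(entry_genes[groups[[gid]]],
                                        use.names = FALSE))
  }
  nodes <- sort(unique(unlist(entry_genes, use.names = FALSE)))
  edges <- .empty_edges()
  add_edges <- function(srcs, tgts, directed, sign, label) {
    grid <- expand.grid(source = srcs, target = tgts,
                        stringsAsFactors = FALSE)
    if (!nrow(grid)) return(invisible())
    edges <<- rbind(edges, data.frame(grid, directed = directed,
                                      sign = sign, subtype = label,
                                      stringsAsFactors = FALSE))
  }
  n_unknown <- 0L
  for (rel in xml2::xml_find_all(doc, "relation")) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "subtype"), "name")
    ty <- .relation_type(subtypes, dialect)
    if (is.null(ty)) {
      skipped["relation_compound"] <- skipped["relation_compound"] + 1L
      next
    }
    if (ty$unknown) n_unknown <- n_unknown + 1L
    srcs <- entry_genes[[e1]]; tgts <- entry_genes[[e2]]
    if (is.null(srcs) || is.null(tgts)) next   # endpoints not gene entries
    add_edges(srcs, tgts, ty$directed, ty$sign, ty$label)
  }
  if (n_unknown) {
    skipped["unknown_subtype"] <- n_unknown
    warning(n_unknown, " relation(s) with unknown subtype kept as sign 0")
  }
  # complexes: all-to-all undirected binding among group members
  for (gid in names(groups)) {
    mem <- entry_genes[[gid]]
    if (length(mem) > 1L) {
      pairs <- utils::combn(mem, 2)
      add_edges_rows <- data.frame(source = pairs[1, ], target = pairs[2, ],
                                   directed = FALSE, sign = 0L,
                                   subtype = "binding",
                                   stringsAsFactors = FALSE)
      edges <- rbind(edges, add_edges_rows)
    }
  }
  if (nrow(edges)) {
    ord <- order(edges$source, edges$target, edges$directed, edges$sign,
                 edges$subtype)
    edges <- edges[ord, , drop = FALSE]
    key <- do.call(paste, c(edges, sep = "\r"))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  p <- build_pathway(if (is.na(pid)) "kgml" else pid, nodes, edges,
                     id_namespace = "kegg",
                     title = if (is.na(title)) pid else title,
                     species = org)
  attr(p, "skipped") <- skipped
  p
}
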