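# Tabular I/O. Everything is TSV with a header row and '.' decimals;
# reads are gzip-transparent (via R connections).

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a pathway from a signed edge-list TSV
#'
#' Required columns: `source`, `target`, `directed` (0/1), `sign` (-1/0/1);
#' optional `subtype`. The node set is the union of the endpoint columns;
#' isolated nodes can be added afterwards with [edit_nodes()].
#'
#' @param path TSV file (may be gzip-compressed).
#' @param id Pathway id (defaults to the file name without extension).
#' @param id_namespace Identifier namespace tag.
#' @return A `Pathway`.
#' @examples
#' tsv <- system.file("extdata", "example-pathway.tsv", package = "pathtopo")
#' read_edge_list(tsv, id = "demo")
#' @export
read_edge_list <- function(path, id = NULL,
                           id_namespace = "symbol") {
  d <- .read_tsv(path)
  for (col in c("source", "target", "directed", "sign")) {
    if (!col %in% names(d)) stop("edge list is missing column '", col, "'")
  }
  if (nrow(d)) {
    bad <- which(!d$sign %in% c(-1, 0, 1))
    if (length(bad)) {
      stop("invalid sign '", d$sign[bad[1]], "' in row ", bad[1])
    }
    bad <- which(!d$directed %in% c(0, 1))
    if (length(bad)) {
      stop("invalid directed flag '", d$directed[bad[1]], "' in row ", bad[1])
    }
  }
  if (is.null(id)) {
    id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  }
  nodes <- sort(unique(c(as.character(d$source), as.character(d$target))))
  if (!nrow(d)) return(build_pathway(id, character(), NULL, id_namespace))
  edges <- data.frame(source = as.character(d$source),
                      target = as.character(d$target),
                      directed = d$directed == 1,
                      sign = as.integer(d$sign),
                      subtype = if ("subtype" %in% names(d)) {
                        as.character(d$subtype)
                      } else "",
                      stringsAsFactors = FALSE)
  build_pathway(id, nodes, edges, id_namespace)
}

#' Write a pathway as a signed edge-list TSV
#' @param p A `Pathway`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(p, path) {
  stopifnot(inherits(p, "Pathway"))
  d <- p$edges
  d$directed <- as.integer(d$directed)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read all edge-list pathways in a directory
#' @param dir Directory of `.tsv` edge lists (one pathway per file).
#' @param id_namespace Identifier namespace tag.
#' @return A `PathwayCollection`, files in sorted order.
#' @export
read_pathway_dir <- function(dir, id_namespace = "symbol") {
  files <- sort(list.files(dir, pattern = "\\.(tsv|txt)(\\.gz)?$",
                           full.names = TRUE))
  kgml <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  ps <- c(lapply(files, read_edge_list, id_namespace = id_namespace),
          lapply(kgml, parse_kgml))
  if (!length(ps)) stop("no pathway files found in ", dir)
  pathway_collection(ps)
}

#' Gene expression matrix with a data-kind tag
#'
#' @param values Numeric genes-by-samples matrix with row and column names.
#' @param kind `"counts"` (raw non-negative integers) or `"normalized"`.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, kind = c("counts", "normalized")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample names")
  if (kind == "counts") {
    bad <- which(values < 0 | values != round(values), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("counts must be non-negative integers; offending cell (",
           rownames(values)[bad[1, 1]], ", ", colnames(values)[bad[1, 2]],
           ") = ", values[bad[1, , drop = FALSE]])
    }
  }
  structure(list(values = values, kind = kind), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a gene-by-sample expression TSV
#'
#' First column gene ids, remaining columns numeric sample values.
#'
#' @param path TSV file.
#' @param kind `"counts"` or `"normalized"`.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, kind = c("counts", "normalized")) {
  kind <- match.arg(kind)
  d <- .read_tsv(path)
  if (ncol(d) < 2L) stop("expression table needs gene ids plus >=1 sample")
  genes <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m, kind)
}

#' Write an ExpressionMatrix to TSV
#' @param em An `ExpressionMatrix`.
#' @param path Output file.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  d <- data.frame(gene = rownames(em$values), em$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-level sample group labels
#'
#' @param samples Character vector of sample names.
#' @param groups Per-sample labels with exactly two levels, each present in
#'   at least two samples.
#' @param reference The reference level; defaults to the first label seen.
#' @return A `GroupLabels` object.
#' @export
group_labels <- function(samples, groups, reference = NULL) {
  samples <- as.character(samples); groups <- as.character(groups)
  stopifnot(length(samples) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2L) {
    stop("exactly two group levels required; got: ",
         paste(lev, collapse = ", "))
  }
  if (min(table(groups)) < 2L) stop("each group needs >= 2 samples")
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("unknown reference level: ", reference)
  structure(list(samples = samples, groups = groups, reference = reference),
            class = "GroupLabels")
}

#' Read group labels from a two-column TSV (sample, group)
#' @param path TSV file with columns `sample` and `group`.
#' @param reference Optional reference level.
#' @return A `GroupLabels`.
#' @export
read_groups <- function(path, reference = NULL) {
  d <- .read_tsv(path)
  for (col in c("sample", "group")) {
    if (!col %in% names(d)) stop("groups file is missing column '", col, "'")
  }
  group_labels(d$sample, d$group, reference)
}

#' Write a MethodResultSet as TSV
#'
#' One row per pathway: `name`, `method`, the method's statistic columns,
#' `p`, `p_adjusted`, `status`, in a deterministic column order; round-trips
#' through [read_results()].
#'
#' @param res A `MethodResultSet`.
#' @param path Output file.
#' @export
write_results <- function(res, path) {
  stopifnot(inherits(res, "MethodResultSet"))
  d <- res$records
  first <- c("name", "method")
  last <- c("p", "p_adjusted", "status")
  mid <- setdiff(names(d), c(first, last))
  d <- d[, c(first, mid, last), drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#' @param path TSV file.
#' @return A data.frame of per-pathway records.
#' @export
read_results <- function(path) {
  .read_tsv(path)
}

# Graphviz color for a node given its stats
.dot_node_style <- function(lfc, p, de, threshold) {
  if (is.na(lfc)) {
    return('fillcolor="grey90", color="grey50"')
  }
  fill <- if (isTRUE(de)) {
    if (lfc > 0) "tomato" else "steelblue1"
  } else {
    if (lfc > threshold) "mistyrose" else if (lfc < -threshold) "lightcyan"
    else "grey95"
  }
  border <- if (!is.na(p) && p < 0.05) "black" else "grey60"
  sprintf('fillcolor="%s", color="%s"', fill, border)
}

#' Export a pathway with per-gene statistics as Graphviz DOT
#'
#' Node fill encodes the log fold-change sign and DE status, node border
#' encodes gene-level significance, and edge arrowheads encode the
#' interaction sign (normal +1, tee -1, dashed line sign 0). An edge whose
#' endpoint expression disagrees with its sign -- both endpoints beyond
#' `threshold` in absolute log fold-change but with a fold-change sign
#' product opposite to the edge sign -- is highlighted in orange. Merged
#' nodes (attribute `"members"` from [reduce_graph()]) are rendered with
#' their member list and the aggregated (default mean) fold-change.
#'
#' @param p A `Pathway`, possibly reduced.
#' @param gene_stats Optional data.frame keyed by row name (gene id) with
#'   columns `logFC`, `p` and logical `de`; missing genes render neutral.
#' @param threshold Agreement threshold on |logFC| (default 1).
#' @param aggregate Aggregation for merged-node fold changes (default
#'   [mean()]).
#' @return DOT text (single character string).
#' @export
export_dot <- function(p, gene_stats = NULL, threshold = 1,
                       aggregate = mean) {
  stopifnot(inherits(p, "Pathway"))
  members <- attr(p, "members")
  stat_of <- function(v) {
    if (!is.null(members) && v %in% names(members)) {
      mem <- members[[v]]
      have <- intersect(mem, rownames(gene_stats))
      if (!is.null(gene_stats) && length(have)) {
        return(list(lfc = aggregate(gene_stats[have, "logFC"]),
                    p = suppressWarnings(min(gene_stats[have, "p"])),
                    de = any(gene_stats[have, "de"]),
                    label = sprintf("%s\\n[%s]\\n%.2f", v,
                                    paste(mem, collapse = ","),
                                    aggregate(gene_stats[have, "logFC"]))))
      }
      return(list(lfc = NA_real_, p = NA_real_, de = FALSE,
                  label = sprintf("%s\\n[%s]", v, paste(mem, collapse = ","))))
    }
    if (!is.null(gene_stats) && v %in% rownames(gene_stats)) {
      list(lfc = gene_stats[v, "logFC"], p = gene_stats[v, "p"],
           de = isTRUE(gene_stats[v, "de"]), label = v)
    } else {
      list(lfc = NA_real_, p = NA_real_, de = FALSE, label = v)
    }
  }
  stats_list <- lapply(p$nodes, stat_of)
  names(stats_list) <- p$nodes
  lines <- c("digraph pathway {",
             "  node [style=filled, shape=ellipse];")
  for (v in p$nodes) {
    s <- stats_list[[v]]
    lines <- c(lines, sprintf('  "%s" [label="%s", %s];', v, s$label,
                              .dot_node_style(s$lfc, s$p, s$de, threshold)))
  }
  e <- p$edges
  for (k in seq_len(nrow(e))) {
    s1 <- stats_list[[e$source[k]]]; s2 <- stats_list[[e$target[k]]]
    discordant <- e$sign[k] != 0L && !is.na(s1$lfc) && !is.na(s2$lfc) &&
      abs(s1$lfc) > threshold && abs(s2$lfc) > threshold &&
      sign(s1$lfc) * sign(s2$lfc) != e$sign[k]
    style <- character()
    style <- c(style, if (e$sign[k] > 0) 'arrowhead="normal"'
               else if (e$sign[k] < 0) 'arrowhead="tee"'
               else 'arrowhead="normal", style="dashed"')
    if (!e$directed[k]) style <- c(style, 'dir="none"')
    if (discordant) style <- c(style, 'color="orange", penwidth=2')
    lines <- c(lines, sprintf('  "%s" -> "%s" [%s];', e$source[k],
                              e$target[k], paste(style, collapse = ", ")))
  }
  paste(c(lines, "}"), collapse = "\n")
}
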