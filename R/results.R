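# Uniform method invocation and result container. Every method runs over a
# pathway collection through the same pipeline: counts are normalized and
# log-transformed, differential expression is computed with the moderated-t
# engine, DEGs are selected, and the method is applied per pathway;
# per-pathway failures downgrade to status flags, never abort the run.

.method_names <- c("spia", "prs", "pwea", "tappa", "degraph",
                   "topologygsa", "clipper")

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed, passed
#'   through).
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

.record_row <- function(res, stat_names) {
  row <- list(name = res$name)
  for (s in stat_names) {
    v <- res$stats[[s]]
    row[[s]] <- if (is.null(v)) NA_real_ else as.numeric(v)
  }
  row$p <- if (is.null(res$stats$p)) NA_real_ else as.numeric(res$stats$p)
  row$status <- res$status
  as.data.frame(row, stringsAsFactors = FALSE)
}

.method_stat_names <- function(method) {
  switch(method,
         spia = c("N_pathway_genes", "N_de_on_pathway", "t_A", "p_NDE",
                  "p_PERT"),
         prs = c("raw", "null_mean", "null_sd", "z"),
         pwea = "ES",
         tappa = "U",
         degraph = c("k", "n_components"),
         topologygsa = c("mean_stat", "var_stat", "mean_p", "var_p",
                         "var_p_asymptotic"),
         clipper = c("mean_stat", "var_stat", "mean_p", "var_p"))
}

#' Run a topology-based pathway analysis method over a collection
#'
#' The single entry point for all seven methods. Count data are normalized
#' (TMM by default, median-of-ratios selectable), log-transformed with a
#' prior count and analysed with the moderated-t engine; DEGs are selected
#' at the p-value and |logFC| thresholds; then the chosen method runs on
#' every pathway. Already-normalized data skip the normalization step; a
#' precomputed differential expression table is accepted for the methods
#' that consume only gene-level statistics (SPIA, PRS).
#'
#' @param method One of `"spia"`, `"prs"`, `"pwea"`, `"tappa"`,
#'   `"degraph"`, `"topologygsa"`, `"clipper"`.
#' @param data An `ExpressionMatrix` (kinds `"counts"`/`"normalized"`), a
#'   plain matrix, or a `DifferentialExpressionTable` for
#'   `data_kind = "de-table"`.
#' @param groups A [group_labels()] object (not needed for de-table input).
#' @param pathways A `PathwayCollection`.
#' @param data_kind `"counts"`, `"normalized"` or `"de-table"`.
#' @param norm Normalization for counts: `"tmm"` or `"medianratio"`.
#' @param p_threshold,lfc_threshold DEG selection thresholds (defaults 0.05
#'   and 2).
#' @param nperm Permutations for permutation-based methods (default 1000).
#' @param nboot Bootstrap draws for SPIA (default 2000).
#' @param k DEGraph subspace dimension (`NULL` = heuristic default).
#' @param orient How to orient undirected edges for the directed-topology
#'   methods: `"both"` (default) or `"as-listed"`.
#' @param seed Master seed; all per-pathway and per-permutation streams are
#'   derived from it by stable hashing, so thread counts or pathway order
#'   cannot change results.
#' @param test Driving test for TopologyGSA/clipper: `"mean"` or `"var"`.
#' @param signed Use the signed Laplacian in DEGraph.
#' @param prior Prior count for the log transform (default 0.5).
#' @param d0 Moderated-t prior df override (`NULL` = estimated).
#' @param id_mapping Optional identifier mapping applied to every pathway
#'   via [convert_identifiers()] before analysis.
#' @return A `MethodResultSet`: per-pathway records (ordered by ascending
#'   p, ties by name; skipped pathways kept with a status flag), per-gene
#'   scores, and run metadata.
#' @export
run_method <- function(method, data, groups = NULL, pathways,
                       data_kind = c("counts", "normalized", "de-table"),
                       norm = c("tmm", "medianratio"),
                       p_threshold = 0.05, lfc_threshold = 2,
                       nperm = 1000, nboot = 2000, k = NULL,
                       orient = c("both", "as-listed"),
                       seed = 0L, test = c("mean", "var"), signed = FALSE,
                       prior = 0.5, d0 = NULL, id_mapping = NULL) {
  method <- match.arg(method, .method_names)
  data_kind <- match.arg(data_kind)
  norm <- match.arg(norm)
  orient <- match.arg(orient)
  test <- match.arg(test)
  stopifnot(inherits(pathways, "PathwayCollection"))
  if (length(pathways) == 0L) stop("empty pathway collection")
  if (data_kind == "de-table" && !method %in% c("spia", "prs")) {
    stop("de-table input is only valid for spia and prs; '", method,
         "' needs expression values")
  }
  if (!is.null(id_mapping)) {
    pathways <- pathway_collection(
      lapply(pathways, convert_identifiers, mapping = id_mapping),
      names(pathways))
  }
  em_norm <- NULL
  if (data_kind == "counts") {
    em <- if (inherits(data, "ExpressionMatrix")) data else
      expression_matrix(data, "counts")
    factors <- if (norm == "tmm") tmm_factors(em) else
      median_ratio_factors(em)
    em_norm <- normalize_log(em, factors, prior)
    de <- moderated_t(em_norm, groups, d0)
  } else if (data_kind == "normalized") {
    em_norm <- if (inherits(data, "ExpressionMatrix")) data else
      expression_matrix(data, "normalized")
    de <- moderated_t(em_norm, groups, d0)
  } else {
    de <- data
    if (!all(c("logFC", "p") %in% names(de))) {
      stop("a de-table needs columns logFC and p (rownames = gene ids)")
    }
  }
  deg <- select_deg(de, p_threshold, lfc_threshold)
  all_genes <- rownames(de)
  needs_directed <- method %in% c("spia", "prs")
  perm_stats <- NULL
  if (method == "pwea") {
    perm_stats <- pwea_permutation_stats(em_norm, groups, nperm, seed,
                                         de_engine = function(e, g) {
                                           moderated_t(e, g, d0)
                                         })
  }
  results <- lapply(names(pathways), function(nm) {
    pw <- pathways[[nm]]
    res <- tryCatch({
      if (needs_directed) pw <- orient_undirected(pw, orient)
      out <- switch(method,
        spia = spia(pw, de, deg, all_genes, nboot = nboot, seed = seed),
        prs = prs(pw, de, deg, all_genes, nperm = nperm, seed = seed),
        pwea = pwea(pw, em_norm, groups, nperm = nperm, seed = seed,
                    perm_stats = perm_stats,
                    de_engine = function(e, g) moderated_t(e, g, d0)),
        tappa = tappa(pw, em_norm, groups),
        degraph = degraph(pw, em_norm, groups, k = k, signed = signed),
        topologygsa = topology_gsa(pw, em_norm, groups, test = test,
                                   nperm = nperm, seed = seed,
                                   orient_mode = orient),
        clipper = clipper(pw, em_norm, groups, test = test, nperm = nperm,
                          seed = seed, orient_mode = orient))
      out
    }, error = function(e) {
      list(name = nm, status = paste0("error: ", conditionMessage(e)),
           stats = NULL, scores = NULL)
    })
    res$name <- nm
    res
  })
  stat_names <- .method_stat_names(method)
  records <- do.call(rbind, lapply(results, .record_row,
                                   stat_names = stat_names))
  records$method <- method
  ok <- !is.na(records$p)
  records$p_adjusted <- NA_real_
  records$p_adjusted[ok] <- adjust_bh(records$p[ok])
  ord <- order(is.na(records$p), records$p, records$name)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  scores <- stats::setNames(lapply(results, `[[`, "scores"),
                            vapply(results, `[[`, character(1), "name"))
  extras <- stats::setNames(
    lapply(results, function(r) r[setdiff(names(r),
                                          c("name", "status", "stats",
                                            "scores"))]),
    vapply(results, `[[`, character(1), "name"))
  metadata <- list(method = method, data_kind = data_kind,
                   normalization = if (data_kind == "counts") norm else
                     "none",
                   de_engine = if (data_kind == "de-table") "user" else
                     "moderated_t",
                   p_threshold = p_threshold,
                   lfc_threshold = lfc_threshold, nperm = nperm,
                   nboot = nboot, orient = orient, seed = seed,
                   test = test, signed = signed, prior = prior,
                   committed_formulas = c("prs-score", "pwea-tif",
                                          "tappa-normalization"))
  structure(list(method = method, records = records, scores = scores,
                 details = extras, metadata = metadata),
            class = "MethodResultSet")
}

#' @export
print.MethodResultSet <- function(x, ...) {
  cat(sprintf("MethodResultSet: %s over %d pathway(s)\n", x$method,
              nrow(x$records)))
  print(utils::head(x$records, 10))
  invisible(x)
}

#' Top pathways of a result set
#'
#' @param res A `MethodResultSet`.
#' @param top_n Number of rows (by ascending p, stable ties); values beyond
#'   the result size return everything.
#' @return A data.frame of the top records.
#' @export
summarize <- function(res, top_n = 10) {
  stopifnot(inherits(res, "MethodResultSet"))
  utils::head(res$records, max(0, top_n))
}

#' @export
summary.MethodResultSet <- function(object, top_n = 10, ...) {
  summarize(object, top_n)
}
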