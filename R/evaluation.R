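# Calibration and power evaluation harnesses. These run the methods on
# synthetic data under their respective null hypotheses (exchangeable
# groups for the self-contained methods; differential expression placed
# independently of pathway membership for the competitive methods) and
# under the planted-signal preset, and report empirical rates.

#' Empirical type-I error of a method under its null
#'
#' Self-contained methods (PWEA, TAPPA, DEGraph, TopologyGSA, clipper) are
#' evaluated on fully exchangeable Gaussian data (no effect anywhere), with
#' 300 background genes alongside the pathway genes so the competitive
#' ranking steps see a genome. Competitive methods (SPIA, PRS) test
#' enrichment of a pathway relative to the gene background, so their null
#' keeps genuine differential expression in the data but places it
#' independently of pathway membership: 200 of 1000 genes shift by 3 in
#' group 2, and pathways of 30-50 nodes are drawn at random from the same
#' universe -- large enough that the discrete hypergeometric component of
#' the combined p-value is effectively continuous.
#'
#' Tests within one simulated dataset share the sample draw and are
#' therefore correlated; the default of one pathway per dataset keeps the
#' 200 tests independent, which is what gives the empirical rate its
#' nominal binomial precision.
#'
#' @param method One of the seven method names.
#' @param n_datasets Number of independent simulated datasets.
#' @param pathways_per_dataset Pathways tested per dataset.
#' @param nperm Permutations/bootstraps per test.
#' @param alpha Nominal level (default 0.05).
#' @param seed Master seed.
#' @return A list with `alpha_hat`, `n_tests` and the vector of p-values.
#' @export
null_type1_error <- function(method, n_datasets = 200,
                             pathways_per_dataset = 1, nperm = 200,
                             alpha = 0.05, seed = 1) {
  method <- match.arg(method, .method_names)
  competitive <- method %in% c("spia", "prs")
  ps <- numeric()
  for (rep in seq_len(n_datasets)) {
    universe <- sprintf("G%04d", seq_len(1000))
    size_range <- if (competitive) c(30, 50) else
      if (method %in% c("topologygsa", "clipper")) c(8, 15) else c(20, 40)
    coll <- make_pathway_collection(pathways_per_dataset, size_range,
                                    universe,
                                    seed = .derive_seed(seed, "nullcoll",
                                                        method, rep))
    truth <- simulation_truth(kind = "gaussian", effect = 0,
                              seed = .derive_seed(seed, "nulldata", method,
                                                  rep))
    if (competitive) {
      sim <- simulate_expression(coll, truth,
                                 params = list(background = universe))
      set.seed(.derive_seed(seed, "nullde", method, rep))
      de_genes <- sample(universe, 200)
      x <- sim$em$values
      x[de_genes, sim$groups$groups == "case"] <-
        x[de_genes, sim$groups$groups == "case"] + 3
      em <- expression_matrix(x, "normalized")
      de <- moderated_t(em, sim$groups)
      deg <- select_deg(de)
      for (nm in names(coll)) {
        pw <- orient_undirected(coll[[nm]], "both")
        r <- if (method == "spia") {
          spia(pw, de, deg, rownames(de), nboot = nperm,
               seed = .derive_seed(seed, "run", rep))
        } else {
          prs(pw, de, deg, rownames(de), nperm = nperm,
              seed = .derive_seed(seed, "run", rep))
        }
        if (identical(r$status, "ok")) ps <- c(ps, r$stats$p)
      }
    } else {
      sim <- simulate_expression(coll, truth,
                                 params = list(background = sprintf(
                                   "B%03d", 1:300)))
      run_seed <- .derive_seed(seed, "run", method, rep)
      perm_stats <- if (method == "pwea") {
        pwea_permutation_stats(sim$em, sim$groups, nperm, run_seed)
      } else NULL
      for (nm in names(coll)) {
        r <- switch(method,
          pwea = pwea(coll[[nm]], sim$em, sim$groups, nperm = nperm,
                      seed = run_seed, perm_stats = perm_stats),
          tappa = tappa(coll[[nm]], sim$em, sim$groups),
          degraph = degraph(coll[[nm]], sim$em, sim$groups),
          topologygsa = topology_gsa(coll[[nm]], sim$em, sim$groups,
                                     nperm = nperm, seed = run_seed),
          clipper = clipper(coll[[nm]], sim$em, sim$groups, nperm = nperm,
                            seed = run_seed))
        if (identical(r$status, "ok")) ps <- c(ps, r$stats$p)
      }
    }
  }
  list(alpha_hat = mean(ps <= alpha), n_tests = length(ps), p = ps)
}

#' Planted-pathway recovery rate of the univariable methods
#'
#' Runs the paper-like preset (50 NB-count pathways, one planted with a
#' log2 effect of 2 on 30 percent of its genes, 4 + 4 samples) for a number
#' of replicates and records the rank each univariable method assigns to
#' the planted pathway.
#'
#' @param n_replicates Number of replicate simulations.
#' @param nperm Permutations/bootstraps per run.
#' @param top_n Rank cutoff counted as a recovery (default 5).
#' @param seed Master seed.
#' @return A list with `ranks` (replicates x methods matrix) and
#'   `top_rate` (per-method fraction of replicates with rank <= top_n).
#' @export
planted_recovery <- function(n_replicates = 20, nperm = 200, top_n = 5,
                             seed = 1) {
  methods <- c("spia", "prs", "pwea", "tappa")
  ranks <- matrix(NA_integer_, n_replicates, length(methods),
                  dimnames = list(NULL, methods))
  for (rep in seq_len(n_replicates)) {
    sim <- simulate_preset("paper-like",
                           seed = .derive_seed(seed, "recovery", rep))
    for (m in methods) {
      r <- run_method(m, sim$em, sim$groups, sim$collection, "counts",
                      nperm = nperm, nboot = nperm,
                      seed = .derive_seed(seed, "recovery-run", rep))
      ranks[rep, m] <- which(r$records$name == sim$truth$planted)
    }
  }
  list(ranks = ranks, top_rate = colMeans(ranks <= top_n))
}

#' Clique localization rate of the two-step junction-tree method
#'
#' A five-gene fixture (collider A,B -> C plus chain C -> D -> E, junction
#' tree cliques {A,B,C}, {C,D}, {D,E}) receives a mean shift of 2 on genes
#' A and B, so {A,B,C} is the unique clique carrying signal. Reports how
#' often that clique attains the smallest per-clique p-value and how often
#' it lies on the reported best path.
#'
#' @param n_runs Number of simulated runs.
#' @param nperm Permutations per run.
#' @param effect Mean shift applied to the planted genes.
#' @param seed Master seed.
#' @return A list with `min_p_rate` and `on_path_rate`.
#' @export
clique_localization_rate <- function(n_runs = 50, nperm = 200, effect = 2,
                                     seed = 1) {
  pw <- build_pathway("twoclique", LETTERS[1:5],
                      data.frame(source = c("A", "B", "C", "D"),
                                 target = c("C", "C", "D", "E"), sign = 1))
  hit_min <- 0; hit_path <- 0
  for (rep in seq_len(n_runs)) {
    set.seed(.derive_seed(seed, "clique-loc", rep))
    x <- matrix(stats::rnorm(5 * 8), 5, 8,
                dimnames = list(pw$nodes, sprintf("s%d", 1:8)))
    x[c("A", "B"), 5:8] <- x[c("A", "B"), 5:8] + effect
    gr <- group_labels(colnames(x), rep(c("ctrl", "case"), each = 4))
    r <- clipper(pw, expression_matrix(x, "normalized"), gr,
                 nperm = nperm, seed = .derive_seed(seed, "clique-run",
                                                    rep))
    keys <- vapply(r$cliques, function(cl) paste(sort(cl$clique),
                                                 collapse = "+"),
                   character(1))
    planted <- which(keys == "A+B+C")
    ps <- vapply(r$cliques, function(cl) cl$mean_p, numeric(1))
    if (which.min(ps) == planted) hit_min <- hit_min + 1
    if (planted %in% r$best_path) hit_path <- hit_path + 1
  }
  list(min_p_rate = hit_min / n_runs, on_path_rate = hit_path / n_runs)
}
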