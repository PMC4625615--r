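# RNA-Seq preprocessing: between-sample normalization (TMM or
# median-of-ratios), prior-count log-CPM transformation, and a moderated-t
# differential expression engine with empirical-Bayes variance shrinkage.

#' TMM normalization factors
#'
#' Trimmed mean of M-values. The reference sample is the column whose upper
#' quartile of library-size-scaled counts is closest to the mean upper
#' quartile. For each sample, over genes positive in both sample and
#' reference, M is the log2 ratio of library-scaled proportions and A the
#' average log2 proportion; the top and bottom 30 percent of M and 5 percent
#' of A are trimmed and the factor is two to the power of the weighted mean
#' of the remaining M values, weighted by inverse asymptotic binomial
#' variances. Factors are scaled to have geometric mean one.
#'
#' @param counts An `ExpressionMatrix` of kind `"counts"` or a count matrix
#'   with at least two samples.
#' @param trim_m,trim_a Trim fractions for M and A (defaults 0.3 and 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  x <- .counts_of(counts)
  if (ncol(x) < 2L) stop("TMM needs >= 2 samples")
  lib <- colSums(x)
  f75 <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    obs <- x[, j]; rfc <- x[, ref]
    keep0 <- obs > 0 & rfc > 0
    if (!any(keep0)) {
      stop("sample '", colnames(x)[j],
           "' shares no positive gene with the reference sample")
    }
    o <- obs[keep0]; r <- rfc[keep0]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(M)) < 1e-6) {
      fac[j] <- 1
      next
    }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    w_keep <- 1 / w[keep]
    fac[j] <- 2^(sum(M[keep] * w_keep) / sum(w_keep))
  }
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(x))
}

#' Median-of-ratios size factors
#'
#' For every gene positive in all samples, the ratio of its count to its
#' geometric mean across samples is formed; a sample's size factor is the
#' median of these ratios.
#'
#' @param counts An `ExpressionMatrix` of kind `"counts"` or a count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
median_ratio_factors <- function(counts) {
  x <- .counts_of(counts)
  all_pos <- rowSums(x <= 0) == 0
  if (!any(all_pos)) {
    stop("no gene has positive counts in every sample")
  }
  xp <- x[all_pos, , drop = FALSE]
  loggeo <- rowMeans(log(xp))
  s <- apply(xp, 2, function(col) stats::median(exp(log(col) - loggeo)))
  stats::setNames(s, colnames(x))
}

#' Prior-count log-CPM transformation
#'
#' `log2((count + prior) / (library size * factor) * 1e6)` per cell: a
#' simple variance-tamed log transform that keeps zero counts finite.
#'
#' @param counts An `ExpressionMatrix` of kind `"counts"` or a count matrix.
#' @param factors Per-sample normalization factors; `NULL` computes
#'   [tmm_factors()].
#' @param prior Pseudo-count added before the log (default 0.5).
#' @return An `ExpressionMatrix` of kind `"normalized"`.
#' @export
normalize_log <- function(counts, factors = NULL, prior = 0.5) {
  x <- .counts_of(counts)
  if (is.null(factors)) factors <- tmm_factors(x)
  if (any(factors <= 0)) stop("normalization factors must be positive")
  lib <- colSums(x) * factors
  v <- log2(sweep(x + prior, 2, lib, "/") * 1e6)
  expression_matrix(v, "normalized")
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0).
.trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment-matching fit of the scaled-F prior for gene variances: returns
# prior df d0 and prior variance s02 from observed s2 with df dg.
.fit_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = mean(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' Per-gene two-group comparison on normalized (log-scale) expression.
#' Residual variances are shrunk toward a common prior: the posterior
#' variance is `(d0*s0^2 + dg*sg^2) / (d0 + dg)` where the prior
#' degrees of freedom `d0` and prior variance `s0^2` are fitted by
#' moment-matching the log sample variances against a scaled-F distribution
#' (closed form via trigamma inversion). The t statistic uses the posterior
#' variance with `d0 + dg` degrees of freedom; p-values are two-sided and
#' BH-adjusted. The log fold-change is the non-reference minus the reference
#' group mean.
#'
#' @param em An `ExpressionMatrix` of kind `"normalized"` (or a plain
#'   matrix).
#' @param groups A [group_labels()] object matching the sample columns.
#' @param d0 Override the prior degrees of freedom: `NULL` (default) fits
#'   them; `0` gives the ordinary t-test; `Inf` a pooled-prior z-like test.
#' @return A `DifferentialExpressionTable`: data.frame with row names the
#'   gene ids and columns `gene`, `logFC`, `t`, `p`, `p_adjusted`;
#'   attributes `d0` and `s02` record the fitted prior.
#' @export
moderated_t <- function(em, groups, d0 = NULL) {
  x <- .values_of(em)
  if (inherits(em, "ExpressionMatrix") && em$kind != "normalized") {
    stop("moderated_t() expects normalized expression; see normalize_log()")
  }
  stopifnot(inherits(groups, "GroupLabels"))
  if (!all(groups$samples %in% colnames(x))) {
    stop("group labels name samples absent from the expression matrix")
  }
  x <- x[, groups$samples, drop = FALSE]
  is_ref <- groups$groups == groups$reference
  n1 <- sum(is_ref); n2 <- sum(!is_ref)
  if (min(n1, n2) < 2L) stop("each group needs >= 2 samples")
  m_ref <- rowMeans(x[, is_ref, drop = FALSE])
  m_alt <- rowMeans(x[, !is_ref, drop = FALSE])
  logfc <- m_alt - m_ref
  ss <- rowSums((x[, is_ref, drop = FALSE] - m_ref)^2) +
    rowSums((x[, !is_ref, drop = FALSE] - m_alt)^2)
  dg <- n1 + n2 - 2
  s2 <- ss / dg
  if (is.null(d0)) {
    prior <- .fit_variance_prior(s2, dg)
    d0 <- prior$d0; s02 <- prior$s02
  } else {
    s02 <- if (d0 > 0) .fit_variance_prior(s2, dg)$s02 else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, 0)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = rownames(x), logFC = logfc, t = tstat, p = p,
                    p_adjusted = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- rownames(x)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("DifferentialExpressionTable", "data.frame")
  out
}

#' Select differentially expressed genes
#'
#' Keeps genes with `p < p_threshold` and `|logFC| > lfc_threshold`
#' (defaults 0.05 and 2).
#'
#' @param table A `DifferentialExpressionTable` (or any data.frame with
#'   columns `p` and `logFC`).
#' @param p_threshold,lfc_threshold Selection thresholds (both >= 0).
#' @return The selected rows; `rownames()` give the DEG set and column
#'   `logFC` their log fold-changes.
#' @export
select_deg <- function(table, p_threshold = 0.05, lfc_threshold = 2) {
  stopifnot(p_threshold >= 0, lfc_threshold >= 0)
  if (!nrow(table)) return(table)
  keep <- table$p < p_threshold & abs(table$logFC) > lfc_threshold
  table[keep, , drop = FALSE]
}
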