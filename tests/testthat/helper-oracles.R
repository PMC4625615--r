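# literal step-by-step TMM oracle, written independently of the package
# implementation (follows the published recipe term by term)
tmm_oracle <- function(x) {
  lib <- colSums(x)
  uq <- sapply(seq_len(ncol(x)), function(j) quantile(x[, j] / lib[j], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(x)), function(j) {
    keep <- x[, j] > 0 & x[, ref] > 0
    o <- x[keep, j]; r <- x[keep, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * (log2(o / lib[j]) + log2(r / lib[ref]))
    if (max(abs(M)) < 1e-6) return(1)
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  })
  f / exp(mean(log(f)))
}

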