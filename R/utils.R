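# Deterministic seed derivation: every stochastic step seeds its own RNG
# stream from a stable hash of (master seed, labels...), so adding threads
# or reordering pathways cannot change results.

.derive_seed <- function(seed, ...) {
  tokens <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 17
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 31 + code) %% 2147483629
    }
  }
  as.integer(h)
}

.counts_of <- function(x) {
  if (inherits(x, "ExpressionMatrix")) {
    if (x$kind != "counts") stop("expected an ExpressionMatrix of kind 'counts'")
    x$values
  } else as.matrix(x)
}

.values_of <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
}
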