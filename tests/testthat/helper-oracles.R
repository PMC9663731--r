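# Independent oracles, kept deliberately naive.

# Brute-force anchored ANOVA: the component for a variable subset S at a
# point x is the inclusion-exclusion sum over cuts g(anchor with T -> x_T)
# for all T subseteq S. Enumerates all 2^d subsets.
oracle_subset_component <- function(model, S, x) {
  d <- length(model$columns)
  subsets_of_S <- lapply(0:(2^length(S) - 1), function(m) {
    S[which(bitwAnd(m, 2^(seq_along(S) - 1)) > 0)]
  })
  val <- 0
  for (T in subsets_of_S) {
    z <- rep(0, d)
    z[T] <- x[T]
    cut <- predict_logit(model, matrix(z, 1))
    val <- val + (-1)^(length(S) - length(T)) * cut
  }
  val
}

oracle_all_subsets <- function(d) {
  lapply(0:(2^d - 1), function(m) which(bitwAnd(m, 2^(seq_len(d) - 1)) > 0))
}

# Sum of ALL subset components at x; equals g(x) identically.
oracle_full_reconstruction <- function(model, x) {
  d <- length(model$columns)
  sum(vapply(oracle_all_subsets(d), function(S) {
    oracle_subset_component(model, S, x)
  }, 0))
}

# AUROC by exhaustive pair counting with half-credit for ties.
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}
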