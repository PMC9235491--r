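# Independent oracles: straight-line scalar transcriptions of the formulas,
# deliberately unvectorized and kept separate from the implementation paths
# they check.

# Per-sample contrastive loss, scalar arithmetic only.
oracle_masked_loss <- function(S, donors, tau, mode = "donor_masked") {
  B <- nrow(S)
  li <- numeric(B)
  for (i in seq_len(B)) {
    Bi <- 0
    for (k in seq_len(B)) {
      if (donors[k] == donors[i]) Bi <- Bi + 1
    }
    num <- exp(S[i, i] / tau)
    den <- num
    for (k in seq_len(B)) {
      if (k == i) next
      if (mode == "uniform") {
        den <- den + exp(S[i, k] / tau)
      } else if (donors[k] == donors[i]) {
        den <- den + (B / Bi) * exp(S[i, k] / tau)
      }
    }
    li[i] <- -log(num / den)
  }
  list(total = mean(li), per_sample = li)
}

# ROC AUC by exhaustive pairwise comparison (concordant + half ties).
oracle_auc_paircount <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) tot <- tot + 1
      else if (p == q) tot <- tot + 0.5
    }
  }
  tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by direct pmf summation.
oracle_hyper_upper <- function(k, n_annot, n_universe, n_cluster) {
  p <- 0
  for (j in k:min(n_annot, n_cluster)) {
    p <- p + choose(n_annot, j) * choose(n_universe - n_annot, n_cluster - j) /
      choose(n_universe, n_cluster)
  }
  p
}

# Welch t statistic from the closed form.
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# Soft-label cross-entropy (for finite-difference checks).
oracle_soft_loss <- function(H, A, Y) {
  P <- exp(H %*% A - apply(H %*% A, 1, max))
  P <- P / rowSums(P)
  -sum(Y * log(P))
}

oracle_fd_grad <- function(H, A, Y, eps = 1e-5) {
  G <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      Ap <- A; Ap[i, j] <- Ap[i, j] + eps
      Am <- A; Am[i, j] <- Am[i, j] - eps
      G[i, j] <- (oracle_soft_loss(H, Ap, Y) -
                    oracle_soft_loss(H, Am, Y)) / (2 * eps)
    }
  }
  G
}
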