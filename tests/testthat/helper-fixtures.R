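# Fixtures are built in code; nothing is read from disk.

# Symmetric unit-diagonal similarity with entries in [0,1].
randomSimilarity <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(runif(n * n), n)
    S <- (A + t(A)) / 2
    diag(S) <- 1
    S
  })
}

randomNetwork <- function(n = 12, m = 9, sparsity = 0.7, seed = 1) {
  withr::with_seed(seed, {
    Mrd <- matrix(as.numeric(runif(n * m) > sparsity), n, m)
  })
  HeterogeneousNetwork(
    drugIds = sprintf("r%02d", seq_len(n)),
    diseaseIds = sprintf("d%02d", seq_len(m)),
    Mrr = randomSimilarity(n, seed + 1),
    Mdd = randomSimilarity(m, seed + 2),
    Mrd = Mrd
  )
}

tinyNetwork <- function(Mrd = diag(2), Mrr = diag(nrow(Mrd)),
                        Mdd = diag(ncol(Mrd))) {
  HeterogeneousNetwork(
    drugIds = sprintf("r%d", seq_len(nrow(Mrd))),
    diseaseIds = sprintf("d%d", seq_len(ncol(Mrd))),
    Mrr = Mrr, Mdd = Mdd, Mrd = Mrd
  )
}

# Brute-force Mann-Whitney AUC: concordant pair counting with ties
# counted half. Independent of the rank-based implementation.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# k-nearest-neighbour label propagation baseline: scores a drug-disease
# pair by the similarity-weighted vote of the drug's k most similar
# drugs. Used only to certify that planted synthetic signal is
# learnable by something other than the methods under test.
knnBaselineScores <- function(net, k = 5) {
  Mrr <- drugSim(net)
  Mrd <- assocMatrix(net)
  n <- nrow(Mrd)
  P <- matrix(0, n, ncol(Mrd))
  for (i in seq_len(n)) {
    sims <- Mrr[i, -i]
    nb <- order(sims, decreasing = TRUE)[seq_len(k)]
    idx <- seq_len(n)[-i][nb]
    w <- Mrr[i, idx]
    P[i, ] <- drop(w %*% Mrd[idx, , drop = FALSE]) / sum(w)
  }
  P
}
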