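#' Singular value thresholding
#'
#' Proximal operator of the nuclear norm: computes the SVD, shrinks
#' every singular value by `tau` (truncating at zero) and reconstructs.
#' The result is the unique minimizer of
#' `0.5 * ||Y - X||_F^2 + tau * ||Y||_*`.
#'
#' @param X numeric matrix with finite entries.
#' @param tau shrinkage threshold (>= 0).
#' @return The shrunk matrix (zero matrix when `tau` exceeds the
#'   largest singular value).
#' @export
svtShrink <- function(X, tau) {
  stopifnot(tau >= 0)
  if (any(!is.finite(X))) stop("non-finite input to singular value thresholding")
  if (tau == 0) return(X)
  s <- svd(X)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(X), ncol(X)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' BNNR configuration
#'
#' @param alpha weight of the data-fit term (default 1).
#' @param beta ADMM penalty parameter (default 10).
#' @param tol relative Frobenius change of the iterate below which
#'   iteration stops (default 1e-6).
#' @param maxIter iteration cap (default 500).
#' @return A list of class `bnnrConfig`.
#' @export
bnnrConfig <- function(alpha = 1, beta = 10, tol = 1e-6, maxIter = 500) {
  stopifnot(alpha > 0, beta > 0, tol > 0, maxIter >= 1)
  structure(
    list(alpha = alpha, beta = beta, tol = tol, maxIter = maxIter),
    class = "bnnrConfig"
  )
}

#' Bounded nuclear-norm matrix completion (ADMM)
#'
#' Completes a partially observed matrix by minimizing
#' `||X||_* + alpha/2 * ||P_Omega(X) - P_Omega(M)||^2` subject to
#' `0 <= X <= 1`, where `P_Omega` restricts to the observed entries.
#' The nuclear-norm term favours a low-rank completion; the bound
#' keeps predictions interpretable as association scores; `alpha`
#' controls how much noise in the observed entries the model tolerates.
#'
#' Solved by ADMM on the splitting `X = W`: the `W`-update applies
#' [svtShrink()] with threshold `1/beta`; the `X`-update is the
#' closed-form weighted average of `W - dual` and the data (weight
#' `alpha/(alpha+beta)` on the data over observed entries, plain
#' `W - dual` elsewhere) followed by clipping to [0,1]; then dual
#' ascent. Deterministic: no randomness is involved.
#'
#' @param M the matrix to complete.
#' @param mask logical or 0/1 matrix marking observed entries (at
#'   least one).
#' @param config a [bnnrConfig()].
#' @return A list with `X` (completed matrix, entries in [0,1] exactly),
#'   `iterations`, `residualTrace` (per-iteration relative change) and
#'   `diverged` (TRUE when the relative change increased for 50
#'   consecutive iterations, reported with a warning).
#' @export
bnnrComplete <- function(M, mask = NULL, config = bnnrConfig()) {
  M <- as.matrix(M)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(M), ncol(M))
  mask <- mask != 0
  if (!any(mask)) stop("empty observation mask")
  alpha <- config$alpha
  beta <- config$beta
  X <- M * mask
  Y <- matrix(0, nrow(M), ncol(M))
  trace <- numeric(0)
  rising <- 0L
  diverged <- FALSE
  for (it in seq_len(config$maxIter)) {
    W <- svtShrink(X + Y / beta, 1 / beta)
    Xnew <- W - Y / beta
    Xnew[mask] <- (alpha * M[mask] + beta * Xnew[mask]) / (alpha + beta)
    Xnew[Xnew < 0] <- 0
    Xnew[Xnew > 1] <- 1
    Y <- Y + beta * (Xnew - W)
    ch <- relChange(Xnew, X)
    trace <- c(trace, ch)
    X <- Xnew
    if (it > 1 && ch > trace[it - 1L]) rising <- rising + 1L else rising <- 0L
    if (rising >= 50L) {
      diverged <- TRUE
      warning("BNNR residual increased for 50 consecutive iterations")
      break
    }
    if (ch < config$tol) break
  }
  list(X = X, iterations = length(trace), residualTrace = trace,
       diverged = diverged)
}

#' Predict drug-disease associations by BNNR on the block adjacency
#'
#' Assembles the heterogeneous block adjacency ([buildMCAdjacency()]),
#' completes it with [bnnrComplete()], and returns the completed
#' drug-disease block as the prediction matrix. By default every entry
#' of the block matrix is treated as observed -- similarity blocks and
#' both the 1s and 0s of the association blocks -- so the bound-
#' constrained regression denoises the zeros; with
#' `maskZerosUnknown = TRUE` only the association 1s (and the
#' similarity blocks) are observed.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param config a [bnnrConfig()].
#' @param maskZerosUnknown treat association zeros as unobserved.
#' @return n x m score matrix with entries in [0,1].
#' @export
bnnrPredict <- function(network, config = bnnrConfig(),
                        maskZerosUnknown = FALSE) {
  .assertNetwork(network)
  adj <- buildMCAdjacency(network)
  mask <- matrix(TRUE, nrow(adj$MMC), ncol(adj$MMC))
  if (maskZerosUnknown) {
    di <- adj$blockLayout$drug
    si <- adj$blockLayout$disease
    known <- network@Mrd != 0
    mask[di, si] <- known
    mask[si, di] <- t(known)
  }
  res <- bnnrComplete(adj$MMC, mask, config)
  P <- res$X[adj$blockLayout$drug, adj$blockLayout$disease, drop = FALSE]
  dimnames(P) <- dimnames(network@Mrd)
  P
}

#' Predict drug-disease associations by overlap matrix completion (OMC)
#'
#' Builds the drug-side and disease-side stacked networks
#' ([buildOMCAdjacency()], with KNN imputation so every drug and
#' disease carries at least one association), applies [bnnrComplete()]
#' to each side separately, extracts each side's completed
#' drug-disease block, and returns the element-wise mean of the two.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param config a [bnnrConfig()].
#' @param knnK neighbourhood size for the imputation step.
#' @return n x m score matrix with entries in [0,1].
#' @export
omcPredict <- function(network, config = bnnrConfig(), knnK = 10) {
  .assertNetwork(network)
  adj <- buildOMCAdjacency(network, k = knnK)
  drugFit <- bnnrComplete(adj$drugSide, config = config)
  disFit <- bnnrComplete(adj$diseaseSide, config = config)
  # drug side is (n+m) x n with the association block in the disease rows
  Pdrug <- t(drugFit$X[adj$drugSideAssocRows, , drop = FALSE])
  # disease side is m x (m+n) with the association block in the drug columns
  Pdis <- t(disFit$X[, adj$diseaseSideAssocCols, drop = FALSE])
  P <- (Pdrug + Pdis) / 2
  dimnames(P) <- dimnames(network@Mrd)
  P
}
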