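#' Similarity-weighted adjacency for matrix-factorization methods
#'
#' Computes `M_MF = M_rd o (M_rr %*% M_rd %*% M_dd)` where `o` is the
#' Hadamard (element-wise) product, then normalizes to [0,1] by dividing
#' by the maximum entry. Known associations are re-weighted by how
#' strongly similar drugs connect to similar diseases; pairs without a
#' known association stay exactly 0.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @return A list with `MMF` (n x m matrix in [0,1], support equal to
#'   the support of `M_rd`) and `maxValueUsed` (the normalizing
#'   constant; 0 when the association matrix is all-zero, in which case
#'   no division is performed).
#' @export
buildMFAdjacency <- function(network) {
  .assertNetwork(network)
  Mrd <- network@Mrd
  raw <- Mrd * (network@Mrr %*% Mrd %*% network@Mdd)
  mx <- max(raw)
  if (mx > 0) raw <- raw / mx
  list(MMF = raw, maxValueUsed = mx)
}

#' Block adjacency for matrix-completion methods
#'
#' Assembles the (n+m) x (n+m) block matrix
#' `rbind(cbind(M_rr, M_rd), cbind(t(M_rd), M_dd))`. The similarity
#' blocks are dense; the off-diagonal association blocks carry the
#' unknown entries to be completed.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @return A list with `MMC` (the block matrix) and `blockLayout`, the
#'   row/column index ranges of the drug and disease blocks.
#' @export
buildMCAdjacency <- function(network) {
  .assertNetwork(network)
  n <- nDrugs(network)
  m <- nDiseases(network)
  MMC <- rbind(
    cbind(network@Mrr, network@Mrd),
    cbind(t(network@Mrd), network@Mdd)
  )
  list(
    MMC = MMC,
    blockLayout = list(drug = seq_len(n), disease = n + seq_len(m))
  )
}

#' Impute association profiles of de novo drugs or diseases
#'
#' A drug with an all-zero row (or a disease with an all-zero column) of
#' the association matrix gives a completion method nothing to work
#' with. For each such entity the profile is replaced by the
#' similarity-weighted average of the profiles of its `k` most similar
#' neighbours (neighbours whose own profile is all-zero are excluded),
#' with weights normalized to sum to 1, and the imputed profile rescaled
#' so its maximum is 1 -- imputed pseudo-associations never exceed true
#' ones. Entities that already have at least one association are
#' untouched, so every original 1 is preserved.
#'
#' @param Mrd n x m binary association matrix.
#' @param similarity n x n drug similarity (`side = "drug"`) or m x m
#'   disease similarity (`side = "disease"`).
#' @param side which margin to impute: `"drug"` treats rows,
#'   `"disease"` treats columns.
#' @param k neighbourhood size (>= 1); default 10.
#' @return The imputed matrix, entries in [0,1].
#' @export
knnImputeAssociations <- function(Mrd, similarity, side = c("drug", "disease"),
                                  k = 10) {
  side <- match.arg(side)
  stopifnot(k >= 1)
  M <- if (side == "drug") Mrd else t(Mrd)
  if (nrow(similarity) != nrow(M) || ncol(similarity) != nrow(M)) {
    stop("similarity dimension does not match the chosen side")
  }
  empty <- which(rowSums(M) == 0)
  nonEmpty <- which(rowSums(M) > 0)
  if (length(empty)) {
    if (!length(nonEmpty)) {
      stop("no entity with a nonzero profile exists; imputation impossible")
    }
    for (i in empty) {
      sims <- similarity[i, nonEmpty]
      ord <- nonEmpty[order(sims, decreasing = TRUE)]
      nb <- ord[seq_len(min(k, length(ord)))]
      w <- similarity[i, nb]
      if (sum(w) <= 0) w <- rep(1, length(nb))
      w <- w / sum(w)
      prof <- drop(w %*% M[nb, , drop = FALSE])
      mx <- max(prof)
      if (mx > 0) prof <- prof / mx
      M[i, ] <- prof
    }
  }
  if (side == "drug") M else t(M)
}

#' One-sided stacked adjacency matrices for overlap matrix completion
#'
#' Builds the drug-side and disease-side networks used by OMC. First
#' the association matrix is imputed so no margin is empty: `Mrd1`
#' imputes all-zero disease columns (every disease gets at least one
#' association) and `Mrd2` imputes all-zero drug rows. The drug-side
#' matrix stacks the drug similarity over the transposed `Mrd1`
#' ((n+m) x n, columns indexed by drugs); the disease-side matrix
#' concatenates the disease similarity with the transposed `Mrd2`
#' (m x (m+n), rows indexed by diseases). Completing each side exposes
#' the unknown drug-disease block once.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param k neighbourhood size passed to [knnImputeAssociations()].
#' @return A list with `drugSide`, `diseaseSide`, `Mrd1`, `Mrd2`, and
#'   the index ranges of the association block within each side matrix.
#' @export
buildOMCAdjacency <- function(network, k = 10) {
  .assertNetwork(network)
  n <- nDrugs(network)
  m <- nDiseases(network)
  Mrd1 <- knnImputeAssociations(network@Mrd, network@Mdd, "disease", k)
  Mrd2 <- knnImputeAssociations(network@Mrd, network@Mrr, "drug", k)
  list(
    drugSide = rbind(network@Mrr, t(Mrd1)),
    diseaseSide = cbind(network@Mdd, t(Mrd2)),
    Mrd1 = Mrd1, Mrd2 = Mrd2,
    drugSideAssocRows = n + seq_len(m),
    diseaseSideAssocCols = m + seq_len(n)
  )
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes a disease-disease similarity matrix from a binary
#' symptom-disease profile matrix. With `p_i` the symptom column of
#' disease `i`, the kernel is `K(i, j) = exp(-gamma * ||p_i - p_j||^2)`
#' where the bandwidth `gamma = gammaPrime * m / sum_i ||p_i||^2`
#' normalizes by the mean squared profile norm over the m diseases.
#'
#' @param profile s x m binary symptom-disease matrix (symptoms in
#'   rows, diseases in columns); at least one nonzero column.
#' @param gammaPrime positive bandwidth multiplier, default 1.
#' @return m x m symmetric similarity matrix with unit diagonal and
#'   entries in (0, 1].
#' @export
gipSimilarity <- function(profile, gammaPrime = 1) {
  profile <- as.matrix(profile)
  stopifnot(gammaPrime > 0, ncol(profile) >= 2)
  if (!all(profile %in% c(0, 1))) stop("profile matrix must be binary")
  norms2 <- colSums(profile^2)
  if (sum(norms2) == 0) stop("all-zero profile matrix: GIP bandwidth undefined")
  gamma <- gammaPrime * ncol(profile) / sum(norms2)
  d2 <- outer(norms2, norms2, "+") - 2 * crossprod(profile)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ids <- colnames(profile)
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  K
}
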