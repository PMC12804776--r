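#' Select an NMF rank by cumulative explained variance
#'
#' Computes the singular value decomposition of `V` and the cumulative
#' explained variance curve `CEV_k = sum_{i<=k} sigma_i^2 / sum_i
#' sigma_i^2`. The selected rank is the smallest `k` with `CEV_k >=
#' threshold` (at least 1). A threshold of 0.90 keeps 90% of the total
#' variance.
#'
#' @param V a nonzero numeric matrix.
#' @param threshold CEV threshold in (0, 1]; default 0.90.
#' @return A list with `singularValues`, `cev` (nondecreasing, final
#'   value 1), `threshold` and `selectedRank`.
#' @export
selectRankCEV <- function(V, threshold = 0.90) {
  V <- as.matrix(V)
  stopifnot(threshold > 0, threshold <= 1)
  if (all(V == 0)) stop("all-zero matrix: rank selection undefined")
  sv <- svd(V, nu = 0, nv = 0)$d
  cev <- cumsum(sv^2) / sum(sv^2)
  list(
    singularValues = sv,
    cev = cev,
    threshold = threshold,
    selectedRank = max(1L, min(which(cev >= threshold - 1e-12)))
  )
}

#' Default NMF configuration
#'
#' @param rank positive integer rank, or `"auto"` to select by
#'   [selectRankCEV()] on the input.
#' @param maxIter iteration cap (default 2000).
#' @param tol relative change of the squared reconstruction error below
#'   which iteration stops (default 1e-6).
#' @param epsilon small stabilizer added to update denominators
#'   (default 1e-12).
#' @param cevThreshold threshold used when `rank = "auto"`.
#' @param seed integer seed for the random initialization.
#' @return A list of class `nmfConfig`.
#' @export
nmfConfig <- function(rank = "auto", maxIter = 2000, tol = 1e-6,
                      epsilon = 1e-12, cevThreshold = 0.90, seed = 1) {
  structure(
    list(
      rank = rank, maxIter = maxIter, tol = tol,
      epsilon = epsilon, cevThreshold = cevThreshold, seed = seed
    ),
    class = "nmfConfig"
  )
}

#' Non-negative matrix factorization by Lee-Seung multiplicative updates
#'
#' Factorizes a nonnegative matrix `V` (n x m) as `V ~ W %*% H` with
#' `W` (n x r) and `H` (r x m) nonnegative, minimizing the squared
#' Frobenius reconstruction error `||V - WH||^2` with the classical
#' multiplicative updates
#' `H <- H * (t(W) V) / (t(W) W H + eps)` and
#' `W <- W * (V t(H)) / (W H t(H) + eps)`.
#' The objective is non-increasing across iterations; iteration stops
#' when its relative change drops below `tol` or after `maxIter`
#' updates. Factors are initialized uniform(0,1] scaled by
#' `sqrt(mean(V)/r)` so the initial product matches V's mean; a fixed
#' seed gives identical output.
#'
#' @param V nonnegative matrix, not all-zero, finite entries.
#' @param config an [nmfConfig()] (a numeric `rank` is required here;
#'   use [nmfPredict()] for automatic selection).
#' @return A list with `W`, `H` and `objectiveTrace` (the squared error
#'   after each iteration).
#' @export
nmfFactorize <- function(V, config = nmfConfig(rank = 2)) {
  V <- as.matrix(V)
  if (any(!is.finite(V))) stop("non-finite entries in V")
  if (any(V < 0)) stop("V must be nonnegative")
  if (all(V == 0)) stop("all-zero V cannot be factorized")
  r <- config$rank
  if (identical(r, "auto")) {
    r <- selectRankCEV(V, config$cevThreshold)$selectedRank
  }
  n <- nrow(V); m <- ncol(V)
  stopifnot(r >= 1, r <= min(n, m))
  eps <- config$epsilon
  withSeed(config$seed, {
    scale <- sqrt(mean(V) / r)
    W <- matrix(runif(n * r), n, r) * scale
    H <- matrix(runif(r * m), r, m) * scale
  })
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(config$maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- sum((V - W %*% H)^2)
    obj <- c(obj, cur)
    if (is.finite(prev) && prev > 0 && abs(prev - cur) / prev < config$tol) break
    prev <- cur
  }
  list(W = W, H = H, objectiveTrace = obj)
}

#' Predict drug-disease associations by plain NMF
#'
#' Builds the similarity-weighted adjacency `M_MF` (see
#' [buildMFAdjacency()]), selects the rank by cumulative explained
#' variance when `config$rank = "auto"`, factorizes, and returns the
#' reconstruction `W %*% H` as the prediction score matrix.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param config an [nmfConfig()].
#' @return An n x m nonnegative score matrix with the network's
#'   identifiers as dimnames.
#' @export
nmfPredict <- function(network, config = nmfConfig()) {
  .assertNetwork(network)
  MMF <- buildMFAdjacency(network)$MMF
  cfg <- config
  if (identical(cfg$rank, "auto")) {
    cfg$rank <- selectRankCEV(MMF, cfg$cevThreshold)$selectedRank
  }
  fit <- nmfFactorize(MMF, cfg)
  P <- fit$W %*% fit$H
  dimnames(P) <- dimnames(network@Mrd)
  P
}

#' Permute adjacency values among observed associations
#'
#' Randomly permutes the multiset of adjacency values sitting at the
#' known-association positions (the support of `M_rd`) among those same
#' positions; every zero position is untouched. This preserves which
#' pairs are associated while shuffling how strongly similarity weights
#' them.
#'
#' @param MMF the weighted adjacency matrix.
#' @param positiveMask logical or 0/1 matrix marking known
#'   associations.
#' @param seed integer seed.
#' @return The permuted matrix; with fewer than 2 positives the input
#'   is returned unchanged with attribute `"vacuous" = TRUE` and a
#'   warning.
#' @export
permuteObserved <- function(MMF, positiveMask, seed = 1) {
  idx <- which(positiveMask != 0)
  if (length(idx) < 2) {
    warning("fewer than 2 observed associations: permutation is vacuous")
    attr(MMF, "vacuous") <- TRUE
    return(MMF)
  }
  withSeed(seed, {
    MMF[idx] <- MMF[idx][sample.int(length(idx))]
  })
  MMF
}

#' Permute an adjacency matrix by rows, columns, or both
#'
#' Builds null adjacency matrices by randomly reordering whole rows
#' (`mode = "rows"`), whole columns (`"columns"`), or rows then columns
#' independently (`"both"`). The global multiset of values is preserved
#' exactly; `"rows"` leaves each row's internal order intact.
#'
#' @param MMF the adjacency matrix.
#' @param mode `"rows"`, `"columns"` or `"both"`.
#' @param seed integer seed.
#' @return The permuted matrix.
#' @export
permuteNull <- function(MMF, mode = c("rows", "columns", "both"), seed = 1) {
  mode <- match.arg(mode)
  withSeed(seed, {
    if (mode %in% c("rows", "both")) {
      MMF <- MMF[sample.int(nrow(MMF)), , drop = FALSE]
    }
    if (mode %in% c("columns", "both")) {
      MMF <- MMF[, sample.int(ncol(MMF)), drop = FALSE]
    }
  })
  MMF
}

# One-sided (x > y) Wilcoxon rank-sum z with tie and continuity
# correction; 0 for degenerate (zero-variance) comparisons.
rankSumZ <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  tieTab <- tabulate(match(r, unique(r)))
  s2 <- n1 * n2 / 12 * ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
  if (s2 <= 0) return(0)
  (R1 - mu - 0.5) / sqrt(s2)
}

# Stouffer combination of the three per-pair rank-sum z matrices. The
# three statistics share the observed ensemble, with asymptotic pairwise
# correlation 1/2, so the variance-correct divisor is
# sqrt(3 + 6 * 1/2) = sqrt(6); this keeps the combined score standard
# normal under the null. A monotone rescaling of the plain sum, so
# rankings are unaffected.
stoufferCombine <- function(zR, zC, zB) {
  (zR + zC + zB) / sqrt(6)
}

#' Permutation-null NMF prediction (NMF-PDR)
#'
#' Scores each drug-disease pair by how much larger its NMF predictions
#' on association-preserving permutations of the weighted adjacency are
#' than its predictions on structure-destroying null permutations.
#' The method assumes true associations are driven by chemical and
#' biological relatedness, so NMF reconstruction at a truly associated
#' pair should exceed what random association structure produces.
#'
#' For `K` replicates the observed ensemble `O1` is built by permuting
#' the adjacency values among the known-association positions
#' ([permuteObserved()]) and running NMF on each; three null ensembles
#' `R0`, `C0`, `B0` come from row, column, and row+column permutations
#' ([permuteNull()]). For every pair, one-sided Wilcoxon rank-sum tests
#' (observed greater) of its `K` observed scores against each null
#' ensemble give three z-scores, combined by Stouffer's method with the
#' dependence-corrected divisor (the three tests share the observed
#' sample). The NMF rank is selected once on the unpermuted adjacency
#' and reused across the ensemble.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param K ensemble size (default 100, >= 2).
#' @param config an [nmfConfig()] used inside the ensemble.
#' @param seed master seed; child seeds are drawn per replicate.
#' @return A list with `combinedZ` (the n x m prediction matrix),
#'   `zScores` (list of the three component z matrices) and `K`.
#' @export
nmfpdrPredict <- function(network, K = 100, config = nmfConfig(), seed = 1) {
  .assertNetwork(network)
  stopifnot(K >= 2)
  MMF <- buildMFAdjacency(network)$MMF
  cfg <- config
  if (identical(cfg$rank, "auto")) {
    cfg$rank <- selectRankCEV(MMF, cfg$cevThreshold)$selectedRank
  }
  mask <- network@Mrd
  seeds <- matrix(childSeeds(seed, 8L * K), ncol = 8L)
  n <- nrow(MMF); m <- ncol(MMF)

  runEnsemble <- function(makeInput, seedCol) {
    vals <- array(0, dim = c(n, m, K))
    for (kk in seq_len(K)) {
      Vk <- makeInput(seeds[kk, seedCol])
      c2 <- cfg
      c2$seed <- seeds[kk, seedCol + 4L]
      fit <- nmfFactorize(Vk, c2)
      vals[, , kk] <- fit$W %*% fit$H
    }
    vals
  }

  O1 <- runEnsemble(function(s) permuteObserved(MMF, mask, s), 1L)
  R0 <- runEnsemble(function(s) permuteNull(MMF, "rows", s), 2L)
  C0 <- runEnsemble(function(s) permuteNull(MMF, "columns", s), 3L)
  B0 <- runEnsemble(function(s) permuteNull(MMF, "both", s), 4L)

  zMat <- function(nullVals) {
    z <- matrix(0, n, m)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        z[i, j] <- rankSumZ(O1[i, j, ], nullVals[i, j, ])
      }
    }
    z
  }
  zR <- zMat(R0); zC <- zMat(C0); zB <- zMat(B0)
  combined <- stoufferCombine(zR, zC, zB)
  dimnames(combined) <- dimnames(network@Mrd)
  list(combinedZ = combined, zScores = list(R0 = zR, C0 = zC, B0 = zB), K = K)
}
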