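#' Stratified fold assignment over drug-disease pairs
#'
#' Partitions all n x m pairs into `k` folds, stratified by group: the
#' known associations (the "1" group) and the remaining pairs (the "0"
#' group) are each split independently into k near-equal folds (sizes
#' within each group differ by at most 1), so every fold keeps the
#' global class proportion. Essential on highly sparse association
#' matrices, where unstratified folds can end up with no positives.
#'
#' @param Mrd n x m binary association matrix.
#' @param k fold count (default 10, >= 2).
#' @param seed integer seed; the assignment is reproducible.
#' @return A list with `foldOfPair` (n x m integer matrix, values in
#'   1..k), `k` and `seed`.
#' @export
stratifiedFolds <- function(Mrd, k = 10, seed = 1) {
  stopifnot(k >= 2)
  pos <- which(Mrd == 1)
  neg <- which(Mrd == 0)
  if (length(pos) < k) {
    stop(sprintf("fewer positives (%d) than folds (%d)", length(pos), k))
  }
  if (length(neg) < k) {
    stop(sprintf("fewer negatives (%d) than folds (%d)", length(neg), k))
  }
  fold <- matrix(NA_integer_, nrow(Mrd), ncol(Mrd))
  withSeed(seed, {
    fold[pos] <- sample(rep_len(seq_len(k), length(pos)))
    fold[neg] <- sample(rep_len(seq_len(k), length(neg)))
  })
  list(foldOfPair = fold, k = k, seed = seed)
}

#' Mask a test fold's positives out of the network
#'
#' Returns a copy of the network whose association matrix has the test
#' fold's known associations set to zero. Every adjacency construction
#' downstream of this call sees only training associations -- the CV
#' harness always rebuilds adjacencies from the masked network, never
#' caching them across folds, so no test-set association can leak into
#' training.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param folds a [stratifiedFolds()] assignment.
#' @param testFold the fold index to hold out.
#' @return The masked training network (similarity matrices unchanged).
#' @export
maskForTraining <- function(network, folds, testFold) {
  .assertNetwork(network)
  Mrd <- network@Mrd
  Mrd[folds$foldOfPair == testFold & Mrd == 1] <- 0
  methods::initialize(network, Mrd = Mrd)
}

.predictWith <- function(network, method, methodArgs) {
  switch(method,
    nmf = do.call(nmfPredict, c(list(network), methodArgs)),
    nmfpdr = do.call(nmfpdrPredict, c(list(network), methodArgs))$combinedZ,
    bnnr = do.call(bnnrPredict, c(list(network), methodArgs)),
    omc = do.call(omcPredict, c(list(network), methodArgs)),
    stop("unknown method: ", method)
  )
}

#' Disease-centric ranked association matrix
#'
#' For each disease (column), sorts the predicted scores across all
#' drugs in descending order and reorders the corresponding column of
#' the true association matrix accordingly; a good predictor
#' concentrates the 1s at the top of every column. Tie handling is
#' deterministic: the displayed reordering uses a stable sort by drug
#' index, while `rankOfPair` carries average ranks of the negated
#' scores so that downstream AUC equals the Mann-Whitney statistic
#' under ties.
#'
#' @param P n x m prediction score matrix (finite entries).
#' @param Mrd n x m binary association matrix.
#' @return A list with `Rrd` (each column a permutation of the
#'   corresponding column of `Mrd`), `rankOfPair` (within-disease
#'   average rank, 1 = best score) and `order` (the per-column
#'   permutation used for `Rrd`).
#' @export
rankMatrix <- function(P, Mrd) {
  stopifnot(all(dim(P) == dim(Mrd)))
  if (any(!is.finite(P))) stop("non-finite prediction scores")
  n <- nrow(P); m <- ncol(P)
  Rrd <- matrix(0, n, m)
  rk <- matrix(0, n, m)
  ord <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    o <- order(-P[, j])          # stable: ties by drug index
    Rrd[, j] <- Mrd[o, j]
    ord[, j] <- o
    rk[, j] <- rank(-P[, j])     # average ranks for metrics
  }
  dimnames(Rrd) <- dimnames(Mrd)
  list(Rrd = Rrd, rankOfPair = rk, order = ord)
}

#' AUC and AUPR from a ranked association matrix
#'
#' Implements the pooled disease-centric metrics: every pair's score is
#' the negated within-disease rank, so pairs across diseases compare by
#' rank position, realizing "top-ranked predictions per disease"; AUC
#' and AUPR ([aucScore()], [auprScore()]) are then computed over all
#' pairs pooled. An all-zero or all-one association matrix is an error
#' (metrics undefined), never a silent 0.
#'
#' @param ranked a [rankMatrix()] result.
#' @return A list with `auc` and `aupr`.
#' @export
computeMetrics <- function(ranked) {
  scores <- -as.vector(ranked$rankOfPair)
  # rankOfPair is indexed by original pair position, so labels come from
  # undoing the display permutation of Rrd
  labels <- .labelsFromRanked(ranked)
  list(
    auc = aucScore(scores, labels),
    aupr = auprScore(scores, labels)
  )
}

# Recover the original-position labels from a rankMatrix result: the
# reordered column Rrd[, j] holds Mrd[order, j], so invert the
# permutation used for display.
.labelsFromRanked <- function(ranked) {
  n <- nrow(ranked$Rrd); m <- ncol(ranked$Rrd)
  lab <- matrix(0, n, m)
  for (j in seq_len(m)) {
    lab[ranked$order[, j], j] <- ranked$Rrd[, j]
  }
  as.vector(lab)
}

#' Repeated stratified cross-validation of a prediction method
#'
#' The evaluation protocol for a drug-disease predictor on the full
#' association matrix. Per repeat: draw a stratified fold assignment;
#' for each fold, zero that fold's positives out of the network
#' ([maskForTraining()]), run the method on the masked network (all
#' adjacencies are recomputed from it), and record the predicted scores
#' of every pair in the test fold -- both groups. The per-repeat
#' prediction matrix is assembled from test-fold predictions only, so
#' each pair is scored exactly once per repeat by a model that never
#' saw it; metrics are computed on the disease-centric ranked matrix.
#'
#' @param network a [HeterogeneousNetwork-class].
#' @param method one of `"nmf"`, `"nmfpdr"`, `"bnnr"`, `"omc"`.
#' @param methodArgs named list of extra arguments for the method
#'   (e.g. `list(config = bnnrConfig(alpha = 1))`).
#' @param k fold count (default 10).
#' @param nRepeats CV repetitions (default 25).
#' @param seed master seed; folds and method seeds are re-drawn per
#'   repeat from independent child seeds.
#' @return A list of class `cvReport`: `auc`/`aupr` (medians over
#'   repeats), `aucMean`/`auprMean`, `aucSd`/`auprSd`, `perRepeat`
#'   (data.frame), `predictions` (list of per-repeat score matrices),
#'   `method`, `k`, `nRepeats`.
#' @export
runCV <- function(network, method = c("nmf", "nmfpdr", "bnnr", "omc"),
                  methodArgs = list(), k = 10, nRepeats = 25, seed = 1) {
  method <- match.arg(method)
  .assertNetwork(network)
  seeds <- matrix(childSeeds(seed, 2L * nRepeats), ncol = 2L)
  perRepeat <- data.frame(repeatIdx = seq_len(nRepeats), auc = NA_real_,
                          aupr = NA_real_)
  preds <- vector("list", nRepeats)
  for (rep_ in seq_len(nRepeats)) {
    folds <- stratifiedFolds(network@Mrd, k = k, seed = seeds[rep_, 1L])
    P <- matrix(NA_real_, nDrugs(network), nDiseases(network))
    for (f in seq_len(k)) {
      trainNet <- maskForTraining(network, folds, f)
      args <- .reseedArgs(method, methodArgs, seeds[rep_, 2L] + f)
      Pf <- tryCatch(
        .predictWith(trainNet, method, args),
        error = function(e) {
          stop(sprintf("method %s failed on repeat %d fold %d: %s",
                       method, rep_, f, conditionMessage(e)), call. = FALSE)
        }
      )
      test <- folds$foldOfPair == f
      P[test] <- Pf[test]
    }
    stopifnot(!anyNA(P))
    met <- computeMetrics(rankMatrix(P, network@Mrd))
    perRepeat$auc[rep_] <- met$auc
    perRepeat$aupr[rep_] <- met$aupr
    preds[[rep_]] <- P
  }
  structure(list(
    auc = median(perRepeat$auc), aupr = median(perRepeat$aupr),
    aucMean = mean(perRepeat$auc), auprMean = mean(perRepeat$aupr),
    aucSd = sd(perRepeat$auc), auprSd = sd(perRepeat$aupr),
    perRepeat = perRepeat, predictions = preds,
    method = method, k = k, nRepeats = nRepeats, seed = seed
  ), class = "cvReport")
}

# Give each fold's method call its own seed where the method is
# stochastic; deterministic methods (bnnr, omc) ignore this.
.reseedArgs <- function(method, methodArgs, seed) {
  if (method == "nmf") {
    cfg <- methodArgs$config
    if (is.null(cfg)) cfg <- nmfConfig()
    cfg$seed <- seed
    methodArgs$config <- cfg
  } else if (method == "nmfpdr") {
    methodArgs$seed <- seed
  }
  methodArgs
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf(
    "Cross-validation report: %s, %d folds, %d repeats\n",
    x$method, x$k, x$nRepeats
  ))
  cat(sprintf("  AUC : median %.4f (mean %.4f, sd %.4f)\n",
              x$auc, x$aucMean, x$aucSd))
  cat(sprintf("  AUPR: median %.4f (mean %.4f, sd %.4f)\n",
              x$aupr, x$auprMean, x$auprSd))
  invisible(x)
}

#' Balanced-subsample evaluation (the inflation-prone comparator)
#'
#' Implements the evaluation protocol used by earlier benchmarking
#' studies for contrast: per fold, the test set consists of that fold's
#' positives plus an equal-size random draw from the fold's negatives;
#' metrics are computed over the union of these balanced test sets,
#' using the raw prediction scores. Because almost all negatives are
#' discarded, precision -- and hence AUPR -- is dramatically inflated on
#' sparse association matrices relative to full-matrix evaluation.
#'
#' @param P n x m prediction score matrix.
#' @param Mrd n x m binary association matrix.
#' @param folds a [stratifiedFolds()] assignment.
#' @param seed seed for the negative subsampling.
#' @return A list with `auc`, `aupr`, `strategy = "balanced_subsample"`
#'   and `testIndex` (the pooled pair indices evaluated).
#' @export
balancedSubsampleEval <- function(P, Mrd, folds, seed = 1) {
  stopifnot(all(dim(P) == dim(Mrd)))
  k <- folds$k
  idx <- integer(0)
  subSeeds <- childSeeds(seed, k)
  for (f in seq_len(k)) {
    posF <- which(folds$foldOfPair == f & Mrd == 1)
    negF <- which(folds$foldOfPair == f & Mrd == 0)
    if (length(negF) < length(posF)) {
      stop(sprintf("fold %d has fewer negatives than positives", f))
    }
    negSel <- withSeed(subSeeds[f], sample(negF, length(posF)))
    idx <- c(idx, posF, negSel)
  }
  list(
    auc = aucScore(P[idx], Mrd[idx]),
    aupr = auprScore(P[idx], Mrd[idx]),
    strategy = "balanced_subsample",
    testIndex = idx
  )
}

#' Full-matrix evaluation of a prediction matrix
#'
#' Convenience wrapper: disease-centric rank transform of `P` against
#' `Mrd`, then pooled AUC/AUPR -- the package's standard evaluation on
#' the entire association matrix.
#'
#' @param P n x m prediction score matrix.
#' @param Mrd n x m binary association matrix.
#' @return A list with `auc`, `aupr` and `strategy = "full"`.
#' @export
fullMatrixEval <- function(P, Mrd) {
  met <- computeMetrics(rankMatrix(P, Mrd))
  c(met, list(strategy = "full"))
}
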