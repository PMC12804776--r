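test_that("stratified folds balance both groups to within one pair", {
  # 20 positives, 80 negatives, k = 10: exactly 2 positives and 8
  # negatives per fold
  Mrd <- matrix(c(rep(1, 20), rep(0, 80)), 10, 10)
  f <- stratifiedFolds(Mrd, k = 10, seed = 1)
  expect_true(all(f$foldOfPair %in% 1:10))
  for (fold in 1:10) {
    expect_equal(sum(f$foldOfPair == fold & Mrd == 1), 2)
    expect_equal(sum(f$foldOfPair == fold & Mrd == 0), 8)
  }

  # near-equal sizes when counts do not divide evenly
  net <- randomNetwork(n = 11, m = 9, sparsity = 0.8, seed = 4)
  M2 <- assocMatrix(net)
  f2 <- stratifiedFolds(M2, k = 4, seed = 2)
  posCounts <- vapply(1:4, function(k) sum(f2$foldOfPair == k & M2 == 1), numeric(1))
  negCounts <- vapply(1:4, function(k) sum(f2$foldOfPair == k & M2 == 0), numeric(1))
  expect_lte(diff(range(posCounts)), 1)
  expect_lte(diff(range(negCounts)), 1)
  expect_false(anyNA(f2$foldOfPair))

  expect_identical(stratifiedFolds(M2, 4, seed = 2)$foldOfPair, f2$foldOfPair)
  expect_error(stratifiedFolds(matrix(c(1, rep(0, 8)), 3, 3), k = 3),
               "fewer positives")
})

test_that("masking removes exactly the test fold's positives and nothing else", {
  net <- randomNetwork(n = 10, m = 8, sparsity = 0.7, seed = 6)
  f <- stratifiedFolds(assocMatrix(net), k = 5, seed = 3)
  for (fold in 1:5) {
    masked <- maskForTraining(net, f, fold)
    nZeroed <- sum(assocMatrix(net)) - sum(assocMatrix(masked))
    expect_equal(nZeroed, sum(f$foldOfPair == fold & assocMatrix(net) == 1))
    expect_identical(drugSim(masked), drugSim(net))
    expect_identical(diseaseSim(masked), diseaseSim(net))
    # adjacency built from the masked network is blind to test positives
    MMF <- buildMFAdjacency(masked)$MMF
    testPos <- f$foldOfPair == fold & assocMatrix(net) == 1
    expect_true(all(MMF[testPos] == 0))
  }
})

test_that("ranked matrix reorders each disease column by descending score", {
  # perfect predictor: all 1s rise to the top of every column
  Mrd <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
  perfect <- rankMatrix(Mrd, Mrd)
  for (j in 1:2) {
    col <- perfect$Rrd[, j]
    expect_identical(col, sort(col, decreasing = TRUE))
  }

  # hand-worked 3x2 toy
  P <- matrix(c(.9, .2, .5, .1, .8, .5), 3, 2)
  M <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  rk <- rankMatrix(P, M)
  expect_equal(rk$Rrd[, 1], c(1, 1, 0))   # order r1 (.9), r3 (.5), r2 (.2)
  expect_equal(rk$Rrd[, 2], c(1, 1, 0))   # order r2 (.8), r3 (.5), r1 (.1)
  expect_equal(colSums(rk$Rrd), colSums(M), ignore_attr = TRUE)

  # ties: stable by drug index in the display, average ranks for metrics
  Pt <- matrix(c(.5, .5, .1), 3, 1)
  Mt <- matrix(c(0, 1, 0), 3, 1)
  rkt <- rankMatrix(Pt, Mt)
  expect_equal(rkt$order[, 1], c(1L, 2L, 3L))
  expect_equal(rkt$rankOfPair[, 1], c(1.5, 1.5, 3))

  expect_error(rankMatrix(matrix(c(1, NA), 2, 1), matrix(c(1, 0), 2, 1)),
               "non-finite")
})

test_that("pooled rank metrics agree with the brute-force concordance oracle", {
  expect_equal(computeMetrics(rankMatrix(diag(3), diag(3))),
               list(auc = 1, aupr = 1))

  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(4:10, 1); m <- sample(3:6, 1)
      P <- matrix(runif(n * m), n, m)
      M <- matrix(as.numeric(runif(n * m) > 0.7), n, m)
    })
    if (sum(M) == 0 || sum(M) == length(M)) next
    ranked <- rankMatrix(P, M)
    met <- computeMetrics(ranked)
    scores <- -as.vector(ranked$rankOfPair)
    labels <- as.vector(M)
    expect_equal(met$auc, bruteAUC(scores, labels), tolerance = 1e-12)
    # independent reference implementation
    proc <- suppressMessages(pROC::auc(labels, scores, direction = "<"))
    expect_equal(met$auc, as.numeric(proc), tolerance = 1e-12)
  }

  expect_error(computeMetrics(rankMatrix(matrix(0.3, 2, 2), matrix(0, 2, 2))),
               "positive")
})

test_that("label-independent scores hit the known asymptotics", {
  # 10,000 pairs at prevalence 0.05, averaged over independent draws to
  # tighten the Monte-Carlo estimate of the expectation
  met <- withr::with_seed(123, {
    vapply(1:5, function(i) {
      M <- matrix(as.numeric(runif(10000) < 0.05), 100, 100)
      P <- matrix(runif(10000), 100, 100)
      m <- computeMetrics(rankMatrix(P, M))
      c(auc = m$auc, auprGap = m$aupr - mean(M))
    }, numeric(2))
  })
  expect_true(abs(mean(met["auc", ]) - 0.5) <= 0.02)
  expect_true(abs(mean(met["auprGap", ])) <= 0.01)
})

test_that("cross-validation aggregates each pair exactly once and is stable", {
  net <- generateSyntheticNetwork(nDrugs = 30, nDiseases = 20,
                                  targetSparsity = 0.9, seed = 5)
  cv <- runCV(net, "bnnr", k = 10, nRepeats = 4, seed = 2)
  expect_equal(nrow(cv$perRepeat), 4)
  expect_true(all(vapply(cv$predictions, function(P) !anyNA(P), logical(1))))
  expect_true(all(cv$perRepeat$auc >= 0 & cv$perRepeat$auc <= 1))
  # deterministic method at the protocol's fold count: repeat-to-repeat
  # variation comes only from fold randomness and stays small
  expect_lt(cv$aucSd, 0.02)
  expect_output(print(cv), "Cross-validation report")

  # reproducibility of the full harness
  cv2 <- runCV(net, "bnnr", k = 10, nRepeats = 4, seed = 2)
  expect_identical(cv$perRepeat, cv2$perRepeat)
})

test_that("skipping adjacency recomputation leaks test information", {
  # the honest pipeline recomputes adjacency from the masked network;
  # a corrupted harness that predicts from the unmasked network must
  # score measurably higher
  aupr <- vapply(1:3, function(seed) {
    net <- generateSyntheticNetwork(nDrugs = 30, nDiseases = 20,
                                    targetSparsity = 0.93, seed = seed)
    f <- stratifiedFolds(assocMatrix(net), k = 5, seed = seed)
    honest <- matrix(NA_real_, 30, 20)
    leaky <- matrix(NA_real_, 30, 20)
    Pleak <- nmfPredict(net, nmfConfig(seed = seed))   # never masked
    for (fold in 1:5) {
      masked <- maskForTraining(net, f, fold)
      Pf <- nmfPredict(masked, nmfConfig(seed = seed))
      test <- f$foldOfPair == fold
      honest[test] <- Pf[test]
      leaky[test] <- Pleak[test]
    }
    c(computeMetrics(rankMatrix(honest, assocMatrix(net)))$aupr,
      computeMetrics(rankMatrix(leaky, assocMatrix(net)))$aupr)
  }, numeric(2))
  expect_true(all(aupr[2, ] > aupr[1, ]))
})

test_that("balanced subsampling keeps per-fold class balance and inflates AUPR", {
  net <- generateSyntheticNetwork(nDrugs = 40, nDiseases = 25,
                                  targetSparsity = 0.95, seed = 8)
  M <- assocMatrix(net)
  f <- stratifiedFolds(M, k = 5, seed = 4)
  P <- omcPredict(net, knnK = 5)
  bal <- balancedSubsampleEval(P, M, f, seed = 9)
  for (fold in 1:5) {
    inFold <- bal$testIndex[f$foldOfPair[bal$testIndex] == fold]
    expect_equal(sum(M[inFold] == 1), sum(M[inFold] == 0))
  }
  expect_identical(
    balancedSubsampleEval(P, M, f, seed = 9)$testIndex, bal$testIndex
  )

  # perfect predictor: AUPR 1 under both strategies
  expect_equal(balancedSubsampleEval(M, M, f, seed = 1)$aupr, 1)
  expect_equal(fullMatrixEval(M, M)$aupr, 1)

  # inflation direction on sparse data
  expect_gt(bal$aupr, fullMatrixEval(P, M)$aupr)
})
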