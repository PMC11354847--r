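test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(bacc(1, 1), 1)
  expect_equal(bacc(0, 1), 0.5)
  # published panel row back-solved through the identity
  expect_equal(bacc(0.7920, 0.5742), 0.6831)
  expect_error(bacc(1.2, 0.5), "\\[0, 1\\]")
})

test_that("cleaning drops exactly the zero-variance columns", {
  pos <- cbind(c0 = c(0, 0), k = c(0.3, 0.3), x = c(1, 2))
  neg <- cbind(c0 = c(0, 0), k = c(0.3, 0.3), x = c(0, 0))
  cd <- cleanVariables(cohortData(pos, neg))
  expect_equal(colnames(positiveCohort(cd)), "x")
  allFlat <- cohortData(pos[, 1:2], neg[, 1:2])
  expect_error(cleanVariables(allFlat), "uninformative")
})

test_that("threshold classifiers find the optimal cuts", {
  fit <- fitThresholdClassifier(c(2, 3), c(0, 1), "linear")
  expect_equal(fit$bacc, 1)
  expect_gt(fit$threshold, 1)
  expect_lt(fit$threshold, 2)

  # interleaved classes: quadratic outside-rule separates, linear cannot
  q <- fitThresholdClassifier(c(0, 3), c(1, 2), "quadratic")
  expect_equal(q$bacc, 1)
  expect_equal(q$direction, "outside")
  expect_equal(fitThresholdClassifier(c(0, 3), c(1, 2), "linear")$bacc, 0.75)

  same <- fitThresholdClassifier(c(1, 1, 1), c(1, 1), "linear")
  expect_equal(same$bacc, 0.5)
  expect_error(fitThresholdClassifier(1, c(0, 1)), "at least 2")
})

test_that("threshold fits match the brute-force oracle on small instances", {
  set.seed(5)
  for (rep in 1:120) {
    npos <- sample(2:6, 1)
    nneg <- sample(2:6, 1)
    # discrete values provoke ties between candidate cuts
    pos <- sample(seq(0, 3, by = 0.5), npos, replace = TRUE)
    neg <- sample(seq(0, 3, by = 0.5), nneg, replace = TRUE)
    expect_equal(fitThresholdClassifier(pos, neg, "linear")$bacc,
                 bruteLinearBacc(pos, neg), tolerance = 1e-12)
    expect_equal(fitThresholdClassifier(pos, neg, "quadratic")$bacc,
                 bruteQuadraticBacc(pos, neg), tolerance = 1e-12)
  }
})

test_that("prediction agrees with the fitted rule", {
  fit <- fitThresholdClassifier(c(2, 3), c(0, 1), "linear")
  expect_equal(predictThreshold(fit, c(0, 3)), c(FALSE, TRUE))
  q <- fitThresholdClassifier(c(0, 3), c(1, 2), "quadratic")
  expect_equal(predictThreshold(q, c(0, 1.5, 3)), c(TRUE, FALSE, TRUE))
})

test_that("leave-one-out threshold averages the per-fold cuts", {
  pos <- c(2, 3); neg <- c(0, 1)
  loo <- looThreshold(pos, neg)
  expect_length(loo$thresholds, 4)
  # independent enumeration of the four leave-one-out folds
  folds <- list(list(p = pos[-1], n = neg), list(p = pos[-2], n = neg),
                list(p = pos, n = neg[-1]), list(p = pos, n = neg[-2]))
  oracle <- vapply(folds, function(f) {
    v <- sort(unique(c(f$p, f$n)))
    cuts <- (v[-1] + v[-length(v)]) / 2
    baccs <- vapply(cuts, function(t)
      (mean(f$p > t) + mean(f$n <= t)) / 2, numeric(1))
    min(cuts[baccs >= max(baccs) - 1e-12])   # smallest-threshold tie-break
  }, numeric(1))
  expect_equal(loo$thresholds, oracle)
  expect_equal(loo$threshold, mean(oracle))
  expect_gt(loo$threshold, 1)
  expect_lt(loo$threshold, 2)

  # symmetric data: every fold yields the same cut as the full fit
  sym <- looThreshold(c(10, 10, 10), c(0, 0, 0))
  expect_equal(unique(sym$thresholds), 5)
  expect_equal(sym$threshold,
               fitThresholdClassifier(c(10, 10, 10), c(0, 0, 0))$threshold)
  expect_error(looThreshold(2, 1), "3 samples")
})

test_that("cross-validated p-value is the exact binomial tail", {
  y <- rep(c(TRUE, FALSE), 10)
  expect_equal(cvPValue(y, y), 0.5^20)
  half <- y; half[seq(1, 20, 2)] <- !half[seq(1, 20, 2)]
  expect_equal(cvPValue(y, half),
               pbinom(sum(y == half) - 1, 20, 0.5, lower.tail = FALSE))
  expect_equal(round(pbinom(9, 20, 0.5, lower.tail = FALSE), 3), 0.588)
  # unbalanced classes: chance is the majority prior
  y2 <- rep(c(TRUE, FALSE), c(15, 5))
  expect_equal(cvPValue(y2, rep(TRUE, 20)),
               pbinom(14, 20, 0.75, lower.tail = FALSE))
  expect_error(cvPValue(logical(0), logical(0)), "no predictions")
  # permutation alternative is calibrated on the same data
  pperm <- cvPValue(y, y, method = "permutation", B = 200)
  expect_lt(pperm, 0.05)
})

test_that("cross-validation recovers separable and null structure", {
  set.seed(1)
  pos <- matrix(rnorm(60, 5), 30, dimnames = list(NULL, c("A", "B")))
  neg <- matrix(rnorm(60, -5), 30, dimnames = list(NULL, c("A", "B")))
  cd <- cohortData(pos, neg)
  m <- crossValidateCandidate(cd, "A", "linear_threshold", k = 10, seed = 1)
  expect_equal(m$bacc, 1)
  expect_equal(m$precision, 1)

  # permuted labels: BACC inside the 99% binomial band around 0.5
  set.seed(2)
  permPos <- matrix(rnorm(100), 50, dimnames = list(NULL, c("A", "B")))
  permNeg <- matrix(rnorm(100), 50, dimnames = list(NULL, c("A", "B")))
  mp <- crossValidateCandidate(cohortData(permPos, permNeg), "A",
                               "linear_threshold", k = 10, seed = 3)
  half <- 2.576 * sqrt(0.25 / 100)
  expect_gt(mp$bacc, 0.5 - 3 * half)
  expect_lt(mp$bacc, 0.5 + 3 * half)

  expect_error(crossValidateCandidate(cd, "A", "linear_threshold", k = 40),
               "smaller k")
  expect_error(crossValidateCandidate(cd, "Z", "linear_threshold"), "Z")

  # multivariate kinds run and behave on separable data
  for (kind in c("logistic", "naive_bayes", "small_mlp")) {
    mm <- crossValidateCandidate(cd, c("A", "B"), kind, k = 5, seed = 1)
    expect_gte(mm$bacc, 0.95)
  }
})

test_that("a 2-sigma planted marker reaches its Bayes balanced accuracy", {
  ds <- generateEnsembleDataset(syntheticSpec(nProteins = 3,
                                              nSolutions = 250, seed = 8))
  cd <- cohortData(ds$positive, ds$negative)
  m <- crossValidateCandidate(cd, "MK_SKEL", "linear_threshold", k = 10,
                              seed = 8)
  expect_equal(m$bacc, pnorm(1), tolerance = 0.05)
})

test_that("metric identities hold for every scored candidate", {
  ds <- generateEnsembleDataset(syntheticSpec(nProteins = 8,
                                              nSolutions = 40, seed = 4))
  cd <- cohortData(ds$positive, ds$negative)
  sc <- searchCandidates(cd, sizes = 1:2, k = 5, seed = 2, shortlistK = 4)
  expect_true(all(abs(sc$bacc - (sc$sensitivity + sc$specificity) / 2)
                  < 1e-12))
  expect_true(all(sc$cv_p > 0 & sc$cv_p <= 1))
})

test_that("candidate search enumerates tuples and respects its budget", {
  ds <- generateEnsembleDataset(syntheticSpec(nProteins = 5,
                                              nSolutions = 30, seed = 6))
  cd <- cohortData(ds$positive, ds$negative)
  sc2 <- searchCandidates(cd, sizes = 2, k = 5, seed = 1, exhaustive = TRUE)
  expect_equal(nrow(sc2), combinationCount(5, 2))   # 10 tuples
  expect_false(attr(sc2, "truncated"))

  tr <- searchCandidates(cd, sizes = 2, k = 5, seed = 1, exhaustive = TRUE,
                         maxTuples = 4)
  expect_equal(nrow(tr), 4)
  expect_true(attr(tr, "truncated"))

  # size-1 exhaustive search is invariant to column order
  sc1 <- searchCandidates(cd, sizes = 1, k = 5, seed = 1)
  rev <- cohortData(positiveCohort(cd)[, 5:1], negativeCohort(cd)[, 5:1])
  sc1r <- searchCandidates(rev, sizes = 1, k = 5, seed = 1)
  expect_equal(sc1, sc1r, ignore_attr = TRUE)
})
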