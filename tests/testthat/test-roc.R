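mkTable <- function(X, labels, tag = "train15T") {
  colnames(X) <- featureNames()
  CohortTable(X, data.frame(study_id = sprintf("s%03d", seq_len(nrow(X))),
                            label = labels, cohort_tag = tag,
                            stringsAsFactors = FALSE))
}
randTable <- function(n, seed, tag = "train15T") {
  set.seed(seed)
  mkTable(matrix(rnorm(n * 27, 10, 3), n), rep(c("benign", "malignant"),
                                               length.out = n), tag)
}

test_that("z-normalization centres and scales every feature", {
  tab <- zNormalize(randTable(40, 1))
  X <- featureMatrix(tab)
  expect_lt(max(abs(colMeans(X))), 1e-12)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-12)
  expect_equal(normalizationState(tab)$state, "z")

  # affine changes of the raw table do not change the normalized table
  raw <- randTable(40, 2)
  shifted <- mkTable(featureMatrix(raw) * 3.7 + 11, cohortInfo(raw)$label)
  expect_equal(featureMatrix(zNormalize(shifted)),
               featureMatrix(zNormalize(raw)), tolerance = 1e-12)

  const <- raw
  cm <- featureMatrix(raw); cm[, "adc"] <- 5
  expect_error(zNormalize(mkTable(cm, cohortInfo(raw)$label)), "adc")
})

test_that("best cutoff separates separable classes and degrades gracefully", {
  r <- bestCutoff(pos = c(3, 4), neg = c(1, 2))
  expect_equal(r@sensitivity, 1)
  expect_equal(r@specificity, 1)
  expect_gt(r@cutoff, 2); expect_lt(r@cutoff, 3)
  expect_equal(r@direction, "higher")

  same <- bestCutoff(pos = c(1, 2, 3), neg = c(1, 2, 3))
  expect_equal((same@sensitivity + same@specificity) / 2, 0.5)

  deg <- bestCutoff(pos = rep(2, 4), neg = rep(2, 4))
  expect_true(deg@degenerate)
  expect_equal(deg@sensitivity + deg@specificity, 1)
})

test_that("the scanned best cutoff equals exhaustive enumeration", {
  set.seed(30)
  for (i in 1:100) {
    nPos <- sample(2:6, 1); nNeg <- sample(2:6, 1)
    pos <- round(rnorm(nPos, 1), 1)
    neg <- round(rnorm(nNeg), 1)
    r <- bestCutoff(pos, neg)
    expect_equal((r@sensitivity + r@specificity) / 2, bruteBestCutoff(pos, neg))
  }
})

test_that("empirical AUC equals the Mann-Whitney statistic", {
  set.seed(31)
  for (i in 1:100) {
    pos <- rnorm(sample(3:10, 1), 0.5)
    neg <- rnorm(sample(3:10, 1))
    u <- unname(wilcox.test(pos, neg, exact = FALSE)$statistic)
    expect_equal(empiricalAUC(pos, neg), u / (length(pos) * length(neg)))
  }
})

test_that("binormal AUC matches its closed form and is affine invariant", {
  expect_equal(binormalAUC(c(1, 2, 3), c(1, 2, 3)), 0.5)

  # samples with ML moments exactly (mu1 - mu0 = sigma, sigma0 = sigma1)
  set.seed(32)
  n <- 200
  mkExact <- function(mu) {
    z <- rnorm(n)
    (z - mean(z)) / (sd(z) * sqrt((n - 1) / n)) + mu
  }
  pos <- mkExact(1); neg <- mkExact(0)
  expect_equal(binormalAUC(pos, neg), pnorm(1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(binormalAUC(pos * 5 - 2, neg * 5 - 2),
               binormalAUC(pos, neg), tolerance = 1e-12)
  expect_error(binormalAUC(c(1, 1), c(0, 1)), "variance")
})

test_that("large-sample binormal estimates converge to the closed form", {
  set.seed(33)
  est <- binormalAUC(rnorm(1e5, 1), rnorm(1e5))
  expect_equal(est, pnorm(1 / sqrt(2)), tolerance = 0.005)
})

test_that("the Welch screen behaves at the null and under strong signal", {
  set.seed(36)
  Xn <- matrix(rnorm(40 * 27), 40)
  Xn[21:40, ] <- Xn[1:20, ]   # malignant values identical to benign
  same <- tTestScreen(mkTable(Xn, rep(c("benign", "malignant"), each = 20)),
                      "compactness")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  set.seed(34)
  Xs <- matrix(rnorm(100 * 27), 100)
  lab <- rep(c("benign", "malignant"), each = 50)
  Xs[lab == "malignant", 5] <- Xs[lab == "malignant", 5] + 3
  scr <- tTestScreen(mkTable(Xs, lab), featureNames()[5])
  expect_true(scr$significant)
  expect_lt(scr$p, 1e-6)
})

test_that("the cross-cohort report applies training cutoffs to the test set", {
  set.seed(35)
  mkCoh <- function(n, tag, shift) {
    X <- matrix(rnorm(n * 27), n)
    lab <- rep(c("benign", "malignant"), length.out = n)
    X[lab == "malignant", 27] <- X[lab == "malignant", 27] - shift  # adc lower
    mkTable(X, lab, tag)
  }
  rep <- rocReport(zNormalize(mkCoh(80, "train15T", 2)),
                   zNormalize(mkCoh(40, "test30T", 2)))
  expect_equal(nrow(rep), 27)
  adcRow <- rep[rep$feature == "adc", ]
  expect_equal(adcRow$direction, "lower")
  expect_gt(adcRow$auc_binormal, 0.7)
  expect_true(adcRow$significant)
  # screened-out features carry no t-test
  weak <- rep[!is.na(rep$auc_binormal) & rep$auc_binormal <= 0.5, ]
  if (nrow(weak)) expect_true(all(is.na(weak$p)))
})
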