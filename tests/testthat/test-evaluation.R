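mkCohort <- function(n, tag, d = 3, seed = 1, allFeatures = FALSE) {
  set.seed(seed)
  lab <- rep(c("benign", "malignant"), length.out = n)
  X <- matrix(rnorm(n * 27), n, dimnames = list(NULL, featureNames()))
  if (allFeatures) {
    X[lab == "malignant", ] <- X[lab == "malignant", ] + d
  } else {
  X[lab == "malignant", "adc"] <- X[lab == "malignant", "adc"] - d
  X[lab == "malignant", "ser"] <- X[lab == "malignant", "ser"] + d
  X[lab == "malignant", "area"] <- X[lab == "malignant", "area"] + d
  }
  CohortTable(X, data.frame(study_id = sprintf("%s%03d", tag, seq_len(n)),
                            label = lab, cohort_tag = tag,
                            stringsAsFactors = FALSE))
}

test_that("subset names resolve to the canonical columns", {
  expect_length(resolveSubset("morphology"), 11)
  expect_length(resolveSubset("texture"), 13)
  expect_equal(resolveSubset("kinetic"), c("epe", "ser"))
  expect_equal(resolveSubset("adc+ser"), c("adc", "ser"))
  expect_length(resolveSubset("entire"), 27)
  expect_equal(resolveSubset("selected5"),
               c("adc", "sum_average", "entropy", "elongation", "sum_variance"))
  expect_length(resolveSubset("morphology+texture+kinetic"), 26)
  expect_error(resolveSubset("morphology+nonsense"), "unknown")
})

test_that("every classifier nails a clearly separable pair of cohorts", {
  tr <- zNormalize(mkCohort(60, "train15T", d = 6, seed = 41, allFeatures = TRUE))
  te <- zNormalize(mkCohort(30, "test30T", d = 6, seed = 42, allFeatures = TRUE))
  for (cl in c("svm", "knn", "random_forest")) {
    r <- trainAndTest(tr, te, "entire", cl, seed = 7)
    expect_equal(r$sensitivity, 1)
    expect_equal(r$specificity, 1)
    expect_gte(r$auc, 0.999)
  }
})

test_that("reported metrics equal the metrics recomputed from the confusion counts", {
  tr <- zNormalize(mkCohort(60, "train15T", d = 1, seed = 43))
  te <- zNormalize(mkCohort(40, "test30T", d = 1, seed = 44))
  for (cl in c("svm", "knn", "random_forest")) {
    r <- trainAndTest(tr, te, "entire", cl, seed = 7)
    expect_equal(r$sensitivity, r$tp / (r$tp + r$fn))
    expect_equal(r$specificity, r$tn / (r$tn + r$fp))
    expect_equal(r$accuracy, (r$tp + r$tn) / (r$tp + r$tn + r$fp + r$fn))
  }
})

test_that("permuted training labels give chance-level test AUC", {
  set.seed(45)
  aucs <- replicate(20, {
    tr <- mkCohort(60, "train15T", d = 2, seed = sample.int(1e6, 1))
    info <- cohortInfo(tr)
    info$label <- sample(info$label)
    trPerm <- zNormalize(CohortTable(featureMatrix(tr), info))
    te <- zNormalize(mkCohort(40, "test30T", d = 2, seed = sample.int(1e6, 1)))
    trainAndTest(trPerm, te, "entire", "svm", seed = 7)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("the fitted model never sees the test cohort", {
  tr <- zNormalize(mkCohort(60, "train15T", d = 2, seed = 46))
  te <- zNormalize(mkCohort(30, "test30T", d = 2, seed = 47))
  full <- trainAndTest(tr, te, "entire", "svm", seed = 7)
  dropped <- CohortTable(featureMatrix(te)[-1, ], cohortInfo(te)[-1, ])
  dropped@normalization <- te@normalization  # same table minus one row
  part <- trainAndTest(tr, dropped, "entire", "svm", seed = 7)
  shared <- names(attr(part, "scores"))
  expect_equal(attr(part, "scores")[shared], attr(full, "scores")[shared])
})

test_that("single-class training and raw tables are rejected", {
  tr <- mkCohort(20, "train15T")
  te <- zNormalize(mkCohort(20, "test30T"))
  expect_error(trainAndTest(tr, te, "entire", "svm"), "z-normalized")
  info <- cohortInfo(tr); info$label <- "malignant"
  oneClass <- zNormalize(CohortTable(featureMatrix(tr), info))
  expect_error(trainAndTest(oneClass, te, "entire", "svm"), "single class")
})

test_that("the scenario grid has 24 scenario rows plus 8 averages", {
  tr <- zNormalize(mkCohort(40, "train15T", d = 2, seed = 48))
  te <- zNormalize(mkCohort(20, "test30T", d = 2, seed = 49))
  rep <- runAllScenarios(tr, te, seed = 7)
  expect_equal(nrow(rep), 32)
  expect_equal(sum(rep$classifier == "average"), 8)
  avg <- rep[rep$classifier == "average" & rep$subset == "entire", ]
  single <- rep[rep$classifier != "average" & rep$subset == "entire", ]
  expect_equal(avg$auc, mean(single$auc))
  expect_equal(avg$accuracy, mean(single$accuracy))
})
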