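# Cross-cohort classification scenarios: train on one protocol's cohort,
# test on the other's, over the fixed feature-subset vocabulary and the
# three classifier back-ends.

.subsetVocabulary <- c("morphology", "morphology+texture", "adc+ser",
                       "morphology+kinetic", "morphology+adc",
                       "morphology+texture+kinetic", "entire", "selected5")
.classifiers <- c("svm", "knn", "random_forest")

#' Resolve a feature-subset name to column names
#'
#' Vocabulary: group names (`morphology`, `texture`, `kinetic`, `adc`,
#' `ser`) combined with `+`, plus `entire` (all 27 features) and `selected5`
#' (the compact diagnostic subset: adc, sum_average, entropy, elongation,
#' sum_variance).
#'
#' @param name subset name.
#' @return character vector of feature columns.
#' @examples
#' resolveSubset("adc+ser")
#' length(resolveSubset("entire"))
#' @export
resolveSubset <- function(name) {
  if (name == "entire") return(featureNames())
  if (name == "selected5") return(.selected5)
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  cols <- unlist(lapply(parts, function(p) {
    switch(p,
           morphology = featureNames("morphology"),
           texture    = featureNames("texture"),
           kinetic    = featureNames("kinetic"),
           adc        = "adc",
           ser        = "ser",
           stop("unknown feature subset component: '", p, "'"))
  }))
  unique(cols)
}

# Fit one classifier and return continuous malignant scores + hard labels
# for the test matrix. Malignant is the positive class throughout.
.fitAndScore <- function(Xtr, ytr, Xte, classifier, seed) {
  ytr <- factor(ytr, levels = .lesionLabels)
  switch(classifier,
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
      pr <- predict(fit, Xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sgn <- if (grepl("^malignant", colnames(dv)[1])) 1 else -1
      list(score = sgn * dv[, 1], label = as.character(pr))
    },
    knn = {
      pr <- withSeed(seed, class::knn(Xtr, Xte, ytr, k = 5, prob = TRUE))
      pwin <- attr(pr, "prob")
      score <- ifelse(pr == "malignant", pwin, 1 - pwin)
      list(score = score, label = as.character(pr))
    },
    random_forest = {
      fit <- withSeed(seed, randomForest::randomForest(Xtr, ytr, ntree = 500))
      prob <- predict(fit, Xte, type = "prob")[, "malignant"]
      list(score = prob, label = ifelse(prob > 0.5, "malignant", "benign"))
    },
    stop("unknown classifier: ", classifier))
}

#' Train on one cohort, test on the other
#'
#' Fits the classifier on the training cohort only (both cohorts must be
#' independently z-normalized), scores the test cohort, and reports
#' sensitivity (malignant recall), specificity (benign recall), accuracy and
#' the empirical AUC of the continuous classifier score.
#'
#' @param train,test z-normalized [CohortTable-class] objects.
#' @param subset subset name (see [resolveSubset()]) or a character vector of
#'   feature columns.
#' @param classifier `"svm"` (linear kernel, C = 1), `"knn"` (k = 5) or
#'   `"random_forest"` (500 trees).
#' @param seed integer seed controlling classifier randomness.
#' @return one-row data.frame: subset, classifier, specificity, sensitivity,
#'   accuracy, auc, and the confusion counts tp/fn/tn/fp.
#' @export
trainAndTest <- function(train, test, subset, classifier = .classifiers,
                         seed = 1L) {
  classifier <- match.arg(classifier)
  if (train@normalization$state != "z" || test@normalization$state != "z")
    stop("both cohorts must be z-normalized (see zNormalize)")
  cols <- if (length(subset) == 1 && subset %in% c(.subsetVocabulary,
                                                   "texture", "kinetic", "adc"))
    resolveSubset(subset) else as.character(subset)
  ytr <- as.character(lesionLabels(train))
  if (length(unique(ytr)) < 2) stop("training cohort has a single class")
  yte <- as.character(lesionLabels(test))
  res <- .fitAndScore(train@features[, cols, drop = FALSE], ytr,
                      test@features[, cols, drop = FALSE], classifier, seed)
  tp <- sum(res$label == "malignant" & yte == "malignant")
  fn <- sum(res$label == "benign" & yte == "malignant")
  tn <- sum(res$label == "benign" & yte == "benign")
  fp <- sum(res$label == "malignant" & yte == "benign")
  out <- data.frame(subset = if (length(subset) == 1) subset else paste(cols, collapse = "+"),
                    classifier = classifier,
                    specificity = tn / (tn + fp), sensitivity = tp / (tp + fn),
                    accuracy = (tp + tn) / length(yte),
                    auc = empiricalAUC(res$score[yte == "malignant"],
                                       res$score[yte == "benign"]),
                    tp = tp, fn = fn, tn = tn, fp = fp,
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- setNames(as.numeric(res$score), cohortInfo(test)$study_id)
  out
}

#' Run every scenario: all subsets x all classifiers
#'
#' Evaluates the eight feature subsets with the three classifiers
#' (24 scenario rows) and appends one per-subset row averaging the metrics
#' across classifiers (`classifier = "average"`).
#'
#' @param train,test z-normalized [CohortTable-class] objects.
#' @param seed integer seed for the classifier back-ends.
#' @param subsets subset names; default the full vocabulary.
#' @return data.frame with 24 + 8 rows (metrics stored as proportions).
#' @export
runAllScenarios <- function(train, test, seed = 1L,
                            subsets = .subsetVocabulary) {
  rows <- list()
  for (s in subsets) for (cl in .classifiers)
    rows[[paste(s, cl)]] <- trainAndTest(train, test, s, cl, seed = seed)
  rep <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(subsets, function(s) {
    sub <- rep[rep$subset == s, ]
    data.frame(subset = s, classifier = "average",
               specificity = mean(sub$specificity),
               sensitivity = mean(sub$sensitivity),
               accuracy = mean(sub$accuracy), auc = mean(sub$auc),
               tp = NA, fn = NA, tn = NA, fp = NA, stringsAsFactors = FALSE)
  }))
  out <- rbind(rep, avg)
  rownames(out) <- NULL
  out
}
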