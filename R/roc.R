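# Per-feature diagnostics: z-normalization, best-cutoff operating points,
# empirical and maximum-likelihood binormal AUC, and the t-test screen.

#' Z-normalize a cohort table
#'
#' Transforms every feature column to mean 0, SD 1 *within the cohort* and
#' stores the centring parameters. Each cohort is normalized independently,
#' which removes cohort-level intensity-scale bias (e.g. from different field
#' strengths) before cross-cohort comparison.
#'
#' @param cohort a [CohortTable-class].
#' @return the normalized [CohortTable-class].
#' @export
zNormalize <- function(cohort) {
  X <- cohort@features
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  bad <- scl <= .Machine$double.eps * (abs(ctr) + 1)
  if (any(bad))
    stop("zero-variance feature(s): ", paste(names(scl)[bad], collapse = ", "))
  Xn <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  new("CohortTable", features = Xn, info = cohort@info,
      normalization = list(state = "z", center = ctr, scale = scl))
}

#' Empirical (Mann-Whitney) AUC
#'
#' Probability that a positive score exceeds a negative one, ties counting
#' one half.
#'
#' @param pos,neg numeric score vectors for the positive (malignant) and
#'   negative (benign) class.
#' @return AUC in \[0, 1\].
#' @export
empiricalAUC <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Maximum-likelihood binormal AUC
#'
#' Fits `N(mu1, sigma1^2)` and `N(mu0, sigma0^2)` to the two score samples by
#' maximum likelihood (sample moments with 1/n variance) and returns the
#' binormal area `Phi(a / sqrt(1 + b^2))` with `a = (mu1 - mu0)/sigma1`,
#' `b = sigma0/sigma1`.
#'
#' @param pos,neg score vectors with at least 2 values each.
#' @return AUC in \[0, 1\].
#' @examples
#' binormalAUC(rnorm(1e4, 1), rnorm(1e4))  # ~ pnorm(1/sqrt(2)) = 0.760
#' @export
binormalAUC <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 scores per class")
  s1 <- sd(pos) * sqrt((length(pos) - 1) / length(pos))
  s0 <- sd(neg) * sqrt((length(neg) - 1) / length(neg))
  if (s1 <= 0 || s0 <= 0) stop("zero variance in one class")
  a <- (mean(pos) - mean(neg)) / s1
  b <- s0 / s1
  pnorm(a / sqrt(1 + b^2))
}

# Sensitivity/specificity/accuracy of a cutoff applied to two score sets.
applyCutoff <- function(cutoff, direction, pos, neg) {
  callPos <- function(s) if (direction == "higher") s > cutoff else s < cutoff
  tp <- sum(callPos(pos)); fn <- length(pos) - tp
  tn <- sum(!callPos(neg)); fp <- length(neg) - tn
  list(sensitivity = tp / length(pos), specificity = tn / length(neg),
       accuracy = (tp + tn) / (length(pos) + length(neg)),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Best cutoff by the highest mean of sensitivity and specificity
#'
#' Scans every midpoint between adjacent sorted unique scores (plus points
#' outside the range), in both polarities, and picks the cutoff maximising
#' `(sensitivity + specificity) / 2`. Ties are broken toward higher
#' specificity, then toward the lower cutoff, with the `"higher"`-is-malignant
#' polarity preferred on exact ties.
#'
#' @param pos,neg non-empty score vectors (malignant / benign).
#' @return an [ROCResult-class]; `degenerate` is TRUE when all scores are
#'   identical (best achievable sensitivity + specificity = 1).
#' @export
bestCutoff <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both classes must be non-empty")
  u <- sort(unique(c(pos, neg)))
  cuts <- if (length(u) > 1) c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
          else c(u - 1, u + 1)
  best <- NULL
  for (direction in c("higher", "lower")) {
    for (ct in cuts) {
      m <- applyCutoff(ct, direction, pos, neg)
      cand <- list(cutoff = ct, direction = direction, m = m,
                   score = (m$sensitivity + m$specificity) / 2)
      if (is.null(best) ||
          cand$score > best$score + 1e-12 ||
          (abs(cand$score - best$score) <= 1e-12 &&
           (cand$m$specificity > best$m$specificity + 1e-12 ||
            (abs(cand$m$specificity - best$m$specificity) <= 1e-12 &&
             cand$cutoff < best$cutoff - 1e-12))))
        best <- cand
    }
  }
  degenerate <- length(u) == 1L
  aucE <- empiricalAUC(pos, neg)
  if (best$direction == "lower") aucE <- 1 - aucE
  aucB <- tryCatch({
    ab <- binormalAUC(pos, neg)
    if (best$direction == "lower") 1 - ab else ab
  }, error = function(e) NA_real_)
  new("ROCResult", cutoff = best$cutoff, direction = best$direction,
      sensitivity = best$m$sensitivity, specificity = best$m$specificity,
      accuracy = best$m$accuracy, aucBinormal = aucB, aucEmpirical = aucE,
      nPos = length(pos), nNeg = length(neg), degenerate = degenerate)
}

#' Welch t-test screen for one feature
#'
#' Independent-samples (Welch) t-test of malignant versus benign values of
#' one feature; significance at `p < alpha`.
#'
#' @param cohort a [CohortTable-class].
#' @param feature feature name.
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p`, `significant`.
#' @export
tTestScreen <- function(cohort, feature, alpha = 0.05) {
  if (!feature %in% colnames(cohort@features)) stop("unknown feature: ", feature)
  y <- lesionLabels(cohort)
  x <- cohort@features[, feature]
  if (min(table(y)) < 2) stop("each class needs at least 2 samples")
  tt <- t.test(x[y == "malignant"], x[y == "benign"])
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Per-feature diagnostic report across cohorts
#'
#' For every feature: the best cutoff (and polarity) estimated on the
#' z-normalized training cohort, applied unchanged to the independently
#' z-normalized test cohort; binormal and empirical AUC on the test cohort;
#' and, for features with test AUC above 0.5, the Welch t-test screen.
#'
#' @param train,test z-normalized [CohortTable-class] objects.
#' @param alpha t-test significance level.
#' @return data.frame with one row per feature.
#' @export
rocReport <- function(train, test, alpha = 0.05) {
  stopifnot(train@normalization$state == "z", test@normalization$state == "z")
  ytr <- lesionLabels(train); yte <- lesionLabels(test)
  rows <- lapply(featureNames(), function(f) {
    xtr <- train@features[, f]; xte <- test@features[, f]
    rc <- bestCutoff(xtr[ytr == "malignant"], xtr[ytr == "benign"])
    m <- applyCutoff(rc@cutoff, rc@direction,
                     xte[yte == "malignant"], xte[yte == "benign"])
    aucB <- tryCatch({
      ab <- binormalAUC(xte[yte == "malignant"], xte[yte == "benign"])
      if (rc@direction == "lower") 1 - ab else ab
    }, error = function(e) NA_real_)
    screened <- !is.na(aucB) && aucB > 0.5
    tt <- if (screened) tTestScreen(test, f, alpha) else list(t = NA_real_, p = NA_real_, significant = NA)
    data.frame(feature = f, cutoff = rc@cutoff, direction = rc@direction,
               specificity = m$specificity, sensitivity = m$sensitivity,
               accuracy = m$accuracy, auc_binormal = aucB,
               auc_empirical = {
                 ae <- empiricalAUC(xte[yte == "malignant"], xte[yte == "benign"])
                 if (rc@direction == "lower") 1 - ae else ae
               },
               t = tt$t, p = tt$p, significant = tt$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
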