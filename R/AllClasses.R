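# Central S4 data objects and the canonical feature vocabulary.

.morphNames <- c("compactness", "spiculation", "extent", "elongation",
                 "solidity", "circularity", "radial_length_entropy",
                 "fractal_dimension", "heterogeneity", "area", "eccentricity")
.textureNames <- c("asm", "inertia", "correlation", "inverse_difference_moment",
                   "sum_average", "sum_variance", "sum_entropy", "entropy",
                   "difference_average", "difference_variance",
                   "difference_entropy", "info_correlation_1",
                   "info_correlation_2")
.kineticNames <- c("epe", "ser")
.dwiNames <- "adc"
.selected5 <- c("adc", "sum_average", "entropy", "elongation", "sum_variance")

#' Canonical lesion feature names
#'
#' The pipeline characterizes every lesion with 27 named features in four
#' groups: 11 morphological descriptors of the segmented mask, 13 Haralick
#' texture statistics of its gray-level co-occurrence matrix ("inertia" is the
#' co-occurrence contrast), two enhancement-kinetic indices (early-phase
#' enhancement and signal enhancement ratio) and the mean apparent diffusion
#' coefficient of the high-signal lesion core.
#'
#' @param group one of `"all"`, `"morphology"`, `"texture"`, `"kinetic"`,
#'   `"dwi"`.
#' @return character vector of feature (CSV column) names.
#' @examples
#' length(featureNames())       # 27
#' featureNames("kinetic")      # epe, ser
#' @export
featureNames <- function(group = c("all", "morphology", "texture",
                                   "kinetic", "dwi")) {
  group <- match.arg(group)
  switch(group,
         all        = c(.morphNames, .textureNames, .kineticNames, .dwiNames),
         morphology = .morphNames,
         texture    = .textureNames,
         kinetic    = .kineticNames,
         dwi        = .dwiNames)
}

.cohortTags <- c("train15T", "test30T")
.lesionLabels <- c("benign", "malignant")

## ---------------------------------------------------------------------------
## PhantomSpec

#' @title PhantomSpec: parameters of a synthetic two-protocol cohort
#'
#' @description Holds every class-conditional distribution the phantom
#' generator draws from (lesion radius, boundary irregularity, intra-lesion
#' texture, enhancement kinetics, ADC) together with the cohort-level
#' field-strength effects (global gain, additive noise SD) that emulate the
#' change of imaging protocol. See [defaultPhantomSpec()].
#'
#' @slot nBenign,nMalignant lesion counts per class.
#' @slot imageShape integer 2-vector, pixel grid.
#' @slot pixelSpacing mm per pixel.
#' @slot nPostcontrast number of post-contrast DCE frames.
#' @slot cohortTag `"train15T"` or `"test30T"`.
#' @slot seed integer RNG seed; all randomness flows from it.
#' @slot classParams list with `$benign` and `$malignant` parameter lists.
#' @slot fieldEffects list: `gain`, `noiseSD`.
#' @export
setClass("PhantomSpec",
         representation(nBenign = "integer", nMalignant = "integer",
                        imageShape = "integer", pixelSpacing = "numeric",
                        nPostcontrast = "integer", cohortTag = "character",
                        seed = "integer", classParams = "list",
                        fieldEffects = "list"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@nBenign < 1L || object@nMalignant < 1L)
    msg <- c(msg, "need at least one lesion per class")
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    msg <- c(msg, "imageShape must be two dimensions of at least 16 pixels")
  if (!(object@cohortTag %in% .cohortTags))
    msg <- c(msg, sprintf("unknown cohort tag '%s'", object@cohortTag))
  if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be positive")
  rmax <- min(object@imageShape) * object@pixelSpacing / 2
  for (cls in .lesionLabels) {
    p <- object@classParams[[cls]]
    if (is.null(p)) { msg <- c(msg, paste("missing classParams for", cls)); next }
    sds <- c(p$radiusSdMm, p$epeSd, p$serSd, p$adcBetweenSd, p$adcWithinSd)
    if (any(sds <= 0)) msg <- c(msg, paste(cls, ": all SDs must be > 0"))
    if (p$adcMean <= 0) msg <- c(msg, paste(cls, ": ADC mean must be > 0"))
    if (p$radiusMeanMm <= 0 || p$radiusMeanMm >= rmax)
      msg <- c(msg, paste(cls, ": radius mean outside (0, grid half-width)"))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## LesionStudy

#' @title LesionStudy: one subject's imaging data
#'
#' @description A single-slice phantom (or real) study: the DCE time series
#' (one pre-contrast plus `n` post-contrast frames), the two-b-value DWI pair,
#' the ground-truth lesion mask, class label and cohort tag.
#'
#' @slot dce numeric array `h x w x (1 + nPostcontrast)`; frame 1 is
#'   pre-contrast.
#' @slot dwiB0,dwiB800 numeric matrices on the same grid.
#' @slot bValues numeric 2-vector of diffusion weightings (s/mm^2).
#' @slot trueMask logical matrix, non-empty.
#' @slot label `"benign"` or `"malignant"`.
#' @slot cohortTag cohort identifier.
#' @slot studyId unique study identifier.
#' @slot pixelSpacing mm per pixel.
#' @slot params list of generating parameters (phantoms only; empty otherwise).
#' @export
setClass("LesionStudy",
         representation(dce = "array", dwiB0 = "matrix", dwiB800 = "matrix",
                        bValues = "numeric", trueMask = "matrix",
                        label = "character", cohortTag = "character",
                        studyId = "character", pixelSpacing = "numeric",
                        params = "list"))

setValidity("LesionStudy", function(object) {
  msg <- character()
  d <- dim(object@dce)
  if (length(d) != 3L) msg <- c(msg, "dce must be a 3-D array (h x w x frames)")
  else {
    if (!all(dim(object@dwiB0) == d[1:2]) || !all(dim(object@dwiB800) == d[1:2]) ||
        !all(dim(object@trueMask) == d[1:2]))
      msg <- c(msg, "all frames must share one pixel grid")
    if (d[3] < 2L) msg <- c(msg, "dce needs a pre-contrast and at least one post-contrast frame")
  }
  if (!any(object@trueMask)) msg <- c(msg, "trueMask is empty")
  vals <- c(object@dce, object@dwiB0, object@dwiB800)
  if (any(!is.finite(vals))) msg <- c(msg, "non-finite intensities")
  else if (any(vals < 0)) msg <- c(msg, "negative intensities")
  if (!(object@label %in% .lesionLabels)) msg <- c(msg, "label must be benign/malignant")
  if (length(object@bValues) != 2L || diff(object@bValues) <= 0)
    msg <- c(msg, "bValues must be strictly increasing pair")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CohortTable

#' @title CohortTable: labeled feature matrix for one cohort
#'
#' @description One row per lesion, the 27 canonical feature columns, sample
#' metadata (study id, label, cohort tag) and the normalization state (raw, or
#' z-scored with the centring parameters stored).
#'
#' @slot features numeric matrix, columns exactly [featureNames()].
#' @slot info data.frame with `study_id`, `label`, `cohort_tag`.
#' @slot normalization list: `state` ("raw"/"z"), `center`, `scale`.
#' @export
setClass("CohortTable",
         representation(features = "matrix", info = "data.frame",
                        normalization = "list"))

setValidity("CohortTable", function(object) {
  msg <- character()
  if (!identical(colnames(object@features), featureNames()))
    msg <- c(msg, "feature columns must be exactly the 27 canonical names, in order")
  if (nrow(object@features) != nrow(object@info))
    msg <- c(msg, "features and info row counts differ")
  if (!all(c("study_id", "label", "cohort_tag") %in% names(object@info)))
    msg <- c(msg, "info needs study_id, label, cohort_tag")
  else if (!all(object@info$label %in% .lesionLabels))
    msg <- c(msg, "labels must be benign/malignant")
  if (anyNA(object@features) || any(!is.finite(object@features)))
    msg <- c(msg, "missing or non-finite feature values")
  if (!object@normalization$state %in% c("raw", "z"))
    msg <- c(msg, "normalization state must be 'raw' or 'z'")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortTable
#'
#' @param features numeric matrix with the 27 canonical columns (any order;
#'   they are reordered canonically).
#' @param info data.frame with columns `study_id`, `label`, `cohort_tag`.
#' @param normalization normalization state list; defaults to raw.
#' @return a [CohortTable-class] object.
#' @export
CohortTable <- function(features, info,
                        normalization = list(state = "raw")) {
  features <- as.matrix(features)
  miss <- setdiff(featureNames(), colnames(features))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  new("CohortTable", features = features[, featureNames(), drop = FALSE],
      info = info, normalization = normalization)
}

## ---------------------------------------------------------------------------
## ROCResult

#' @title ROCResult: single-score diagnostic summary
#'
#' @description Best cutoff (highest mean of sensitivity and specificity),
#' its operating point, the empirical (Mann-Whitney) AUC and the
#' maximum-likelihood binormal AUC for one score.
#'
#' @slot cutoff threshold on the score scale.
#' @slot direction `"higher"` (score above cutoff called malignant) or
#'   `"lower"`.
#' @slot sensitivity,specificity,accuracy proportions in \[0,1\].
#' @slot aucBinormal,aucEmpirical areas under the ROC curve.
#' @slot nPos,nNeg class sizes.
#' @slot degenerate TRUE when the score carries no contrast.
#' @export
setClass("ROCResult",
         representation(cutoff = "numeric", direction = "character",
                        sensitivity = "numeric", specificity = "numeric",
                        accuracy = "numeric", aucBinormal = "numeric",
                        aucEmpirical = "numeric", nPos = "integer",
                        nNeg = "integer", degenerate = "logical"))

setValidity("ROCResult", function(object) {
  msg <- character()
  props <- c(object@sensitivity, object@specificity, object@accuracy)
  if (any(props < -1e-12 | props > 1 + 1e-12))
    msg <- c(msg, "proportions outside [0,1]")
  aucs <- c(object@aucEmpirical, if (is.finite(object@aucBinormal)) object@aucBinormal)
  if (any(aucs < -1e-12 | aucs > 1 + 1e-12)) msg <- c(msg, "AUC outside [0,1]")
  if (!object@direction %in% c("higher", "lower"))
    msg <- c(msg, "direction must be 'higher' or 'lower'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FeatureWeights

#' @title FeatureWeights: local-hyperplane RELIEF weighting result
#'
#' @description Non-negative per-feature weights (summing to one), the
#' descending ranking and the selected top-m subset.
#'
#' @slot weights named non-negative numeric vector summing to 1.
#' @slot ranking feature names sorted by weight, descending.
#' @slot selected top-m feature names.
#' @slot nIter iterations run.
#' @slot converged TRUE if the weight change fell below tolerance.
#' @slot degenerate TRUE when all margins were non-positive (uniform fallback).
#' @export
setClass("FeatureWeights",
         representation(weights = "numeric", ranking = "character",
                        selected = "character", nIter = "integer",
                        converged = "logical", degenerate = "logical"))

setValidity("FeatureWeights", function(object) {
  msg <- character()
  if (any(object@weights < -1e-12)) msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9) msg <- c(msg, "weights must sum to 1")
  if (is.null(names(object@weights))) msg <- c(msg, "weights must be named")
  if (!all(object@selected %in% names(object@weights)))
    msg <- c(msg, "selected features not among weighted features")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Accessors and show methods

#' @describeIn CohortTable-class feature matrix accessor
#' @param object,x a `CohortTable`.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setMethod("featureMatrix", "CohortTable", function(x) x@features)

#' @describeIn CohortTable-class sample metadata accessor
#' @export
setGeneric("cohortInfo", function(x) standardGeneric("cohortInfo"))
#' @export
setMethod("cohortInfo", "CohortTable", function(x) x@info)

#' @describeIn CohortTable-class class labels as a factor with benign first
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))
#' @export
setMethod("lesionLabels", "CohortTable",
          function(x) factor(x@info$label, levels = .lesionLabels))

#' @describeIn CohortTable-class normalization state list
#' @export
setGeneric("normalizationState", function(x) standardGeneric("normalizationState"))
#' @export
setMethod("normalizationState", "CohortTable", function(x) x@normalization)

#' @describeIn FeatureWeights-class selected feature names
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @export
setMethod("selectedFeatures", "FeatureWeights", function(x) x@selected)

#' @describeIn FeatureWeights-class the weight vector
#' @param object a `FeatureWeights`.
#' @param ... ignored.
#' @export
setMethod("weights", "FeatureWeights", function(object, ...) object@weights)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': %d benign + %d malignant, grid %dx%d @ %.2g mm, %d post-contrast frames\n",
              object@cohortTag, object@nBenign, object@nMalignant,
              object@imageShape[1], object@imageShape[2], object@pixelSpacing,
              object@nPostcontrast))
  cat(sprintf("  field effects: gain %.2f, noise SD %.2f; seed %d\n",
              object@fieldEffects$gain, object@fieldEffects$noiseSD, object@seed))
})

setMethod("show", "LesionStudy", function(object) {
  d <- dim(object@dce)
  cat(sprintf("LesionStudy '%s' (%s, %s): %dx%d grid, %d DCE frames, DWI b = %g/%g, mask %d px\n",
              object@studyId, object@label, object@cohortTag, d[1], d[2], d[3],
              object@bValues[1], object@bValues[2], sum(object@trueMask)))
})

setMethod("show", "CohortTable", function(object) {
  tab <- table(object@info$label)
  cat(sprintf("CohortTable (%s): %d lesions (%s), %d features, normalization: %s\n",
              paste(unique(object@info$cohort_tag), collapse = "+"),
              nrow(object@features),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              ncol(object@features), object@normalization$state))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: cutoff %.4g (%s-is-malignant), sens %.3f, spec %.3f, acc %.3f\n",
              object@cutoff, object@direction, object@sensitivity,
              object@specificity, object@accuracy))
  cat(sprintf("  AUC: empirical %.3f, binormal %.3f (n+ = %d, n- = %d)%s\n",
              object@aucEmpirical, object@aucBinormal, object@nPos, object@nNeg,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "FeatureWeights", function(object) {
  top <- head(object@ranking, length(object@selected))
  cat(sprintf("FeatureWeights: %d features, %d iterations (%sconverged)\n",
              length(object@weights), object@nIter,
              if (object@converged) "" else "not "))
  cat("  selected:", paste(top, collapse = ", "), "\n")
})
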