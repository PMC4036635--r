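# End-to-end orchestration: simulate -> segment -> extract -> normalize ->
# per-feature ROC -> LHR selection -> cross-cohort evaluation.

#' Default run configuration
#'
#' One nested list carries every stage's parameters; [readRunConfig()] merges
#' a YAML file over these defaults and rejects unknown keys, and every
#' [runPipeline()] run writes the resolved configuration next to its outputs.
#'
#' @param seed master seed; cohort seeds derive from it.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohorts = list(
      train = list(cohort_tag = "train15T", n_benign = 20L, n_malignant = 20L),
      test  = list(cohort_tag = "test30T", n_benign = 10L, n_malignant = 10L)),
    simulate = list(write_images = TRUE),
    segmentation = defaultSegmentationConfig(),
    glcm = list(ng = 256L, symmetric = TRUE),
    adc = list(ring_width = 5L),
    lhr = list(K = 5L, lambda = 1.0, n_iter = 50L, tol = 1e-4, m = 5L),
    scenarios = c("morphology", "morphology+texture", "adc+ser",
                  "morphology+kinetic", "morphology+adc",
                  "morphology+texture+kinetic", "entire", "selected5"))
}

# Recursively reject keys not present in the default template.
.checkConfigKeys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(cfg))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) && is.list(cfg[[k]]))
      .checkConfigKeys(cfg[[k]], template[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file; keys override [defaultRunConfig()] values and
#'   unknown keys are rejected.
#' @return the merged configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  template <- defaultRunConfig()
  .checkConfigKeys(user, template)
  modifyList(template, user)
}

#' Extract the 27 features of one study
#'
#' Segments the lesion (or uses the ground-truth mask when
#' `config$segmentation$useTruth` is set), then computes the morphology,
#' GLCM texture, kinetic and ADC feature groups on it.
#'
#' @param study a [LesionStudy-class].
#' @param config run configuration (see [defaultRunConfig()]).
#' @return named numeric vector of the 27 canonical features.
#' @export
extractStudyFeatures <- function(study, config = defaultRunConfig()) {
  mask <- if (isTRUE(config$segmentation$useTruth)) study@trueMask
          else segmentLesion(study, config = config$segmentation)
  mask <- matrix(as.logical(mask), nrow(mask))
  frame1 <- study@dce[, , 2]
  morph <- computeMorphology(mask, frame1, spacing = study@pixelSpacing)
  glcm <- buildGLCM(frame1, mask, ng = config$glcm$ng,
                    symmetric = config$glcm$symmetric)
  tex <- haralickFeatures(glcm)
  cur <- extractCurve(study@dce, mask)
  kin <- c(epe = kineticEPE(cur), ser = kineticSER(cur))
  amap <- computeADCMap(study@dwiB0, study@dwiB800, study@bValues)
  high <- dichotomizeDWI(study@dwiB800, mask,
                         ringWidth = config$adc$ring_width)
  adc <- c(adc = adcFeature(amap, high))
  c(morph, tex, kin, adc)[featureNames()]
}

#' Extract a cohort feature table
#'
#' Accepts either a list of [LesionStudy-class] objects or a cohort
#' directory containing `manifest.json`. Per-study failures are recorded and
#' the study excluded; the run continues.
#'
#' @param x study list or cohort directory path.
#' @param config run configuration.
#' @return a raw [CohortTable-class]; attribute `"exclusions"` is a
#'   data.frame of excluded study ids and reasons.
#' @export
extractFeatures <- function(x, config = defaultRunConfig()) {
  manIds <- NULL
  studies <- if (is.character(x)) {
    man <- readCohortManifest(x)
    manIds <- vapply(man$studies, function(e) e$study_id, character(1))
    lapply(man$studies, function(e)
      tryCatch(readStudy(x, e), error = function(err) err))
  } else x
  ids <- vapply(seq_along(studies), function(i) {
    s <- studies[[i]]
    if (inherits(s, "LesionStudy")) s@studyId
    else if (!is.null(manIds)) manIds[i]
    else sprintf("study%03d", i)
  }, character(1))
  feats <- list(); infos <- list(); excl <- list()
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    res <- if (inherits(s, "error") || inherits(s, "condition")) s else
      tryCatch(extractStudyFeatures(s, config), error = function(e) e)
    if (inherits(res, "error") || inherits(res, "condition")) {
      excl[[length(excl) + 1L]] <- data.frame(
        study_id = ids[i], reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      feats[[length(feats) + 1L]] <- res
      infos[[length(infos) + 1L]] <- data.frame(
        study_id = s@studyId, label = s@label, cohort_tag = s@cohortTag,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(feats)) stop("no study could be extracted")
  tab <- CohortTable(do.call(rbind, feats), do.call(rbind, infos))
  attr(tab, "exclusions") <- if (length(excl)) do.call(rbind, excl)
    else data.frame(study_id = character(), reason = character())
  tab
}

#' Write / read a cohort feature table as CSV
#'
#' Three id columns (`study_id`, `label`, `cohort_tag`) followed by the 27
#' canonical feature columns.
#'
#' @param cohort a [CohortTable-class].
#' @param path CSV path.
#' @return the path (write) or a raw [CohortTable-class] (read).
#' @export
writeCohortCSV <- function(cohort, path) {
  df <- cbind(cohort@info[c("study_id", "label", "cohort_tag")],
              as.data.frame(signif(cohort@features, 12)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  CohortTable(as.matrix(df[featureNames()]),
              df[c("study_id", "label", "cohort_tag")])
}

#' Run the whole pipeline
#'
#' Simulates the two cohorts, extracts features, z-normalizes each cohort
#' independently, writes the per-feature ROC report, runs LHR feature
#' selection on the training cohort, evaluates all classification scenarios,
#' and writes every artifact (manifests, feature CSVs, `weights.json`,
#' `roc_report.json`, `report.json`, `report.csv`, resolved config, log)
#' under `outDir`.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param outDir output directory (created).
#' @return invisibly, a list with the in-memory results and artifact paths.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("cadrun")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "",
                               ..., "\n", sep = "", file = logPath,
                               append = TRUE)
  stage <- function(name, expr) {
    logLine("start ", name)
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logLine("done  ", name)
    res
  }

  yaml::write_yaml(config, file.path(outDir, "config_resolved.yaml"))

  cohorts <- stage("simulate", {
    ctr <- config$cohorts$train; cte <- config$cohorts$test
    specTr <- defaultPhantomSpec(ctr$cohort_tag,
                                 seed = childSeed(config$seed, 1L),
                                 nBenign = ctr$n_benign,
                                 nMalignant = ctr$n_malignant)
    specTe <- defaultPhantomSpec(cte$cohort_tag,
                                 seed = childSeed(config$seed, 2L),
                                 nBenign = cte$n_benign,
                                 nMalignant = cte$n_malignant)
    generateCohorts(specTr, specTe, outDir = outDir,
                    writeImages = isTRUE(config$simulate$write_images))
  })

  train <- stage("extract-train", extractFeatures(cohorts$train, config))
  test <- stage("extract-test", extractFeatures(cohorts$test, config))
  for (nm in c("train", "test")) {
    ex <- attr(get(nm), "exclusions")
    if (nrow(ex)) for (i in seq_len(nrow(ex)))
      logLine("excluded ", ex$study_id[i], ": ", ex$reason[i])
  }
  writeCohortCSV(train, file.path(outDir, "train_features.csv"))
  writeCohortCSV(test, file.path(outDir, "test_features.csv"))

  trainZ <- stage("normalize", zNormalize(train))
  testZ <- zNormalize(test)

  roc <- stage("roc", rocReport(trainZ, testZ))
  jsonlite::write_json(roc, file.path(outDir, "roc_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")

  fw <- stage("select", lhrWeights(featureMatrix(trainZ), lesionLabels(trainZ),
                                   K = config$lhr$K, lambda = config$lhr$lambda,
                                   nIter = config$lhr$n_iter, tol = config$lhr$tol,
                                   m = config$lhr$m))
  jsonlite::write_json(
    list(weights = as.list(weights(fw)),
         ranking = fw@ranking, selected = fw@selected,
         n_iter = fw@nIter, converged = fw@converged),
    file.path(outDir, "weights.json"), auto_unbox = TRUE, digits = 10,
    pretty = TRUE)

  report <- stage("evaluate", {
    scen <- config$scenarios
    if (!length(scen)) {
      warning("empty scenario list: report has 0 rows")
      data.frame()
    } else runAllScenarios(trainZ, testZ, seed = config$seed, subsets = scen)
  })
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")
  repCsv <- report
  if (nrow(repCsv)) repCsv$accuracy <- 100 * repCsv$accuracy  # percent, as reported
  write.csv(repCsv, file.path(outDir, "report.csv"), row.names = FALSE)
  logLine("pipeline complete")

  invisible(list(train = train, test = test, trainZ = trainZ, testZ = testZ,
                 roc = roc, weights = fw, report = report, outDir = outDir,
                 paths = file.path(outDir,
                   c("train_features.csv", "test_features.csv",
                     "roc_report.json", "weights.json", "report.json",
                     "report.csv", "config_resolved.yaml", "run.log"))))
}
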