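#' Pipeline configuration
#'
#' One global seed fans out deterministically to the stage seeds (cohort
#' simulation, evolutionary selection) via [stageSeed()], so adding a stage
#' never perturbs the randomness of earlier ones.
#'
#' @param cohort A [cohortConfig()]; its `seed` is overridden by the fanned
#'   out stage seed.
#' @param registrationEnabled Run slice-wise co-registration before feature
#'   extraction (the synthetic default is motion-free, so `FALSE`).
#' @param registration A [registrationConfig()].
#' @param nLevels Grey levels for texture quantization.
#' @param margin Bounding-box crop margin in voxels.
#' @param twist A [twistConfig()]; its `seed` is likewise overridden.
#' @param k Neighbour count of the final classifier.
#' @param outDir Output directory for all intermediate artefacts, or `NULL`
#'   to keep everything in memory.
#' @param seed Integer global seed.
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           registrationEnabled = FALSE,
                           registration = registrationConfig(),
                           nLevels = 32L, margin = 2L,
                           twist = twistConfig(),
                           k = 3L, outDir = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "CohortConfig"),
            inherits(registration, "RegistrationConfig"),
            inherits(twist, "TwistConfig"),
            .isCount(nLevels, 2L), .isCount(margin, 0L), .isCount(k, 1L))
  cohort$seed <- stageSeed(seed, "simulate")
  twist$seed <- stageSeed(seed, "twist")
  structure(list(cohort = cohort,
                 registrationEnabled = registrationEnabled,
                 registration = registration,
                 nLevels = as.integer(nLevels), margin = as.integer(margin),
                 twist = twist, k = as.integer(k), outDir = outDir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full synthetic pipeline
#'
#' simulate -> (register) -> extract -> evolve selection/split -> classify
#' crosswise -> report. Every intermediate artefact is written under
#' `cfg$outDir` when given (NIfTI cases, `features.csv`,
#' `twist_result.json`, `balance_report.csv`, `report.json`, `report.md`,
#' `roc_points.csv`); rerunning with the same config reproduces them.
#'
#' @param cfg A [pipelineConfig()].
#' @return A [DiagnosticReport-class]; the [FeatureTable-class] and
#'   [TwistResult-class] are attached as attributes `featureTable` and
#'   `twistResult`.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
  }
  out <- cfg$outDir
  cohort <- withStage("simulate", generateCohort(cfg$cohort))
  if (!is.null(out)) {
    dir.create(file.path(out, "cases"), recursive = TRUE,
               showWarnings = FALSE)
    withStage("simulate",
              invisible(lapply(cohort, writeCase,
                               dir = file.path(out, "cases"))))
  }
  if (cfg$registrationEnabled) {
    cohort <- withStage("register", lapply(cohort, function(cs) {
      reg <- registerSeries(cs@series, cfg$registration)
      cs@series <- reg$series
      cs@truth$registration <- reg$transforms
      cs
    }))
  }
  ft <- withStage("extract", extractCohort(cohort, cfg$nLevels, cfg$margin))
  if (!is.null(out)) writeFeatureTable(ft, file.path(out, "features.csv"))
  tw <- withStage("twist", twist(ft, cfg$twist))
  if (!is.null(out)) {
    writeTwistResult(tw, file.path(out, "twist_result.json"))
    utils::write.csv(splitBalanceReport(tw, ft),
                     file.path(out, "balance_report.csv"),
                     row.names = FALSE)
  }
  report <- withStage("evaluate", crossedEvaluation(ft, tw, cfg$k))
  if (!is.null(out)) writeReport(report, out)
  attr(report, "featureTable") <- ft
  attr(report, "twistResult") <- tw
  report
}

#' Write a TwistResult as JSON
#'
#' @param result A [TwistResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTwistResult <- function(result, path) {
  jsonlite::write_json(list(
    selected_features = result@selectedFeatures,
    group_A = result@groupA, group_B = result@groupB,
    best_fitness = result@bestFitness,
    fitness_history = result@fitnessHistory,
    config = result@config[setdiff(names(result@config), "balanced")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TwistResult written by [writeTwistResult()]
#'
#' @param path JSON path.
#' @return A [TwistResult-class].
#' @export
readTwistResult <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TwistResult", selectedFeatures = js$selected_features,
      groupA = js$group_A, groupB = js$group_B,
      bestFitness = js$best_fitness,
      fitnessHistory = as.data.frame(js$fitness_history),
      config = as.list(js$config))
}

# internal: serialisable form of one evaluation arm
.armAsList <- function(arm) {
  cm <- arm$cm
  list(confusion = list(TP = cm@tp, TN = cm@tn, FP = cm@fp, FN = cm@fn),
       metrics = arm$metrics, auc = arm$roc$auc,
       roc_points = arm$roc$points, predictions = arm$predictions)
}

#' Write a DiagnosticReport to disk
#'
#' Emits `report.json` (full precision plus display values), `report.md`
#' (a human-readable grid of both arms and the pooled column) and
#' `roc_points.csv`.
#'
#' @param report A [DiagnosticReport-class].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pooledCm <- report@pooled$cm
  jsonlite::write_json(list(
    arms = lapply(report@arms, .armAsList),
    pooled = list(confusion = list(TP = pooledCm@tp, TN = pooledCm@tn,
                                   FP = pooledCm@fp, FN = pooledCm@fn),
                  metrics = report@pooled$metrics),
    auc_mean = report@aucMean, k = report@k),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  rocs <- do.call(rbind, lapply(names(report@arms), function(nm) {
    data.frame(arm = nm, report@arms[[nm]]$roc$points)
  }))
  utils::write.csv(rocs, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  writeLines(formatReport(report), file.path(dir, "report.md"))
  invisible(dir)
}

#' Format a DiagnosticReport as a markdown grid
#'
#' @param report A [DiagnosticReport-class].
#' @return Character vector of lines.
#' @export
formatReport <- function(report) {
  g <- function(arm, metric, col = "display") {
    m <- arm$metrics
    v <- m[m$metric == metric, col]
    if (is.na(v)) "-" else as.character(v)
  }
  a <- report@arms$AtoB; b <- report@arms$BtoA; p <- report@pooled
  pm <- p$metrics
  rowFor <- function(label, metric, pct = TRUE) {
    ci <- pm[pm$metric == metric, "ci_display"]
    sprintf("| %s | %s%% | %s%% | %s%% | %s |", label,
            g(a, metric), g(b, metric), g(p, metric),
            if (is.na(ci)) "-" else ci)
  }
  cmRow <- function(label, slot) {
    sprintf("| %s | %d | %d | %d | |", label,
            methods::slot(a$cm, slot), methods::slot(b$cm, slot),
            methods::slot(p$cm, slot))
  }
  c("# Crossed A/B diagnostic performance", "",
    "| Metric | A/B | B/A | Total | 95% CI (%) |",
    "|---|---|---|---|---|",
    rowFor("Sensitivity", "sensitivity"),
    rowFor("Specificity", "specificity"),
    rowFor("Accuracy", "accuracy"),
    rowFor("Positive predictive value", "ppv"),
    rowFor("Negative predictive value", "npv"),
    cmRow("True positives", "tp"),
    cmRow("True negatives", "tn"),
    cmRow("False positives", "fp"),
    cmRow("False negatives", "fn"),
    sprintf("| Positive likelihood ratio | %s | %s | %s | |",
            g(a, "lr_positive"), g(b, "lr_positive"), g(p, "lr_positive")),
    sprintf("| Negative likelihood ratio | %s | %s | %s | |",
            g(a, "lr_negative"), g(b, "lr_negative"), g(p, "lr_negative")),
    sprintf("| Area under the curve | %.2f | %.2f | %.2f | |",
            a$roc$auc, b$roc$auc, report@aucMean))
}
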