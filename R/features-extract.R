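.INTENSITY_NAMES <- c("Max", "Min", "Mean", "Sigma", "Variance",
                      "IntegratedIntensity")
.SHAPE_NAMES <- c("Eccentricity", "Elongation", "MajorAxisLength",
                  "MinorAxisLength", "Volume")
.GLCM_NAMES <- c("Energy", "Entropy", "InverseDifferenceMoment", "Inertia",
                 "ClusterShade", "ClusterProminence")
.GLRLM_NAMES <- c("SRE", "LRE", "GLN", "RLN", "LGLRE", "HGLRE", "SRLGLE",
                  "SRHGLE", "LRLGLE", "LRHGLE")

#' Names of the 43 per-time-point features
#'
#' 6 intensity + 5 shape + 12 co-occurrence (mean and SD of 6 statistics
#' over the 13 3D directions) + 20 run-length (mean and SD of 10
#' statistics), in the fixed extraction order.
#'
#' @param timepoint Optional time-point index 0..4; when given, names carry
#'   the `_T<k>` suffix.
#' @return Character vector of 43 (or, with `timepoint = NULL`, the bare
#'   names).
#' @export
featureNames <- function(timepoint = NULL) {
  tex <- function(base) as.vector(rbind(paste0(base, "_Mean"),
                                        paste0(base, "_SD")))
  nm <- c(.INTENSITY_NAMES, .SHAPE_NAMES, tex(.GLCM_NAMES),
          tex(.GLRLM_NAMES))
  if (is.null(timepoint)) nm else paste0(nm, "_T", timepoint)
}

# internal: mean/SD aggregation of texture statistics over directions
.aggregateDirections <- function(statList, base) {
  if (length(statList) < 2L)
    stop("fewer than 2 directions with valid ", base,
         " statistics; ROI too small")
  m <- do.call(rbind, statList)
  out <- as.vector(rbind(colMeans(m), apply(m, 2, sd)))
  names(out) <- as.vector(rbind(paste0(colnames(m), "_Mean"),
                                paste0(colnames(m), "_SD")))
  out
}

#' Extract the 215-feature radiomic vector of one case
#'
#' Per time-point: 6 first-order intensity statistics, 5 shape descriptors
#' (computed once from the single lesion mask and replicated across the five
#' time-points), 12 co-occurrence and 20 run-length texture features (mean
#' and sample SD of each statistic over the 13 unique 3D directions), i.e.
#' 43 features x 5 time-points = 215. The ROI is quantized per time-point
#' onto `nLevels` equal-width grey levels between the masked extrema.
#'
#' @param series A (registered or motion-free) [DynamicSeries-class].
#' @param mask A [LesionMask-class].
#' @param nLevels Grey levels for texture quantization (default 32).
#' @param margin Bounding-box crop margin in voxels.
#' @return Named numeric vector of 215 finite values.
#' @export
extractFeatures <- function(series, mask, nLevels = 32L, margin = 2L) {
  cr <- cropToBbox(series, mask, margin)
  sp <- cr$series@spacing
  m <- cr$mask@mask
  dirs <- directionSet3D()
  shp <- shapeFeatures(m, sp)
  out <- numeric(0)
  for (ti in 0:4) {
    vol <- seriesVolume(cr$series, ti)
    q <- quantizeROI(vol, m, nLevels, sp)
    glc <- list(); glr <- list()
    for (di in seq_len(nrow(dirs))) {
      P <- glcmMatrix(q, dirs[di, ])
      if (!is.null(P)) glc[[length(glc) + 1L]] <- glcmStats(P)
      R <- glrlmMatrix(q, dirs[di, ])
      if (!is.null(R) && sum(R) > 0)
        glr[[length(glr) + 1L]] <- glrlmStats(R)
    }
    v <- c(intensityFeatures(vol, m, sp), shp,
           .aggregateDirections(glc, "GLCM"),
           .aggregateDirections(glr, "GLRLM"))
    names(v) <- featureNames(ti)
    out <- c(out, v)
  }
  stopifnot(length(out) == 215L, all(is.finite(out)))
  out
}

#' Construct a FeatureTable
#'
#' @param x Numeric matrix, cases in rows and named features in columns.
#' @param labels Character vector of case labels (`benign`, `malignant` or
#'   `unknown`).
#' @param caseIds Character case identifiers (default from rownames).
#' @return A [FeatureTable-class] (features x cases
#'   `SummarizedExperiment`).
#' @export
FeatureTable <- function(x, labels, caseIds = rownames(x)) {
  x <- as.matrix(x)
  if (is.null(caseIds)) caseIds <- paste0("case_", seq_len(nrow(x)))
  stopifnot(length(labels) == nrow(x), length(caseIds) == nrow(x))
  mat <- t(x)
  colnames(mat) <- caseIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   row.names = caseIds))
  new("FeatureTable", se)
}

#' @describeIn FeatureTable Feature matrix, cases x features.
#' @param ft A `FeatureTable`.
#' @export
featureMatrix <- function(ft) t(SummarizedExperiment::assay(ft, "features"))

#' @describeIn FeatureTable Case labels.
#' @export
caseLabels <- function(ft) SummarizedExperiment::colData(ft)$label

#' @describeIn FeatureTable Case identifiers.
#' @export
caseIds <- function(ft) colnames(ft)

#' Extract features for a whole cohort
#'
#' @param cases List of [SyntheticCase-class] objects (or lists with
#'   elements `series`, `mask`, `label`, `caseId`).
#' @inheritParams extractFeatures
#' @return A [FeatureTable-class] of 215 features x cases.
#' @export
extractCohort <- function(cases, nLevels = 32L, margin = 2L) {
  rows <- lapply(cases, function(cs) {
    if (is(cs, "SyntheticCase")) {
      extractFeatures(cs@series, cs@mask, nLevels, margin)
    } else {
      extractFeatures(cs$series, cs$mask, nLevels, margin)
    }
  })
  x <- do.call(rbind, rows)
  ids <- vapply(cases, function(cs)
    if (is(cs, "SyntheticCase")) cs@caseId else cs$caseId, character(1))
  labels <- vapply(cases, function(cs)
    if (is(cs, "SyntheticCase")) cs@label else cs$label, character(1))
  rownames(x) <- ids
  FeatureTable(x, labels, ids)
}

#' Write a FeatureTable to CSV (one row per case)
#'
#' @param ft A [FeatureTable-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  df <- data.frame(case_id = caseIds(ft), label = caseLabels(ft),
                   featureMatrix(ft), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a FeatureTable from CSV
#'
#' @param path CSV written by [writeFeatureTable()].
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("case_id", "label") %in% colnames(df)))
  x <- as.matrix(df[, setdiff(colnames(df), c("case_id", "label")),
                    drop = FALSE])
  rownames(x) <- df$case_id
  FeatureTable(x, df$label, df$case_id)
}
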