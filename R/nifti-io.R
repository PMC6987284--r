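#' Write a case to disk as NIfTI volumes plus a JSON sidecar
#'
#' Writes `t0.nii.gz` ... `t4.nii.gz`, `mask.nii.gz` and `case.json` (label,
#' ground-truth kinetic parameters when present, acquisition times) into one
#' directory per case.
#'
#' @param case A [SyntheticCase-class], or a list with `series`, `mask`,
#'   `label`, `caseId`.
#' @param dir Output directory (created if missing).
#' @return The case directory, invisibly.
#' @export
writeCase <- function(case, dir) {
  if (is(case, "SyntheticCase")) {
    series <- case@series; mask <- case@mask
    label <- case@label; caseId <- case@caseId
    truth <- case@truth
  } else {
    series <- case$series; mask <- case$mask
    label <- case$label; caseId <- case$caseId
    truth <- case$truth
  }
  caseDir <- file.path(dir, caseId)
  dir.create(caseDir, recursive = TRUE, showWarnings = FALSE)
  for (ti in 0:4) {
    RNifti::writeNifti(
      RNifti::asNifti(seriesVolume(series, ti),
                      pixdim = series@spacing),
      file.path(caseDir, sprintf("t%d.nii.gz", ti)))
  }
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(mask@mask), dim = dim(mask@mask)),
                    pixdim = mask@spacing),
    file.path(caseDir, "mask.nii.gz"))
  sidecar <- list(case_id = caseId, label = label,
                  spacing_mm = series@spacing, times_min = series@times)
  if (!is.null(truth$kinetics))
    sidecar$kinetics <- unclass(truth$kinetics)
  jsonlite::write_json(sidecar, file.path(caseDir, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(caseDir)
}

#' Read a case directory written by [writeCase()]
#'
#' @param caseDir Directory containing `t0.nii.gz` ... `t4.nii.gz`,
#'   `mask.nii.gz` and optionally `case.json`.
#' @return List with `series` ([DynamicSeries-class]), `mask`
#'   ([LesionMask-class]), `label` and `caseId`.
#' @export
readCase <- function(caseDir) {
  vols <- lapply(0:4, function(ti) {
    f <- file.path(caseDir, sprintf("t%d.nii.gz", ti))
    if (!file.exists(f)) stop("missing volume: ", f)
    v <- RNifti::readNifti(f)
    list(data = as.array(v), spacing = RNifti::pixdim(v))
  })
  dims <- dim(vols[[1]]$data)
  data <- array(0, dim = c(dims, 5L))
  for (ti in 1:5) data[, , , ti] <- vols[[ti]]$data
  mf <- file.path(caseDir, "mask.nii.gz")
  if (!file.exists(mf)) stop("missing mask: ", mf)
  mask <- as.array(RNifti::readNifti(mf)) > 0
  meta <- list(label = "unknown", case_id = basename(caseDir),
               times_min = 0:4)
  jf <- file.path(caseDir, "case.json")
  if (file.exists(jf)) {
    js <- jsonlite::read_json(jf, simplifyVector = TRUE)
    meta[names(js)] <- js
  }
  sp <- vols[[1]]$spacing[1:3]
  list(series = DynamicSeries(data, sp, as.numeric(meta$times_min)),
       mask = LesionMask(mask, sp),
       label = meta$label, caseId = meta$case_id)
}

#' Validate a directory of case subdirectories
#'
#' Checks that every case directory holds the five dynamic volumes plus one
#' mask, that shapes and spacings agree within the case, and that the mask
#' is nonempty. Problems are reported in the manifest, never raised.
#'
#' @param seriesDir Directory whose subdirectories are cases.
#' @return data.frame manifest with one row per case: `case_id`, `ok` and
#'   `reason` (`""` when valid).
#' @export
validateInputs <- function(seriesDir) {
  caseDirs <- list.dirs(seriesDir, recursive = FALSE)
  rows <- lapply(caseDirs, function(cd) {
    status <- tryCatch({
      files <- file.path(cd, c(sprintf("t%d.nii.gz", 0:4), "mask.nii.gz"))
      missing <- files[!file.exists(files)]
      if (length(missing) > 0)
        stop("missing file(s): ",
             paste(basename(missing), collapse = ", "))
      shapes <- lapply(files, function(f) dim(as.array(RNifti::readNifti(f))))
      if (length(unique(vapply(shapes, paste, character(1),
                               collapse = "x"))) != 1L)
        stop("volume/mask shape mismatch")
      if (!any(as.array(RNifti::readNifti(files[6])) > 0))
        stop("empty mask")
      ""
    }, error = function(e) conditionMessage(e))
    data.frame(case_id = basename(cd), ok = status == "", reason = status)
  })
  if (length(rows) == 0)
    return(data.frame(case_id = character(0), ok = logical(0),
                      reason = character(0)))
  do.call(rbind, rows)
}
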