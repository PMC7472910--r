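.score_cols <- function() as.vector(outer(c("rh", "lh", "rf", "lf"),
                                          c("_acute", "_3m"), paste0))

#' Read a patient cohort table
#'
#' Reads a CSV with one row per patient: relative TDD scores for right/left
#' hand and foot at the acute and 3-month time points, a free-text lesion
#' annotation, a `target` flag (lesion includes a target area), and a
#' `side_diff` column listing side-difference footnote flags as
#' semicolon-separated `site_time` codes (e.g. `"rf_acute;rf_3m"`). Unicode
#' minus signs are normalised to ASCII on ingest; unparseable numeric cells
#' fail with the offending row and column named.
#'
#' @param path Path to the cohort CSV.
#' @return Data frame of class `tdd_cohort` with numeric score columns and
#'   logical `sd_<site>_<time>` flag columns.
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  required <- c("patient", "age", "sex", .score_cols(), "lesion", "target",
                "side_diff")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  num <- function(col) {
    x <- gsub("−", "-", trimws(raw[[col]]))
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(x %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("unparseable number in column '%s', row %d: '%s'",
                   col, bad[1], x[bad[1]]))
    v
  }
  out <- data.frame(patient = num("patient"), age = num("age"),
                    sex = trimws(raw$sex), stringsAsFactors = FALSE)
  for (cl in .score_cols()) out[[cl]] <- num(cl)
  out$lesion <- raw$lesion
  out$target <- num("target") != 0
  codes <- strsplit(trimws(raw$side_diff), "[;,[:space:]]+")
  valid <- .score_cols()
  for (cl in valid) out[[paste0("sd_", cl)]] <- logical(nrow(out))
  for (i in seq_along(codes)) {
    for (cd in codes[[i]]) {
      if (cd == "") next
      if (!cd %in% valid)
        stop(sprintf("unknown side-difference code '%s' in row %d", cd, i))
      out[i, paste0("sd_", cd)] <- TRUE
    }
  }
  if (nrow(out) == 0) warning("cohort file has a header but no records")
  class(out) <- c("tdd_cohort", "data.frame")
  out
}

#' The packaged 28-patient cohort table
#'
#' Relative TDD scores (right/left hand and foot, acute and 3-month), lesion
#' annotations with target-area markers, and side-difference footnote flags
#' for the 28 stroke patients of the follow-up cohort, as printed in the
#' source study's patient table.
#'
#' @return A `tdd_cohort` data frame with 28 rows (see [read_cohort()]).
#' @export
table2_fixture <- function() {
  read_cohort(system.file("extdata", "table2_cohort.csv", package = "tactdd",
                          mustWork = TRUE))
}

#' Read a NIfTI label volume
#'
#' @param path Path to a NIfTI-1 file (optionally gzip-compressed).
#' @return An `RNifti` image array (geometry preserved).
#' @export
read_volume <- function(path) RNifti::readNifti(path)

#' Write a volume to NIfTI
#'
#' @param volume 3-D array (plain or `RNifti` image).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(volume, path)
  invisible(path)
}

#' Read a binary lesion mask
#'
#' @param path Path to a NIfTI mask whose voxels are all 0 or 1.
#' @return The mask volume; non-binary files are rejected.
#' @export
read_lesion_mask <- function(path) {
  v <- read_volume(path)
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1)))
    stop("mask is not binary: contains value(s) ",
         paste(setdiff(u, c(0, 1)), collapse = ", "))
  v
}
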