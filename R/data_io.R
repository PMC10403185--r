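#' @useDynLib fusemass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile pnorm qnorm ks.test setNames cov
#' @importFrom utils read.csv write.csv head modifyList packageVersion
"_PACKAGE"

#' Recognized MRI modality tags
#'
#' T2-weighted (fat suppressed), non-fat-suppressed T1-weighted, and the
#' dynamic contrast-enhanced T1 phases: `d1` (pre-contrast), `d2` (first
#' post-contrast), `d4` and `d6` (delayed phases).
#' @export
MODALITY_TAGS <- c("T2WI", "nonfs_T1WI", "d1", "d2", "d4", "d6")

# manifest CSV column order
.manifest_cols <- c("case_id", "label", "t2wi", "nonfs_t1wi", "d1", "d2",
                    "d4", "d6", "mask", "reference_modality")

.manifest_col_for <- function(modality) {
  c(T2WI = "t2wi", nonfs_T1WI = "nonfs_t1wi", d1 = "d1", d2 = "d2",
    d4 = "d4", d6 = "d6")[[modality]]
}

#' Construct a single-modality 3D volume
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length 3, mm per axis; strictly positive.
#' @param modality One of [MODALITY_TAGS].
#' @param case_id Lesion identifier.
#' @return An object of class `ModalityVolume`.
#' @export
modality_volume <- function(voxels, spacing, modality, case_id = "case") {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1)) stop("all three dimensions must be >= 1")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  modality <- match.arg(modality, MODALITY_TAGS)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 modality = modality, case_id = case_id),
            class = "ModalityVolume")
}

#' @export
print.ModalityVolume <- function(x, ...) {
  cat(sprintf("<ModalityVolume %s/%s  %s voxels  spacing %s mm>\n",
              x$case_id, x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x")))
  invisible(x)
}

#' Construct a binary segmentation mask
#'
#' Any nonzero label value is binarized to 1. The mask must share the grid
#' of the reference modality it was drawn on and contain at least one
#' nonzero voxel.
#'
#' @param voxels 3D array; nonzero entries mark the lesion.
#' @param case_id Lesion identifier.
#' @param reference_modality Modality tag the mask was drawn on.
#' @param spacing Voxel spacing of the reference grid (mm).
#' @return An object of class `SegmentationMask`.
#' @export
segmentation_mask <- function(voxels, case_id = "case",
                              reference_modality = "d2",
                              spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("mask must be a 3D array")
  reference_modality <- match.arg(reference_modality, MODALITY_TAGS)
  bin <- array(as.numeric(voxels != 0), dim = dim(voxels))
  if (sum(bin) == 0) stop("empty mask: no nonzero voxels")
  structure(list(voxels = bin, case_id = case_id,
                 reference_modality = reference_modality,
                 spacing = as.numeric(spacing)),
            class = "SegmentationMask")
}

#' Load one modality volume from a NIfTI file
#'
#' No intensity rescaling beyond the file's own slope/intercept is applied.
#'
#' @inheritParams modality_volume
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @export
load_volume <- function(path, modality, case_id = "case") {
  img <- read_nifti(path)
  modality_volume(img$voxels, img$spacing, modality, case_id)
}

#' Load a segmentation mask and validate it against its reference volume
#'
#' @param path Path to the mask NIfTI.
#' @param reference The `ModalityVolume` the mask was drawn on.
#' @export
load_mask <- function(path, reference) {
  stopifnot(inherits(reference, "ModalityVolume"))
  img <- read_nifti(path)
  if (!identical(dim(img$voxels), dim(reference$voxels)))
    stop("shape mismatch: mask is ",
         paste(dim(img$voxels), collapse = "x"), " but reference is ",
         paste(dim(reference$voxels), collapse = "x"))
  segmentation_mask(img$voxels, case_id = reference$case_id,
                    reference_modality = reference$modality,
                    spacing = reference$spacing)
}

#' Build a cohort manifest
#'
#' A manifest maps each lesion to its per-modality image files, mask file,
#' label and reference modality, and carries enrollment bookkeeping:
#' `retained = enrolled - sum(excluded)` is enforced on every mutation.
#'
#' @param records `data.frame` with columns `case_id`, `label`
#'   (`"benign"`/`"malignant"`), one column per modality file
#'   (`t2wi`, `nonfs_t1wi`, `d1`, `d2`, `d4`, `d6`; `NA` if absent),
#'   `mask`, `reference_modality`. May be `NULL` for count-only bookkeeping.
#' @param enrolled Number of subjects enrolled before exclusions; defaults
#'   to the number of records.
#' @param excluded Named numeric vector of per-reason exclusion counts.
#' @return An object of class `CohortManifest` (a `data.frame` with count
#'   attributes).
#' @export
cohort_manifest <- function(records = NULL, enrolled = NULL,
                            excluded = numeric(0)) {
  if (is.null(records)) {
    records <- as.data.frame(setNames(rep(list(character(0)),
                                          length(.manifest_cols)),
                                      .manifest_cols))
  }
  missing_cols <- setdiff(c("case_id", "label"), names(records))
  if (length(missing_cols))
    stop("manifest records lack columns: ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(.manifest_cols, names(records))) records[[col]] <- NA
  records <- records[, .manifest_cols]
  if (anyDuplicated(records$case_id)) stop("case_ids must be unique")
  if (nrow(records) && !all(records$label %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  if (is.null(enrolled)) enrolled <- nrow(records) + sum(excluded)
  retained <- enrolled - sum(excluded)
  if (retained < 0) stop("exclusions exceed enrolled count")
  structure(records, class = c("CohortManifest", "data.frame"),
            enrolled = enrolled, excluded = excluded, retained = retained)
}

#' Cohort bookkeeping counts
#' @param manifest A `CohortManifest`.
#' @return List with `enrolled`, `excluded` (named per-reason counts) and
#'   `retained`.
#' @export
manifest_counts <- function(manifest) {
  stopifnot(inherits(manifest, "CohortManifest"))
  list(enrolled = attr(manifest, "enrolled"),
       excluded = attr(manifest, "excluded"),
       retained = attr(manifest, "retained"))
}

#' Apply per-reason exclusion counts to a manifest
#'
#' Adds the given exclusion counts to the audit trail and recomputes
#' `retained = enrolled - sum(all exclusions)`.
#'
#' @param manifest A `CohortManifest`.
#' @param exclusion_counts Named numeric vector: reason -> count.
#' @export
apply_exclusions <- function(manifest, exclusion_counts) {
  stopifnot(inherits(manifest, "CohortManifest"))
  if (length(exclusion_counts) && is.null(names(exclusion_counts)))
    names(exclusion_counts) <- paste0("reason_", seq_along(exclusion_counts))
  if (any(exclusion_counts < 0)) stop("exclusion counts must be >= 0")
  excluded <- c(attr(manifest, "excluded"), exclusion_counts)
  enrolled <- attr(manifest, "enrolled")
  if (sum(excluded) > enrolled)
    stop("exclusion counts (", sum(excluded), ") exceed enrolled (",
         enrolled, ")")
  cohort_manifest(as.data.frame(manifest), enrolled = enrolled,
                  excluded = excluded)
}

#' Read / write the manifest CSV
#'
#' Layout: `case_id, label, t2wi, nonfs_t1wi, d1, d2, d4, d6, mask,
#' reference_modality`, one row per lesion.
#' @param path CSV file path.
#' @name manifest_io
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cohort_manifest(df)
}

#' @rdname manifest_io
#' @param manifest A `CohortManifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "CohortManifest"))
  write.csv(as.data.frame(manifest), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert a DICOM series to NIfTI (unsupported stub)
#'
#' The runtime environment ships no DICOM reader, so series conversion is
#' not available; convert series to NIfTI upstream and load those instead.
#' @param series_dir Directory containing a DICOM series.
#' @param out_path Output NIfTI path.
#' @export
dicom_to_nifti <- function(series_dir, out_path) {
  stop("DICOM conversion is not supported in this build: no DICOM reader ",
       "is available in the runtime environment. Convert the series to ",
       "NIfTI with external tooling and use load_volume().")
}
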