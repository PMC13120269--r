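# Volume, mask, and cohort-table IO with geometric validation.
#
# Volumes are stored as plain S3 objects: a 3D numeric array plus per-axis
# voxel spacing (mm) and the physical position of voxel (1,1,1) (mm, voxel
# centers). On load, NIfTI images are reoriented to the canonical RAS axis
# order (x = left-right, y = anterior-posterior, z = inferior-superior) so
# that the contralateral mirror operation is well defined.

GRID_TOL <- 1e-3  # mm tolerance when comparing spacing/origin of two grids

MASK_ROLES <- c("tumor", "shell", "exclusion", "reference")

#' Construct an image volume
#'
#' An `image_volume` is a 3D scalar grid (for this package, ADC values in
#' units of 10^-3 mm^2/s) with physical voxel spacing and origin. Axes follow
#' the canonical order x = left-right, y = anterior-posterior,
#' z = inferior-superior.
#'
#' @param data 3D numeric array. `NA` marks missing voxels.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin Numeric length-3, physical position (mm) of the center of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all three dimensions must be positive", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite values", call. = FALSE)
  if (any(!is.finite(data) & !is.na(data)))
    stop("voxel values must be finite or NA", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary mask on a volume grid
#'
#' @param data 3D array; any nonzero (and non-`NA`) value is treated as 1.
#' @param spacing,origin As in [image_volume()].
#' @param role One of `"tumor"`, `"shell"`, `"exclusion"`, `"reference"`.
#'   Only exclusion masks may be empty.
#' @return An object of class `binary_mask` with logical `data`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        role = "tumor") {
  role <- match.arg(role, MASK_ROLES)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array", call. = FALSE)
  d <- array(!is.na(data) & data != 0, dim = dim(data))
  if (!any(d) && role != "exclusion")
    stop(sprintf("empty-mask error: '%s' mask has no nonzero voxel", role),
         call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values", call. = FALSE)
  structure(list(data = d, spacing = spacing, origin = origin, role = role),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask (%s): %d / %s voxels set\n", x$role,
              sum(x$data), format(length(x$data))))
  invisible(x)
}

same_grid <- function(a, b, tol = GRID_TOL) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file, reorients it to the canonical RAS axis order and
#' extracts spacing and origin from the header affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("dimensionality error: expected a 3D image, got %dD",
                 length(dim(img))), call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3],
               origin = as.numeric(aff[1:3, 4]))
}

#' Write a volume or mask to NIfTI
#'
#' @param x An [image_volume()] or [binary_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- if (inherits(x, "binary_mask")) array(as.numeric(x$data),
                                               dim = dim(x$data)) else x$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask and validate it against a reference volume
#'
#' Values are binarized (nonzero to 1). The mask grid must match the
#' reference grid to within 1e-3 mm on spacing and origin and have identical
#' dimensions.
#'
#' @param path NIfTI file path.
#' @param reference The [image_volume()] the mask annotates.
#' @param role Mask role; only `"exclusion"` masks may be empty.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, reference, role = "tumor") {
  v <- read_volume(path)
  if (!same_grid(v, reference))
    stop("geometry error: mask grid does not match reference volume",
         call. = FALSE)
  binary_mask(v$data, spacing = reference$spacing, origin = reference$origin,
              role = role)
}

# ---- cohort tables ---------------------------------------------------------

COHORT_METRICS <- c("adc_tumor", "adc_shell1", "adc_shell2", "adc_shell3",
                    "adc_reference", "radc_tumor", "radc_shell1",
                    "radc_shell2", "radc_shell3", "ratio_shell1",
                    "ratio_shell2", "ratio_shell3")
SUBTYPE_LEVELS <- c("LumA", "LumB", "HER2E", "TNBC")

#' Validate a cohort table
#'
#' Checks the per-patient schema: unique `id`, categorical fields drawn from
#' their stated sets (`pN_status`/`LVI` in \{0,1\}, `molecular_subtype` in
#' \{LumA, LumB, HER2E, TNBC\}, `grade` in \{1,2,3\}, `ki67` in \[0,1\]),
#' and strictly positive metric values where present. Missing values are
#' kept as `NA` and excluded pairwise by downstream statistics.
#'
#' @param df A data frame with one row per patient.
#' @return The validated data frame (classed `cohort_table`).
#' @export
validate_cohort <- function(df) {
  if (!"id" %in% names(df))
    stop("validation error: cohort table must have an 'id' column",
         call. = FALSE)
  if (anyDuplicated(df$id))
    stop("validation error: duplicated patient ids", call. = FALSE)
  chk01 <- function(col) {
    v <- df[[col]]
    if (!is.null(v) && !all(is.na(v) | v %in% c(0, 1)))
      stop(sprintf("validation error: '%s' must be 0/1", col), call. = FALSE)
  }
  chk01("pN_status"); chk01("LVI")
  if (!is.null(df$molecular_subtype)) {
    v <- as.character(df$molecular_subtype)
    if (!all(is.na(v) | v %in% SUBTYPE_LEVELS))
      stop("validation error: unknown molecular subtype", call. = FALSE)
    df$molecular_subtype <- factor(v, levels = SUBTYPE_LEVELS)
  }
  if (!is.null(df$grade) && !all(is.na(df$grade) | df$grade %in% 1:3))
    stop("validation error: 'grade' must be 1, 2 or 3", call. = FALSE)
  if (!is.null(df$ki67) &&
      !all(is.na(df$ki67) | (df$ki67 >= 0 & df$ki67 <= 1)))
    stop("validation error: 'ki67' must lie in [0, 1]", call. = FALSE)
  for (m in intersect(c(COHORT_METRICS, "tumor_volume_mm3"), names(df))) {
    v <- df[[m]]
    if (!all(is.na(v) | v > 0))
      stop(sprintf("validation error: '%s' must be positive where present",
                   m), call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from CSV
#'
#' Expects an RFC-4180 CSV with a header row naming the schema fields
#' (`id`, the 12 per-patient ADC metrics, `tumor_volume_mm3`, `pN_status`,
#' `LVI`, `molecular_subtype`, `grade`, `ki67`). Unknown columns are
#' preserved but ignored by analyses; empty cells become `NA`.
#'
#' @param path CSV file path.
#' @return A validated `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  validate_cohort(df)
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Outcome prevalence in a cohort
#'
#' @param cohort A cohort table.
#' @param outcome Name of a 0/1 outcome column (default `"pN_status"`).
#' @return Fraction of non-missing rows with outcome 1.
#' @export
prevalence <- function(cohort, outcome = "pN_status") {
  v <- cohort[[outcome]]
  if (is.null(v)) stop(sprintf("no column '%s'", outcome), call. = FALSE)
  mean(v[!is.na(v)] == 1)
}
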