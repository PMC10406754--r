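#' Construct a 3D label volume
#'
#' A `label_volume` is the unit of segmentation I/O: a 3D grid of
#' non-negative integer labels together with the physical voxel size along
#' each stored axis. Volumes are kept in the file's native array order; no
#' reorientation is performed, and all downstream metrics consume the
#' spacing per stored axis (they are orientation-invariant).
#'
#' @param voxels 3D array of non-negative integers (numeric arrays whose
#'   values are within `1e-6` of integers are accepted and rounded).
#' @param spacing numeric length-3, physical voxel size in mm per axis;
#'   strictly positive and finite.
#' @param source_id optional case identifier string.
#' @return An object of class `label_volume` with fields `voxels`,
#'   `spacing`, `source_id`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), source_id = NA_character_) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions")
  if (!is.numeric(voxels))
    stop("`voxels` must be numeric or integer")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("`voxels` contains non-finite values")
  if (!is.integer(voxels)) {
    r <- round(voxels)
    if (max(abs(voxels - r)) > 1e-6)
      stop("non-integer labels: voxel values deviate from integers by more than 1e-6")
    voxels <- r
    storage.mode(voxels) <- "integer"
  }
  if (min(voxels) < 0L)
    stop("label values must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 source_id = as.character(source_id)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$voxels)))
  cat(sprintf("<label_volume> %s  %s voxels  spacing %s mm  labels {%s}\n",
              if (is.na(x$source_id)) "" else x$source_id,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(labs, collapse = ",")))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

is_label_volume <- function(x) inherits(x, "label_volume")

#' Read a label volume from a NIfTI-1 file
#'
#' Voxel spacing is taken from the header `pixdim`; the rotation/flip
#' content of the affine is ignored (documented limitation: volumes are
#' compared on identical grids, so orientation metadata never enters the
#' metrics). Stored values within `1e-6` of an integer are rounded;
#' anything else is an error rather than a silent cast.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [label_volume]; `source_id` is the file name without extension.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path, "': ",
                                           conditionMessage(e)))
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3D image, got ", nd, "D: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  label_volume(arr, spacing = sp, source_id = strip_nii_ext(basename(path)))
}

strip_nii_ext <- function(x) sub("\\.nii(\\.gz)?$", "", x)

#' Write a label volume to a NIfTI-1 file
#'
#' Data are written integer-typed with spacing encoded in the header, so
#' that [read_label_volume] after `write_label_volume` is the identity on
#' voxels and spacing.
#'
#' @param volume a [label_volume].
#' @param path output path (`.nii` or `.nii.gz`); parent directories are
#'   created if needed.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(is_label_volume(volume))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  dt <- if (max(volume$voxels) <= 32767L) "int16" else "int32"
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Check that two volumes live on the same grid
#'
#' Two volumes are comparable iff their shapes are identical and their
#' spacings agree within `1e-6` relative tolerance. All pairwise metrics
#' require comparability; volumes on different grids are refused rather
#' than resampled.
#'
#' @param reference,prediction [label_volume] objects.
#' @return Invisibly `TRUE`; raises an error naming the offending axis
#'   otherwise.
#' @export
check_comparable <- function(reference, prediction) {
  stopifnot(is_label_volume(reference), is_label_volume(prediction))
  dr <- dim(reference$voxels); dp <- dim(prediction$voxels)
  for (ax in 1:3) {
    if (dr[ax] != dp[ax])
      stop(sprintf("shape mismatch on axis %d: %d vs %d", ax, dr[ax], dp[ax]))
  }
  for (ax in 1:3) {
    sr <- reference$spacing[ax]; sp <- prediction$spacing[ax]
    if (abs(sr - sp) > 1e-6 * max(abs(sr), abs(sp)))
      stop(sprintf("spacing mismatch on axis %d: %g vs %g mm", ax, sr, sp))
  }
  invisible(TRUE)
}

#' Define a label map
#'
#' Maps structure names to integer label values, e.g. kidney = 1,
#' tumor = 2, with a designated background value that is not among the
#' named labels.
#'
#' @param ... named integer label values.
#' @param background background label value (default 0).
#' @return A named integer vector of class `label_map` with attribute
#'   `background`.
#' @examples
#' label_map(kidney = 1, tumor = 2)
#' @export
label_map <- function(..., background = 0L) {
  vals <- c(...)
  if (length(vals) == 0L) stop("at least one named label required")
  if (is.null(names(vals)) || any(names(vals) == ""))
    stop("all labels must be named")
  vals <- vapply(vals, function(v) as.integer(v), integer(1))
  if (anyDuplicated(vals)) stop("label values must be distinct")
  if (anyDuplicated(names(vals))) stop("label names must be distinct")
  background <- as.integer(background)
  if (background %in% vals) stop("background value must not be a named label")
  structure(vals, background = background, class = "label_map")
}

#' Default kidney/tumor label map
#'
#' Background/kidney/tumor = 0/1/2, the conventional scheme for renal
#' segmentation masks.
#' @return A [label_map].
#' @export
default_label_map <- function() label_map(kidney = 1L, tumor = 2L, background = 0L)

#' Parse a label map from a "name=value,name=value" string
#' @param text e.g. `"kidney=1,tumor=2"`.
#' @param background background label value.
#' @return A [label_map].
#' @export
parse_label_map <- function(text, background = 0L) {
  parts <- strsplit(trimws(strsplit(text, ",")[[1]]), "=")
  if (any(lengths(parts) != 2L))
    stop("label map must look like 'kidney=1,tumor=2'")
  vals <- as.integer(vapply(parts, `[`, "", 2L))
  names(vals) <- vapply(parts, `[`, "", 1L)
  do.call(label_map, c(as.list(vals), list(background = background)))
}
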