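#' @title Volumetric containers
#' @description
#' Three light S3 containers carry the pipeline's data together with their
#' geometry: [intensity_volume()] (scalar 3D image), [binary_mask()]
#' (logical 3D volume) and [label_volume()] (non-negative integer
#' parcellation).  Each holds the voxel size in mm, the 4x4 voxel-to-world
#' affine and the mapping of array axes to radiological views.
#' @name volumes
NULL

default_axis_roles <- function() c(sagittal = 1L, coronal = 2L, axial = 3L)

check_geometry <- function(data, voxel_size, affine) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims",
         call. = FALSE)
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three positive values (mm)", call. = FALSE)
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  invisible(TRUE)
}

#' Construct an intensity volume
#'
#' @param data 3D numeric array of voxel intensities.
#' @param voxel_size length-3 positive numeric, mm per axis.
#' @param affine 4x4 voxel-to-world matrix; default diag of voxel sizes.
#' @param axis_roles named integer vector mapping the views
#'   \code{sagittal}, \code{coronal}, \code{axial} to array axes.
#' @return An object of class \code{intensity_volume}.
#' @export
intensity_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                             axis_roles = default_axis_roles()) {
  data <- as.array(data)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  check_geometry(data, voxel_size, affine)
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 affine = affine, axis_roles = check_axis_roles(axis_roles)),
            class = "intensity_volume")
}

check_axis_roles <- function(axis_roles) {
  needed <- c("sagittal", "coronal", "axial")
  if (!all(needed %in% names(axis_roles)) ||
      !setequal(as.integer(axis_roles[needed]), 1:3))
    stop("axis_roles must map sagittal/coronal/axial onto axes 1..3", call. = FALSE)
  vapply(axis_roles[needed], as.integer, integer(1))
}

#' Construct a binary mask
#'
#' @inheritParams intensity_volume
#' @param data 3D logical (or coercible) array.
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                        axis_roles = default_axis_roles()) {
  data <- as.array(data)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  check_geometry(data, voxel_size, affine)
  storage.mode(data) <- "logical"
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 affine = affine, axis_roles = check_axis_roles(axis_roles)),
            class = "binary_mask")
}

#' Construct a label volume
#'
#' @inheritParams intensity_volume
#' @param data 3D array of non-negative integer labels; 0 is
#'   unknown/background.
#' @param label_names named character vector: names are label ids, values
#'   their anatomical names.  Every nonzero label present in \code{data}
#'   must appear.
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(data, label_names, voxel_size = c(1, 1, 1),
                         affine = NULL, axis_roles = default_axis_roles()) {
  data <- as.array(data)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  check_geometry(data, voxel_size, affine)
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE)) stop("labels must be non-negative", call. = FALSE)
  present <- setdiff(sort(unique(as.vector(data))), 0L)
  missing <- setdiff(as.character(present), names(label_names))
  if (length(missing))
    stop("labels present in the volume but absent from label_names: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(data = data, label_names = label_names,
                 voxel_size = as.numeric(voxel_size), affine = affine,
                 axis_roles = check_axis_roles(axis_roles)),
            class = "label_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 5), ", ", signif(max(x$data), 5),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " on (", signif(mask_volume_cm3(x), 5), " cm^3)\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      length(setdiff(unique(as.vector(x$data)), 0L)), " labels\n", sep = "")
  invisible(x)
}

#' Mask volume in cubic centimetres
#'
#' Number of true voxels times the voxel volume, in cm^3.
#'
#' @param m a [binary_mask()].
#' @return Non-negative scalar.
#' @export
mask_volume_cm3 <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  sum(m$data) * prod(m$voxel_size) / 1000
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-6))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same voxel grid (shape/voxel size mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

axis_roles_from_affine <- function(affine) {
  # A view axis is the world direction its slices stack along: L-R ->
  # sagittal, A-P -> coronal, S-I -> axial.  Pick, per array axis, the
  # dominant world component of the affine's direction columns; if the
  # assignment is not a permutation the affine is ambiguous and axis 3 is
  # treated as axial (identity fallback).
  dir <- affine[1:3, 1:3]
  dom <- apply(abs(dir), 2, which.max)
  if (!setequal(dom, 1:3)) return(default_axis_roles())
  roles <- c("sagittal", "coronal", "axial")[dom]  # view of each array axis
  out <- match(c("sagittal", "coronal", "axial"), roles)
  names(out) <- c("sagittal", "coronal", "axial")
  out
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) > 3L && all(dim(arr)[-(1:3)] == 1L))  # trailing singletons
    arr <- array(arr, dim(arr)[1:3])
  arr <- array(as.vector(arr), dim(arr))  # drop NIfTI header attributes
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  vs <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  list(data = arr, voxel_size = abs(vs), affine = aff,
       axis_roles = axis_roles_from_affine(aff))
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image as an [intensity_volume()]; voxel sizes and the
#' affine come from the header, and the view/axis mapping is derived from
#' the affine orientation.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path) {
  x <- read_nifti_array(path)
  intensity_volume(x$data, x$voxel_size, x$affine, x$axis_roles)
}

#' Read a NIfTI binary mask
#'
#' Voxels strictly greater than zero are true.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  x <- read_nifti_array(path)
  binary_mask(x$data > 0, x$voxel_size, x$affine, x$axis_roles)
}

#' Read a NIfTI parcellation
#'
#' @inheritParams read_volume
#' @param name_table named character vector (or data frame with columns
#'   \code{label_id} and \code{name}) naming every nonzero label present.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, name_table) {
  x <- read_nifti_array(path)
  if (is.data.frame(name_table)) {
    nm <- as.character(name_table$name)
    names(nm) <- as.character(name_table$label_id)
    name_table <- nm
  }
  label_volume(round(x$data), name_table, x$voxel_size, x$affine, x$axis_roles)
}

write_nifti_array <- function(data, voxel_size, affine, path, datatype) {
  x <- structure(data, pixdim = voxel_size)
  x <- RNifti::`qform<-`(x, structure(affine, code = 2L))
  RNifti::writeNifti(RNifti::asNifti(x, datatype = datatype), path)
  invisible(path)
}

#' Write volumes to NIfTI
#'
#' Lossless round trip of voxel data and affine; masks are written as uint8
#' 0/1, label volumes as int32, intensity volumes as float64.
#'
#' @param x an [intensity_volume()], [binary_mask()] or [label_volume()].
#' @param path destination \code{.nii} / \code{.nii.gz} path.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "binary_mask"))
    write_nifti_array(array(as.integer(x$data), dim(x$data)), x$voxel_size,
                      x$affine, path, "uint8")
  else if (inherits(x, "label_volume"))
    write_nifti_array(x$data, x$voxel_size, x$affine, path, "int32")
  else if (inherits(x, "intensity_volume"))
    write_nifti_array(x$data, x$voxel_size, x$affine, path, "double")
  else stop("unsupported volume type: ", paste(class(x), collapse = "/"),
            call. = FALSE)
}

#' @rdname write_volume
#' @param m a [binary_mask()].
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "binary_mask"))
  write_volume(m, path)
}

#' Convert a volume to the uint8 class range
#'
#' Linearly rescales intensities from the whole-volume \code{[min, max]} to
#' \code{[0, 255]} and rounds (half away from zero) to integers, mirroring a
#' uint8 conversion.  A constant volume maps to all zeros: it carries no
#' structure and the degenerate rescale is undefined.
#'
#' @param v an [intensity_volume()].
#' @return An [intensity_volume()] with integer values in \code{[0, 255]}.
#' @export
to_uint8 <- function(v) {
  stopifnot(inherits(v, "intensity_volume"))
  x <- v$data
  if (any(!is.finite(x)))
    stop("volume contains NaN/Inf voxels; cannot convert to uint8", call. = FALSE)
  lo <- min(x); hi <- max(x)
  out <- if (hi > lo) round_half_away((x - lo) / (hi - lo) * 255) else array(0, dim(x))
  intensity_volume(out, v$voxel_size, v$affine, v$axis_roles)
}

# round half away from zero (uint8 semantics), vectorised
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
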