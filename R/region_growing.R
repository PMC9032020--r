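#' Pipeline configuration
#'
#' One point in the segmentation parameter grid: the standardization method,
#' the brain-mask smoothing standard deviation (voxels), the region-growing
#' tolerance (fraction of the uint8 class range; the admission threshold in
#' intensity units is \code{tolerance * 255}), the ADJ saturation fraction
#' (ADJ family only), and the final output smoothing standard deviation.
#' Defaults are the optimal local contrast-adjustment settings (mask
#' smoothing 0.5, tolerance 0.05, saturation 10\%, final smoothing 0.5).
#'
#' @param method a [standardization_method()] or tag such as \code{"adj-l"}.
#' @param tolerance admission tolerance as a fraction of the class range.
#' @param mask_smoothing_std brain-mask Gaussian std, voxels.
#' @param final_smoothing_std output Gaussian std, voxels.
#' @param saturation ADJ saturation fraction; must be supplied for ADJ and
#'   omitted (NULL) for NORM.
#' @param exclude_ventricles logical: drop ventricle labels from the brain
#'   mask before growth (requires a parcellation at segmentation time).
#' @param ventricle_ids ventricle label ids used when
#'   \code{exclude_ventricles} is set.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(method = "adj-l", tolerance = 0.05,
                            mask_smoothing_std = 0.5,
                            final_smoothing_std = 0.5,
                            saturation = if (parse_method(method)$family == "adj") 0.10 else NULL,
                            exclude_ventricles = FALSE,
                            ventricle_ids = integer(0)) {
  method <- parse_method(method)
  if (!is.finite(tolerance) || tolerance <= 0 || tolerance > 1)
    stop("tolerance must be a fraction of the class range in (0, 1]", call. = FALSE)
  if (!is.finite(mask_smoothing_std) || mask_smoothing_std <= 0)
    stop("mask_smoothing_std must be positive", call. = FALSE)
  if (!is.finite(final_smoothing_std) || final_smoothing_std <= 0)
    stop("final_smoothing_std must be positive", call. = FALSE)
  if (method$family == "adj" && is.null(saturation))
    stop("ADJ methods require a saturation fraction", call. = FALSE)
  if (method$family == "norm" && !is.null(saturation))
    stop("saturation applies to the ADJ family only", call. = FALSE)
  structure(list(method = method, tolerance = tolerance,
                 mask_smoothing_std = mask_smoothing_std,
                 final_smoothing_std = final_smoothing_std,
                 saturation = saturation,
                 exclude_ventricles = isTRUE(exclude_ventricles),
                 ventricle_ids = as.integer(ventricle_ids)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> ", format(x$method),
      " | mask std ", x$mask_smoothing_std,
      " | tolerance ", x$tolerance,
      if (!is.null(x$saturation)) paste0(" | saturation ", x$saturation),
      " | final std ", x$final_smoothing_std,
      if (x$exclude_ventricles) " | ventricles excluded", "\n", sep = "")
  invisible(x)
}

check_seed <- function(seed, dims) {
  seed <- as.integer(round(seed))
  if (length(seed) != 3L)
    stop("seed must be a voxel index triple (i, j, k)", call. = FALSE)
  if (any(seed < 1L) || any(seed > dims))
    stop("seed ", paste(seed, collapse = ","),
         " outside volume bounds ", paste(dims, collapse = "x"), call. = FALSE)
  seed
}

#' Seeded best-first region growing
#'
#' Grows a 6-connected region from the seed inside the brain mask.  At every
#' iteration the queued neighbour whose intensity is closest to the current
#' mean intensity of the region is examined; it is admitted if that
#' difference is strictly below \code{tolerance * 255}, and its in-mask
#' 6-neighbours join the queue.  Queued differences are re-evaluated against
#' the drifting mean at each iteration.  Growth stops when the queue is
#' empty or the minimal difference reaches the threshold.  Ties are broken
#' by lexicographic \code{(i, j, k)} order, making the result deterministic.
#'
#' @param v an [intensity_volume()] standardized to \code{[0, 255]}
#'   (integer-valued, as produced by [to_uint8()] / [standardize()]).
#' @param brain a [binary_mask()] confining the growth.
#' @param seed voxel index triple (1-based), inside the brain mask.
#' @param tolerance admission tolerance as a fraction of the class range.
#' @return A [binary_mask()]: the grown region (contains the seed).
#' @export
grow <- function(v, brain, seed, tolerance) {
  stopifnot(inherits(v, "intensity_volume"), inherits(brain, "binary_mask"))
  stop_if_grid_mismatch(v, brain, "volume and brain mask")
  check_class_range(v)
  dims <- dim(v$data)
  seed <- check_seed(seed, dims)
  if (!brain$data[seed[1], seed[2], seed[3]])
    stop("seed ", paste(seed, collapse = ","), " lies outside the brain mask",
         call. = FALSE)
  reg <- grow_region_cpp(as.numeric(v$data), as.logical(brain$data),
                         as.integer(dims), seed - 1L, tolerance * 255)
  binary_mask(array(reg, dims), v$voxel_size, v$affine, v$axis_roles)
}

#' Smooth and re-binarize a grown region
#'
#' Casts the region to \code{{0, 1}}, smooths it with an isotropic 3D
#' Gaussian of standard deviation \code{final_smoothing_std} voxels, and
#' binarizes at 10\% of the maximum of the smoothed field (inclusive, so a
#' lone voxel survives a tiny sigma).
#'
#' @param region a [binary_mask()], typically the output of [grow()].
#' @param final_smoothing_std Gaussian std in voxels.
#' @return A [binary_mask()].
#' @export
finalize_region <- function(region, final_smoothing_std) {
  stopifnot(inherits(region, "binary_mask"))
  if (!sum(region$data)) {
    warning("empty region: nothing to smooth", call. = FALSE)
    return(region)
  }
  s <- gauss_smooth_3d(array(as.numeric(region$data), dim(region$data)),
                       final_smoothing_std)
  binary_mask(s >= 0.10 * max(s), region$voxel_size, region$affine,
              region$axis_roles)
}

#' Segment a resection cavity
#'
#' Runs the full pipeline: uint8 conversion of the postoperative volume,
#' intensity standardization per the configuration, Gaussian preprocessing
#' of the preoperative brain mask (optionally excluding ventricle labels),
#' seeded region growing, and final smoothing/binarization.  The final mask
#' is intersected with the growth mask so the model never extends outside
#' the brain space the region grew in.
#'
#' @param post_mri postoperative [intensity_volume()].
#' @param pre_mask preoperative [binary_mask()] (skull-strip output),
#'   co-registered with \code{post_mri}.
#' @param seed voxel index triple (1-based) inside the resection cavity.
#' @param config a [pipeline_config()].
#' @param labels optional [label_volume()] parcellation; required when
#'   \code{config$exclude_ventricles} is set.
#' @return An object of class \code{resection_model}: list with the final
#'   \code{mask} ([binary_mask()]), the \code{seed}, the \code{config} and
#'   the cavity \code{volume_cm3}.
#' @export
segment <- function(post_mri, pre_mask, seed, config = pipeline_config(),
                    labels = NULL) {
  stopifnot(inherits(post_mri, "intensity_volume"),
            inherits(pre_mask, "binary_mask"),
            inherits(config, "pipeline_config"))
  stop_if_grid_mismatch(post_mri, pre_mask, "postoperative MRI and brain mask")
  if (!isTRUE(all.equal(post_mri$affine, pre_mask$affine, tolerance = 1e-4)))
    stop("postoperative MRI and brain mask affines differ; inputs must be co-registered",
         call. = FALSE)

  u <- to_uint8(post_mri)
  s <- standardize(u, config$method, config$saturation)
  bm <- prepare_brain_mask(pre_mask, config$mask_smoothing_std)
  if (config$exclude_ventricles) {
    if (is.null(labels))
      stop("exclude_ventricles requires a parcellation (labels)", call. = FALSE)
    bm <- exclude_ventricles(bm, labels, config$ventricle_ids)
  }

  seed <- check_seed(seed, dim(s$data))
  if (!bm$data[seed[1], seed[2], seed[3]])
    stop("seed lies outside the (preprocessed) brain mask", call. = FALSE)

  region <- grow(s, bm, seed, config$tolerance)
  final <- finalize_region(region, config$final_smoothing_std)
  final$data <- final$data & bm$data

  structure(list(mask = final, seed = seed, config = config,
                 volume_cm3 = mask_volume_cm3(final)),
            class = "resection_model")
}

#' @export
print.resection_model <- function(x, ...) {
  cat("<resection_model> ", sum(x$mask$data), " voxels (",
      signif(x$volume_cm3, 5), " cm^3), seed ",
      paste(x$seed, collapse = ","), ", method ",
      format(x$config$method), "\n", sep = "")
  invisible(x)
}
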