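#' 3D Gaussian smoothing of an array
#'
#' Separable convolution with an isotropic Gaussian sampled at integer
#' offsets, truncated at 4 sigma (kernel radius \code{ceiling(4*sigma)}) and
#' normalized to unit sum.  Out-of-volume voxels contribute zero (the
#' background outside the head is genuinely zero).
#'
#' @param x 3D numeric array.
#' @param sigma standard deviation in voxels; \code{sigma <= 0} returns
#'   \code{x} unchanged.
#' @return 3D numeric array of the same shape.
#' @export
gauss_smooth_3d <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3L)
  if (sigma <= 0) return(x)
  r <- ceiling(4 * sigma)
  off <- -r:r
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- x
  for (axis in 1:3) out <- convolve_axis(out, k, off, axis)
  out
}

convolve_axis <- function(x, k, off, axis) {
  dm <- dim(x)
  acc <- array(0, dm)
  idx <- lapply(dm, seq_len)
  for (t in seq_along(k)) {
    d <- off[t]
    if (abs(d) >= dm[axis]) next
    dst <- idx; src <- idx
    if (d >= 0) {
      dst[[axis]] <- seq.int(1 + d, dm[axis])
      src[[axis]] <- seq.int(1, dm[axis] - d)
    } else {
      dst[[axis]] <- seq.int(1, dm[axis] + d)
      src[[axis]] <- seq.int(1 - d, dm[axis])
    }
    acc[dst[[1]], dst[[2]], dst[[3]]] <-
      acc[dst[[1]], dst[[2]], dst[[3]]] +
      k[t] * x[src[[1]], src[[2]], src[[3]]]
  }
  acc
}

#' Standardization methods
#'
#' The four intensity-standardization variants: contrast-stretch adjustment
#' (\code{adj}) or min-max normalization (\code{norm}), applied to the whole
#' volume (\code{global}) or slice by slice along the axial axis
#' (\code{local}).
#'
#' @param family \code{"adj"} or \code{"norm"}.
#' @param scope \code{"global"} or \code{"local"}.
#' @return An object of class \code{standardization_method}.
#' @export
standardization_method <- function(family = c("adj", "norm"),
                                   scope = c("global", "local")) {
  family <- match.arg(family)
  scope <- match.arg(scope)
  structure(list(family = family, scope = scope),
            class = "standardization_method")
}

#' Parse a method tag such as \code{"adj-l"}
#'
#' @param x one of \code{"adj-g"}, \code{"adj-l"}, \code{"norm-g"},
#'   \code{"norm-l"} (or an existing \code{standardization_method}).
#' @return A [standardization_method()].
#' @export
parse_method <- function(x) {
  if (inherits(x, "standardization_method")) return(x)
  parts <- strsplit(tolower(x), "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("adj", "norm") ||
      !parts[2] %in% c("g", "l"))
    stop("unknown standardization method: ", x,
         " (expected adj-g, adj-l, norm-g or norm-l)", call. = FALSE)
  standardization_method(parts[1], if (parts[2] == "g") "global" else "local")
}

#' @export
format.standardization_method <- function(x, ...)
  paste0(x$family, "-", substr(x$scope, 1, 1))

#' @export
print.standardization_method <- function(x, ...) {
  cat("<standardization_method>", format(x), "\n")
  invisible(x)
}

# apply f (array -> array) per scope unit: whole volume, or each axial slice
apply_scoped <- function(v, scope, f) {
  x <- v$data
  if (scope == "global") {
    out <- f(x)
  } else {
    ax <- v$axis_roles[["axial"]]
    out <- x
    idx <- lapply(dim(x), seq_len)
    for (s in seq_len(dim(x)[ax])) {
      ii <- idx
      ii[[ax]] <- s
      slice <- x[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
      out[ii[[1]], ii[[2]], ii[[3]]] <- f(slice)
    }
  }
  intensity_volume(out, v$voxel_size, v$affine, v$axis_roles)
}

#' Contrast-stretch adjustment (ADJ)
#'
#' Linearly remaps intensities so that values at or below the
#' \code{saturation}-th lower quantile saturate to 0 and values at or above
#' the \code{(1 - saturation)}-th upper quantile saturate to 255, linear in
#' between and rounded to the integer class range.  The saturation fraction
#' is split equally between the bottom and top tails.  With
#' \code{scope = "local"} quantiles are computed and the remap applied per
#' axial slice.  A degenerate unit (equal quantiles) maps to all zeros.
#'
#' @param v an [intensity_volume()] in the class range \code{[0, 255]}.
#' @param saturation fraction in \code{[0, 0.5)} of voxels saturated at each
#'   tail.
#' @param scope \code{"global"} or \code{"local"}.
#' @return An [intensity_volume()] with integer values in \code{[0, 255]}.
#' @export
adjust_contrast <- function(v, saturation, scope = c("global", "local")) {
  stopifnot(inherits(v, "intensity_volume"))
  scope <- match.arg(scope)
  if (!is.finite(saturation) || saturation < 0 || saturation >= 0.5)
    stop("saturation must lie in [0, 0.5)", call. = FALSE)
  check_class_range(v)
  apply_scoped(v, scope, function(x) {
    q <- quantile(x, c(saturation, 1 - saturation), names = FALSE, type = 7)
    remap_linear(x, q[1], q[2])
  })
}

#' Min-max normalization (NORM)
#'
#' Remaps intensities by the intensity span: \code{(x - min) / (max - min)}
#' rescaled to \code{[0, 255]} and rounded.  With \code{scope = "local"} the
#' min/max are taken per axial slice.  Constant units map to zeros.
#'
#' @inheritParams adjust_contrast
#' @return An [intensity_volume()] with integer values in \code{[0, 255]}.
#' @export
normalize_intensity <- function(v, scope = c("global", "local")) {
  stopifnot(inherits(v, "intensity_volume"))
  scope <- match.arg(scope)
  check_class_range(v)
  apply_scoped(v, scope, function(x) remap_linear(x, min(x), max(x)))
}

remap_linear <- function(x, lo, hi) {
  if (!(hi > lo)) return(array(0, dim(x)))
  y <- (x - lo) / (hi - lo) * 255
  round_half_away(pmin(pmax(y, 0), 255))
}

check_class_range <- function(v) {
  if (any(!is.finite(v$data)))
    stop("volume contains non-finite voxels", call. = FALSE)
  if (min(v$data) < 0 || max(v$data) > 255)
    stop("volume is not in the uint8 class range [0,255]; run to_uint8() first",
         call. = FALSE)
  invisible(TRUE)
}

#' Standardize a volume
#'
#' Dispatches to [adjust_contrast()] or [normalize_intensity()] according to
#' the method's family and scope.
#'
#' @param v an [intensity_volume()] in the class range.
#' @param method a [standardization_method()] or tag (\code{"adj-l"}, ...).
#' @param saturation saturation fraction; required for the ADJ family,
#'   ignored for NORM.
#' @return An [intensity_volume()].
#' @export
standardize <- function(v, method, saturation = NULL) {
  method <- parse_method(method)
  if (method$family == "adj") {
    if (is.null(saturation))
      stop("the ADJ family requires a saturation fraction", call. = FALSE)
    adjust_contrast(v, saturation, method$scope)
  } else {
    normalize_intensity(v, method$scope)
  }
}

#' Preprocess the preoperative brain mask
#'
#' Casts the mask to \code{{0, 1}}, smooths it with an isotropic 3D Gaussian
#' of the given standard deviation (voxels) to soften its margins, and
#' re-binarizes keeping every voxel with smoothed value strictly greater
#' than 0.01.  Small sigmas give a conservative mask, large sigmas a more
#' extended, smoother one.
#'
#' @param m a [binary_mask()].
#' @param smoothing_std Gaussian standard deviation in voxels.
#' @return A [binary_mask()].
#' @export
prepare_brain_mask <- function(m, smoothing_std) {
  stopifnot(inherits(m, "binary_mask"))
  if (!sum(m$data)) {
    warning("empty brain mask: smoothing has no support", call. = FALSE)
    return(m)
  }
  s <- gauss_smooth_3d(array(as.numeric(m$data), dim(m$data)), smoothing_std)
  binary_mask(s > 0.01, m$voxel_size, m$affine, m$axis_roles)
}

#' Exclude ventricle labels from a brain mask
#'
#' Sets mask voxels whose parcellation label belongs to
#' \code{ventricle_ids} to false; useful when the resection borders the
#' ventricular space, harmless otherwise.
#'
#' @param m a [binary_mask()].
#' @param labels a [label_volume()] on the same grid.
#' @param ventricle_ids integer vector of ventricle label ids.
#' @return A [binary_mask()], a subset of \code{m}.
#' @export
exclude_ventricles <- function(m, labels, ventricle_ids) {
  stopifnot(inherits(m, "binary_mask"), inherits(labels, "label_volume"))
  stop_if_grid_mismatch(m, labels, "mask and parcellation")
  keep <- m$data & !(labels$data %in% as.integer(ventricle_ids))
  binary_mask(array(keep, dim(m$data)), m$voxel_size, m$affine, m$axis_roles)
}
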