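mask_data <- function(x) {
  if (inherits(x, "binary_mask")) x$data
  else if (is.array(x) && is.logical(x)) x
  else stop("expected a binary_mask or logical array", call. = FALSE)
}

#' Dice similarity coefficient
#'
#' \code{DSC = 2 |X intersect Y| / (|X| + |Y|)}, the standard volumetric
#' overlap score in \code{[0, 1]} (above 0.6 good, 0.7 high, 0.8 excellent).
#'
#' @param x,y [binary_mask()]s (or logical arrays) of the same shape, not
#'   both empty.
#' @return Scalar in \code{[0, 1]}.
#' @export
dice <- function(x, y) {
  a <- mask_data(x); b <- mask_data(y)
  if (!identical(dim(a), dim(b)))
    stop("dice: masks have different shapes", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    stop("dice is undefined for two empty masks", call. = FALSE)
  2 * sum(a & b) / (na + nb)
}

#' Volume ratio between two masks
#'
#' Agreement score \code{min(|X|, |Y|) / max(|X|, |Y|)} in \code{[0, 1]};
#' symmetric, 1 for equal voxel counts.
#'
#' @inheritParams dice
#' @return Scalar in \code{[0, 1]}.
#' @export
volume_ratio <- function(x, y) {
  na <- sum(mask_data(x)); nb <- sum(mask_data(y))
  if (max(na, nb) == 0)
    stop("volume_ratio is undefined for two empty masks", call. = FALSE)
  min(na, nb) / max(na, nb)
}

#' Mean quadratic discard
#'
#' \code{MQD = sum_i (MaxS_i - MaxP_i)^2 / N}: the mean squared gap between
#' the best DSC reachable by tuning the tolerance only (\code{MaxS}) and the
#' best DSC over the whole parameter grid (\code{MaxP}).  A small MQD means
#' single-parameter tuning nearly matches full tuning.
#'
#' @param max_s numeric vector of per-case maximum-selectable DSCs, or a
#'   [tuning_bounds()] object (then \code{max_p} is taken from it).
#' @param max_p numeric vector of per-case maximum-possible DSCs.
#' @return Non-negative scalar.
#' @export
mqd <- function(max_s, max_p = NULL) {
  if (inherits(max_s, "tuning_bounds")) {
    max_p <- max_s$max_p
    max_s <- max_s$max_s
  }
  if (length(max_s) != length(max_p) || !length(max_s))
    stop("max_s and max_p must be paired non-empty vectors", call. = FALSE)
  mean((max_s - max_p)^2)
}

# Table of tested values for the factorial sweep
grid_values <- function() {
  list(mask_smoothing_std = c(0.5, 1, 3),
       tolerance = c(0.02, 0.05, 0.08, 0.11, 0.14, 0.17, 0.20),
       saturation = c(0.001, 0.005, 0.01, 0.05, 0.10, 0.15),
       final_smoothing_std = c(0.1, 0.5, 1, 1.5))
}

#' Enumerate the parameter grid for a standardization method
#'
#' Full Cartesian product of the tested values: mask smoothing
#' \{0.5, 1, 3\}, tolerance \{0.02...0.20\} (7 values), final smoothing
#' \{0.1, 0.5, 1, 1.5\}, and for the ADJ family the saturation fraction
#' \{0.001...0.15\} (6 values): 504 configurations for ADJ methods, 84 for
#' NORM.
#'
#' @param method a [standardization_method()] or tag.
#' @return A data frame with one row per configuration (columns
#'   \code{config_id}, \code{method}, \code{mask_smoothing_std},
#'   \code{tolerance}, \code{saturation} (NA for NORM),
#'   \code{final_smoothing_std}).
#' @export
enumerate_grid <- function(method) {
  method <- parse_method(method)
  gv <- grid_values()
  sat <- if (method$family == "adj") gv$saturation else NA_real_
  g <- expand.grid(final_smoothing_std = gv$final_smoothing_std,
                   tolerance = gv$tolerance,
                   saturation = sat,
                   mask_smoothing_std = gv$mask_smoothing_std,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("mask_smoothing_std", "tolerance", "saturation",
             "final_smoothing_std")]
  g$method <- format(method)
  g$config_id <- sprintf("%s|m%g|t%g|s%s|f%g", g$method,
                         g$mask_smoothing_std, g$tolerance,
                         ifelse(is.na(g$saturation), "-",
                                format(g$saturation)),
                         g$final_smoothing_std)
  rownames(g) <- NULL
  g[, c("config_id", "method", "mask_smoothing_std", "tolerance",
        "saturation", "final_smoothing_std")]
}

as_config_row <- function(row) {
  pipeline_config(method = row$method, tolerance = row$tolerance,
                  mask_smoothing_std = row$mask_smoothing_std,
                  final_smoothing_std = row$final_smoothing_std,
                  saturation = if (is.na(row$saturation)) NULL else row$saturation)
}

#' Run a factorial parameter sweep
#'
#' Segments every case with every configuration of the method's grid and
#' scores it against the case's gold-standard mask with [dice()].  A failing
#' segmentation (e.g. a seed falling outside a heavily smoothed mask) is
#' recorded as DSC 0 with a warning rather than aborting the sweep.
#' Intermediate products that do not depend on all grid axes (standardized
#' volumes, preprocessed masks, pre-finalize regions) are cached, so the
#' composition is identical to [segment()] configuration by configuration.
#'
#' @param cases list of cases; each a list with elements \code{post}
#'   ([intensity_volume()]), \code{mask} ([binary_mask()]), \code{seed}
#'   (voxel triple) and \code{gold} ([binary_mask()]), plus an optional
#'   \code{id}.
#' @param method a [standardization_method()] or tag.
#' @return A data frame of class \code{sweep_result}: one row per
#'   (case, configuration) with the grid columns and \code{dsc}.
#' @export
run_sweep <- function(cases, method) {
  method <- parse_method(method)
  grid <- enumerate_grid(method)
  gv <- grid_values()
  sats <- if (method$family == "adj") gv$saturation else NA_real_
  out <- vector("list", length(cases))

  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    id <- if (!is.null(case$id)) case$id else paste0("case", ci)
    u <- to_uint8(case$post)
    seed <- check_seed(case$seed, dim(u$data))
    rows <- vector("list", nrow(grid))
    ri <- 1L
    masks <- lapply(gv$mask_smoothing_std,
                    function(ms) prepare_brain_mask(case$mask, ms))
    for (si in seq_along(sats)) {
      s <- standardize(u, method, if (is.na(sats[si])) NULL else sats[si])
      for (mi in seq_along(gv$mask_smoothing_std)) {
        bm <- masks[[mi]]
        for (tol in gv$tolerance) {
          region <- tryCatch(grow(s, bm, seed, tol), error = function(e) e)
          for (fs in gv$final_smoothing_std) {
            d <- if (inherits(region, "error")) {
              warning("case ", id, ": segmentation failed (",
                      conditionMessage(region), "); DSC recorded as 0",
                      call. = FALSE)
              0
            } else {
              final <- finalize_region(region, fs)
              final$data <- final$data & bm$data
              dice(final, case$gold)
            }
            rows[[ri]] <- data.frame(
              case = id, method = format(method),
              mask_smoothing_std = gv$mask_smoothing_std[mi],
              tolerance = tol, saturation = sats[si],
              final_smoothing_std = fs, dsc = d,
              stringsAsFactors = FALSE)
            ri <- ri + 1L
          }
        }
      }
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res$config_id <- sprintf("%s|m%g|t%g|s%s|f%g", res$method,
                           res$mask_smoothing_std, res$tolerance,
                           ifelse(is.na(res$saturation), "-",
                                  format(res$saturation)),
                           res$final_smoothing_std)
  class(res) <- c("sweep_result", "data.frame")
  attr(res, "method") <- format(method)
  res
}

sweep_parameters <- function(method) {
  ps <- c("mask_smoothing_std", "tolerance", "final_smoothing_std")
  if (parse_method(method)$family == "adj") c(ps, "saturation") else ps
}

#' Marginal DSC summaries per parameter value
#'
#' For each tunable parameter, the distribution of DSC over all sweep rows
#' with that parameter fixed at each tested value (all other parameters
#' varying): the layout used to pick optimal values.
#'
#' @param sweep a [run_sweep()] result.
#' @return Data frame with columns \code{parameter}, \code{value}, \code{n},
#'   \code{mean_dsc}, \code{median_dsc}, \code{q25}, \code{q75}.
#' @export
sweep_marginals <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  rows <- list()
  for (p in sweep_parameters(attr(sweep, "method"))) {
    for (v in sort(unique(sweep[[p]]))) {
      d <- sweep$dsc[sweep[[p]] == v]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, value = v, n = length(d), mean_dsc = mean(d),
        median_dsc = median(d),
        q25 = unname(quantile(d, 0.25)), q75 = unname(quantile(d, 0.75)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Wilcoxon signed-rank comparisons between consecutive parameter values
#'
#' For each parameter, pairs sweep rows at consecutive tested values matched
#' on case and all other parameters, and runs a paired two-sided Wilcoxon
#' signed-rank test; p-values are Bonferroni-corrected over all comparisons.
#' A reporting utility for choosing optimal values.
#'
#' @param sweep a [run_sweep()] result.
#' @return Data frame with columns \code{parameter}, \code{value_a},
#'   \code{value_b}, \code{median_a}, \code{median_b}, \code{p},
#'   \code{p_bonferroni}.
#' @export
sweep_parameter_tests <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  params <- sweep_parameters(attr(sweep, "method"))
  rows <- list()
  for (p in params) {
    vals <- sort(unique(sweep[[p]]))
    others <- c("case", setdiff(params, p))
    key <- do.call(paste, c(lapply(others, function(o) sweep[[o]]), sep = "|"))
    for (vi in seq_len(length(vals) - 1L)) {
      a <- sweep[sweep[[p]] == vals[vi], ]
      b <- sweep[sweep[[p]] == vals[vi + 1L], ]
      ka <- key[sweep[[p]] == vals[vi]]
      kb <- key[sweep[[p]] == vals[vi + 1L]]
      m <- match(ka, kb)
      da <- a$dsc[!is.na(m)]
      db <- b$dsc[m[!is.na(m)]]
      pv <- if (all(da == db)) 1
            else suppressWarnings(wilcox.test(da, db, paired = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, value_a = vals[vi], value_b = vals[vi + 1L],
        median_a = median(da), median_b = median(db), p = pv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Twelve-seed placement protocol
#'
#' Reproduces the seed-robustness protocol: four seeds per MRI view
#' (sagittal, coronal, axial), placed on slices around the initial seed at
#' offsets \{-2, 0, +2, +4\} along the view axis (consecutive seeds two
#' voxels apart, spanning six voxels per direction); the 0-offset seed is
#' displaced one voxel in-plane (along the next axis, cyclically) so that
#' all 12 seeds are distinct from each other and from the initial seed.
#'
#' @param initial voxel index triple (1-based), strictly inside the cavity
#'   with enough margin for the offsets.
#' @param dims volume dimensions (length-3 integer).
#' @param axis_roles view-to-axis mapping, as stored on volumes.
#' @return A 12 x 3 integer matrix (columns i, j, k) with attributes
#'   \code{view} and \code{offset}.
#' @export
perturb_seeds <- function(initial, dims, axis_roles = default_axis_roles()) {
  initial <- check_seed(initial, dims)
  axis_roles <- check_axis_roles(axis_roles)
  offsets <- c(-2L, 0L, 2L, 4L)
  seeds <- matrix(0L, 12L, 3L, dimnames = list(NULL, c("i", "j", "k")))
  view <- character(12L)
  off <- integer(12L)
  r <- 1L
  for (vn in c("sagittal", "coronal", "axial")) {
    ax <- axis_roles[[vn]]
    inplane <- (ax %% 3L) + 1L
    for (d in offsets) {
      s <- initial
      s[ax] <- s[ax] + d
      if (d == 0L) s[inplane] <- s[inplane] + 1L
      seeds[r, ] <- s
      view[r] <- vn
      off[r] <- d
      r <- r + 1L
    }
  }
  bad <- which(apply(seeds, 1, function(s) any(s < 1L) || any(s > dims)))
  if (length(bad))
    stop("perturbed seeds out of volume bounds: ",
         paste(apply(seeds[bad, , drop = FALSE], 1, paste, collapse = ","),
               collapse = "; "), call. = FALSE)
  if (anyDuplicated(seeds) || any(apply(seeds, 1, identical, y = initial)))
    stop("internal error: perturbed seeds are not distinct", call. = FALSE)
  attr(seeds, "view") <- view
  attr(seeds, "offset") <- off
  seeds
}

#' Per-case tuning bounds (MaxS / MaxP)
#'
#' From a full-grid sweep, computes for each case the best DSC reachable by
#' varying the tolerance only, with all other parameters fixed at the
#' supplied optimal configuration (\code{MaxS}, 7 options), and the best DSC
#' over the whole grid (\code{MaxP}).  \code{MaxS <= MaxP} by construction.
#'
#' @param sweep a [run_sweep()] result covering the full grid for each case.
#' @param optimal a [pipeline_config()] giving the fixed parameter values.
#' @return An object of class \code{tuning_bounds}: data frame with columns
#'   \code{case}, \code{max_s}, \code{max_p}.
#' @export
tuning_bounds <- function(sweep, optimal = pipeline_config()) {
  stopifnot(inherits(sweep, "sweep_result"),
            inherits(optimal, "pipeline_config"))
  grid_n <- nrow(enumerate_grid(attr(sweep, "method")))
  rows <- list()
  for (id in unique(sweep$case)) {
    sc <- sweep[sweep$case == id, ]
    if (nrow(sc) != grid_n)
      stop("case ", id, " covers ", nrow(sc), " configurations; the full grid has ",
           grid_n, call. = FALSE)
    sel <- sc$mask_smoothing_std == optimal$mask_smoothing_std &
      sc$final_smoothing_std == optimal$final_smoothing_std
    if (!is.null(optimal$saturation))
      sel <- sel & !is.na(sc$saturation) & sc$saturation == optimal$saturation
    if (sum(sel) != length(grid_values()$tolerance))
      stop("case ", id, ": expected one row per tolerance value at the optimal settings",
           call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      case = id, max_s = max(sc$dsc[sel]), max_p = max(sc$dsc),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tuning_bounds", "data.frame")
  out
}
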