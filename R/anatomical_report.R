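#' Canonical anatomical areas
#'
#' The seven areas a parcellation label can be assigned to (plus
#' \code{"unknown"} for background/CSF/unmapped labels).
#'
#' @return Character vector of the seven area names.
#' @export
anatomical_areas <- function()
  c("frontal", "temporal", "parietal", "occipital", "cingulate",
    "hippocampus", "amygdala")

#' Read a label-to-area lookup table
#'
#' CSV with columns \code{label_id}, \code{name}, \code{hemisphere}
#' (\code{lh}, \code{rh} or empty) and \code{area} (one of the seven
#' anatomical areas or \code{unknown}).  A default Desikan-Killiany-style
#' table ships with the package
#' (\code{system.file("extdata", "dk_area_lookup.csv", package = "resectseg")}).
#'
#' @param path CSV file path.
#' @return Data frame with the four columns above.
#' @export
read_area_lookup <- function(path) {
  lk <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label_id", "name", "hemisphere", "area")
  if (!all(need %in% names(lk)))
    stop("area lookup must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(lk$area), c(anatomical_areas(), "unknown"))
  if (length(bad))
    stop("unknown areas in lookup: ", paste(bad, collapse = ", "), call. = FALSE)
  lk
}

sided_area <- function(hemisphere, area) {
  ifelse(area == "unknown", "unknown",
         ifelse(hemisphere %in% c("lh", "rh"),
                paste(hemisphere, area, sep = "-"), area))
}

#' Map parcellation labels to anatomical areas
#'
#' Recodes a parcellation into the seven anatomical areas (sided when the
#' lookup provides a hemisphere), with code 0 for unknown.  Voxel counts are
#' preserved: every voxel keeps exactly one (possibly unknown) area.
#'
#' @param labels a [label_volume()].
#' @param lookup a lookup table as returned by [read_area_lookup()].
#' @return A [label_volume()] whose labels are area codes and whose
#'   \code{label_names} are the sided area names.
#' @export
map_areas <- function(labels, lookup) {
  stopifnot(inherits(labels, "label_volume"))
  present <- setdiff(sort(unique(as.vector(labels$data))), 0L)
  missing <- setdiff(present, lookup$label_id)
  if (length(missing))
    stop("parcellation labels missing from the area lookup: ",
         paste(missing, collapse = ", "), call. = FALSE)
  areas <- sided_area(lookup$hemisphere, lookup$area)
  keep <- areas != "unknown" & lookup$label_id %in% present
  area_names <- sort(unique(areas[keep]))
  code_of_area <- seq_along(area_names)
  names(code_of_area) <- area_names
  # label id -> area code (0 = unknown), via a dense lookup vector
  max_id <- max(c(present, lookup$label_id))
  id2code <- integer(max_id + 1L)
  id2code[lookup$label_id + 1L] <- ifelse(areas == "unknown", 0L,
                                          code_of_area[areas])
  coded <- array(id2code[labels$data + 1L], dim(labels$data))
  nm <- area_names
  names(nm) <- as.character(seq_along(area_names))
  label_volume(coded, nm, labels$voxel_size, labels$affine, labels$axis_roles)
}

area_codes <- function(areas) {
  stopifnot(inherits(areas, "label_volume"))
  code <- as.integer(names(areas$label_names))
  names(code) <- unname(areas$label_names)
  code[order(code)]
}

build_report <- function(resected_counts, totals, area_names, method,
                         unknown_voxels, grid) {
  out <- data.frame(area = area_names, resected_voxels = resected_counts,
                    area_total_voxels = totals,
                    resection_pct = 100 * resected_counts / totals,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, method = method, unknown_voxels = unknown_voxels,
            voxel_size = grid, class = c("area_report", "data.frame"))
}

#' Overlap-based anatomical report
#'
#' Counts, for each anatomical area, the resection voxels landing on that
#' area of the (preoperative) area-coded parcellation, and reports the
#' resection percentage: resection voxels assigned to the area divided by
#' the area's total voxel count, times 100.  Resection voxels on unknown
#' labels are tallied (attribute \code{unknown_voxels}) but enter no area's
#' numerator.
#'
#' @param resection a [binary_mask()] (the resection model).
#' @param areas an area-coded [label_volume()] from [map_areas()].
#' @return An \code{area_report} data frame: one row per area with
#'   \code{resected_voxels}, \code{area_total_voxels},
#'   \code{resection_pct}.
#' @export
overlap_report <- function(resection, areas) {
  stopifnot(inherits(resection, "binary_mask"))
  stop_if_grid_mismatch(resection, areas, "resection and parcellation")
  codes <- area_codes(areas)
  K <- max(codes)
  totals <- tabulate(areas$data[areas$data > 0L], nbins = K)
  rc <- areas$data[resection$data]
  resected <- tabulate(rc[rc > 0L], nbins = K)
  build_report(resected[codes], totals[codes], names(codes), "overlap",
               sum(rc == 0L), resection$voxel_size)
}

#' KNN-based anatomical report
#'
#' Like [overlap_report()], but resection voxels that land on unknown
#' parcellation labels (background/CSF, typically from imperfect pre/post
#' alignment) are first assigned to the area of their nearest known-labelled
#' voxel (k-nearest-neighbour label propagation in voxel coordinates,
#' \code{k = 1} by default).  Distance ties are broken towards the smallest
#' area code; vote ties for \code{k > 1} likewise.
#'
#' @inheritParams overlap_report
#' @param k number of nearest known voxels voting for the assignment.
#' @return An \code{area_report} data frame (attribute \code{method}
#'   \code{"knn"}).
#' @export
knn_report <- function(resection, areas, k = 1L) {
  stopifnot(inherits(resection, "binary_mask"))
  stop_if_grid_mismatch(resection, areas, "resection and parcellation")
  if (!any(areas$data > 0L))
    stop("parcellation has no known-labelled voxels to propagate from",
         call. = FALSE)
  codes <- area_codes(areas)
  K <- max(codes)
  totals <- tabulate(areas$data[areas$data > 0L], nbins = K)
  rc <- areas$data[resection$data]
  resected <- tabulate(rc[rc > 0L], nbins = K)
  unknown_idx <- which(resection$data & areas$data == 0L)
  if (length(unknown_idx)) {
    q <- arrayInd(unknown_idx, dim(areas$data))
    assigned <- nearest_area_code(q, areas$data, k)
    resected <- resected + tabulate(assigned, nbins = K)
  }
  build_report(resected[codes], totals[codes], names(codes), "knn",
               length(unknown_idx), resection$voxel_size)
}

# Nearest known-labelled voxel by expanding Chebyshev shells: a candidate at
# squared distance d2 is the true Euclidean nearest once d2 <= r^2 for the
# explored cube radius r.  Queries sit near labelled tissue, so r stays small.
nearest_area_code <- function(queries, codes, k = 1L) {
  dm <- dim(codes)
  out <- integer(nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q <- queries[qi, ]
    r <- 0L
    repeat {
      r <- r + 1L
      lo <- pmax(q - r, 1L)
      hi <- pmin(q + r, dm)
      box <- codes[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      kn <- which(box > 0L)
      if (length(kn) >= k) {
        bi <- arrayInd(kn, dim(box))
        d2 <- (bi[, 1] + lo[1] - 1L - q[1])^2 +
              (bi[, 2] + lo[2] - 1L - q[2])^2 +
              (bi[, 3] + lo[3] - 1L - q[3])^2
        ord <- order(d2, box[kn])
        kth <- d2[ord[min(k, length(ord))]]
        if (kth <= r^2 || all(lo == 1L) && all(hi == dm)) {
          votes <- box[kn][ord[seq_len(min(k, length(ord)))]]
          tab <- table(votes)
          best <- as.integer(names(tab)[tab == max(tab)])
          out[qi] <- min(best)
          break
        }
      }
      if (all(lo == 1L) && all(hi == dm))
        stop("no known-labelled voxel reachable", call. = FALSE)
    }
  }
  out
}

#' Call areas resected at a percentage threshold
#'
#' Adds a boolean \code{resected} column: an area is called resected if its
#' resection percentage is strictly above \code{threshold_pct}.  At 0\%
#' every area with at least one assigned voxel is called; at 100\% none is.
#'
#' @param report an \code{area_report} from [overlap_report()] /
#'   [knn_report()].
#' @param threshold_pct scalar in \code{[0, 100]}.
#' @return The report with a \code{resected} column and a
#'   \code{threshold_pct} attribute.
#' @export
call_resected <- function(report, threshold_pct) {
  stopifnot(inherits(report, "area_report"),
            is.finite(threshold_pct), threshold_pct >= 0, threshold_pct <= 100)
  report$resected <- report$resection_pct > threshold_pct
  attr(report, "threshold_pct") <- threshold_pct
  report
}

#' Concordance of an automated report with the clinical report
#'
#' Compares the called resected areas with the clinically reported ones over
#' the report's area universe and classifies the match as fully concordant
#' (no false classifications), partly concordant (i: clinical subset of
#' called, i.e. extra false positives; ii: called subset of clinical, i.e.
#' false negatives; iii: partial overlap with both), or discordant (no true
#' classifications among the called/reported areas).
#'
#' @param calls an \code{area_report} with a \code{resected} column (see
#'   [call_resected()]).
#' @param clinical non-empty character vector of clinically reported
#'   resected areas (sided names matching the report).
#' @return An object of class \code{concordance_verdict}: list with
#'   \code{category} and the \code{tp}/\code{fp}/\code{fn}/\code{tn}
#'   tallies.
#' @export
concordance <- function(calls, clinical) {
  stopifnot(inherits(calls, "area_report"))
  if (is.null(calls$resected))
    stop("run call_resected() before scoring concordance", call. = FALSE)
  if (!length(clinical))
    stop("the clinical report must name at least one resected area", call. = FALSE)
  extra <- setdiff(clinical, calls$area)
  if (length(extra))
    stop("clinical areas absent from the report universe: ",
         paste(extra, collapse = ", "), call. = FALSE)
  truth <- calls$area %in% clinical
  called <- calls$resected
  tp <- sum(called & truth); fp <- sum(called & !truth)
  fn <- sum(!called & truth); tn <- sum(!called & !truth)
  category <- if (fp == 0L && fn == 0L) "fully_concordant"
  else if (tp == 0L) "discordant"
  else if (fn == 0L) "partly_concordant_i"
  else if (fp == 0L) "partly_concordant_ii"
  else "partly_concordant_iii"
  structure(list(category = category, tp = tp, fp = fp, fn = fn, tn = tn),
            class = "concordance_verdict")
}

#' @export
print.concordance_verdict <- function(x, ...) {
  cat("<concordance_verdict>", x$category,
      sprintf("(TP %d, FP %d, FN %d, TN %d)\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Pooled cohort classification metrics
#'
#' Pools the per-area TP/FP/FN/TN tallies of a set of concordance verdicts
#' and returns accuracy \code{(TP+TN)/(TP+TN+FP+FN)}, sensitivity
#' \code{TP/(TP+FN)} and specificity \code{TN/(TN+FP)}; a metric with a
#' zero denominator is reported as \code{NA}.
#'
#' @param verdicts list of [concordance()] verdicts.
#' @return List with \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, the pooled tallies and per-category counts.
#' @export
cohort_metrics <- function(verdicts) {
  stopifnot(length(verdicts) >= 1L)
  tp <- sum(vapply(verdicts, `[[`, 0L, "tp"))
  fp <- sum(vapply(verdicts, `[[`, 0L, "fp"))
  fn <- sum(vapply(verdicts, `[[`, 0L, "fn"))
  tn <- sum(vapply(verdicts, `[[`, 0L, "tn"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = safe_div(tp + tn, tp + tn + fp + fn),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       tp = tp, fp = fp, fn = fn, tn = tn,
       categories = table(vapply(verdicts, `[[`, "", "category")))
}

# per-case classification profile over a vector of thresholds
case_profile <- function(report, clinical, thresholds) {
  truth <- report$area %in% clinical
  calls <- outer(report$resection_pct, thresholds, ">")
  tp <- colSums(calls & truth); fp <- colSums(calls & !truth)
  fn <- colSums(!calls & truth); tn <- colSums(!calls & !truth)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       fully = (fp == 0L & fn == 0L), discordant = (tp == 0L))
}

pick_threshold <- function(profiles, thresholds, criterion) {
  tp <- Reduce(`+`, lapply(profiles, `[[`, "tp"))
  fp <- Reduce(`+`, lapply(profiles, `[[`, "fp"))
  fn <- Reduce(`+`, lapply(profiles, `[[`, "fn"))
  tn <- Reduce(`+`, lapply(profiles, `[[`, "tn"))
  if (criterion == "roc" && (max(tp + fn) == 0 || max(fp + tn) == 0))
    criterion <- "accuracy"  # degenerate: no positives or no negatives pooled
  if (criterion == "concordance") {
    n_fully <- Reduce(`+`, lapply(profiles, function(p) as.integer(p$fully)))
    n_disc <- Reduce(`+`, lapply(profiles, function(p) as.integer(p$discordant)))
    best <- which(n_fully == max(n_fully))
    best <- best[n_disc[best] == min(n_disc[best])]
  } else if (criterion == "accuracy") {
    acc <- (tp + tn) / (tp + tn + fp + fn)
    best <- which(acc == max(acc))
  } else {  # roc: closest operating point to (FPR, TPR) = (0, 1)
    tpr <- tp / (tp + fn)
    fpr <- fp / (fp + tn)
    d <- sqrt((1 - tpr)^2 + fpr^2)
    best <- which(d == min(d))
  }
  thresholds[min(best)]  # ties: smallest optimal threshold
}

#' LOOCV selection of the resected-area threshold
#'
#' Leave-one-out cross-validation over a cohort of (report, clinical) pairs:
#' for each held-out case the threshold is scanned over a fixed grid (0 to
#' 100\% in \code{grid_step} steps, plus every observed percentage) on the
#' remaining cases and the criterion-optimal value picked — maximizing the
#' number of fully concordant reports while minimizing discordances
#' (\code{"concordance"}), maximizing pooled accuracy (\code{"accuracy"}),
#' or taking the ROC operating point closest to (FPR, TPR) = (0, 1)
#' (\code{"roc"}).  Ties resolve to the smallest threshold; a degenerate
#' training pool (no positives or no negatives) falls back from the ROC to
#' the accuracy criterion.  The summary threshold is the mean over folds.
#'
#' @param cohort list of cases, each a list with \code{report} (an
#'   \code{area_report}) and \code{clinical} (character vector of resected
#'   areas); at least 2 cases.
#' @param criterion \code{"concordance"}, \code{"accuracy"} or \code{"roc"}.
#' @param grid_step threshold scan step in percentage points.
#' @return List of class \code{loocv_result}: \code{folds} (data frame with
#'   per-fold threshold and held-out verdict), \code{threshold} (mean) and
#'   \code{criterion}.
#' @export
loocv_threshold <- function(cohort,
                            criterion = c("concordance", "accuracy", "roc"),
                            grid_step = 0.01) {
  criterion <- match.arg(criterion)
  n <- length(cohort)
  if (n < 2L) stop("LOOCV needs a cohort of at least 2 cases", call. = FALSE)
  observed <- unlist(lapply(cohort, function(cs) cs$report$resection_pct))
  thresholds <- sort(unique(c(seq(0, 100, by = grid_step), observed)))
  profiles <- lapply(cohort, function(cs)
    case_profile(cs$report, cs$clinical, thresholds))
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    thr <- pick_threshold(profiles[-i], thresholds, criterion)
    v <- concordance(call_resected(cohort[[i]]$report, thr),
                     cohort[[i]]$clinical)
    folds[[i]] <- data.frame(fold = i, threshold = thr,
                             heldout_category = v$category,
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  structure(list(folds = folds, threshold = mean(folds$threshold),
                 criterion = criterion),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result>", x$criterion, "criterion |", nrow(x$folds),
      "folds | mean threshold", signif(x$threshold, 4), "%\n")
  print(table(x$folds$heldout_category))
  invisible(x)
}
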