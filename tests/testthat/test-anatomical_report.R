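toy_lookup <- function() {
  data.frame(label_id = c(1L, 2L, 3L, 4L, 9L),
             name = c("a", "b", "c", "d", "vent"),
             hemisphere = c("lh", "lh", "rh", "rh", ""),
             area = c("frontal", "frontal", "parietal", "temporal", "unknown"),
             stringsAsFactors = FALSE)
}

toy_labels <- function(dm = c(6, 6, 6)) {
  lab <- array(0L, dm)
  lab[1:3, , 1:3] <- 1L   # lh-frontal, 54 voxels
  lab[1:3, , 4:6] <- 2L   # lh-frontal too
  lab[4:6, , 1:3] <- 3L   # rh-parietal, 54
  lab[4:6, 1:3, 4:6] <- 4L  # rh-temporal, 27
  # remaining 27 voxels stay unknown (0)
  label_volume(lab, c(`1` = "a", `2` = "b", `3` = "c", `4` = "d"))
}

test_that("labels map onto sided areas with voxel counts preserved", {
  areas <- map_areas(toy_labels(), toy_lookup())
  nm <- unname(areas$label_names)
  expect_setequal(nm, c("lh-frontal", "rh-parietal", "rh-temporal"))
  code <- as.integer(names(areas$label_names)[areas$label_names == "lh-frontal"])
  expect_identical(sum(areas$data == code), 108L)  # labels 1 and 2 merged
  expect_identical(sum(areas$data == 0L), 27L)
  expect_error(map_areas(toy_labels(),
                         toy_lookup()[toy_lookup()$label_id != 2L, ]),
               "missing from the area lookup")
})

test_that("area percentages are invariant to area-preserving relabelling", {
  lab <- toy_labels()
  res <- array(FALSE, dim(lab$data)); res[2:5, 2:4, 2:5] <- TRUE
  resection <- binary_mask(res)
  r1 <- overlap_report(resection, map_areas(lab, toy_lookup()))
  # swap label ids 1<->2 (both lh-frontal): report must not change
  swapped <- lab$data
  swapped[lab$data == 1L] <- 2L
  swapped[lab$data == 2L] <- 1L
  lab2 <- label_volume(swapped, lab$label_names)
  r2 <- overlap_report(resection, map_areas(lab2, toy_lookup()))
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("overlap report counts resection voxels per area by hand", {
  areas <- map_areas(toy_labels(), toy_lookup())
  res <- array(FALSE, c(6, 6, 6))
  res[1:3, 1:3, 1:3] <- TRUE          # 27 voxels on lh-frontal (of 108)
  res[4:6, 1, 1] <- TRUE              # 3 voxels on rh-parietal (of 54)
  rep <- overlap_report(binary_mask(res), areas)
  expect_equal(rep$resection_pct[rep$area == "lh-frontal"], 27 / 108 * 100)
  expect_equal(rep$resection_pct[rep$area == "rh-parietal"], 3 / 54 * 100)
  expect_equal(rep$resection_pct[rep$area == "rh-temporal"], 0)
  expect_identical(attr(rep, "unknown_voxels"), 0L)

  # resection entirely on unknown voxels: every area at 0%
  res0 <- array(FALSE, c(6, 6, 6))
  res0[which(toy_labels()$data == 0L)[1]] <- TRUE
  rep0 <- overlap_report(binary_mask(res0), areas)
  expect_true(all(rep0$resection_pct == 0))
  expect_identical(attr(rep0, "unknown_voxels"), 1L)
})

test_that("knn report equals overlap report when no unknown voxels are hit", {
  areas <- map_areas(toy_labels(), toy_lookup())
  res <- array(FALSE, c(6, 6, 6)); res[2:3, 2:3, 2:3] <- TRUE
  rep_o <- overlap_report(binary_mask(res), areas)
  rep_k <- knn_report(binary_mask(res), areas)
  expect_equal(rep_o$resection_pct, rep_k$resection_pct)
  expect_identical(attr(rep_k, "unknown_voxels"), 0L)
})

test_that("knn assigns unknown resection voxels to the nearest area, ties to the smallest code", {
  dm <- c(7, 3, 3)
  lab <- array(0L, dm)
  lab[1, , ] <- 1L  # area code 1 at i=1
  lab[7, , ] <- 2L  # area code 2 at i=7
  areas <- label_volume(lab, c(`1` = "lh-frontal", `2` = "rh-parietal"))
  near1 <- array(FALSE, dm); near1[2, 2, 2] <- TRUE
  r <- knn_report(binary_mask(near1), areas)
  expect_identical(r$resected_voxels[r$area == "lh-frontal"], 1L)
  # i=4 is equidistant from both planes: smallest area code wins
  tie <- array(FALSE, dm); tie[4, 2, 2] <- TRUE
  r2 <- knn_report(binary_mask(tie), areas)
  expect_identical(r2$resected_voxels[r2$area == "lh-frontal"], 1L)
  expect_identical(r2$resected_voxels[r2$area == "rh-parietal"], 0L)
  # no known voxels at all: error
  none <- label_volume(array(0L, dm), character(0))
  expect_error(knn_report(binary_mask(tie), none), "no known")
})

test_that("resected calls follow the strict threshold with its limiting behaviours", {
  areas <- map_areas(toy_labels(), toy_lookup())
  res <- array(FALSE, c(6, 6, 6))
  res[1:3, 1:3, 1:3] <- TRUE; res[4, 1, 1] <- TRUE
  rep <- overlap_report(binary_mask(res), areas)
  at0 <- call_resected(rep, 0)
  expect_identical(at0$resected, at0$resected_voxels > 0L)
  at100 <- call_resected(rep, 100)
  expect_false(any(at100$resected))
  exact <- call_resected(rep, rep$resection_pct[rep$area == "lh-frontal"])
  expect_false(exact$resected[exact$area == "lh-frontal"])  # strict >
  # monotone: raising the threshold never adds a call
  prev <- at0$resected
  for (thr in c(1, 5, 25, 50, 99)) {
    cur <- call_resected(rep, thr)$resected
    expect_true(all(!cur | prev))
    prev <- cur
  }
})

test_that("concordance categories match an exhaustive set-logic enumeration", {
  areas <- c("lh-frontal", "rh-parietal", "rh-temporal")
  verdict_by_sets <- function(called, clin) {
    if (setequal(called, clin)) "fully_concordant"
    else if (!length(intersect(called, clin))) "discordant"
    else if (all(clin %in% called)) "partly_concordant_i"
    else if (all(called %in% clin)) "partly_concordant_ii"
    else "partly_concordant_iii"
  }
  for (called_bits in 0:7) for (clin_bits in 1:7) {
    called <- areas[bitwAnd(called_bits, c(1L, 2L, 4L)) > 0]
    clin <- areas[bitwAnd(clin_bits, c(1L, 2L, 4L)) > 0]
    rep <- structure(
      data.frame(area = areas, resected_voxels = 0L,
                 area_total_voxels = 10L, resection_pct = 0,
                 resected = areas %in% called, stringsAsFactors = FALSE),
      class = c("area_report", "data.frame"), method = "overlap")
    v <- concordance(rep, clin)
    expect_identical(v$category, verdict_by_sets(called, clin),
                     label = sprintf("called={%s} clin={%s}",
                                     paste(called, collapse = ","),
                                     paste(clin, collapse = ",")))
    expect_identical(v$tp + v$fp + v$fn + v$tn, 3L)
  }
})

test_that("cohort metrics pool tallies and leave undefined rates missing", {
  v1 <- structure(list(category = "fully_concordant",
                       tp = 2L, fp = 0L, fn = 1L, tn = 2L),
                  class = "concordance_verdict")
  v2 <- structure(list(category = "partly_concordant_i",
                       tp = 0L, fp = 1L, fn = 0L, tn = 1L),
                  class = "concordance_verdict")
  m <- cohort_metrics(list(v1, v2))
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 3 / 4)
  nopos <- structure(list(category = "fully_concordant",
                          tp = 0L, fp = 0L, fn = 0L, tn = 3L),
                     class = "concordance_verdict")
  expect_true(is.na(cohort_metrics(list(nopos))$sensitivity))
})

test_that("LOOCV scans thresholds per fold and resolves ties to the smallest", {
  mk_case <- function(pcts, clin, areas = c("lh-frontal", "rh-parietal")) {
    rep <- structure(
      data.frame(area = areas, resected_voxels = round(pcts),
                 area_total_voxels = 100L, resection_pct = pcts,
                 stringsAsFactors = FALSE),
      class = c("area_report", "data.frame"), method = "overlap")
    list(report = rep, clinical = clin)
  }
  # threshold anywhere in (5, 40) separates perfectly in every fold
  cohort <- list(mk_case(c(40, 2), "lh-frontal"),
                 mk_case(c(60, 5), "lh-frontal"),
                 mk_case(c(1, 45), "rh-parietal"),
                 mk_case(c(3, 80), "rh-parietal"))
  # each fold trains perfectly; fold 2's training threshold (3) sits below
  # the held-out case's 5% nuisance area, which becomes a false positive
  for (crit in c("concordance", "accuracy", "roc")) {
    res <- loocv_threshold(cohort, crit)
    expect_identical(nrow(res$folds), 4L)
    expect_identical(res$folds$heldout_category,
                     c("fully_concordant", "partly_concordant_i",
                       "fully_concordant", "fully_concordant"))
  }
  # ties resolve to the smallest separating threshold, which is the largest
  # nuisance percentage in each training set (strict > call): 5, 3, 5, 5
  res <- loocv_threshold(cohort, "concordance")
  expect_equal(res$folds$threshold, c(5, 3, 5, 5))
  expect_equal(res$threshold, mean(c(5, 3, 5, 5)))
  # two-case cohort: two folds, each trained on one case
  res2 <- loocv_threshold(cohort[c(1, 3)], "accuracy")
  expect_identical(nrow(res2$folds), 2L)
  expect_error(loocv_threshold(cohort[1], "accuracy"), "at least 2")
})
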