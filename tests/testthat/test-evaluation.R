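mk <- function(idx, dm = c(4, 4, 4)) {
  m <- array(FALSE, dm); m[idx] <- TRUE
  binary_mask(m)
}

test_that("dice reproduces the direct formula and its properties", {
  x <- mk(1:4); y <- mk(2:7)                 # |X|=4, |Y|=6, |X^Y|=3
  expect_equal(dice(x, y), 0.6)
  expect_equal(dice(x, x), 1)
  expect_equal(dice(mk(1:3), mk(10:12)), 0)
  expect_error(dice(mk(1:2), mk(1:2, dm = c(3, 3, 3))), "shapes")
  expect_error(dice(mk(integer(0)), mk(integer(0))), "empty")
})

test_that("volume ratio is the symmetric min/max voxel-count ratio", {
  expect_equal(volume_ratio(mk(1:50), mk(1:50)), 1)
  expect_equal(volume_ratio(mk(1:5), mk(1:10)), 0.5)
  expect_equal(volume_ratio(mk(1:10), mk(1:5)), 0.5)
  expect_error(volume_ratio(mk(integer(0)), mk(integer(0))), "empty")
})

test_that("MQD is the mean squared selectable-vs-possible discard", {
  expect_equal(mqd(c(0.8, 0.9), c(0.8, 0.9)), 0)
  expect_equal(mqd(0.8, 0.9), 0.01)
  expect_equal(mqd(c(0.8, 0.7), c(0.9, 0.9)), 0.025)
  expect_equal(mqd(c(0.7, 0.8), c(0.9, 0.9)), 0.025)  # order-invariant
  expect_error(mqd(c(0.8, 0.7), 0.9), "paired")
})

test_that("the parameter grid matches the published factorial design", {
  adj <- enumerate_grid("adj-l")
  norm <- enumerate_grid("norm-g")
  expect_identical(nrow(adj), 504L)
  expect_identical(nrow(norm), 84L)
  expect_identical(anyDuplicated(adj$config_id), 0L)
  # marginal value counts: 3 mask stds x 7 tolerances x 6 saturations x 4 final stds
  expect_identical(length(unique(adj$mask_smoothing_std)), 3L)
  expect_identical(length(unique(adj$tolerance)), 7L)
  expect_identical(length(unique(adj$saturation)), 6L)
  expect_identical(length(unique(adj$final_smoothing_std)), 4L)
  expect_true(all(is.na(norm$saturation)))
  # scope is not a grid axis: ADJ-L and ADJ-G share the same value tuples
  tup <- function(g) g[, c("mask_smoothing_std", "tolerance", "saturation",
                           "final_smoothing_std")]
  expect_identical(tup(adj), tup(enumerate_grid("adj-g")))
})

test_that("a NORM sweep covers cases x grid and never loses the seed", {
  p1 <- small_phantom()
  p2 <- small_phantom(noise_std = 4, rng_seed = 2)
  cases <- list(as_case(p1, "a"),
                as_case(p2, "b", gold = p2$brain))  # gold = whole brain mask
  sw <- run_sweep(cases, "norm-l")
  expect_s3_class(sw, "sweep_result")
  expect_identical(nrow(sw), 168L)
  expect_true(all(sw$dsc >= 0 & sw$dsc <= 1))
  expect_true(all(sw$dsc > 0))  # the model always contains the in-gold seed

  marg <- sweep_marginals(sw)
  counts <- table(marg$parameter)
  expect_identical(as.integer(counts[["tolerance"]]), 7L)
  expect_identical(as.integer(counts[["mask_smoothing_std"]]), 3L)
  expect_identical(as.integer(counts[["final_smoothing_std"]]), 4L)

  tests <- sweep_parameter_tests(sw)
  expect_true(all(tests$p >= 0 & tests$p <= 1, na.rm = TRUE))
  expect_true(all(tests$p_bonferroni >= tests$p, na.rm = TRUE))
  # consecutive-value pairs: 6 tolerance + 2 mask + 3 final comparisons
  expect_identical(nrow(tests), 11L)

  tb <- tuning_bounds(sw, pipeline_config("norm-l", tolerance = 0.02,
                                          final_smoothing_std = 0.5))
  expect_true(all(tb$max_s <= tb$max_p + 1e-12))
})

test_that("tuning bounds take the right maxima from a known table", {
  grid <- enumerate_grid("norm-g")
  sw <- grid[rep(seq_len(nrow(grid)), 2), ]
  sw$case <- rep(c("p1", "p2"), each = nrow(grid))
  set.seed(5)
  sw$dsc <- runif(nrow(sw), 0.2, 0.9)
  class(sw) <- c("sweep_result", "data.frame")
  attr(sw, "method") <- "norm-g"
  opt <- pipeline_config("norm-g", tolerance = 0.02, mask_smoothing_std = 1,
                         final_smoothing_std = 0.1)
  tb <- tuning_bounds(sw, opt)
  for (cs in c("p1", "p2")) {
    rows <- sw[sw$case == cs, ]
    expect_equal(tb$max_p[tb$case == cs], max(rows$dsc))
    sel <- rows$mask_smoothing_std == 1 & rows$final_smoothing_std == 0.1
    expect_identical(sum(sel), 7L)
    expect_equal(tb$max_s[tb$case == cs], max(rows$dsc[sel]))
  }
  expect_error(tuning_bounds(sw[-1, ], opt), "full grid")
})

test_that("the seed-perturbation protocol spans slices two voxels apart per view", {
  dm <- c(21, 21, 21)
  seeds <- perturb_seeds(c(11, 11, 11), dm)
  expect_identical(dim(seeds), c(12L, 3L))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_false(any(apply(seeds, 1, identical, y = c(11L, 11L, 11L))))
  for (vn in c("sagittal", "coronal", "axial")) {
    ax <- c(sagittal = 1, coronal = 2, axial = 3)[[vn]]
    sl <- sort(seeds[attr(seeds, "view") == vn, ax])
    expect_identical(length(sl), 4L)
    expect_true(all(diff(sl) == 2))       # consecutive slices two voxels apart
    expect_lte(max(sl) - min(sl), 6)      # span of six voxels per direction
  }
  expect_error(perturb_seeds(c(1, 1, 1), dm), "out of volume bounds")
})
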