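homog_cavity <- function() {
  x <- array(200, c(11, 11, 11))
  x[5:7, 5:7, 5:7] <- 10
  intensity_volume(x)
}

test_that("a homogeneous dark cavity is recovered exactly", {
  v <- homog_cavity()
  brain <- binary_mask(array(TRUE, dim(v$data)))
  r <- grow(v, brain, c(6, 6, 6), 0.05)
  expect_identical(sum(r$data), 27L)
  expect_true(all(r$data[5:7, 5:7, 5:7]))
  # cross-check against the exhaustive simulation
  expect_identical(r$data, grow_oracle(v$data, brain$data, c(6, 6, 6), 0.05))
})

test_that("growth stops immediately when all neighbours exceed the tolerance", {
  x <- array(200, c(5, 5, 5)); x[3, 3, 3] <- 10
  r <- grow(intensity_volume(x), binary_mask(array(TRUE, c(5, 5, 5))),
            c(3, 3, 3), 0.05)
  expect_identical(sum(r$data), 1L)
  expect_true(r$data[3, 3, 3])
})

test_that("the brain mask truncates the region", {
  v <- homog_cavity()
  half <- array(FALSE, dim(v$data)); half[1:6, , ] <- TRUE
  brain <- binary_mask(half)
  r <- grow(v, brain, c(5, 6, 6), 0.05)
  expected <- array(FALSE, dim(v$data)); expected[5:6, 5:7, 5:7] <- TRUE
  expect_identical(r$data, expected)
  expect_true(all(!r$data | brain$data))  # region within mask, always
  expect_identical(r$data, grow_oracle(v$data, half, c(5, 6, 6), 0.05))
})

test_that("seed preconditions are enforced", {
  v <- homog_cavity()
  brain <- binary_mask(array(TRUE, dim(v$data)))
  expect_error(grow(v, brain, c(0, 1, 1), 0.05), "bounds")
  expect_error(grow(v, brain, c(12, 6, 6), 0.05), "bounds")
  off <- array(TRUE, dim(v$data)); off[6, 6, 6] <- FALSE
  expect_error(grow(v, binary_mask(off), c(6, 6, 6), 0.05), "brain mask")
})

test_that("growth is deterministic, 6-connected and mask-contained on random inputs", {
  set.seed(101)
  for (rep in 1:12) {
    dm <- sample(6:10, 3, replace = TRUE)
    vol <- array(sample(95:160, prod(dm), replace = TRUE), dm)
    brain <- array(runif(prod(dm)) < 0.85, dm)
    seed <- pmax(pmin(round(dm / 2), dm), 1)
    brain[seed[1], seed[2], seed[3]] <- TRUE
    v <- intensity_volume(vol); bm <- binary_mask(brain)
    tol <- runif(1, 0.02, 0.2)
    r1 <- grow(v, bm, seed, tol)
    r2 <- grow(v, bm, seed, tol)
    expect_identical(r1$data, r2$data)
    expect_true(all(!r1$data | brain))
    expect_true(is_connected6(r1$data, seed))
  }
})

test_that("finalize smooths and re-binarizes at 10% of the smoothed maximum", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  m <- binary_mask(cube)
  expect_identical(finalize_region(m, 0.1)$data, cube)  # near-delta kernel

  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  out <- finalize_region(binary_mask(single), 0.5)$data
  expect_true(out[4, 4, 4])
  expect_identical(out, conv_oracle(single * 1, 0.5) >=
                     0.10 * max(conv_oracle(single * 1, 0.5)))
  expect_identical(out, out[7:1, 7:1, 7:1])  # symmetric about the voxel

  empty <- binary_mask(array(FALSE, c(4, 4, 4)))
  expect_warning(out <- finalize_region(empty, 0.5), "empty")
  expect_false(any(out$data))
})

test_that("pipeline configs enforce the saturation/family pairing", {
  expect_error(pipeline_config("adj-l", saturation = NULL), "saturation")
  expect_error(pipeline_config("norm-l", saturation = 0.1), "ADJ family")
  expect_silent(pipeline_config("norm-g"))
  cfg <- pipeline_config()
  expect_equal(cfg$tolerance, 0.05)
  expect_equal(cfg$mask_smoothing_std, 0.5)
  expect_equal(cfg$final_smoothing_std, 0.5)
  expect_equal(cfg$saturation, 0.10)
  expect_identical(format(cfg$method), "adj-l")
})

test_that("segment composes the pipeline and reports a consistent volume", {
  ph <- small_phantom()
  m <- segment(ph$post, ph$brain, ph$seed)
  expect_s3_class(m, "resection_model")
  expect_true(m$mask$data[ph$seed[1], ph$seed[2], ph$seed[3]])
  expect_equal(m$volume_cm3,
               sum(m$mask$data) * prod(m$mask$voxel_size) / 1000)
  expect_gt(dice(m$mask, ph$gold), 0.6)
  expect_error(segment(ph$post, ph$brain, c(1, 1, 1)), "brain mask")
})

test_that("higher tolerance yields larger resection models on phantoms", {
  ph <- small_phantom(noise_std = 4, rng_seed = 3)
  v02 <- segment(ph$post, ph$brain, ph$seed,
                 pipeline_config("adj-l", tolerance = 0.02))$volume_cm3
  v20 <- segment(ph$post, ph$brain, ph$seed,
                 pipeline_config("adj-l", tolerance = 0.20))$volume_cm3
  expect_gte(v20, v02)
})

test_that("ventricle exclusion keeps the region out of the ventricle space", {
  # ventricle ellipsoid abuts the cavity and is nearly as dark, so growth
  # leaks into it unless the ventricle labels are removed from the mask
  sp <- phantom_spec(shape = c(32, 32, 32), brain_radii = c(13, 13, 12),
                     cavity_center = c(21, 17, 16), cavity_radii = c(3.5, 3.5, 3.5),
                     ventricles = list(list(center = c(14, 17, 16),
                                            radii = c(3, 4, 3))),
                     noise_std = 0)
  ph <- make_phantom(sp)
  vent <- ph$labels$data == 99L & !ph$gold$data
  plain <- segment(ph$post, ph$brain, ph$seed, pipeline_config(),
                   labels = ph$labels)
  expect_true(any(plain$mask$data & vent))
  cfg <- pipeline_config(exclude_ventricles = TRUE, ventricle_ids = 99L)
  m <- segment(ph$post, ph$brain, ph$seed, cfg, labels = ph$labels)
  expect_false(any(m$mask$data & vent))
  expect_gt(dice(m$mask, ph$gold), dice(plain$mask, ph$gold))
})
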