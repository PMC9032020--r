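# Compact phantoms used across the suite.  `small_phantom` is cheap (28^3);
# `roomy_phantom` has a cavity wide enough (radius 6.5) for the 12-seed
# protocol's +/-4-slice offsets to stay strictly inside it.

small_phantom <- function(noise_std = 0, rng_seed = 1, ...) {
  make_phantom(phantom_spec(shape = c(28, 28, 28),
                            brain_radii = c(11, 12, 10),
                            cavity_center = c(16.5, 15.5, 14.5),
                            cavity_radii = c(3.5, 3.5, 3.5),
                            csf_thickness = 1.5,
                            noise_std = noise_std, rng_seed = rng_seed, ...))
}

roomy_phantom <- function(noise_std = 0, rng_seed = 1) {
  make_phantom(phantom_spec(shape = c(34, 34, 34),
                            brain_radii = c(14, 15, 13),
                            cavity_center = c(17.5, 17.5, 17.5),
                            cavity_radii = c(6.5, 6.5, 6.5),
                            csf_thickness = 1.5,
                            noise_std = noise_std, rng_seed = rng_seed))
}

as_case <- function(ph, id, gold = ph$gold)
  list(post = ph$post, mask = ph$brain, seed = ph$seed, gold = gold, id = id)

# large-cavity phantom for recovery checks: the 10%-of-max output
# binarization adds a one-voxel halo at flat faces, so DSC is bounded by
# 2V/(2V + H) with H the face-surface count; a radius-30 cavity keeps that
# ceiling above 0.97
recovery_phantom <- function(noise_std = 0, rng_seed = 1) {
  make_phantom(phantom_spec(shape = c(100, 100, 100),
                            brain_radii = c(44, 46, 42),
                            cavity_center = c(54.5, 52.5, 50.5),
                            cavity_radii = c(30, 30, 30),
                            noise_std = noise_std, rng_seed = rng_seed))
}
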