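#' Synthetic phantom specification
#'
#' Describes a brain-shaped phantom: an ellipsoidal brain inside a zero
#' background, a thin dark-ish CSF shell of unknown labels between cortex
#' and brain edge, a homogeneous dark ellipsoidal cavity (the resection)
#' carved strictly inside the brain, optional ventricle ellipsoids, additive
#' Gaussian noise clipped to the class range, and a toy parcellation
#' partitioning the interior into sided anatomical areas.  Defaults emulate
#' a typical clinical case on a 1 mm grid: tissue around 140, cavity around
#' 15 class units (markedly darker and homogeneous), a ~19 cm^3 cavity, and
#' noise standard deviation 5.  The separability invariant
#' \code{cavity + 3*noise < tissue - 3*noise} must hold so recovery tests
#' are well posed.
#'
#' @param shape volume dimensions (voxels).
#' @param brain_radii,brain_center ellipsoid semi-axes/centre of the brain
#'   (voxels; centre defaults to the volume midpoint).
#' @param cavity_center,cavity_radii ellipsoid centre/semi-axes of the
#'   cavity (voxels).
#' @param cavity_intensity,tissue_intensity,background_intensity,csf_intensity
#'   class-range intensities of the compartments.
#' @param csf_thickness thickness (voxels) of the unknown-label shell.
#' @param ventricles optional list of \code{list(center=, radii=)}
#'   ellipsoids labelled as ventricle (dark, label id 99).
#' @param ventricle_intensity intensity of ventricle voxels.
#' @param noise_std additive Gaussian noise standard deviation (class
#'   units); 0 disables noise (and consumes no randomness).
#' @param voxel_size mm per axis.
#' @param rng_seed integer seed fixing all randomness of [make_phantom()].
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(72, 72, 72),
                         brain_radii = c(30, 32, 28),
                         brain_center = (shape + 1) / 2,
                         cavity_center = brain_center + c(6, 4, 0),
                         cavity_radii = c(16.5, 16.5, 16.5),
                         cavity_intensity = 15,
                         tissue_intensity = 140,
                         background_intensity = 0,
                         csf_intensity = 60,
                         csf_thickness = 2,
                         ventricles = NULL,
                         ventricle_intensity = 20,
                         noise_std = 5,
                         voxel_size = c(1, 1, 1),
                         rng_seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            length(brain_radii) == 3L, all(brain_radii > 0),
            length(cavity_radii) == 3L, all(cavity_radii > 0),
            length(cavity_center) == 3L, length(brain_center) == 3L,
            csf_thickness >= 0, noise_std >= 0)
  if (!(cavity_intensity + 3 * noise_std < tissue_intensity - 3 * noise_std))
    stop("separability violated: cavity + 3*noise must stay below tissue - 3*noise",
         call. = FALSE)
  structure(list(shape = as.integer(shape), brain_radii = brain_radii,
                 brain_center = brain_center, cavity_center = cavity_center,
                 cavity_radii = cavity_radii,
                 cavity_intensity = cavity_intensity,
                 tissue_intensity = tissue_intensity,
                 background_intensity = background_intensity,
                 csf_intensity = csf_intensity, csf_thickness = csf_thickness,
                 ventricles = ventricles,
                 ventricle_intensity = ventricle_intensity,
                 noise_std = noise_std, voxel_size = voxel_size,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

voxel_grids <- function(dm) {
  list(i = array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm),
       j = array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm),
       k = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm))
}

ellipsoid_mask <- function(g, center, radii) {
  ((g$i - center[1]) / radii[1])^2 + ((g$j - center[2]) / radii[2])^2 +
    ((g$k - center[3]) / radii[3])^2 <= 1
}

dilate6 <- function(m) {
  dm <- dim(m)
  out <- m
  for (axis in 1:3) for (d in c(-1L, 1L)) {
    idx <- lapply(dm, seq_len)
    dst <- idx; src <- idx
    if (d > 0) { dst[[axis]] <- 2:dm[axis]; src[[axis]] <- 1:(dm[axis] - 1L) }
    else { dst[[axis]] <- 1:(dm[axis] - 1L); src[[axis]] <- 2:dm[axis] }
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | m[src[[1]], src[[2]], src[[3]]]
  }
  out
}

# toy parcellation: sided lobes by anterior-posterior fraction and height,
# a midline cingulate strip, and small hippocampus/amygdala ellipsoids
phantom_parcellation <- function(g, spec, interior) {
  bc <- spec$brain_center; br <- spec$brain_radii
  t <- (g$j - (bc[2] - br[2])) / (2 * br[2])   # 0 posterior .. 1 anterior
  lobe <- ifelse(t >= 0.6, 1L,                  # frontal
          ifelse(t < 0.2, 4L,                   # occipital
          ifelse(g$k < bc[3] - 0.15 * br[3], 2L, 3L)))  # temporal / parietal
  lab <- array(lobe, dim(interior))
  cing <- abs(g$i - bc[1]) < 0.12 * br[1] & g$k > bc[3] & t >= 0.2 & t < 0.8
  lab[cing] <- 5L
  for (side in c(-1, 1)) {
    hc <- bc + c(side * 0.45 * br[1], 0.05 * br[2], -0.35 * br[3])
    ac <- bc + c(side * 0.45 * br[1], 0.28 * br[2], -0.35 * br[3])
    lab[ellipsoid_mask(g, hc, c(3, 3, 3))] <- 6L
    lab[ellipsoid_mask(g, ac, c(2.5, 2.5, 2.5))] <- 7L
  }
  lab <- lab + ifelse(g$i < bc[1], 0L, 10L)    # lh = 1..7, rh = 11..17
  lab[!interior] <- 0L
  lab
}

phantom_lookup <- function(ids) {
  base <- data.frame(code = 1:7, area = anatomical_areas(),
                     stringsAsFactors = FALSE)
  lk <- rbind(data.frame(label_id = base$code, hemisphere = "lh",
                         area = base$area, stringsAsFactors = FALSE),
              data.frame(label_id = base$code + 10L, hemisphere = "rh",
                         area = base$area, stringsAsFactors = FALSE),
              data.frame(label_id = 99L, hemisphere = "",
                         area = "unknown", stringsAsFactors = FALSE))
  lk$name <- ifelse(lk$area == "unknown", "ventricle",
                    paste(lk$hemisphere, lk$area, sep = "-"))
  lk <- lk[lk$label_id %in% ids, c("label_id", "name", "hemisphere", "area")]
  rownames(lk) <- NULL
  lk
}

#' Generate a phantom
#'
#' Voxelizes a [phantom_spec()] into the co-registered input set the
#' segmentation pipeline consumes: the postoperative volume (tissue with the
#' cavity carved out, plus clipped Gaussian noise), the brain mask, a toy
#' parcellation with its label-to-area lookup, the exact gold-standard
#' cavity mask, and a seed at the cavity centroid.  Deterministic given the
#' spec's \code{rng_seed}; a noiseless spec consumes no randomness.
#'
#' @param spec a [phantom_spec()].
#' @return List of class \code{resect_phantom} with elements \code{post},
#'   \code{brain}, \code{labels}, \code{lookup}, \code{gold}, \code{seed},
#'   \code{ventricle_ids} and \code{spec}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape
  g <- voxel_grids(dm)
  brain <- ellipsoid_mask(g, spec$brain_center, spec$brain_radii)
  interior <- ellipsoid_mask(g, spec$brain_center,
                             pmax(spec$brain_radii - spec$csf_thickness, 1))
  cavity <- ellipsoid_mask(g, spec$cavity_center, spec$cavity_radii)
  if (!sum(cavity)) stop("cavity contains no voxels", call. = FALSE)
  if (any(dilate6(cavity) & !brain))
    stop("cavity touches the brain boundary; it must lie strictly inside the brain",
         call. = FALSE)

  post <- array(spec$background_intensity, dm)
  post[brain] <- spec$csf_intensity
  post[interior] <- spec$tissue_intensity

  lab <- phantom_parcellation(g, spec, interior)
  vent <- array(FALSE, dm)
  for (ve in spec$ventricles) {
    vm <- ellipsoid_mask(g, ve$center, ve$radii) & brain
    vent <- vent | vm
  }
  post[vent] <- spec$ventricle_intensity
  lab[vent] <- 99L
  post[cavity] <- spec$cavity_intensity

  if (spec$noise_std > 0)
    post <- with_rng(spec$rng_seed,
                     post + array(rnorm(prod(dm), 0, spec$noise_std), dm))
  post <- pmin(pmax(post, 0), 255)

  vs <- spec$voxel_size
  lookup <- phantom_lookup(sort(unique(as.vector(lab))))
  nm <- lookup$name
  names(nm) <- as.character(lookup$label_id)
  # seed placement mirrors the user instructions the pipeline assumes: a
  # voxel at the centre of the cavity whose intensity is representative of
  # the (dark, homogeneous) cavity — at or just below its mean intensity.
  # A rater would re-pick a seed sitting on a noise outlier, bright or dark.
  cav_idx <- which(cavity)
  ci <- arrayInd(cav_idx, dm)
  d2 <- (ci[, 1] - spec$cavity_center[1])^2 +
        (ci[, 2] - spec$cavity_center[2])^2 +
        (ci[, 3] - spec$cavity_center[3])^2
  cav_mean <- mean(post[cav_idx])
  central <- which(d2 <= min(d2) + 8 & post[cav_idx] <= cav_mean)
  if (!length(central)) central <- which(post[cav_idx] <= cav_mean)
  sel <- central[order(cav_mean - post[cav_idx][central], d2[central],
                       ci[central, 1], ci[central, 2], ci[central, 3])][1]
  seed <- as.integer(ci[sel, ])
  gold <- binary_mask(cavity, vs)

  structure(list(post = intensity_volume(array(post, dm), vs),
                 brain = binary_mask(brain, vs),
                 labels = label_volume(lab, nm, vs),
                 lookup = lookup, gold = gold, seed = seed,
                 ventricle_ids = 99L, spec = spec),
            class = "resect_phantom")
}

#' @export
print.resect_phantom <- function(x, ...) {
  cat("<resect_phantom> ", paste(dim(x$post$data), collapse = "x"),
      " voxels | cavity ", sum(x$gold$data), " voxels (",
      signif(mask_volume_cm3(x$gold), 4), " cm^3) | noise std ",
      x$spec$noise_std, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort with clinical ground truth
#'
#' Produces \code{n} phantom cases with cavities of varying size placed in
#' varying anatomical areas, each carrying a synthetic "clinical report":
#' the set of areas whose gold-cavity resection percentage (same percentage
#' rule as the anatomical report) exceeds \code{report_threshold_pct}.  The
#' clinical truth is thus perfectly consistent with the constructed
#' geometry, which is what cohort-level report and LOOCV tests need.
#' Deterministic given \code{rng_seed}.
#'
#' @param n number of cases (>= 2).
#' @param base_spec a [phantom_spec()] providing the anatomy shared by all
#'   cases; its cavity settings are overridden per case.  Defaults to a
#'   compact 48-voxel anatomy to keep cohorts cheap.
#' @param target_areas character vector of sided area names to cycle
#'   cavities through (defaults to the eight sided lobes).
#' @param cavity_radius_range min/max isotropic cavity radius (voxels).
#' @param report_threshold_pct percentage rule defining the synthetic
#'   clinical report (strictly above; 0 = any touched area).
#' @param rng_seed integer seed for size draws and per-case noise.
#' @return List of \code{n} cases: each has \code{id}, \code{post},
#'   \code{mask} (= \code{brain}), \code{labels}, \code{lookup},
#'   \code{gold}, \code{seed} and \code{clinical}.
#' @export
make_cohort <- function(n, base_spec = NULL, target_areas = NULL,
                        cavity_radius_range = c(4, 6),
                        report_threshold_pct = 0, rng_seed = 1L) {
  stopifnot(n >= 2L)
  if (is.null(base_spec))
    base_spec <- phantom_spec(shape = c(48, 48, 48),
                              brain_radii = c(19, 20, 18),
                              cavity_center = c(24, 24, 24) + c(4, 3, 0),
                              cavity_radii = c(5, 5, 5), noise_std = 5)
  if (is.null(target_areas)) {
    lobes <- c("frontal", "temporal", "parietal", "occipital")
    target_areas <- c(paste0("lh-", lobes), paste0("rh-", lobes))
  }
  g <- voxel_grids(base_spec$shape)
  interior <- ellipsoid_mask(g, base_spec$brain_center,
                             pmax(base_spec$brain_radii - base_spec$csf_thickness, 1))
  lab <- phantom_parcellation(g, base_spec, interior)
  lookup <- phantom_lookup(sort(unique(as.vector(lab))))
  nm <- lookup$name; names(nm) <- as.character(lookup$label_id)
  areas_vol <- map_areas(label_volume(lab, nm, base_spec$voxel_size), lookup)

  radii <- with_rng(rng_seed,
                    runif(n, cavity_radius_range[1], cavity_radius_range[2]))
  cases <- vector("list", n)
  for (ci in seq_len(n)) {
    target <- target_areas[((ci - 1L) %% length(target_areas)) + 1L]
    code <- which(sort(unique(nm[nm != "ventricle"])) == target)
    vox <- which(areas_vol$data == code)
    if (!length(vox)) stop("target area ", target, " has no voxels", call. = FALSE)
    center <- round(colMeans(arrayInd(vox, base_spec$shape)))
    r <- radii[ci]
    spec_i <- NULL
    for (try in 1:40) {
      cand <- tryCatch({
        s <- phantom_spec(shape = base_spec$shape,
                          brain_radii = base_spec$brain_radii,
                          brain_center = base_spec$brain_center,
                          cavity_center = center, cavity_radii = rep(r, 3),
                          cavity_intensity = base_spec$cavity_intensity,
                          tissue_intensity = base_spec$tissue_intensity,
                          background_intensity = base_spec$background_intensity,
                          csf_intensity = base_spec$csf_intensity,
                          csf_thickness = base_spec$csf_thickness,
                          ventricles = base_spec$ventricles,
                          ventricle_intensity = base_spec$ventricle_intensity,
                          noise_std = base_spec$noise_std,
                          voxel_size = base_spec$voxel_size,
                          rng_seed = rng_seed * 131L + ci)
        make_phantom(s)
      }, error = function(e) NULL)
      if (!is.null(cand)) { spec_i <- cand; break }
      # cavity clipped the boundary: shrink, then drift towards the centre
      if (r > 3) r <- r - 0.5
      else center <- round(center + 0.3 * (base_spec$brain_center - center))
    }
    if (is.null(spec_i))
      stop("could not place a cavity inside area ", target, call. = FALSE)
    rep_i <- overlap_report(spec_i$gold, areas_vol)
    clinical <- rep_i$area[rep_i$resection_pct > report_threshold_pct]
    cases[[ci]] <- list(id = sprintf("phantom%02d", ci), post = spec_i$post,
                        mask = spec_i$brain, brain = spec_i$brain,
                        labels = spec_i$labels, lookup = spec_i$lookup,
                        gold = spec_i$gold, seed = spec_i$seed,
                        clinical = clinical, target_area = target)
  }
  cases
}
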