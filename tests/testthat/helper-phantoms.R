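# Shared desk-scale phantom configurations. Physics parameters (PSF, MFPs,
# signal levels, bleaching) are the package defaults; grids are coarsened /
# TMs shrunk so the whole suite stays fast.

# 400 um TM on a 4 um grid: penetration / contrast scale.
nuclear_cfg <- function(...) {
  args <- utils::modifyList(
    list(tm_diameter = 400, voxel_size = c(4, 4, 4),
         nucleus_count = 350, nucleus_diameter_mean = 14,
         nucleus_diameter_sd = 2, rng_seed = 7),
    list(...))
  do.call(phantom_config, args)
}

# small, finely-sampled bead field: PSF scale.
bead_cfg <- function(...) {
  args <- utils::modifyList(
    list(tm_diameter = 30, voxel_size = c(0.5, 0.3, 0.3),
         nucleus_count = 0, tm_base_fraction = 0, bead_count = 20,
         psf_sigma = c(1.5, 0.6, 0.6), mfp_illum = 1e9, mfp_det = 1e9,
         noise_model = "none", rng_seed = 11),
    list(...))
  do.call(phantom_config, args)
}

# tiny TM for bleach series.
bleach_cfg <- function(...) {
  args <- utils::modifyList(
    list(tm_diameter = 60, voxel_size = c(4, 4, 4),
         nucleus_count = 12, nucleus_diameter_mean = 10,
         mfp_illum = 1e9, mfp_det = 1e9,
         noise_model = "multiplicative", noise_frac = 0.02,
         bleach_tau = 27.6, n_frames = 12, frame_interval = 10,
         rng_seed = 5),
    list(...))
  do.call(phantom_config, args)
}

# render cache: identical configs are rendered once per test run.
.render_cache <- new.env(parent = emptyenv())

cached_render <- function(cfg) {
  key <- paste(deparse(unclass(cfg)), collapse = "")
  if (!exists(key, envir = .render_cache))
    assign(key, render_phantom(cfg), envir = .render_cache)
  get(key, envir = .render_cache)
}

cached_tm <- function(cfg) {
  key <- paste("tm", paste(deparse(unclass(cfg)), collapse = ""))
  if (!exists(key, envir = .render_cache))
    assign(key, segment_tm(cached_render(cfg)$stack), envir = .render_cache)
  get(key, envir = .render_cache)
}

# logical mask of the true nuclei (from ground truth), for region-based
# metrics that should not depend on the segmenter.
truth_nuclei_mask <- function(stack, truth, shrink = 0) {
  d <- dim(stack$voxels)
  vs <- stack$voxel_size
  m <- array(FALSE, d)
  for (i in seq_len(nrow(truth$nucleus_centers))) {
    cen <- truth$nucleus_centers[i, ]
    r <- truth$nucleus_radii[i] - shrink
    lo <- pmax(1L, floor((cen - r) / vs))
    hi <- pmin(d, ceiling((cen + r) / vs))
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    cz <- (iz - 0.5) * vs[1] - cen[1]
    cy <- (iy - 0.5) * vs[2] - cen[2]
    cx <- (ix - 0.5) * vs[3] - cen[3]
    m[iz, iy, ix] <- m[iz, iy, ix] |
      (outer(outer(cz^2, cy^2, "+"), cx^2, "+") <= r^2)
  }
  m
}

# region well outside the TM (background sampling)
far_background_mask <- function(stack, truth, margin = 6) {
  d <- dim(stack$voxels)
  vs <- stack$voxel_size
  far <- array(TRUE, d)
  for (k in 1:3) {
    co <- (seq_len(d[k]) - 0.5) * vs[k]
    idx <- abs(co - truth$tm_center[k]) < truth$tm_radius + margin
    if (k == 1) far[idx, , ] <- FALSE
    if (k == 2) far[, idx, ] <- FALSE
    if (k == 3) far[, , idx] <- FALSE
  }
  far
}

# sphere image builder for unit-level segmentation tests
sphere_image <- function(dims, vs, centers, radii, amp = 1000, bg = 0) {
  v <- array(bg, dims)
  for (i in seq_len(nrow(centers))) {
    cz <- (seq_len(dims[1]) - 0.5) * vs[1] - centers[i, 1]
    cy <- (seq_len(dims[2]) - 0.5) * vs[2] - centers[i, 2]
    cx <- (seq_len(dims[3]) - 0.5) * vs[3] - centers[i, 3]
    v[outer(outer(cz^2, cy^2, "+"), cx^2, "+") <= radii[i]^2] <- amp
  }
  v
}
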