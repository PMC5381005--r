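# Synthetic tissue-mimic (TM) phantom with full ground truth.
#
# Forward model, in order: (1) spherical nuclei (non-overlapping hard
# spheres) and point-like beads placed inside the TM sphere; (2) each
# object's emission scaled by ballistic attenuation exp(-d_ill / MFP_ill)
# along the illumination path (entering at the +x face, propagating toward
# -x) and exp(-d_det / MFP_det) along the detection path (+z, toward the
# objective); (3) convolution with an anisotropic Gaussian PSF whose axial
# kernel gains a wide mixture component when a Bessel side-lobe fraction is
# set; (4) constant background; (5) camera noise; (6) for time series,
# per-frame exponential photobleaching of the signal (not the background).

#' Phantom configuration
#'
#' Defaults reproduce the imaging conditions of a 400 um multicellular
#' tumour spheroid acquired on a digitally-scanned light-sheet system:
#' 1 um z step and 0.65 um lateral pixels, ~5.4 um axial / ~1.4 um lateral
#' PSF FWHM, a photon mean free path of 0.2 mm (visible excitation) on both
#' optical paths, a 100:1 peak-to-background ratio with Poisson noise, and
#' for time series a 27.6 s bleaching decay time sampled every 10 s. Tests
#' and examples typically override `voxel_size`/`tm_diameter` to keep desk
#' runtimes small; the physics parameters are the defaults above.
#'
#' @param tm_diameter TM diameter in micrometres.
#' @param voxel_size `(dz, dy, dx)` voxel pitch in micrometres.
#' @param shape optional stack shape `(nz, ny, nx)`; default fits the TM
#'   plus a margin of at least twice the largest PSF FWHM.
#' @param tm_center_offset `(z, y, x)` offset of the TM centre from the
#'   stack centre, micrometres.
#' @param nucleus_diameter_mean,nucleus_diameter_sd nucleus diameter
#'   distribution, micrometres.
#' @param nucleus_count number of nuclei (hard spheres, rejection-sampled;
#'   an error is raised after 10000 consecutive placement failures).
#' @param bead_count,bead_diameter,bead_min_separation sub-resolution beads:
#'   count, diameter (um; rendered as points) and minimum pairwise
#'   separation (um).
#' @param psf_sigma PSF Gaussian sigmas `(sz, sy, sx)` in micrometres.
#' @param bessel_sidelobe_fraction fraction `f` in `[0, 1)` of axial energy
#'   placed in a 3x wider axial component (Bessel side-lobe surrogate).
#' @param mfp_illum,mfp_det photon mean free paths in millimetres along the
#'   illumination (x) and detection (z) paths; `Inf` disables attenuation.
#' @param peak_signal,background_level signal amplitude and additive
#'   background, in camera counts.
#' @param tm_base_fraction diffuse in-sample signal (cytoplasmic stain /
#'   autofluorescence) painted over the whole TM sphere as a fraction of
#'   `peak_signal`, attenuated per voxel; makes the TM a connected bright
#'   body, as stained spheroids are. 0 disables.
#' @param noise_model one of `"none"`, `"poisson"`, `"gaussian"`, `"mixed"`,
#'   `"multiplicative"`.
#' @param noise_sd additive Gaussian sigma in counts (gaussian/mixed).
#' @param noise_frac relative sigma for multiplicative noise.
#' @param bleach_tau photobleaching decay time in seconds (`Inf` disables).
#' @param n_frames,frame_interval time-series length and frame spacing (s).
#' @param rng_seed integer seed; renders are deterministic given the seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(tm_diameter = 400,
                           voxel_size = c(1, 0.65, 0.65),
                           shape = NULL,
                           tm_center_offset = c(0, 0, 0),
                           nucleus_diameter_mean = 12,
                           nucleus_diameter_sd = 2,
                           nucleus_count = 500,
                           bead_count = 0,
                           bead_diameter = 0.5,
                           bead_min_separation = 3,
                           psf_sigma = c(2.3, 0.6, 0.6),
                           bessel_sidelobe_fraction = 0,
                           mfp_illum = 0.2,
                           mfp_det = 0.2,
                           peak_signal = 10000,
                           background_level = 10,
                           tm_base_fraction = 0.15,
                           noise_model = c("poisson", "none", "gaussian",
                                           "mixed", "multiplicative"),
                           noise_sd = 0,
                           noise_frac = 0.02,
                           bleach_tau = 27.6,
                           n_frames = 12,
                           frame_interval = 10,
                           rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(tm_diameter = tm_diameter, voxel_size = as.numeric(voxel_size),
              shape = shape, tm_center_offset = as.numeric(tm_center_offset),
              nucleus_diameter_mean = nucleus_diameter_mean,
              nucleus_diameter_sd = nucleus_diameter_sd,
              nucleus_count = nucleus_count,
              bead_count = bead_count, bead_diameter = bead_diameter,
              bead_min_separation = bead_min_separation,
              psf_sigma = as.numeric(psf_sigma),
              bessel_sidelobe_fraction = bessel_sidelobe_fraction,
              mfp_illum = mfp_illum, mfp_det = mfp_det,
              peak_signal = peak_signal, background_level = background_level,
              tm_base_fraction = tm_base_fraction,
              noise_model = noise_model, noise_sd = noise_sd,
              noise_frac = noise_frac,
              bleach_tau = bleach_tau, n_frames = n_frames,
              frame_interval = frame_interval, rng_seed = as.integer(rng_seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$tm_diameter > 0, all(cfg$voxel_size > 0),
            length(cfg$psf_sigma) == 3L, all(cfg$psf_sigma >= 0),
            cfg$bessel_sidelobe_fraction >= 0,
            cfg$bessel_sidelobe_fraction < 1,
            cfg$mfp_illum > 0, cfg$mfp_det > 0,
            cfg$peak_signal > 0, cfg$background_level >= 0,
            cfg$bleach_tau > 0, cfg$frame_interval > 0,
            cfg$nucleus_count >= 0, cfg$bead_count >= 0)
  fwhm_max <- 2 * sqrt(2 * log(2)) * max(cfg$psf_sigma)
  shape <- phantom_shape(cfg)
  extent <- shape * cfg$voxel_size
  if (any(cfg$tm_diameter + 2 * abs(cfg$tm_center_offset) +
            2 * fwhm_max > extent + 1e-9))
    stop("TM does not fit inside the stack with a margin of 2 PSF FWHM; ",
         "enlarge 'shape' or reduce 'tm_diameter'")
  invisible(cfg)
}

# Stack shape (nz, ny, nx) implied by a config.
phantom_shape <- function(cfg) {
  if (!is.null(cfg$shape)) return(as.integer(cfg$shape))
  fwhm_max <- 2 * sqrt(2 * log(2)) * max(cfg$psf_sigma)
  margin <- max(2 * fwhm_max, 10)
  as.integer(ceiling((cfg$tm_diameter + 2 * margin +
                        2 * abs(cfg$tm_center_offset)) / cfg$voxel_size))
}

# Ballistic attenuation factors for objects at positions `pos` (n x 3 matrix,
# um, (z,y,x)) inside a TM sphere at `center` with radius R. The illumination
# path runs from the +x entry point of the sphere to the object; the
# detection path from the object to the +z exit point. MFPs in mm.
attenuation_factors <- function(pos, center, radius, mfp_illum, mfp_det) {
  rel <- sweep(pos, 2L, center)
  d_ill <- sqrt(pmax(0, radius^2 - rel[, 1L]^2 - rel[, 2L]^2)) - rel[, 3L]
  d_det <- sqrt(pmax(0, radius^2 - rel[, 2L]^2 - rel[, 3L]^2)) - rel[, 1L]
  list(ill = exp(-pmax(0, d_ill) / (mfp_illum * 1000)),
       det = exp(-pmax(0, d_det) / (mfp_det * 1000)))
}

# Sample `n` points uniformly in a sphere (radius in um, centre (z,y,x) um),
# optionally keeping a minimum pairwise separation by rejection.
sample_in_sphere <- function(n, center, radius, min_sep = 0, own_radii = NULL,
                            max_failures = 10000L) {
  pts <- matrix(0, 0L, 3L)
  radii <- numeric(0)
  failures <- 0L
  while (nrow(pts) < n) {
    p <- stats::runif(3, -1, 1)
    if (sum(p^2) > 1) next
    r_new <- if (is.null(own_radii)) 0 else own_radii[nrow(pts) + 1L]
    if (sqrt(sum(p^2)) * radius > radius - r_new) {
      failures <- failures + 1L
      if (failures > max_failures)
        stop("could not place objects: too dense after ", max_failures,
             " rejections")
      next
    }
    cand <- center + p * radius
    ok <- TRUE
    if (nrow(pts)) {
      dd <- sqrt(colSums((t(pts) - cand)^2))
      lim <- if (is.null(own_radii)) min_sep else radii + r_new
      ok <- all(dd >= pmax(lim, min_sep))
    }
    if (ok) {
      pts <- rbind(pts, cand)
      radii <- c(radii, r_new)
      failures <- 0L
    } else {
      failures <- failures + 1L
      if (failures > max_failures)
        stop("could not place objects: too dense after ", max_failures,
             " rejections")
    }
  }
  pts
}

# Paint a solid sphere (amplitude `amp`) into `vol` (modified in place via
# return); coordinates in um.
paint_sphere <- function(vol, voxel_size, center, radius, amp) {
  d <- dim(vol)
  lo <- pmax(1L, floor((center - radius) / voxel_size - 0.5) + 1L)
  hi <- pmin(d, ceiling((center + radius) / voxel_size + 0.5))
  iz <- lo[1L]:hi[1L]; iy <- lo[2L]:hi[2L]; ix <- lo[3L]:hi[3L]
  cz <- (iz - 0.5) * voxel_size[1L] - center[1L]
  cy <- (iy - 0.5) * voxel_size[2L] - center[2L]
  cx <- (ix - 0.5) * voxel_size[3L] - center[3L]
  inside <- outer(outer(cz^2, cy^2, "+"), cx^2, "+") <= radius^2
  sub <- vol[iz, iy, ix, drop = FALSE]
  sub[inside] <- sub[inside] + amp
  vol[iz, iy, ix] <- sub
  vol
}

# Trilinear splat of a point source with total intensity `amp` at `center`
# (um) into `vol`.
splat_point <- function(vol, voxel_size, center, amp) {
  d <- dim(vol)
  f <- center / voxel_size + 0.5   # fractional voxel index
  i0 <- floor(f)
  w1 <- f - i0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    idx <- i0 + c(dz, dy, dx)
    if (any(idx < 1) || any(idx > d)) next
    w <- prod(ifelse(c(dz, dy, dx) == 1, w1, 1 - w1))
    vol[idx[1L], idx[2L], idx[3L]] <- vol[idx[1L], idx[2L], idx[3L]] + amp * w
  }
  vol
}

#' Per-voxel ballistic attenuation volumes
#'
#' Attenuation factors `exp(-d / MFP)` at every voxel of a grid, along the
#' illumination path (entering the TM sphere at its +x pole and propagating
#' toward -x) and the detection path (leaving toward +z). Voxels outside the
#' TM get factor 1.
#'
#' @param shape stack shape `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param center,radius TM sphere centre (z, y, x, um) and radius (um).
#' @param mfp_illum,mfp_det mean free paths in millimetres.
#' @return list of two arrays `ill` and `det` in `(0, 1]`.
#' @export
attenuation_volume <- function(shape, voxel_size, center, radius,
                               mfp_illum, mfp_det) {
  cz <- axis_coords(shape[1L], voxel_size[1L]) - center[1L]
  cy <- axis_coords(shape[2L], voxel_size[2L]) - center[2L]
  cx <- axis_coords(shape[3L], voxel_size[3L]) - center[3L]
  one <- function(u) rep(1, length(u))
  zz <- outer(outer(cz^2, one(cy)), one(cx))
  yy <- outer(outer(one(cz), cy^2), one(cx))
  xx <- outer(outer(one(cz), one(cy)), cx^2)
  zv <- outer(outer(cz, one(cy)), one(cx))
  xv <- outer(outer(one(cz), one(cy)), cx)
  inside <- zz + yy + xx <= radius^2
  d_ill <- sqrt(pmax(0, radius^2 - zz - yy)) - xv
  d_det <- sqrt(pmax(0, radius^2 - yy - xx)) - zv
  ill <- array(1, shape)
  det <- array(1, shape)
  ill[inside] <- exp(-pmax(0, d_ill[inside]) / (mfp_illum * 1000))
  det[inside] <- exp(-pmax(0, d_det[inside]) / (mfp_det * 1000))
  list(ill = ill, det = det)
}

# Noise-free emission volume plus ground truth (shared by the 3D and 4D
# renderers). Consumes RNG for object placement only.
render_emission <- function(cfg) {
  shape <- phantom_shape(cfg)
  vs <- cfg$voxel_size
  center <- shape * vs / 2 + cfg$tm_center_offset
  radius <- cfg$tm_diameter / 2

  nuc_r <- numeric(0)
  nuc_pos <- matrix(0, 0L, 3L)
  if (cfg$nucleus_count > 0) {
    nuc_r <- abs(stats::rnorm(cfg$nucleus_count, cfg$nucleus_diameter_mean,
                              cfg$nucleus_diameter_sd)) / 2
    nuc_r <- pmax(nuc_r, 0.5)
    nuc_pos <- sample_in_sphere(cfg$nucleus_count, center, radius,
                                own_radii = nuc_r)
  }
  bead_pos <- matrix(0, 0L, 3L)
  if (cfg$bead_count > 0)
    bead_pos <- sample_in_sphere(cfg$bead_count, center, radius,
                                 min_sep = cfg$bead_min_separation)

  sig <- array(0, shape)
  if (cfg$tm_base_fraction > 0) {
    att_v <- attenuation_volume(shape, vs, center, radius,
                                cfg$mfp_illum, cfg$mfp_det)
    cz <- axis_coords(shape[1L], vs[1L]) - center[1L]
    cy <- axis_coords(shape[2L], vs[2L]) - center[2L]
    cx <- axis_coords(shape[3L], vs[3L]) - center[3L]
    inside <- outer(outer(cz^2, cy^2, "+"), cx^2, "+") <= radius^2
    sig[inside] <- cfg$peak_signal * cfg$tm_base_fraction *
      (att_v$ill * att_v$det)[inside]
  }
  att_n <- list(ill = numeric(0), det = numeric(0))
  if (nrow(nuc_pos)) {
    att_n <- attenuation_factors(nuc_pos, center, radius,
                                 cfg$mfp_illum, cfg$mfp_det)
    for (i in seq_len(nrow(nuc_pos)))
      sig <- paint_sphere(sig, vs, nuc_pos[i, ], nuc_r[i],
                          cfg$peak_signal * att_n$ill[i] * att_n$det[i])
  }

  sigma_vox <- cfg$psf_sigma / vs
  f <- cfg$bessel_sidelobe_fraction
  kz_max <- max(gaussian_kernel_1d(sigma_vox[1L], f)) *
    max(gaussian_kernel_1d(sigma_vox[2L])) *
    max(gaussian_kernel_1d(sigma_vox[3L]))

  att_b <- list(ill = numeric(0), det = numeric(0))
  if (nrow(bead_pos)) {
    att_b <- attenuation_factors(bead_pos, center, radius,
                                 cfg$mfp_illum, cfg$mfp_det)
    # scale so a bead's post-blur peak is ~ peak_signal * attenuation
    for (i in seq_len(nrow(bead_pos)))
      sig <- splat_point(sig, vs, bead_pos[i, ],
                         cfg$peak_signal * att_b$ill[i] * att_b$det[i] / kz_max)
  }

  sig <- smooth_gaussian_3d(sig, sigma_vox, axial_mixture_frac = f)
  sig[sig < 0] <- 0

  truth <- structure(
    list(nucleus_centers = nuc_pos, nucleus_radii = nuc_r,
         bead_centers = bead_pos,
         nucleus_attenuation = att_n, bead_attenuation = att_b,
         tm_center = center, tm_radius = radius,
         psf_sigma = cfg$psf_sigma,
         bessel_sidelobe_fraction = f,
         mfp_illum = cfg$mfp_illum, mfp_det = cfg$mfp_det,
         bleach_tau = cfg$bleach_tau, rng_seed = cfg$rng_seed),
    class = "phantom_truth")
  list(signal = sig, truth = truth)
}

apply_noise <- function(v, cfg) {
  switch(cfg$noise_model,
         none = v,
         poisson = {
           out <- stats::rpois(length(v), lambda = as.vector(v))
           array(out, dim(v))
         },
         gaussian = pmax(v + stats::rnorm(length(v), 0, cfg$noise_sd), 0),
         mixed = {
           out <- stats::rpois(length(v), lambda = as.vector(v)) +
             stats::rnorm(length(v), 0, cfg$noise_sd)
           array(pmax(out, 0), dim(v))
         },
         multiplicative = pmax(v * (1 + stats::rnorm(length(v), 0,
                                                     cfg$noise_frac)), 0))
}

#' Render a 3D tissue-mimic phantom
#'
#' @param config a [phantom_config()].
#' @return a list with elements `stack` (an [image_stack()]) and `truth`
#'   (the generating ground truth: object positions and radii, per-object
#'   attenuation factors, PSF sigmas, MFPs, seed).
#' @export
render_phantom <- function(config) {
  validate_phantom_config(config)
  set.seed(config$rng_seed)
  em <- render_emission(config)
  v <- apply_noise(em$signal + config$background_level, config)
  list(stack = image_stack(v, config$voxel_size,
                           channel_label = "phantom"),
       truth = em$truth)
}

#' Render a 4D photobleaching time series
#'
#' Frame n (n = 1..n_frames, times t_n = (n-1) * frame_interval) has the
#' noise-free signal scaled by `exp(-t_n / bleach_tau)`; the background does
#' not bleach. Noise is drawn independently per frame.
#'
#' @param config a [phantom_config()] with `n_frames >= 3`.
#' @return a list with `stack` (4D [image_stack()]) and `truth`.
#' @export
render_bleach_series <- function(config) {
  validate_phantom_config(config)
  if (config$n_frames < 3) stop("a bleach series needs n_frames >= 3")
  set.seed(config$rng_seed)
  em <- render_emission(config)
  shape <- dim(em$signal)
  vox <- array(0, c(config$n_frames, shape))
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  for (n in seq_len(config$n_frames)) {
    fade <- if (is.finite(config$bleach_tau))
      exp(-times[n] / config$bleach_tau) else 1
    vox[n, , , ] <- apply_noise(em$signal * fade + config$background_level,
                                config)
  }
  list(stack = image_stack(vox, config$voxel_size,
                           frame_interval = config$frame_interval,
                           channel_label = "phantom bleach series"),
       truth = em$truth)
}

#' Simulate a ballistic attenuation profile
#'
#' Generates `I(d) = i0 * exp(-d / MFP)` with multiplicative Gaussian noise,
#' the measurement model behind mean-free-path estimation in scattering
#' tissue.
#'
#' @param mfp mean free path in millimetres.
#' @param depths depths in micrometres (strictly increasing).
#' @param i0 intensity at zero depth.
#' @param noise_frac relative noise sigma (0 for noise-free).
#' @param seed optional integer seed.
#' @param label wavelength / condition label.
#' @return an [attenuation_profile()].
#' @export
simulate_attenuation_profile <- function(mfp, depths = seq(0, 350, by = 5),
                                         i0 = 100, noise_frac = 0.02,
                                         seed = NULL, label = "") {
  stopifnot(mfp > 0)
  if (!is.null(seed)) set.seed(seed)
  intensity <- i0 * exp(-depths / (mfp * 1000))
  if (noise_frac > 0)
    intensity <- intensity * (1 + stats::rnorm(length(depths), 0, noise_frac))
  attenuation_profile(depths, pmax(intensity, 0), label = label)
}
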