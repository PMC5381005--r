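# Low-level 3D array primitives shared by the phantom generator and the
# segmentation/metric modules. Arrays are indexed (z, y, x); physical
# coordinates of voxel i along an axis with pitch d are (i - 0.5) * d.

#' Sampled 1D Gaussian kernel, optionally a two-component mixture
#'
#' The mixture form `(1 - f) * N(sigma) + f * N(scale * sigma)` is the
#' surrogate used for Bessel-beam side lobes: a fraction `f` of the axial
#' energy is carried by a kernel `scale` times wider than the central lobe.
#'
#' @param sigma_vox standard deviation in voxels; `<= 0` returns the identity
#'   kernel `1`.
#' @param mixture_frac fraction of energy in the wide component, in `[0, 1)`.
#' @param mixture_scale width ratio of the wide component (default 3).
#' @return numeric kernel of odd length summing to 1.
#' @keywords internal
gaussian_kernel_1d <- function(sigma_vox, mixture_frac = 0, mixture_scale = 3) {
  if (sigma_vox <= 0) return(1)
  stopifnot(mixture_frac >= 0, mixture_frac < 1)
  s_max <- if (mixture_frac > 0) mixture_scale * sigma_vox else sigma_vox
  r <- max(1L, as.integer(ceiling(4 * s_max)))
  u <- seq.int(-r, r)
  k <- (1 - mixture_frac) * exp(-u^2 / (2 * sigma_vox^2)) / sigma_vox
  if (mixture_frac > 0) {
    sw <- mixture_scale * sigma_vox
    k <- k + mixture_frac * exp(-u^2 / (2 * sw^2)) / sw
  }
  k / sum(k)
}

# Convolve a 3D array along one axis (1 = z, 2 = y, 3 = x) with a 1D kernel,
# zero-padded at the borders. The convolution is a banded-matrix product so
# it runs through BLAS rather than an R loop.
convolve_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  n <- dp[1L]
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  ri <- row(K) - col(K)
  for (off in seq.int(-r, r)) K[ri == off] <- kernel[off + r + 1L]
  out <- K %*% matrix(ap, nrow = n)
  dim(out) <- dp
  aperm(out, order(perm))
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' @param a 3D array indexed (z, y, x).
#' @param sigma_vox per-axis standard deviations in voxels, `(z, y, x)`.
#' @param axial_mixture_frac,axial_mixture_scale optional wide-component
#'   mixture on the z (axial) kernel; see [gaussian_kernel_1d()].
#' @keywords internal
smooth_gaussian_3d <- function(a, sigma_vox,
                               axial_mixture_frac = 0,
                               axial_mixture_scale = 3) {
  a <- convolve_axis(a, gaussian_kernel_1d(sigma_vox[1L], axial_mixture_frac,
                                           axial_mixture_scale), 1L)
  a <- convolve_axis(a, gaussian_kernel_1d(sigma_vox[2L]), 2L)
  convolve_axis(a, gaussian_kernel_1d(sigma_vox[3L]), 3L)
}

# Shift a 3D array by integer offsets (dz, dy, dx), padding with `fill`.
shift_array_3d <- function(a, s, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (s[k] >= 0) {
      if (s[k] >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - s[k])
      dst[[k]] <- seq.int(s[k] + 1L, d[k])
    } else {
      if (-s[k] >= d[k]) return(out)
      src[[k]] <- seq.int(1L - s[k], d[k])
      dst[[k]] <- seq_len(d[k] + s[k])
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Logical array of 26-connected local maxima (>= all neighbours).
local_maxima_3d <- function(a) {
  nb <- array(-Inf, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pmax(nb, shift_array_3d(a, c(dz, dy, dx), fill = -Inf))
  }
  a >= nb
}

# Otsu's threshold on a numeric vector (histogram with `n_bins` bins).
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1L]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# --- 6-connected component machinery -----------------------------------------

# Linear-index 6-neighbours of `idx` in an array with dims `d`; returns a list
# of equal-length vectors (neighbour index, source position), out-of-bounds
# neighbours dropped.
neighbours_6 <- function(idx, d) {
  nz <- d[1L]; ny <- d[2L]
  iz <- (idx - 1L) %% nz + 1L
  iy <- ((idx - 1L) %/% nz) %% ny + 1L
  ix <- (idx - 1L) %/% (nz * ny) + 1L
  res_idx <- integer(0); res_src <- integer(0)
  add <- function(ok, off) {
    res_idx <<- c(res_idx, idx[ok] + off)
    res_src <<- c(res_src, which(ok))
  }
  add(iz > 1L, -1L)
  add(iz < nz, 1L)
  add(iy > 1L, -nz)
  add(iy < ny, nz)
  add(ix > 1L, -nz * ny)
  add(ix < d[3L], nz * ny)
  list(idx = res_idx, src = res_src)
}

# Label 6-connected components of a logical 3D array. Components are numbered
# in order of their first (column-major) voxel, so ties between equally-sized
# components are broken by first label.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  todo <- which(mask)
  n_lab <- 0L
  seen <- !mask
  for (seed in todo) {
    if (lab[seed] != 0L || !mask[seed]) next
    if (seen[seed]) next
    n_lab <- n_lab + 1L
    frontier <- seed
    lab[frontier] <- n_lab
    seen[frontier] <- TRUE
    while (length(frontier)) {
      nb <- neighbours_6(frontier, d)$idx
      nb <- unique(nb[mask[nb] & !seen[nb]])
      if (length(nb)) {
        lab[nb] <- n_lab
        seen[nb] <- TRUE
      }
      frontier <- nb
    }
  }
  lab
}

# Fill interior holes of a logical 3D mask: background components not touching
# the array border are converted to foreground.
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- label_components_3d(!mask)
  if (max(bg) == 0L) return(mask)
  border <- array(FALSE, d)
  border[c(1L, d[1L]), , ] <- TRUE
  border[, c(1L, d[2L]), ] <- TRUE
  border[, , c(1L, d[3L])] <- TRUE
  outside <- unique(bg[border & !mask])
  mask | (bg != 0L & !(bg %in% outside))
}

# Ellipsoidal structuring-element offsets for a physical radius (micrometres)
# on an anisotropic grid.
ball_offsets <- function(radius_um, voxel_size) {
  r_vox <- pmax(0L, floor(radius_um / voxel_size))
  offs <- expand.grid(dz = -r_vox[1L]:r_vox[1L],
                      dy = -r_vox[2L]:r_vox[2L],
                      dx = -r_vox[3L]:r_vox[3L])
  keep <- (offs$dz * voxel_size[1L])^2 + (offs$dy * voxel_size[2L])^2 +
    (offs$dx * voxel_size[3L])^2 <= radius_um^2
  as.matrix(offs[keep, , drop = FALSE])
}

dilate_3d <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift_array_3d(mask, offsets[i, ], fill = FALSE)
  out
}

erode_3d <- function(mask, offsets) {
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift_array_3d(mask, offsets[i, ], fill = FALSE)
  out
}

close_3d <- function(mask, radius_um, voxel_size) {
  offs <- ball_offsets(radius_um, voxel_size)
  if (nrow(offs) <= 1L) return(mask)
  erode_3d(dilate_3d(mask, offs), offs)
}

# --- seeded watershed ---------------------------------------------------------

# Level-set seeded watershed: voxels of `intensity` inside `mask` are flooded
# from the seed voxels in descending-intensity bands; within a band, unlabeled
# voxels adjacent to a labeled voxel take the label of their brightest labeled
# 6-neighbour. Voxels not connected to any seed stay 0.
watershed_seeded_3d <- function(intensity, mask, seed_idx, n_bands = 32L) {
  d <- dim(intensity)
  lab <- array(0L, d)
  lab[seed_idx] <- seq_along(seed_idx)
  fg <- which(mask & lab == 0L)
  if (!length(fg)) return(lab)
  qs <- stats::quantile(intensity[fg], probs = seq(1, 0, length.out = n_bands + 1L))
  for (b in seq_len(n_bands)) {
    active_level <- qs[b + 1L]
    repeat {
      cand <- which(mask & lab == 0L & intensity >= active_level)
      if (!length(cand)) break
      nb <- neighbours_6(cand, d)
      nb_lab <- lab[nb$idx]
      has <- nb_lab > 0L
      if (!any(has)) break
      src <- nb$src[has]
      nb_int <- intensity[nb$idx[has]]
      nb_lab <- nb_lab[has]
      # per candidate, label of the brightest labeled neighbour
      ord <- order(src, -nb_int)
      first <- !duplicated(src[ord])
      lab[cand[src[ord][first]]] <- nb_lab[ord][first]
    }
  }
  lab
}
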