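# Penetration-depth analysis: TM segmentation, equatorial z-x section,
# local-contrast map, Contrasted Imaging Volume (CIV), its Centre of Mass
# (CoM) and quadrant coverage.
#
# Quadrant convention on the equatorial z-x section, fixed package-wide:
# Q1 = (+z, +x)  near the detection objective AND near the illumination entry
# Q2 = (-z, +x)  illumination-entry half, far from the objective
# Q3 = (-z, -x)  far from both
# Q4 = (+z, -x)  detection-near half, far from the entry
# so Q1/Q4 probe the detection path and Q2/Q3 the illumination path, and a
# well-imaged TM concentrates its CIV near the Q1/Q2 boundary.

#' Segment the tissue mimic
#'
#' Gaussian-smoothed stack thresholded by Otsu on the log intensities (the
#' log compresses the huge dynamic range that ballistic attenuation imposes
#' across a TM, so the threshold separates background from tissue rather
#' than dim tissue from bright tissue); the largest 6-connected component is
#' kept (ties broken by first label), interior holes are filled, and a
#' morphological closing regularizes the surface.
#'
#' @param stack a 3D [image_stack()].
#' @param smooth_sigma_um isotropic smoothing sigma in micrometres.
#' @param close_radius_um closing structuring-element radius in micrometres
#'   (0 disables).
#' @return an object of class `tm_mask`: logical `mask`, `center` (z, y, x)
#'   in um, `radius` (equivalent-sphere, um), `sphericity` (Jaccard overlap
#'   with the ideal sphere at that centre/radius).
#' @export
segment_tm <- function(stack, smooth_sigma_um = 4, close_radius_um = 3) {
  stopifnot(inherits(stack, "image_stack"), !is_time_series(stack))
  v <- stack$voxels
  vs <- stack$voxel_size
  g <- smooth_gaussian_3d(v, smooth_sigma_um / vs)
  lg <- log1p(g)
  fg <- lg > otsu_threshold(lg)
  if (!any(fg)) stop("no foreground after Otsu threshold")
  lab <- label_components_3d(fg)
  counts <- tabulate(lab[lab > 0L])
  fg <- lab == which.max(counts)
  fg <- fill_holes_3d(fg)
  if (close_radius_um > 0) fg <- close_3d(fg, close_radius_um, vs)
  idx <- arrayInd(which(fg), dim(fg))
  center <- colMeans(sweep(idx - 0.5, 2L, vs, "*"))
  vol <- sum(fg) * prod(vs)
  radius <- (3 * vol / (4 * pi))^(1 / 3)
  coords <- lapply(1:3, function(k) axis_coords(dim(fg)[k], vs[k]) - center[k])
  sph <- outer(outer(coords[[1L]]^2, coords[[2L]]^2, "+"), coords[[3L]]^2,
               "+") <= radius^2
  sphericity <- sum(fg & sph) / sum(fg | sph)
  structure(list(mask = fg, center = center, radius = radius,
                 sphericity = sphericity, voxel_size = vs),
            class = "tm_mask")
}

#' @export
print.tm_mask <- function(x, ...) {
  cat("tm_mask: centre (z,y,x) =",
      paste(round(x$center, 1), collapse = ", "), "um;",
      "equivalent radius", round(x$radius, 1), "um;",
      "sphericity", round(x$sphericity, 3), "\n")
  invisible(x)
}

#' Equatorial z-x section of a tissue mimic
#'
#' The z-x plane at the y index of the TM centre, averaged over a 3-slice
#' slab to reduce noise, with the TM mask restricted to the central plane.
#'
#' @param stack a 3D [image_stack()].
#' @param mask a [tm_mask()] from [segment_tm()].
#' @return an object of class `tm_section`: `image` (z-by-x matrix), `mask`
#'   (logical, same shape), `center_zx` (TM centre in the section, um),
#'   `voxel_size` `(dz, dx)` in um.
#' @export
equatorial_section <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "tm_mask"))
  v <- stack$voxels
  vs <- stack$voxel_size
  iy <- round(mask$center[2L] / vs[2L] + 0.5)
  if (iy <= 1L || iy >= dim(v)[2L])
    stop("TM centre y lies at the stack border; cannot take a 3-slice slab")
  img <- (v[, iy - 1L, ] + v[, iy, ] + v[, iy + 1L, ]) / 3
  structure(list(image = img, mask = mask$mask[, iy, ],
                 center_zx = mask$center[c(1L, 3L)],
                 voxel_size = vs[c(1L, 3L)]),
            class = "tm_section")
}

# --- local contrast machinery -------------------------------------------------

# Summed-area-table box sum of matrix `m` with half-extents (lo, hi) per
# dimension; windows are clipped at the matrix edge.
box_sum <- function(m, rlo, rhi, clo, chi) {
  nr <- nrow(m); nc <- ncol(m)
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- s
  ri <- rep(seq_len(nr), times = nc)
  ci <- rep(seq_len(nc), each = nr)
  r1 <- pmax(ri - rlo, 1L); r2 <- pmin(ri + rhi, nr)
  c1 <- pmax(ci - clo, 1L); c2 <- pmin(ci + chi, nc)
  out <- sat[cbind(r2 + 1L, c2 + 1L)] - sat[cbind(r1, c2 + 1L)] -
    sat[cbind(r2 + 1L, c1)] + sat[cbind(r1, c1)]
  matrix(out, nr, nc)
}

#' Local-contrast map of a section
#'
#' Windowed NCI: the mean absolute difference of 4-connected in-mask pixel
#' pairs inside a sliding square window, divided by the dynamic range of the
#' whole in-mask section. The normalization is global, not per window, so
#' that regions where attenuation has crushed the signal score low; a
#' per-window range would cancel out of the ratio in noise-dominated areas
#' (noise normalizes itself) and make the map blind to penetration loss.
#' Pixels outside the mask and windows with no pairs score 0.
#'
#' @param section a [tm_section()].
#' @param window_um window edge length in micrometres (default 10).
#' @return matrix of local contrast values (same shape as the section).
#' @export
local_contrast_map <- function(section, window_um = 10) {
  img <- section$image
  msk <- section$mask
  vs <- section$voxel_size
  wr <- max(1L, round(window_um / (2 * vs[1L])))   # half-extent, rows = z
  wc <- max(1L, round(window_um / (2 * vs[2L])))   # cols = x
  nr <- nrow(img); nc <- ncol(img)
  # pair differences along rows (z): pair i sits between rows i and i+1
  dz <- abs(img[-1L, , drop = FALSE] - img[-nr, , drop = FALSE])
  vz <- msk[-1L, , drop = FALSE] & msk[-nr, , drop = FALSE]
  dx <- abs(img[, -1L, drop = FALSE] - img[, -nc, drop = FALSE])
  vx <- msk[, -1L, drop = FALSE] & msk[, -nc, drop = FALSE]
  pad_rows <- function(m) rbind(m, 0)
  pad_cols <- function(m) cbind(m, 0)
  # a row-pair at (i, i+1) is inside the window of centre p iff
  # i in [p - wr, p + wr - 1]: box with asymmetric half-extents (wr, wr - 1)
  num <- box_sum(pad_rows(dz * vz), wr, wr - 1L, wc, wc) +
    box_sum(pad_cols(dx * vx), wr, wr, wc, wc - 1L)
  cnt <- box_sum(pad_rows(vz * 1), wr, wr - 1L, wc, wc) +
    box_sum(pad_cols(vx * 1), wr, wr, wc, wc - 1L)
  rng <- diff(range(img[msk]))
  lc <- matrix(0, nr, nc)
  ok <- msk & cnt > 0
  if (rng > 0) lc[ok] <- (num[ok] / cnt[ok]) / rng
  lc
}

#' Contrasted Imaging Volume of an equatorial section
#'
#' The CIV is the set of in-mask pixels whose local contrast (see
#' [local_contrast_map()]) reaches `contrast_threshold` times the 95th
#' percentile of the in-mask local-contrast map — a relative threshold so
#' the CIV is comparable across exposure levels. The CoM is the unweighted
#' centroid of the CIV relative to the TM centre, signed `(dz, dx)` with +z
#' toward the detection objective and +x toward the illumination entry.
#' Quadrant fractions are CIV area within each quadrant divided by the TM
#' section area in that quadrant.
#'
#' @param section a [tm_section()].
#' @param window_um local-contrast window edge, micrometres.
#' @param contrast_threshold fraction of the 95th-percentile local contrast
#'   (default 0.3).
#' @param reference_percentile percentile defining the threshold reference
#'   (default 95).
#' @return an object of class `civ_result`: `civ_mask`, `com` `(dz, dx)` um
#'   (NA if the CIV is empty, with `empty = TRUE`), `quadrant_fractions`
#'   (q1..q4), `civ_fraction_q1q2`, `civ_area_px`, `local_contrast`.
#' @export
civ <- function(section, window_um = 10, contrast_threshold = 0.3,
                reference_percentile = 95) {
  stopifnot(inherits(section, "tm_section"))
  lc <- local_contrast_map(section, window_um)
  msk <- section$mask
  ref <- stats::quantile(lc[msk], reference_percentile / 100, names = FALSE)
  civ_mask <- msk & lc >= contrast_threshold * ref & lc > 0
  vs <- section$voxel_size
  zc <- axis_coords(nrow(msk), vs[1L]) - section$center_zx[1L]
  xc <- axis_coords(ncol(msk), vs[2L]) - section$center_zx[2L]
  zrel <- matrix(zc, nrow(msk), ncol(msk))
  xrel <- matrix(rep(xc, each = nrow(msk)), nrow(msk), ncol(msk))
  quad <- list(q1 = zrel > 0 & xrel > 0, q2 = zrel <= 0 & xrel > 0,
               q3 = zrel <= 0 & xrel <= 0, q4 = zrel > 0 & xrel <= 0)
  qf <- vapply(quad, function(q) {
    denom <- sum(msk & q)
    if (denom == 0) 0 else sum(civ_mask & q) / denom
  }, 0)
  q12 <- quad$q1 | quad$q2
  f12 <- if (sum(msk & q12) == 0) 0 else sum(civ_mask & q12) / sum(msk & q12)
  empty <- !any(civ_mask)
  com <- if (empty) c(dz = NA_real_, dx = NA_real_) else
    c(dz = mean(zrel[civ_mask]), dx = mean(xrel[civ_mask]))
  structure(list(civ_mask = civ_mask, com = com,
                 quadrant_fractions = qf, civ_fraction_q1q2 = f12,
                 civ_area_px = sum(civ_mask), empty = empty,
                 local_contrast = lc, threshold = contrast_threshold * ref),
            class = "civ_result")
}

#' @export
print.civ_result <- function(x, ...) {
  if (x$empty) {
    cat("civ_result: empty CIV\n")
    return(invisible(x))
  }
  cat("civ_result: CIV area", x$civ_area_px, "px;",
      sprintf("CoM (dz, dx) = (%.1f, %.1f) um\n", x$com[1L], x$com[2L]))
  cat("  quadrant fractions:",
      paste(sprintf("%s=%.2f", names(x$quadrant_fractions),
                    x$quadrant_fractions), collapse = ", "),
      sprintf("; Q1+Q2 coverage = %.2f\n", x$civ_fraction_q1q2))
  invisible(x)
}
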