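# 3D PSF measurement from sub-resolution beads: detection, per-bead FWHM
# along x, y, z from 1D Gaussian fits, and lognormal population statistics.

#' Detect bead candidates in a stack
#'
#' Local maxima (26-connected) above an intensity percentile, non-maximum
#' suppressed at `min_separation`, refined to sub-voxel precision by
#' centre-of-mass in a 3-voxel-radius neighbourhood (above the local
#' minimum). Candidates closer than `border_margin` to a stack face are
#' discarded because their fit window would leave the stack.
#'
#' @param stack a 3D [image_stack()].
#' @param min_separation minimum distance between accepted candidates, um.
#' @param intensity_percentile detection threshold percentile (default 99.5).
#' @param border_margin exclusion margin at the stack border, um; defaults
#'   to `min_separation` (of the order of one PSF FWHM).
#' @return a matrix with columns `z`, `y`, `x` (centroids in um; possibly
#'   zero rows) and attribute `voxel` (integer voxel indices).
#' @export
detect_beads <- function(stack, min_separation = 3,
                         intensity_percentile = 99.5,
                         border_margin = NULL) {
  stopifnot(inherits(stack, "image_stack"), !is_time_series(stack))
  if (is.null(border_margin)) border_margin <- min_separation
  v <- stack$voxels
  vs <- stack$voxel_size
  thr <- stats::quantile(v, intensity_percentile / 100, names = FALSE)
  cand <- which(local_maxima_3d(v) & v > thr)
  empty <- matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("z", "y", "x")))
  if (!length(cand)) return(structure(empty, voxel = empty))
  ord <- order(v[cand], decreasing = TRUE)
  cand <- cand[ord]
  pos_vox <- arrayInd(cand, dim(v))
  pos_um <- sweep(pos_vox - 0.5, 2L, vs, "*")
  # greedy non-maximum suppression in physical distance
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt(colSums((t(pos_um[keep, , drop = FALSE]) - pos_um[i, ])^2))
    if (all(dd >= min_separation)) keep[i] <- TRUE
  }
  pos_vox <- pos_vox[keep, , drop = FALSE]
  # sub-voxel refinement: centre of mass in a 3-voxel-radius box
  d <- dim(v)
  out <- matrix(NA_real_, nrow(pos_vox), 3L,
                dimnames = list(NULL, c("z", "y", "x")))
  for (i in seq_len(nrow(pos_vox))) {
    p <- pos_vox[i, ]
    lo <- pmax(1L, p - 3L); hi <- pmin(d, p + 3L)
    box <- v[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
    w <- box - min(box)
    if (sum(w) == 0) { out[i, ] <- (p - 0.5) * vs; next }
    idx <- arrayInd(seq_along(w), dim(w))
    com_vox <- colSums(idx * as.vector(w)) / sum(w) + (lo - 1L)
    out[i, ] <- (com_vox - 0.5) * vs
  }
  extent <- d * vs
  inside <- apply(out, 1L, function(p)
    all(p >= border_margin) && all(extent - p >= border_margin))
  out <- out[inside, , drop = FALSE]
  structure(out, voxel = pos_vox[inside, , drop = FALSE])
}

#' Measure the 3D FWHM of one bead
#'
#' Extracts the 1D intensity profile through the bead centroid along each
#' axis, subtracts the local background (median of the profile ends), fits a
#' 1D Gaussian and converts `FWHM = 2 * sqrt(2 * ln 2) * sigma` to
#' micrometres. The record is accepted only if the coefficient of
#' determination is at least `r2_min` on every axis; a profile window that
#' would leave the stack yields a rejected record, not an error.
#'
#' @param stack a 3D [image_stack()].
#' @param centroid bead centroid `(z, y, x)` in micrometres (one row of
#'   [detect_beads()] output).
#' @param window_um profile half-window in micrometres (default 8).
#' @param r2_min per-axis acceptance threshold on R^2 (default 0.8).
#' @return a one-row data frame (class `psf_record`): centroid, `fwhm_z/y/x`
#'   in um, per-axis `r2_z/y/x`, `accepted`, `reason`.
#' @export
measure_fwhm <- function(stack, centroid, window_um = 8, r2_min = 0.8) {
  stopifnot(inherits(stack, "image_stack"), !is_time_series(stack))
  v <- stack$voxels
  vs <- stack$voxel_size
  d <- dim(v)
  cen_vox <- pmin(pmax(round(centroid / vs + 0.5), 1L), d)
  rec <- data.frame(z = centroid[1L], y = centroid[2L], x = centroid[3L],
                    fwhm_z = NA_real_, fwhm_y = NA_real_, fwhm_x = NA_real_,
                    r2_z = NA_real_, r2_y = NA_real_, r2_x = NA_real_,
                    accepted = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  class(rec) <- c("psf_record", "data.frame")
  fw <- r2 <- rep(NA_real_, 3L)
  for (ax in 1:3) {
    w <- max(4L, ceiling(window_um / vs[ax]))
    lo <- cen_vox[ax] - w; hi <- cen_vox[ax] + w
    if (lo < 1L || hi > d[ax]) {
      rec$reason <- "profile window exceeds stack bounds"
      return(rec)
    }
    prof <- switch(ax,
                   v[lo:hi, cen_vox[2L], cen_vox[3L]],
                   v[cen_vox[1L], lo:hi, cen_vox[3L]],
                   v[cen_vox[1L], cen_vox[2L], lo:hi])
    g <- fit_gaussian_1d(prof, pitch = vs[ax])
    fw[ax] <- g$fwhm
    r2[ax] <- g$r2
  }
  rec$fwhm_z <- fw[1L]; rec$fwhm_y <- fw[2L]; rec$fwhm_x <- fw[3L]
  rec$r2_z <- r2[1L]; rec$r2_y <- r2[2L]; rec$r2_x <- r2[3L]
  ok <- all(is.finite(fw)) && all(fw > 0) &&
    all(is.finite(r2)) && all(r2 >= r2_min)
  rec$accepted <- ok
  rec$reason <- if (ok) "" else "fit quality below threshold"
  rec
}

# Background-corrected 1D Gaussian fit of a profile sampled at `pitch` um.
# Returns fwhm (um) and R^2 (both NA on failure).
fit_gaussian_1d <- function(prof, pitch) {
  n <- length(prof)
  u <- seq_len(n)
  bg <- stats::median(c(prof[1:2], prof[(n - 1):n]))
  y <- prof - bg
  if (max(y) <= 0) return(list(fwhm = NA_real_, r2 = NA_real_))
  w0 <- pmax(y, 0)
  mu0 <- sum(u * w0) / sum(w0)
  s0 <- sqrt(sum((u - mu0)^2 * w0) / sum(w0))
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(u - mu)^2 / (2 * s^2)),
                      start = list(A = max(y), mu = mu0, s = s0),
                      lower = c(0, 1, 1e-3), upper = c(Inf, n, n),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(fwhm = NA_real_, r2 = NA_real_))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  list(fwhm = 2 * sqrt(2 * log(2)) * unname(cf["s"]) * pitch, r2 = r2)
}

#' Measure all detected beads in a stack
#'
#' Convenience wrapper: [detect_beads()] then [measure_fwhm()] per candidate.
#'
#' @inheritParams detect_beads
#' @inheritParams measure_fwhm
#' @return a data frame of PSF records (one row per candidate).
#' @export
measure_psf <- function(stack, min_separation = 3,
                        intensity_percentile = 99.5,
                        border_margin = NULL, window_um = 8, r2_min = 0.8) {
  cands <- detect_beads(stack, min_separation, intensity_percentile,
                        border_margin)
  if (!nrow(cands))
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      fwhm_z = numeric(0), fwhm_y = numeric(0),
                      fwhm_x = numeric(0), r2_z = numeric(0),
                      r2_y = numeric(0), r2_x = numeric(0),
                      accepted = logical(0), reason = character(0)))
  recs <- lapply(seq_len(nrow(cands)), function(i)
    measure_fwhm(stack, cands[i, ], window_um = window_um, r2_min = r2_min))
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}

#' Fit the PSF population distribution
#'
#' Maximum-likelihood lognormal fit of the accepted FWHM sample per axis
#' (the canonical choice for resolution distributions, which are positive
#' and right-skewed), plus a normal fit and the sample mean and s.d. for
#' comparison. At least `min_n` accepted records per axis are required;
#' otherwise the population statistics are flagged unavailable.
#'
#' @param records data frame of PSF records (from [measure_psf()] or rbound
#'   [measure_fwhm()] rows).
#' @param min_n minimum accepted sample size per axis (default 5).
#' @return an object of class `psf_population`: `records`, `n_accepted`,
#'   `available`, and per-axis statistics `stats` (a data frame with
#'   `meanlog`, `sdlog`, `lognormal_median`, `lognormal_mode`, `mean`, `sd`).
#' @export
fit_psf_population <- function(records, min_n = 5L) {
  acc <- records[records$accepted, , drop = FALSE]
  axes <- c(z = "fwhm_z", y = "fwhm_y", x = "fwhm_x")
  available <- nrow(acc) >= min_n
  stats_df <- data.frame(axis = names(axes), meanlog = NA_real_,
                         sdlog = NA_real_, lognormal_median = NA_real_,
                         lognormal_mode = NA_real_,
                         mean = NA_real_, sd = NA_real_,
                         stringsAsFactors = FALSE)
  if (available) {
    for (i in seq_along(axes)) {
      x <- acc[[axes[i]]]
      fit <- MASS::fitdistr(x, "lognormal")
      ml <- unname(fit$estimate["meanlog"])
      sl <- unname(fit$estimate["sdlog"])
      stats_df$meanlog[i] <- ml
      stats_df$sdlog[i] <- sl
      stats_df$lognormal_median[i] <- exp(ml)
      stats_df$lognormal_mode[i] <- exp(ml - sl^2)
      stats_df$mean[i] <- mean(x)
      stats_df$sd[i] <- stats::sd(x)
    }
  }
  structure(list(records = records, n_accepted = nrow(acc),
                 available = available, stats = stats_df),
            class = "psf_population")
}

#' @export
print.psf_population <- function(x, ...) {
  cat("psf_population:", x$n_accepted, "accepted beads",
      if (!x$available) "(too few for distribution fitting)" else "", "\n")
  if (x$available) print(x$stats, row.names = FALSE)
  invisible(x)
}
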