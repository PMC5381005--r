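# Photobleaching kinetics and ballistic mean-free-path estimation.
#
# Photobleaching is normalized as PB_n = (I_n - I_BKG) / (I_1 - I_BKG),
# where I_n is the mean ROI intensity of frame n and I_BKG the mean
# background; PB_1 is 1 by construction. The decay time tau comes from a
# mono-exponential fit PB(t) = A * exp(-t / tau), optionally with a
# constant offset. MFP estimation fits ln(I) vs depth by weighted linear
# regression of a ballistic (single-exponential) attenuation profile.

#' Construct a bleach series
#'
#' Usually produced by [normalize_bleach()]; the constructor is exported so
#' series from external measurements can be fitted directly.
#'
#' @param times frame times in seconds (first frame at any origin; fitting
#'   uses times relative to the first frame).
#' @param intensity raw mean ROI intensities per frame.
#' @param i_bkg background intensity used for correction.
#' @return an object of class `bleach_series`.
#' @export
bleach_series <- function(times, intensity, i_bkg) {
  stopifnot(length(times) == length(intensity), length(times) >= 3,
            all(diff(times) > 0))
  if (intensity[1L] <= i_bkg)
    stop("first-frame intensity does not exceed background: no signal")
  pb <- (intensity - i_bkg) / (intensity[1L] - i_bkg)
  structure(list(times = as.numeric(times),
                 intensity = as.numeric(intensity),
                 i_bkg = i_bkg, pb = pb,
                 tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
                 r_squared = NA_real_, converged = NA, note = ""),
            class = "bleach_series")
}

#' @export
print.bleach_series <- function(x, ...) {
  cat("bleach_series:", length(x$times), "frames,",
      "I_BKG =", format(x$i_bkg), "\n")
  if (!is.na(x$tau)) {
    tau_txt <- if (is.infinite(x$tau)) "Inf (no bleach)" else
      paste0(format(x$tau, digits = 4), " s")
    cat("  fitted tau:", tau_txt, " R^2 =", format(x$r_squared, digits = 4),
        "\n")
  }
  invisible(x)
}

#' Normalize a 4D series into photobleaching kinetics
#'
#' Computes `I_n` as the mean intensity inside `roi_mask` per frame and
#' `I_BKG` as the mean of `background_mask` pooled over all frames, then
#' `PB_n = (I_n - I_BKG) / (I_1 - I_BKG)` so `PB_1` is exactly 1.
#'
#' @param stack a 4D [image_stack()].
#' @param roi_mask,background_mask logical 3D masks over `(z, y, x)`,
#'   disjoint and non-empty.
#' @return an unfitted [bleach_series()].
#' @export
normalize_bleach <- function(stack, roi_mask, background_mask) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is_time_series(stack)) stop("normalize_bleach needs a 4D stack")
  d <- dim(stack$voxels)
  if (d[1L] < 3) stop("need at least 3 frames")
  stopifnot(identical(dim(roi_mask), d[-1L]),
            identical(dim(background_mask), d[-1L]))
  if (!any(roi_mask) || !any(background_mask))
    stop("masks must be non-empty")
  if (any(roi_mask & background_mask))
    stop("ROI and background masks must be disjoint")
  i_n <- vapply(seq_len(d[1L]),
                function(t) mean(stack$voxels[t, , , ][roi_mask]), 0)
  i_bkg <- mean(vapply(seq_len(d[1L]),
                       function(t) mean(stack$voxels[t, , , ][background_mask]),
                       0))
  times <- (seq_len(d[1L]) - 1) * stack$frame_interval
  bleach_series(times, i_n, i_bkg)
}

#' Fit a mono-exponential decay to a bleach series
#'
#' Fits `PB(t) = A * exp(-t / tau)` (model `"mono"`) or with an added
#' constant (`"mono_offset"`) by nonlinear least squares, initialized from a
#' log-linear regression. A series with no measurable decay gets
#' `tau = Inf` and note `"no_bleach"`; a non-converging fit is returned
#' flagged (`converged = FALSE`) with diagnostics, never silently replaced.
#'
#' @param series a [bleach_series()].
#' @param model `"mono"` (default) or `"mono_offset"`.
#' @return the series with `tau`, `amplitude`, `offset`, `r_squared`,
#'   `converged` filled in.
#' @export
fit_decay <- function(series, model = c("mono", "mono_offset")) {
  stopifnot(inherits(series, "bleach_series"))
  model <- match.arg(model)
  t <- series$times - series$times[1L]
  pb <- series$pb
  eps <- 1e-12
  # log-linear initialization; for the offset model, subtract a floor first
  # so the log slope reflects the decaying component, not the plateau
  floor0 <- if (model == "mono_offset")
    min(pb) - 0.05 * max(diff(range(pb)), eps) else 0
  pb0 <- pb - floor0
  pos <- pb0 > eps
  slope <- if (sum(pos) >= 2)
    unname(stats::coef(stats::lm(log(pb0[pos]) ~ t[pos]))[2L]) else 0
  if (!is.finite(slope) || slope >= -1e-12) {
    series$tau <- Inf
    series$amplitude <- mean(pb)
    series$offset <- 0
    series$r_squared <- NA_real_
    series$converged <- TRUE
    series$note <- "no_bleach"
    return(series)
  }
  start <- list(A = unname(pb0[1L]), tau = -1 / slope)
  formula <- pb ~ A * exp(-t / tau)
  if (model == "mono_offset") {
    start$c0 <- floor0
    formula <- pb ~ A * exp(-t / tau) + c0
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = list(pb = pb, t = t), start = start,
                      lower = c(0, eps, if (model == "mono_offset") -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    series$converged <- FALSE
    series$note <- paste("fit failed:", conditionMessage(fit))
    return(series)
  }
  cf <- stats::coef(fit)
  series$tau <- unname(cf["tau"])
  series$amplitude <- unname(cf["A"])
  series$offset <- if (model == "mono_offset") unname(cf["c0"]) else 0
  res <- stats::resid(fit)
  series$r_squared <- 1 - sum(res^2) / sum((pb - mean(pb))^2)
  series$converged <- TRUE
  series
}

# --- mean free path -----------------------------------------------------------

#' Construct a ballistic attenuation profile
#'
#' @param depths depths in micrometres from the beam entry face, strictly
#'   increasing.
#' @param intensity background-corrected ballistic intensities.
#' @param label wavelength / condition label.
#' @return an object of class `attenuation_profile`.
#' @export
attenuation_profile <- function(depths, intensity, label = "") {
  stopifnot(length(depths) == length(intensity), all(diff(depths) > 0))
  structure(list(depths = as.numeric(depths),
                 intensity = as.numeric(intensity),
                 label = label,
                 mfp = NA_real_, r_squared = NA_real_,
                 converged = NA, note = ""),
            class = "attenuation_profile")
}

#' @export
print.attenuation_profile <- function(x, ...) {
  cat("attenuation_profile:", length(x$depths), "depths",
      sprintf("(%g..%g um)", min(x$depths), max(x$depths)),
      if (nzchar(x$label)) paste0("[", x$label, "]") else "", "\n")
  if (!is.na(x$mfp))
    cat("  fitted MFP:", format(x$mfp, digits = 4), "mm, R^2 =",
        format(x$r_squared, digits = 4), "\n")
  invisible(x)
}

#' Extract an attenuation profile from a stack along an optical path
#'
#' The profile follows a beam through the centre of the TM: voxels within
#' `column_radius_um` of the axis line through the TM centre are kept, and
#' for each depth plane from the beam entry face inward (illumination: from
#' the +x face toward -x; detection: from the +z face toward -z) the
#' in-column intensity is summarized by a robust quantile, with the
#' per-plane mean outside the TM mask subtracted as background. The central
#' column matters: near the TM rim the path length to the surface shrinks to
#' zero, so plane-wide summaries would mix depths and flatten the decay.
#'
#' @param stack a 3D [image_stack()].
#' @param mask a [tm_mask()] from [segment_tm()].
#' @param axis `"illumination"` (x) or `"detection"` (z).
#' @param quantile robust per-plane summary quantile (default 0.9).
#' @param column_radius_um lateral radius of the central column, um;
#'   default a quarter of the TM radius (at least 10 um).
#' @param min_voxels minimum in-column voxels for a plane to contribute.
#' @return an [attenuation_profile()].
#' @export
extract_attenuation_profile <- function(stack, mask,
                                        axis = c("illumination", "detection"),
                                        quantile = 0.9,
                                        column_radius_um = NULL,
                                        min_voxels = 5L) {
  axis <- match.arg(axis)
  stopifnot(inherits(mask, "tm_mask"))
  v <- stack$voxels
  m <- mask$mask
  stopifnot(identical(dim(m), dim(v)))
  if (is.null(column_radius_um))
    column_radius_um <- max(10, mask$radius / 4)
  dim_i <- if (axis == "illumination") 3L else 1L
  pitch <- stack$voxel_size[dim_i]
  n <- dim(v)[dim_i]
  # lateral distance from the beam axis through the TM centre
  d <- dim(v)
  if (dim_i == 3L) {
    lz <- axis_coords(d[1L], stack$voxel_size[1L]) - mask$center[1L]
    ly <- axis_coords(d[2L], stack$voxel_size[2L]) - mask$center[2L]
    lat2 <- outer(lz^2, ly^2, "+")
  } else {
    ly <- axis_coords(d[2L], stack$voxel_size[2L]) - mask$center[2L]
    lx <- axis_coords(d[3L], stack$voxel_size[3L]) - mask$center[3L]
    lat2 <- outer(ly^2, lx^2, "+")
  }
  in_col <- lat2 <= column_radius_um^2
  plane <- function(i) {
    if (dim_i == 3L) list(v = v[, , i], m = m[, , i] & in_col,
                          bg = m[, , i])
    else list(v = v[i, , ], m = m[i, , ] & in_col, bg = m[i, , ])
  }
  depths <- numeric(0); intensity <- numeric(0)
  entry <- NA_real_
  for (i in rev(seq_len(n))) {        # entry at the + face: descend indices
    p <- plane(i)
    if (sum(p$m) < min_voxels) next
    coord <- (i - 0.5) * pitch
    if (is.na(entry)) entry <- coord
    bg <- if (any(!p$bg)) mean(p$v[!p$bg]) else 0
    depths <- c(depths, entry - coord)
    intensity <- c(intensity, stats::quantile(p$v[p$m], quantile,
                                              names = FALSE) - bg)
  }
  if (length(depths) < 5)
    stop("fewer than 5 usable depth planes inside the mask")
  attenuation_profile(depths, intensity,
                      label = paste0(axis, " path"))
}

#' Fit the mean free path from an attenuation profile
#'
#' Weighted linear regression of `ln(I)` on depth with weights proportional
#' to `I` (countering log-space heteroscedasticity); `MFP = -1 / slope`,
#' reported in millimetres. A non-negative slope means no measurable
#' attenuation and is returned flagged, not as a value.
#'
#' @param profile an [attenuation_profile()] with at least 5 positive
#'   intensities.
#' @return the profile with `mfp` (mm), `r_squared`, `converged` filled in.
#' @export
fit_mfp <- function(profile) {
  stopifnot(inherits(profile, "attenuation_profile"))
  keep <- profile$intensity > 0
  if (sum(keep) < 5) {
    profile$converged <- FALSE
    profile$note <- "fewer than 5 positive intensities"
    return(profile)
  }
  d <- profile$depths[keep]
  i <- profile$intensity[keep]
  fit <- stats::lm(log(i) ~ d, weights = i)
  slope <- stats::coef(fit)[2L]
  if (!is.finite(slope) || slope >= 0) {
    profile$converged <- FALSE
    profile$note <- "non-negative slope: no measurable attenuation"
    return(profile)
  }
  profile$mfp <- unname(-1 / slope) / 1000
  profile$r_squared <- summary(fit)$r.squared
  profile$converged <- TRUE
  profile
}
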