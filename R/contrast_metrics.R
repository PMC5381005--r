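# Global image-quality metrics: signal-to-noise ratio in decibels and the
# Normalized Contrast Index (NCI).

#' Signal-to-noise ratio in decibels
#'
#' Signal is the robust maximum (99.9th percentile, resistant to hot pixels)
#' of the signal region; background is the mean of the background region;
#' `SNR = 10 * log10(signal / background)`. The 10-log (power-like)
#' convention is the package default and can be swapped to 20-log via
#' `db_factor` since acquisition reports vary in convention.
#'
#' @param stack a 3D [image_stack()] (or bare numeric array).
#' @param signal_region,background_region logical arrays congruent with the
#'   voxels, non-empty and disjoint.
#' @param signal_quantile quantile for the robust maximum (default 0.999).
#' @param db_factor 10 (power convention, default) or 20 (amplitude).
#' @return SNR in dB (scalar).
#' @export
snr_db <- function(stack, signal_region, background_region,
                   signal_quantile = 0.999, db_factor = 10) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  stopifnot(identical(dim(signal_region), dim(v)),
            identical(dim(background_region), dim(v)))
  if (!any(signal_region) || !any(background_region))
    stop("signal and background regions must be non-empty")
  if (any(signal_region & background_region))
    stop("signal and background regions must be disjoint")
  s <- stats::quantile(v[signal_region], signal_quantile, names = FALSE)
  b <- mean(v[background_region])
  if (b <= 0) stop("background estimate is not positive; cannot form a ratio")
  db_factor * log10(s / b)
}

#' Normalized Contrast Index
#'
#' Mean absolute intensity difference over all 6-connected in-region voxel
#' pairs, divided by the region's dynamic range (max - min). Dimensionless,
#' invariant under affine intensity maps `I -> a*I + b` (a > 0); 0 for a
#' constant region by convention, 1 for an extreme checkerboard.
#'
#' @param stack a 2D/3D array or an [image_stack()].
#' @param region_mask logical array congruent with the data; `NULL` uses the
#'   whole array. At least 2 voxels.
#' @return NCI (scalar in `[0, 1]` for face-connected data).
#' @export
nci <- function(stack, region_mask = NULL) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (is.null(dim(v))) v <- array(v, c(length(v), 1L))
  if (is.null(region_mask)) region_mask <- array(TRUE, dim(v))
  stopifnot(identical(dim(region_mask), dim(v)))
  n_in <- sum(region_mask)
  if (n_in < 2) stop("region must contain at least 2 voxels")
  rng <- range(v[region_mask])
  if (diff(rng) == 0) return(0)
  total <- 0
  count <- 0
  nd <- length(dim(v))
  for (ax in seq_len(nd)) {
    n <- dim(v)[ax]
    if (n < 2) next
    idx_a <- idx_b <- rep(list(quote(expr = )), nd)
    idx_a[[ax]] <- 1:(n - 1)
    idx_b[[ax]] <- 2:n
    va <- do.call(`[`, c(list(v), idx_a, list(drop = FALSE)))
    vb <- do.call(`[`, c(list(v), idx_b, list(drop = FALSE)))
    ma <- do.call(`[`, c(list(region_mask), idx_a, list(drop = FALSE)))
    mb <- do.call(`[`, c(list(region_mask), idx_b, list(drop = FALSE)))
    pair <- ma & mb
    total <- total + sum(abs(va - vb)[pair])
    count <- count + sum(pair)
  }
  if (count == 0) return(0)
  (total / count) / diff(rng)
}
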