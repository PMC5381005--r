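# Calibrated image stacks and metric reports.
#
# Coordinate convention used throughout the package (fixed, not configurable):
# voxel arrays are indexed (z, y, x), with a leading t for time series. The
# light sheet enters the sample at the +x face and propagates toward -x; the
# detection objective sits on the +z side. The physical centre of voxel i
# along an axis with pitch d is (i - 0.5) * d micrometres.

#' Construct a calibrated image stack
#'
#' `ImageStack` is the container every metric module consumes: a non-negative
#' intensity array indexed `(z, y, x)` (or `(t, z, y, x)` for time series)
#' plus its physical calibration. The illumination axis is x and the
#' detection axis is z by construction; they are orthogonal and fixed so
#' that penetration-depth signs mean the same thing in every module.
#'
#' @param voxels numeric array, 3D `(z, y, x)` or 4D `(t, z, y, x)`, finite
#'   and non-negative.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres, all
#'   positive.
#' @param frame_interval frame spacing in seconds (time series only).
#' @param channel_label free-text channel description (e.g. "H2B-mCherry",
#'   "beads").
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size, frame_interval = NULL,
                        channel_label = "") {
  nd <- length(dim(voxels))
  if (!nd %in% c(3L, 4L))
    stop("'voxels' must be a 3D (z,y,x) or 4D (t,z,y,x) array")
  if (!all(is.finite(voxels)))
    stop("all intensities must be finite")
  if (min(voxels) < 0)
    stop("all intensities must be >= 0")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive values (dz, dy, dx) in um")
  if (nd == 4L) {
    if (is.null(frame_interval) || frame_interval <= 0)
      stop("4D stacks require a positive 'frame_interval' in seconds")
  }
  structure(
    list(voxels = voxels,
         voxel_size = voxel_size,
         frame_interval = if (nd == 4L) as.numeric(frame_interval) else NULL,
         illumination_axis = "x",
         detection_axis = "z",
         channel_label = channel_label),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  kind <- if (length(d) == 4L) "4D (t,z,y,x)" else "3D (z,y,x)"
  cat("image_stack:", kind, paste(d, collapse = " x "), "\n")
  cat("  voxel size (dz,dy,dx):", paste(x$voxel_size, collapse = ", "), "um\n")
  if (!is.null(x$frame_interval))
    cat("  frame interval:", x$frame_interval, "s\n")
  cat("  illumination axis: x (entry at +x); detection axis: z (+z)\n")
  if (nzchar(x$channel_label)) cat("  channel:", x$channel_label, "\n")
  invisible(x)
}

is_time_series <- function(stack) length(dim(stack$voxels)) == 4L

# Physical voxel-centre coordinates along one spatial axis of a stack.
axis_coords <- function(n, pitch) (seq_len(n) - 0.5) * pitch

#' Read a multi-page TIFF into an image stack
#'
#' Pages map to z (z-major). For 4D hyperstacks pass `n_z` (or put
#' `dimension_order: tzyx` plus `n_z` in the calibration file); pages are
#' then read t-major with z fastest within each frame (the ImageJ hyperstack
#' order). Calibration comes, in order of precedence, from the `voxel_size`
#' argument, an explicit `calibration` YAML, a `<path>.yaml` sidecar written
#' by [write_stack()], or an ImageJ-style `spacing=` description tag in the
#' file. If none is available the function stops rather than inventing a
#' default.
#'
#' @param path TIFF file path.
#' @param voxel_size `(dz, dy, dx)` in micrometres; required when the file
#'   carries no usable calibration metadata.
#' @param frame_interval seconds between frames (4D only).
#' @param n_z number of z planes per time point; `NULL` (default) reads the
#'   file as a single 3D stack.
#' @param calibration path to a YAML file with keys `voxel_size`,
#'   `frame_interval`, `dimension_order`, `n_z`, `channel`.
#' @param channel_label free-text channel description.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL, frame_interval = NULL,
                       n_z = NULL, calibration = NULL, channel_label = "") {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(calibration)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) calibration <- sidecar
  }
  if (!is.null(calibration)) {
    cal <- yaml::read_yaml(calibration)
    if (is.null(voxel_size)) voxel_size <- as.numeric(unlist(cal$voxel_size))
    if (is.null(frame_interval)) frame_interval <- cal$frame_interval
    if (is.null(n_z) && identical(cal$dimension_order, "tzyx")) n_z <- cal$n_z
    if (!nzchar(channel_label) && !is.null(cal$channel))
      channel_label <- cal$channel
  }
  if (is.null(voxel_size)) {
    voxel_size <- tiff_calibration(pages[[1L]])
    if (is.null(voxel_size))
      stop("no voxel-size metadata for ", path,
           "; supply 'voxel_size' (dz, dy, dx) or a calibration YAML")
  }
  np <- length(pages)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  flat <- vapply(pages, function(p) as.numeric(p), numeric(h * w))
  if (is.null(n_z)) {
    vox <- array(0, c(np, h, w))
    for (i in seq_len(np)) vox[i, , ] <- matrix(flat[, i], h, w)
    image_stack(vox, voxel_size, channel_label = channel_label)
  } else {
    if (np %% n_z != 0L)
      stop("page count ", np, " is not a multiple of n_z = ", n_z)
    nt <- np %/% n_z
    vox <- array(0, c(nt, n_z, h, w))
    for (t in seq_len(nt)) for (z in seq_len(n_z))
      vox[t, z, , ] <- matrix(flat[, (t - 1L) * n_z + z], h, w)
    image_stack(vox, voxel_size, frame_interval = frame_interval,
                channel_label = channel_label)
  }
}

# Parse an ImageJ-style description for calibration; returns (dz, dy, dx) in
# micrometres or NULL.
tiff_calibration <- function(page) {
  desc <- attr(page, "description")
  if (is.null(desc)) return(NULL)
  get_num <- function(key) {
    m <- regmatches(desc, regexpr(paste0(key, "=[0-9.eE+-]+"), desc))
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0(key, "="), "", m))
  }
  dz <- get_num("spacing")
  xres <- attr(page, "x.resolution")
  yres <- attr(page, "y.resolution")
  dx <- if (!is.null(xres) && is.finite(xres) && xres > 0) 1 / xres else NA_real_
  dy <- if (!is.null(yres) && is.finite(yres) && yres > 0) 1 / yres else NA_real_
  out <- c(dz, dy, dx)
  if (any(!is.finite(out)) || any(out <= 0)) return(NULL)
  out
}

#' Write an image stack to a 16-bit multi-page TIFF
#'
#' The on-disk dtype is 16-bit unsigned (the canonical acquisition format);
#' intensities must fit in `[0, 65535]` and are rounded to integers, so
#' integer stacks round-trip losslessly. 4D stacks are written t-major with
#' z fastest. Calibration is written to a `<path>.yaml` sidecar that
#' [read_stack()] picks up automatically.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  v <- stack$voxels
  if (max(v) > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing")
  d <- dim(v)
  pages <- list()
  if (length(d) == 3L) {
    for (z in seq_len(d[1L])) pages[[z]] <- round(v[z, , ]) / 65535
  } else {
    i <- 0L
    for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) {
      i <- i + 1L
      pages[[i]] <- round(v[t, z, , ]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  reduce = FALSE, compression = "none")
  cal <- list(voxel_size = as.numeric(stack$voxel_size),
              dimension_order = if (length(d) == 4L) "tzyx" else "zyx",
              channel = stack$channel_label)
  if (length(d) == 4L) {
    cal$frame_interval <- stack$frame_interval
    cal$n_z <- d[2L]
  }
  yaml::write_yaml(cal, paste0(path, ".yaml"))
  invisible(path)
}

# --- metric reports -----------------------------------------------------------

#' Construct a metric report
#'
#' A flat table of named scalar metrics, each with a unit string, plus
#' provenance (input identifier and the parameters used). Serializes
#' losslessly to CSV and JSON via [write_report()].
#'
#' @param metrics named numeric vector (or named list of scalars).
#' @param units character vector of unit strings, one per metric (e.g. "dB",
#'   "um", "s", "mm", "" for dimensionless).
#' @param input identifier of the input the metrics were computed from.
#' @param parameters named list of analysis parameters (provenance).
#' @return an object of class `metric_report`: a data frame with columns
#'   `metric`, `unit`, `value`.
#' @export
metric_report <- function(metrics = numeric(0), units = character(0),
                          input = "", parameters = list()) {
  metrics <- unlist(metrics)
  if (length(metrics) != length(units))
    stop("every metric needs a unit string")
  df <- data.frame(metric = names(metrics) %||% character(0),
                   unit = as.character(units),
                   value = as.numeric(metrics),
                   stringsAsFactors = FALSE)
  structure(df, class = c("metric_report", "data.frame"),
            input = input, parameters = parameters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metric report to CSV and JSON
#'
#' Writes `<path>.csv` (columns `metric,unit,value`, full precision) and
#' `<path>.json` (metrics plus provenance). [read_report()] restores the
#' numeric fields bit-exactly from the JSON.
#'
#' @param report a [metric_report()].
#' @param path output path stem (extensions are appended).
#' @return the two paths, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  df <- as.data.frame(report)
  df$value <- vapply(df$value, function(x) format(x, digits = 17), "")
  utils::write.table(df, csv, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(metrics = as.data.frame(report),
         input = attr(report, "input"),
         parameters = attr(report, "parameters")),
    json, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(c(csv = csv, json = json))
}

#' Read a metric report back from its JSON serialization
#'
#' @param path path stem or `.json` path written by [write_report()].
#' @return a [metric_report()].
#' @export
read_report <- function(path) {
  json <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  obj <- jsonlite::read_json(json, simplifyVector = TRUE)
  m <- obj$metrics
  if (is.null(m) || !length(m)) {
    metric_report(input = obj$input %||% "",
                  parameters = as.list(obj$parameters %||% list()))
  } else {
    metric_report(stats::setNames(m$value, m$metric), m$unit,
                  input = obj$input %||% "",
                  parameters = as.list(obj$parameters %||% list()))
  }
}
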