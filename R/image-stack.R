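#' Multi-channel, multi-plane image stack
#'
#' Light container for calibrated microscopy data. Pixels are stored as a
#' 4-D numeric array indexed `[y, x, channel, plane]` where a plane is a
#' confocal z-slice (fixed stacks) or a time frame (movies). Coordinates are
#' pixel-centred, 0-based, origin top-left, `(y, x)` order throughout the
#' package.
#'
#' @param pixels numeric array; 2-D (`y,x`), 3-D (`y,x,channel`) or 4-D
#'   (`y,x,channel,plane`). Lower-dimensional input is promoted.
#' @param channel_names character vector naming the channels, e.g.
#'   `c("dna", "signal")`.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param slice_step z-step between slices in micrometres, or `NA` for movies.
#' @param frame_interval time between frames in seconds, or `NA` for fixed
#'   stacks.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channel_names = NULL, pixel_size = 0.1,
                        slice_step = NA_real_, frame_interval = NA_real_) {
  stopifnot(is.numeric(pixels), is.numeric(pixel_size), pixel_size > 0)
  d <- dim(pixels)
  if (is.null(d)) stop("`pixels` must be an array, not a bare vector")
  if (length(d) == 2L) dim(pixels) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(pixels) <- c(d, 1L)
  d <- dim(pixels)
  if (length(d) != 4L) stop("`pixels` must have 2 to 4 dimensions")
  if (is.null(channel_names)) {
    channel_names <- if (d[3] == 1L) "signal" else paste0("ch", seq_len(d[3]))
  }
  if (length(channel_names) != d[3]) {
    stop("length(channel_names) must equal the number of channels (", d[3], ")")
  }
  structure(
    list(pixels = pixels, channel_names = channel_names,
         pixel_size = pixel_size, slice_step = slice_step,
         frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (!is.na(x$frame_interval)) "frames" else "slices"
  cat(sprintf("<image_stack> %d x %d px, %d channel(s) [%s], %d %s\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              d[4], kind))
  cat(sprintf("  pixel_size: %g um/px", x$pixel_size))
  if (!is.na(x$frame_interval)) cat(sprintf(", frame_interval: %g s", x$frame_interval))
  if (!is.na(x$slice_step)) cat(sprintf(", slice_step: %g um", x$slice_step))
  cat("\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

n_planes <- function(stack) dim(stack$pixels)[4]

channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) {
      stop("channel '", channel, "' not found; available: ",
           paste(stack$channel_names, collapse = ", "))
    }
    i
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > dim(stack$pixels)[3]) stop("channel index out of range")
    ci
  }
}

#' Extract one plane of one channel as a 2-D matrix
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param plane slice or frame index (default 1).
#' @return Numeric matrix `[y, x]`.
#' @export
get_plane <- function(stack, channel = 1, plane = 1) {
  stopifnot(inherits(stack, "image_stack"))
  stack$pixels[, , channel_index(stack, channel), plane, drop = TRUE]
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered plane-major, channel-minor (all channels of plane 1,
#' then plane 2, ...). Calibration and channel names go to `<path>.json`.
#' Intensities are stored as 32-bit floats; arbitrary units are preserved.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (p in seq_len(d[4])) {
    for (ch in seq_len(d[3])) {
      pages[[k]] <- stack$pixels[, , ch, p, drop = TRUE]
      k <- k + 1L
    }
  }
  # TIFF pages are stored in [0, 1]; the affine transform back to the
  # original arbitrary units goes to the sidecar
  lo <- min(stack$pixels); hi <- max(stack$pixels)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(pages, function(p) (p - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    channel_names = stack$channel_names,
    n_channels = d[3], n_planes = d[4],
    intensity_offset = lo, intensity_scale = scale,
    pixel_size_um = stack$pixel_size,
    slice_step_um = stack$slice_step,
    frame_interval_s = stack$frame_interval,
    page_order = "plane_major_channel_minor"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nc <- meta$n_channels
  np <- meta$n_planes
  stopifnot(length(pages) == nc * np)
  d <- dim(pages[[1]])
  px <- array(0, dim = c(d[1], d[2], nc, np))
  k <- 1L
  for (p in seq_len(np)) {
    for (ch in seq_len(nc)) {
      px[, , ch, p] <- pages[[k]]
      k <- k + 1L
    }
  }
  off <- meta$intensity_offset %||% 0
  scl <- meta$intensity_scale %||% 1
  px <- px * scl + off
  image_stack(px, channel_names = meta$channel_names,
              pixel_size = meta$pixel_size_um,
              slice_step = if (is.null(meta$slice_step_um)) NA_real_ else meta$slice_step_um,
              frame_interval = if (is.null(meta$frame_interval_s)) NA_real_ else meta$frame_interval_s)
}
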