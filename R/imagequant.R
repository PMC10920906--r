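#' Maximum-intensity projection over consecutive z-slices
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param n_slices number of consecutive slices to project (default: all).
#' @param start first slice of the window.
#' @return Numeric matrix `[y, x]`, the per-pixel maximum.
#' @export
max_project <- function(stack, channel = 1, n_slices = NULL, start = 1) {
  stopifnot(inherits(stack, "image_stack"))
  np <- n_planes(stack)
  n_slices <- n_slices %||% np
  if (n_slices < 1 || start < 1 || start + n_slices - 1 > np) {
    stop("requested ", n_slices, " slice(s) from ", start,
         " but the stack has only ", np)
  }
  ci <- channel_index(stack, channel)
  sl <- stack$pixels[, , ci, start:(start + n_slices - 1), drop = FALSE]
  apply(sl, c(1, 2), max)
}

otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(Inf)  # constant image: nothing above threshold
  scaled <- (img - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + thr01 * diff(rng)
}

label_stats <- function(label_image) {
  labs <- sort(unique(as.vector(label_image)))
  labs <- labs[labs > 0]
  if (!length(labs)) {
    return(tibble::tibble(label = integer(), y_px = numeric(),
                          x_px = numeric(), area_px = numeric(),
                          touches_border = logical()))
  }
  idx <- which(label_image > 0, arr.ind = TRUE)
  lab <- label_image[label_image > 0]
  h <- nrow(label_image); w <- ncol(label_image)
  df <- tibble::tibble(label = as.integer(lab),
                       y = idx[, 1] - 1, x = idx[, 2] - 1)
  dplyr::summarise(dplyr::group_by(df, .data$label),
                   y_px = mean(.data$y), x_px = mean(.data$x),
                   area_px = dplyr::n(),
                   touches_border = any(.data$y == 0 | .data$y == h - 1 |
                                        .data$x == 0 | .data$x == w - 1),
                   .groups = "drop")
}

#' Segment nuclei in a projected DNA-stain image
#'
#' Global Otsu threshold, connected-component labelling, removal of objects
#' below `min_area`, and flagging of border-touching objects (dropped when
#' `exclude_border = TRUE`, following the rule that nuclei in contact with
#' the image borders are excluded). A blank or constant image yields zero
#' nuclei, not an error. Touching nuclei are not split.
#'
#' @param dna_image 2-D numeric matrix (a projection).
#' @param min_area minimum object area in pixel^2.
#' @param exclude_border drop border-touching nuclei (default `TRUE`).
#' @return A list: `nuclei` (tibble with `label`, `y_px`, `x_px`, `area_px`,
#'   `touches_border`) and `label_image` (integer matrix; 0 = background,
#'   relabelled consecutively after filtering).
#' @export
#' @examples
#' sim <- simulate_nuclei_stack(scene_config(n_nuclei = 4, seed = 1))
#' seg <- segment_nuclei(max_project(sim$stack, "dna"))
#' seg$nuclei
segment_nuclei <- function(dna_image, min_area = 200, exclude_border = TRUE) {
  stopifnot(is.matrix(dna_image))
  thr <- otsu_threshold(dna_image)
  mask <- dna_image > thr
  if (!any(mask)) {
    return(list(nuclei = label_stats(matrix(0L, nrow(dna_image), ncol(dna_image))),
                label_image = matrix(0L, nrow(dna_image), ncol(dna_image))))
  }
  lab <- as.matrix(EBImage::bwlabel(mask))
  stats <- label_stats(lab)
  keep <- stats$area_px >= min_area
  if (exclude_border) keep <- keep & !stats$touches_border
  kept <- stats[keep, , drop = FALSE]
  relabel <- integer(max(lab))
  relabel[kept$label] <- seq_len(nrow(kept))
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  new_lab[nz] <- relabel[lab[nz]]
  kept$label <- seq_len(nrow(kept))
  list(nuclei = kept, label_image = new_lab)
}

#' Per-nucleus reporter-spot quantification with cell-by-cell background
#' subtraction
#'
#' Within each segmented nucleus, the spot mask is the set of pixels whose
#' reporter intensity exceeds `mean + k * sd` of the within-nucleus reporter
#' distribution (per-nucleus threshold; robust to between-cell expression
#' differences). The background mask is the nucleus minus the spot mask, so
#' the two partition the nucleus exactly. The corrected signal is the
#' per-cell spot mean minus the per-cell background mean; a nucleus whose
#' spot mask is empty keeps its record with `corrected_signal = NA`.
#'
#' @param label_image integer nucleus label matrix from [segment_nuclei()].
#' @param reporter_image numeric matrix, same geometry.
#' @param k spot-threshold multiplier (default 3).
#' @return Tibble with one row per nucleus: `nucleus_label`,
#'   `spot_pixel_count`, `spot_count` (connected components),
#'   `spot_mean`, `background_mean`, `corrected_signal`.
#' @export
quantify_spots <- function(label_image, reporter_image, k = 3) {
  if (!all(dim(label_image) == dim(reporter_image))) {
    stop("label and reporter images must share geometry")
  }
  labs <- sort(unique(as.vector(label_image)))
  labs <- labs[labs > 0]
  out <- purrr::map(labs, function(l) {
    sel <- label_image == l
    vals <- reporter_image[sel]
    thr <- mean(vals) + k * stats::sd(vals)
    spot_sel <- sel & (reporter_image > thr)
    n_spot <- sum(spot_sel)
    if (n_spot == 0) {
      return(tibble::tibble(nucleus_label = l, spot_pixel_count = 0L,
                            spot_count = 0L, spot_mean = NA_real_,
                            background_mean = mean(vals),
                            corrected_signal = NA_real_))
    }
    comp <- as.matrix(EBImage::bwlabel(spot_sel))
    spot_mean <- mean(reporter_image[spot_sel])
    bg_sel <- sel & !spot_sel
    bg_mean <- mean(reporter_image[bg_sel])
    tibble::tibble(nucleus_label = l, spot_pixel_count = as.integer(n_spot),
                   spot_count = as.integer(max(comp)),
                   spot_mean = spot_mean, background_mean = bg_mean,
                   corrected_signal = spot_mean - bg_mean)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(nucleus_label = integer(), spot_pixel_count = integer(),
                          spot_count = integer(), spot_mean = numeric(),
                          background_mean = numeric(),
                          corrected_signal = numeric())
  }
  res
}

#' Mean nuclear area across fields of view
#'
#' Per field: the projected DNA image is smoothed with a Gaussian kernel
#' matched to a 10-pixel artifact diameter (FWHM = diameter, i.e.
#' `sigma = diameter / 2.355`), thresholded (Otsu), and the total stained
#' area of non-border objects is divided by the number of non-border nuclei.
#' Fields with zero usable nuclei are skipped with a warning.
#'
#' @param fields list of 2-D projected DNA images (matrices).
#' @param pixel_size um per pixel, for the physical-area column.
#' @param min_area minimum nucleus area (px^2) when counting nuclei.
#' @param artifact_diameter smoothing artifact diameter in pixels.
#' @return Tibble with one row per usable field (`field`, `n_nuclei`,
#'   `mean_area_px`, `mean_area_um2`) plus attribute `"pooled"`, a one-row
#'   tibble of the across-field means.
#' @export
mean_nuclear_area <- function(fields, pixel_size = 0.1, min_area = 200,
                              artifact_diameter = 10) {
  stopifnot(length(fields) >= 1)
  sigma <- artifact_diameter / 2.355
  rows <- purrr::imap(fields, function(img, i) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
    # Smoothing conserves integrated intensity, so the stained area is
    # recovered by a mass-conserving threshold: the number of masked
    # pixels equals the integrated above-background signal divided by the
    # per-pixel foreground level. A fixed-height contour would shrink
    # objects whose radius is comparable to the kernel width.
    raw_mask <- img > otsu_threshold(img)
    if (!any(raw_mask) || all(raw_mask)) {
      warning("field ", i, " has no usable (non-border) nuclei; skipped")
      return(NULL)
    }
    bgl <- mean(img[!raw_mask]); fgl <- mean(img[raw_mask])
    area_mass <- sum(pmax(sm - bgl, 0)) / (fgl - bgl)
    frac <- min(1, area_mass / length(sm))
    thr <- stats::quantile(sm, 1 - frac, names = FALSE)
    mask <- sm > thr
    lab <- if (any(mask)) as.matrix(EBImage::bwlabel(mask)) else
      matrix(0L, nrow(sm), ncol(sm))
    stats <- label_stats(lab)
    stats <- stats[stats$area_px >= min_area & !stats$touches_border, ]
    n <- nrow(stats)
    if (n == 0) {
      warning("field ", i, " has no usable (non-border) nuclei; skipped")
      return(NULL)
    }
    total_area <- sum(stats$area_px)
    tibble::tibble(field = as.integer(i), n_nuclei = n,
                   mean_area_px = total_area / n,
                   mean_area_um2 = total_area / n * pixel_size^2)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warning("no field contained usable nuclei; empty summary")
    return(out)
  }
  attr(out, "pooled") <- tibble::tibble(
    n_fields = nrow(out),
    mean_area_px = mean(out$mean_area_px),
    mean_area_um2 = mean(out$mean_area_um2))
  out
}

#' Mean channel intensity per nucleus
#'
#' @param label_image integer nucleus label matrix.
#' @param channel_image numeric matrix of the channel to average (e.g. a
#'   5mC immunostain), same geometry.
#' @return Tibble with `nucleus_label`, `n_pixels`, `mean_intensity`.
#' @export
mean_nuclear_intensity <- function(label_image, channel_image) {
  if (!all(dim(label_image) == dim(channel_image))) {
    stop("label and channel images must share geometry")
  }
  sel <- label_image > 0
  if (!any(sel)) {
    return(tibble::tibble(nucleus_label = integer(), n_pixels = integer(),
                          mean_intensity = numeric()))
  }
  df <- tibble::tibble(nucleus_label = as.integer(label_image[sel]),
                       value = channel_image[sel])
  dplyr::summarise(dplyr::group_by(df, .data$nucleus_label),
                   n_pixels = dplyr::n(),
                   mean_intensity = mean(.data$value), .groups = "drop")
}
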