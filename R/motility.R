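#' Temporal moving average of a movie
#'
#' Output frame `t` is the mean of input frames `t ... t + window - 1`
#' (trailing window), so an `N`-frame movie yields `N - window + 1` frames.
#' The time origin of frame `t` shifts by `(window - 1) / 2` frame
#' intervals; the shift is recorded in the `"time_origin_shift_s"`
#' attribute.
#'
#' @param movie an [image_stack()] time series.
#' @param window number of adjacent frames to average (default 5).
#' @return An [image_stack()] with `N - window + 1` frames.
#' @export
temporal_moving_average <- function(movie, window = 5) {
  stopifnot(inherits(movie, "image_stack"))
  nf <- n_planes(movie)
  if (window < 1 || window > nf) {
    stop("window must be between 1 and the number of frames (", nf, ")")
  }
  if (window == 1) return(movie)
  d <- dim(movie$pixels)
  n_out <- nf - window + 1
  out <- array(0, dim = c(d[1], d[2], d[3], n_out))
  acc <- array(0, dim = c(d[1:3], 1))
  for (t in seq_len(window)) acc <- acc + movie$pixels[, , , t, drop = FALSE]
  out[, , , 1] <- acc / window
  if (n_out > 1) {
    for (t in 2:n_out) {
      acc <- acc - movie$pixels[, , , t - 1, drop = FALSE] +
        movie$pixels[, , , t + window - 1, drop = FALSE]
      out[, , , t] <- acc / window
    }
  }
  res <- image_stack(out, channel_names = movie$channel_names,
                     pixel_size = movie$pixel_size,
                     frame_interval = movie$frame_interval)
  attr(res, "time_origin_shift_s") <-
    (window - 1) / 2 * (movie$frame_interval %||% NA_real_)
  res
}

#' Detect spots in each frame of a movie
#'
#' Per frame: pixels above `mean + k * sd` of the frame form the spot mask;
#' connected components of at least `min_pixels` pixels are reported with
#' intensity-weighted centroids.
#'
#' @param movie an [image_stack()] movie (single channel used).
#' @param channel channel name or index.
#' @param k threshold multiplier.
#' @param min_pixels minimum component size.
#' @return Tibble with `frame`, `y_px`, `x_px`, `intensity`, `n_pixels`.
#' @export
detect_spots <- function(movie, channel = 1, k = 3, min_pixels = 3) {
  stopifnot(inherits(movie, "image_stack"))
  ci <- channel_index(movie, channel)
  nf <- n_planes(movie)
  rows <- purrr::map(seq_len(nf), function(t) {
    img <- movie$pixels[, , ci, t, drop = TRUE]
    thr <- mean(img) + k * stats::sd(img)
    mask <- img > thr
    if (!any(mask)) return(NULL)
    lab <- as.matrix(EBImage::bwlabel(mask))
    idx <- which(lab > 0, arr.ind = TRUE)
    df <- tibble::tibble(label = lab[lab > 0],
                         y = idx[, 1] - 1, x = idx[, 2] - 1,
                         v = img[lab > 0])
    comp <- dplyr::summarise(dplyr::group_by(df, .data$label),
                             y_px = sum(.data$y * .data$v) / sum(.data$v),
                             x_px = sum(.data$x * .data$v) / sum(.data$v),
                             intensity = sum(.data$v),
                             n_pixels = dplyr::n(), .groups = "drop")
    comp <- comp[comp$n_pixels >= min_pixels, , drop = FALSE]
    if (nrow(comp) == 0) return(NULL)
    dplyr::mutate(comp[, c("y_px", "x_px", "intensity", "n_pixels")],
                  frame = t, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(frame = integer(), y_px = numeric(),
                          x_px = numeric(), intensity = numeric(),
                          n_pixels = integer())
  }
  out
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking: candidate links between
#' consecutive frames are sorted by displacement and accepted in order
#' (minimal total displacement under the greedy rule) while the
#' displacement stays below `max_displacement`; exact distance ties are
#' broken deterministically by detection order. Unmatched detections start
#' new trajectories; a track with no match terminates (no gap closing).
#' Trajectories shorter than `min_length` frames are discarded.
#'
#' @param detections tibble with columns `frame`, `y_px`, `x_px` (pixels).
#' @param max_displacement maximum frame-to-frame displacement in um.
#' @param min_length minimum trajectory length in frames.
#' @param pixel_size um per pixel for coordinate conversion.
#' @param frame_interval seconds between frames.
#' @return Tibble of trajectories: `trajectory_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, with attribute `"frame_interval"`.
#' @export
track_spots <- function(detections, max_displacement = 0.5, min_length = 10,
                        pixel_size = 0.1, frame_interval = 0.1) {
  req <- c("frame", "y_px", "x_px")
  if (!all(req %in% names(detections))) {
    stop("detections must have columns ", paste(req, collapse = ", "))
  }
  det <- dplyr::arrange(tibble::as_tibble(detections), .data$frame)
  det$y_um <- det$y_px * pixel_size
  det$x_um <- det$x_px * pixel_size
  det$track <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 0L
  prev_idx <- integer(0)
  prev_frame <- NA_integer_
  for (f in frames) {
    cur_idx <- which(det$frame == f)
    # no gap closing: only detections in the immediately preceding frame
    # are link candidates; after a missed frame every track terminates
    if (!is.na(prev_frame) && f != prev_frame + 1) prev_idx <- integer(0)
    if (length(prev_idx)) {
      # all candidate pairs under the displacement cap, closest first
      cand <- tidyr::expand_grid(i = seq_along(prev_idx),
                                 j = seq_along(cur_idx))
      cand$d <- sqrt((det$y_um[prev_idx[cand$i]] - det$y_um[cur_idx[cand$j]])^2 +
                     (det$x_um[prev_idx[cand$i]] - det$x_um[cur_idx[cand$j]])^2)
      cand <- cand[cand$d <= max_displacement, , drop = FALSE]
      cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
      used_i <- logical(length(prev_idx)); used_j <- logical(length(cur_idx))
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (!used_i[i] && !used_j[j]) {
          det$track[cur_idx[j]] <- det$track[prev_idx[i]]
          used_i[i] <- TRUE; used_j[j] <- TRUE
        }
      }
    }
    fresh <- cur_idx[is.na(det$track[cur_idx])]
    if (length(fresh)) {
      det$track[fresh] <- next_id + seq_along(fresh)
      next_id <- next_id + length(fresh)
    }
    prev_idx <- cur_idx
    prev_frame <- f
  }
  lengths <- table(det$track)
  keep <- as.integer(names(lengths)[lengths >= min_length])
  det <- det[det$track %in% keep, , drop = FALSE]
  if (nrow(det) == 0) {
    out <- tibble::tibble(trajectory_id = integer(), frame = integer(),
                          t_s = numeric(), x_um = numeric(), y_um = numeric())
  } else {
    det$trajectory_id <- match(det$track, sort(unique(det$track)))
    det$t_s <- (det$frame - min(det$frame)) * frame_interval
    out <- dplyr::arrange(
      det[, c("trajectory_id", "frame", "t_s", "x_um", "y_um")],
      .data$trajectory_id, .data$frame)
  }
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Mean square displacement as a function of lag time
#'
#' `MSD(tau) = <|r(t) - r(t + tau)|^2>`, the average over all ordered time
#' pairs within a trajectory (overlapping windows, maximal pair usage) and,
#' in ensemble mode, additionally over trajectories (pair-count weighted).
#' Lags with zero pairs are omitted, never reported as 0.
#'
#' @param trajectories tibble with `trajectory_id`, `t_s`, `x_um`, `y_um`;
#'   all trajectories must share the frame interval.
#' @param max_lag largest lag in seconds (default: longest available).
#' @param mode `"per_trajectory"` or `"ensemble"`.
#' @return Tibble of class `msd_profile`: `trajectory_id` (or
#'   `"ensemble"`), `lag_s`, `msd_um2`, `n_pairs`.
#' @export
#' @examples
#' tr <- tibble::tibble(trajectory_id = 1, frame = 1:4, t_s = 0:3,
#'                      x_um = c(0, 1, 1, 2), y_um = c(0, 0, 1, 1))
#' compute_msd(tr)
compute_msd <- function(trajectories, max_lag = NULL,
                        mode = c("per_trajectory", "ensemble")) {
  mode <- match.arg(mode)
  req <- c("trajectory_id", "t_s", "x_um", "y_um")
  if (!all(req %in% names(trajectories))) {
    stop("trajectories must have columns ", paste(req, collapse = ", "))
  }
  split_tr <- split(trajectories, trajectories$trajectory_id)
  dts <- purrr::map_dbl(split_tr, function(tr) {
    if (nrow(tr) < 2) return(NA_real_)
    d <- diff(sort(tr$t_s))
    if (diff(range(d)) > 1e-9) stop("non-uniform time spacing in trajectory ",
                                    tr$trajectory_id[1])
    d[1]
  })
  dts <- dts[!is.na(dts)]
  if (!length(dts)) stop("no trajectory with >= 2 points")
  if (diff(range(dts)) > 1e-9) stop("trajectories do not share a frame interval")
  dt <- dts[[1]]
  per <- purrr::map(split_tr, function(tr) {
    tr <- tr[order(tr$t_s), ]
    n <- nrow(tr)
    if (n < 2) return(NULL)
    kmax <- n - 1
    if (!is.null(max_lag)) kmax <- min(kmax, floor(max_lag / dt + 1e-9))
    if (kmax < 1) return(NULL)
    purrr::map_dfr(seq_len(kmax), function(k) {
      dx <- tr$x_um[(k + 1):n] - tr$x_um[1:(n - k)]
      dy <- tr$y_um[(k + 1):n] - tr$y_um[1:(n - k)]
      tibble::tibble(trajectory_id = as.character(tr$trajectory_id[1]),
                     lag_s = k * dt, msd_um2 = mean(dx^2 + dy^2),
                     n_pairs = n - k)
    })
  })
  per <- dplyr::bind_rows(per)
  out <- if (mode == "ensemble") {
    dplyr::summarise(dplyr::group_by(per, .data$lag_s),
                     msd_um2 = sum(.data$msd_um2 * .data$n_pairs) /
                       sum(.data$n_pairs),
                     n_pairs = sum(.data$n_pairs), .groups = "drop") |>
      dplyr::mutate(trajectory_id = "ensemble", .before = 1)
  } else {
    per
  }
  class(out) <- c("msd_profile", class(out))
  attr(out, "frame_interval") <- dt
  out
}

#' Scaled-MAD outlier filter
#'
#' Flags values lying more than three scaled median absolute deviations
#' from the median. The scaled MAD is `1.4826 * median(|x - median(x)|)`
#' (consistent with the sd under normality). When the scaled MAD is 0, any
#' value different from the median is flagged (degenerate rule).
#'
#' @param values numeric vector with at least one finite value.
#' @param n_mad flag threshold in scaled-MAD units (default 3).
#' @return Tibble with `value` and logical `outlier`; the kept values are
#'   `value[!outlier]`.
#' @export
#' @examples
#' scaled_mad_filter(c(1, 2, 3, 4, 100))
scaled_mad_filter <- function(values, n_mad = 3) {
  values <- as.numeric(values)
  if (length(values) == 0 || !any(is.finite(values))) {
    stop("scaled_mad_filter needs at least one finite value")
  }
  med <- stats::median(values)
  smad <- 1.4826 * stats::median(abs(values - med))
  outlier <- if (smad == 0) values != med else abs(values - med) > n_mad * smad
  tibble::tibble(value = values, outlier = outlier)
}

#' Per-trajectory mobility scores at a target lag
#'
#' For each trajectory two summaries are computed: the MSD value at
#' `lag_target` (`msd_at_1s`, the default comparison readout) and the mean
#' of MSD over all lags `0 < tau <= lag_target` (`msd_mean_to_1s`, the
#' integral reading). Trajectories too short to reach `lag_target` are
#' excluded and counted. The scaled-MAD filter is applied to `msd_at_1s`
#' within each condition (or over all trajectories if no `condition`
#' grouping column is present) before any aggregation; per-repeat means are
#' computed on the retained trajectories.
#'
#' @param trajectories tibble with `trajectory_id`, `t_s`, `x_um`, `y_um`
#'   and optional `condition` / `biological_repeat` columns.
#' @param lag_target target lag in seconds (default 1).
#' @return A list: `scores` (per-trajectory tibble with `msd_at_1s`,
#'   `msd_mean_to_1s`, `outlier`), `repeat_means` (per
#'   condition x biological repeat means of the retained trajectories, when
#'   grouping columns exist) and `n_excluded_short`.
#' @export
mobility_summary <- function(trajectories, lag_target = 1) {
  meta_cols <- intersect(c("condition", "biological_repeat"),
                         names(trajectories))
  msd <- compute_msd(trajectories, max_lag = lag_target,
                     mode = "per_trajectory")
  dt <- attr(msd, "frame_interval")
  if (abs(lag_target / dt - round(lag_target / dt)) > 1e-6) {
    stop("frame interval must divide lag_target")
  }
  scores <- dplyr::summarise(
    dplyr::group_by(msd, .data$trajectory_id),
    msd_at_1s = .data$msd_um2[which(abs(.data$lag_s - lag_target) < 1e-9)][1],
    msd_mean_to_1s = mean(.data$msd_um2[.data$lag_s <= lag_target + 1e-9]),
    reaches_lag = any(abs(.data$lag_s - lag_target) < 1e-9),
    .groups = "drop")
  n_excluded <- sum(!scores$reaches_lag)
  scores <- scores[scores$reaches_lag, setdiff(names(scores), "reaches_lag")]
  if (length(meta_cols)) {
    meta <- tibble::as_tibble(trajectories)[, c("trajectory_id", meta_cols)]
    meta$trajectory_id <- as.character(meta$trajectory_id)
    meta <- dplyr::distinct(meta)
    scores <- dplyr::left_join(scores, meta, by = "trajectory_id")
  }
  if (nrow(scores)) {
    grp <- if ("condition" %in% names(scores)) "condition" else character()
    scores <- dplyr::mutate(
      dplyr::group_by(scores, dplyr::across(dplyr::all_of(grp))),
      outlier = scaled_mad_filter(.data$msd_at_1s)$outlier)
    scores <- dplyr::ungroup(scores)
  } else {
    scores$outlier <- logical()
  }
  repeat_means <- NULL
  if (all(c("condition", "biological_repeat") %in% names(scores)) &&
      nrow(scores)) {
    repeat_means <- dplyr::summarise(
      dplyr::group_by(scores[!scores$outlier, ],
                      .data$condition, .data$biological_repeat),
      msd_at_1s = mean(.data$msd_at_1s),
      msd_mean_to_1s = mean(.data$msd_mean_to_1s),
      n_trajectories = dplyr::n(), .groups = "drop")
  }
  list(scores = scores, repeat_means = repeat_means,
       n_excluded_short = n_excluded)
}

#' Fit a diffusion coefficient to an MSD profile
#'
#' Ordinary least-squares line through `(lag, MSD)`; for 2-D Brownian
#' motion with static localization error the expectation is
#' `MSD(tau) = 4 D tau + 4 sigma_loc^2`, so `D = slope / 4` and the
#' intercept estimates `4 sigma_loc^2`. A negative fitted D is returned
#' as-is with a warning flag, never clamped.
#'
#' @param msd_profile tibble with `lag_s` and `msd_um2` (>= 2 lags); an
#'   ensemble profile from [compute_msd()] is the usual input.
#' @return Object of class `diffusion_fit`: list with `D`, `offset`,
#'   `sigma_loc` (sqrt(offset / 4), NA when offset < 0), `negative_D` flag,
#'   `n_lags` and the `lm` fit.
#' @export
fit_diffusion <- function(msd_profile) {
  stopifnot(all(c("lag_s", "msd_um2") %in% names(msd_profile)))
  if (nrow(msd_profile) < 2) stop("need at least 2 lags to fit")
  fit <- stats::lm(msd_um2 ~ lag_s, data = msd_profile)
  co <- stats::coef(fit)
  D <- unname(co[2]) / 4
  offset <- unname(co[1])
  if (D < 0) warning("fitted diffusion coefficient is negative")
  structure(list(D = D, offset = offset,
                 sigma_loc = if (offset >= 0) sqrt(offset / 4) else NA_real_,
                 negative_D = D < 0, n_lags = nrow(msd_profile), fit = fit),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s, offset = %.4g um^2 (%d lags)%s\n",
              x$D, x$offset, x$n_lags,
              if (x$negative_D) " [negative D]" else ""))
  invisible(x)
}
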