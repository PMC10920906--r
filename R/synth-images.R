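#' Scene configuration for synthetic nuclei fields
#'
#' Describes a confocal field of view: disc-like nuclei with softened edges
#' in a DNA-stain channel and, in a second channel, either diffuse nuclear
#' signal (a 5mC immunostain) or bright sub-nuclear Gaussian spots (the
#' methylation-reporter foci, 2-3 per nucleus by default). Intensities are
#' arbitrary units; geometry is in pixels with `pixel_size` carrying the
#' physical calibration.
#'
#' @param image_width,image_height field size in pixels.
#' @param n_slices confocal z-slices per field (default 7, matching a 1.2 um
#'   stack at 200 nm z-step).
#' @param n_nuclei nuclei to place.
#' @param nucleus_radius_range radius range in pixels, sampled uniformly.
#' @param spots_per_nucleus_range inclusive integer range of reporter spots
#'   per nucleus (default 2-3).
#' @param spot_sigma Gaussian spot width (sd) in pixels.
#' @param spot_amplitude peak spot intensity above the local nuclear level;
#'   set to 0 for a stain-only scene.
#' @param dna_amplitude intensity of the DNA stain inside nuclei.
#' @param nuclear_background diffuse signal-channel intensity inside nuclei
#'   (the 5mC-stain level in stain scenes; sensor background otherwise).
#' @param extranuclear_background intensity outside nuclei, both channels.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param nucleus_brightness_cv coefficient of variation of per-nucleus
#'   brightness (applied to nuclear signal and spot amplitudes; emulates
#'   cell-to-cell expression/staining variability).
#' @param edge_softness width (px) of the sigmoidal nuclear edge roll-off.
#' @param pixel_size um per pixel.
#' @param slice_step z-step in um.
#' @param border_margin minimum distance (px) from nucleus rim to the field
#'   border at placement.
#' @param seed integer seed; fully determines the generated scene.
#'
#' @return A `scene_config` list, validated.
#' @export
scene_config <- function(image_width = 256, image_height = 256, n_slices = 7,
                         n_nuclei = 10, nucleus_radius_range = c(14, 20),
                         spots_per_nucleus_range = c(2, 3),
                         spot_sigma = 2, spot_amplitude = 150,
                         dna_amplitude = 100, nuclear_background = 20,
                         extranuclear_background = 2, noise_sd = 2,
                         nucleus_brightness_cv = 0.1, edge_softness = 1.5,
                         pixel_size = 0.1, slice_step = 0.2,
                         border_margin = 2, seed = NULL) {
  cfg <- list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    n_slices = as.integer(n_slices), n_nuclei = as.integer(n_nuclei),
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    spots_per_nucleus_range = as.integer(spots_per_nucleus_range),
    spot_sigma = spot_sigma, spot_amplitude = spot_amplitude,
    dna_amplitude = dna_amplitude, nuclear_background = nuclear_background,
    extranuclear_background = extranuclear_background, noise_sd = noise_sd,
    nucleus_brightness_cv = nucleus_brightness_cv, edge_softness = edge_softness,
    pixel_size = pixel_size, slice_step = slice_step,
    border_margin = border_margin, seed = seed
  )
  stopifnot(cfg$image_width > 0, cfg$image_height > 0, cfg$n_slices >= 1,
            cfg$n_nuclei >= 0, length(cfg$nucleus_radius_range) == 2,
            all(cfg$nucleus_radius_range > 0),
            diff(cfg$nucleus_radius_range) >= 0,
            length(cfg$spots_per_nucleus_range) == 2,
            all(cfg$spots_per_nucleus_range >= 0),
            cfg$spot_sigma > 0, cfg$spot_amplitude >= 0,
            cfg$dna_amplitude > 0, cfg$nuclear_background >= 0,
            cfg$extranuclear_background >= 0, cfg$noise_sd >= 0,
            cfg$nucleus_brightness_cv >= 0, cfg$pixel_size > 0)
  class(cfg) <- c("scene_config", "list")
  cfg
}

# place non-overlapping nucleus centres by rejection sampling
place_nuclei <- function(cfg) {
  if (cfg$n_nuclei == 0) {
    return(tibble::tibble(nucleus_id = integer(), y_px = numeric(),
                          x_px = numeric(), radius_px = numeric()))
  }
  radii <- stats::runif(cfg$n_nuclei, cfg$nucleus_radius_range[1],
                        cfg$nucleus_radius_range[2])
  ys <- xs <- numeric(cfg$n_nuclei)
  # scenes are non-overlapping by design: the gap must clear the sigmoidal
  # edge tails of both nuclei or adjacent threshold masks would fuse
  gap <- 4 + 4 * cfg$edge_softness
  max_tries <- 400L
  for (i in seq_len(cfg$n_nuclei)) {
    lo_y <- radii[i] + cfg$border_margin
    hi_y <- cfg$image_height - 1 - radii[i] - cfg$border_margin
    lo_x <- radii[i] + cfg$border_margin
    hi_x <- cfg$image_width - 1 - radii[i] - cfg$border_margin
    if (hi_y <= lo_y || hi_x <= lo_x) {
      stop("nucleus radius + border_margin exceed the field size; ",
           "reduce nucleus_radius_range or border_margin")
    }
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      y <- stats::runif(1, lo_y, hi_y)
      x <- stats::runif(1, lo_x, hi_x)
      if (i == 1 || all(sqrt((ys[seq_len(i - 1)] - y)^2 +
                             (xs[seq_len(i - 1)] - x)^2) >
                        radii[seq_len(i - 1)] + radii[i] + gap)) {
        ys[i] <- y; xs[i] <- x; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("could not place nucleus ", i, " of ", cfg$n_nuclei,
           " without overlap after ", max_tries,
           " tries; the limiting parameter is n_nuclei (or ",
           "nucleus_radius_range) for this field size")
    }
  }
  tibble::tibble(nucleus_id = seq_len(cfg$n_nuclei), y_px = ys, x_px = xs,
                 radius_px = radii)
}

#' Simulate a two-channel confocal stack of nuclei with reporter signal
#'
#' Generates `n_slices` z-slices of a DNA-stain channel (`"dna"`) and a
#' signal channel (`"signal"`). Nuclei are discs with a sigmoidal edge;
#' reporter spots are 2-D Gaussians placed fully inside their nucleus, each
#' with a Gaussian intensity profile across z centred on a random interior
#' slice (so a maximum projection recovers the full amplitude). Presets
#' scale spot amplitude (dense, aza-treated dimmer than sparse/mock) or the
#' diffuse nuclear 5mC level (Bobcat339-treated 1.5x mock); see
#' [scene_preset()].
#'
#' @param cfg a [scene_config()].
#' @param preset condition preset name (see [scene_preset()]).
#' @return A list with elements `stack` (an [image_stack()]), `nuclei` and
#'   `spots` (ground-truth tibbles keyed by `nucleus_id`/`spot_id`).
#' @export
#' @examples
#' sim <- simulate_nuclei_stack(scene_config(n_nuclei = 3, seed = 1))
#' sim$nuclei
simulate_nuclei_stack <- function(cfg, preset = "none") {
  stopifnot(inherits(cfg, "scene_config"))
  ps <- scene_preset(preset)
  with_seed_local(cfg$seed, {
    nuclei <- place_nuclei(cfg)
    h <- cfg$image_height; w <- cfg$image_width; ns <- cfg$n_slices
    dna <- array(cfg$extranuclear_background, dim = c(h, w, ns))
    sig <- array(cfg$extranuclear_background, dim = c(h, w, ns))
    nuclei$brightness <- if (nrow(nuclei)) {
      pmax(0.2, stats::rnorm(nrow(nuclei), 1, cfg$nucleus_brightness_cv))
    } else numeric()
    nuclei$n_spots <- if (nrow(nuclei)) {
      sample(seq(cfg$spots_per_nucleus_range[1], cfg$spots_per_nucleus_range[2]),
             nrow(nuclei), replace = TRUE)
    } else integer()
    nuclei$area_px <- pi * nuclei$radius_px^2

    spots <- vector("list", nrow(nuclei))
    sfac <- ps$spot_factor
    nfac <- ps$nuclear_factor
    for (i in seq_len(nrow(nuclei))) {
      r <- nuclei$radius_px[i]; cy <- nuclei$y_px[i]; cx <- nuclei$x_px[i]
      pad <- ceiling(r + 4 * cfg$edge_softness)
      yy <- max(1, floor(cy - pad + 1)):min(h, ceiling(cy + pad + 1))
      xx <- max(1, floor(cx - pad + 1)):min(w, ceiling(cx + pad + 1))
      # pixel centres are 0-based: pixel index j covers coordinate j-1
      dist <- sqrt(outer((yy - 1 - cy)^2, (xx - 1 - cx)^2, `+`))
      wgt <- 1 / (1 + exp((dist - r) / cfg$edge_softness))
      bf <- nuclei$brightness[i]
      for (s in seq_len(ns)) {
        dna[yy, xx, s] <- dna[yy, xx, s] + cfg$dna_amplitude * bf * wgt
        sig[yy, xx, s] <- sig[yy, xx, s] +
          cfg$nuclear_background * nfac * bf * wgt
      }
      # spots fully inside: centre within 0.6 r, plus 3 sigma clearance
      nsp <- nuclei$n_spots[i]
      if (nsp > 0 && cfg$spot_amplitude > 0) {
        rho <- sqrt(stats::runif(nsp)) * pmax(0, 0.6 * r)
        th <- stats::runif(nsp, 0, 2 * pi)
        sy <- cy + rho * sin(th); sx <- cx + rho * cos(th)
        amp <- cfg$spot_amplitude * sfac * bf *
          pmax(0.2, stats::rnorm(nsp, 1, 0.1))
        zc <- if (ns == 1) rep(1, nsp) else
          sample(seq(2, max(2, ns - 1)), nsp, replace = TRUE)
        for (k in seq_len(nsp)) {
          g <- exp(-(outer((yy - 1 - sy[k])^2, (xx - 1 - sx[k])^2, `+`)) /
                     (2 * cfg$spot_sigma^2))
          zw <- exp(-(seq_len(ns) - zc[k])^2 / 2)  # sigma_z = 1 slice
          for (s in seq_len(ns)) {
            sig[yy, xx, s] <- sig[yy, xx, s] + amp[k] * zw[s] * g
          }
        }
        spots[[i]] <- tibble::tibble(
          nucleus_id = nuclei$nucleus_id[i], spot_id = seq_len(nsp),
          y_px = sy, x_px = sx, amplitude = amp, z_slice = zc)
      }
    }
    spots <- dplyr::bind_rows(spots)
    if (nrow(spots) == 0) {
      spots <- tibble::tibble(nucleus_id = integer(), spot_id = integer(),
                              y_px = numeric(), x_px = numeric(),
                              amplitude = numeric(), z_slice = integer())
    }
    px <- array(0, dim = c(h, w, 2, ns))
    px[, , 1, ] <- dna
    px[, , 2, ] <- sig
    if (cfg$noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, cfg$noise_sd)
    }
    stack <- image_stack(px, channel_names = c("dna", "signal"),
                         pixel_size = cfg$pixel_size,
                         slice_step = cfg$slice_step)
    list(stack = stack, nuclei = nuclei, spots = spots, preset = ps$name)
  })
}

#' Render trajectories into a time-lapse movie
#'
#' Produces one single-channel frame per time point with each spot drawn as
#' a Gaussian of `cfg$spot_sigma` on a uniform background plus pixel noise.
#' Trajectory coordinates (um) are converted to pixels via `cfg$pixel_size`
#' and must land inside the field.
#'
#' @param trajectories tibble with columns `trajectory_id`, `frame`, `t_s`,
#'   `x_um`, `y_um` (as produced by [simulate_trajectories()], possibly
#'   shifted into the field).
#' @param cfg a [scene_config()]; `image_width/height`, `spot_sigma`,
#'   `spot_amplitude`, `extranuclear_background`, `noise_sd`, `pixel_size`
#'   and `seed` are used.
#' @param frame_interval seconds between frames, recorded in the output.
#' @return An [image_stack()] movie (channel `"signal"`).
#' @export
render_movie <- function(trajectories, cfg, frame_interval = 0.1) {
  stopifnot(inherits(cfg, "scene_config"))
  req <- c("trajectory_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(trajectories))) {
    stop("trajectories must have columns ", paste(req, collapse = ", "))
  }
  h <- cfg$image_height; w <- cfg$image_width
  frames <- if (nrow(trajectories)) sort(unique(trajectories$frame)) else 1L
  nf <- length(frames)
  ypx <- trajectories$y_um / cfg$pixel_size
  xpx <- trajectories$x_um / cfg$pixel_size
  bad <- which(ypx < 0 | ypx > h - 1 | xpx < 0 | xpx > w - 1)
  if (length(bad)) {
    stop("trajectory ", trajectories$trajectory_id[bad[1]], " leaves the field at frame ",
         trajectories$frame[bad[1]],
         " (coordinate outside the rendered field of view)")
  }
  with_seed_local(cfg$seed, {
    px <- array(cfg$extranuclear_background, dim = c(h, w, 1, nf))
    for (fi in seq_len(nf)) {
      rows <- which(trajectories$frame == frames[fi])
      for (k in rows) {
        cy <- ypx[k]; cx <- xpx[k]
        pad <- ceiling(4 * cfg$spot_sigma)
        yy <- max(1, floor(cy - pad + 1)):min(h, ceiling(cy + pad + 1))
        xx <- max(1, floor(cx - pad + 1)):min(w, ceiling(cx + pad + 1))
        g <- exp(-(outer((yy - 1 - cy)^2, (xx - 1 - cx)^2, `+`)) /
                   (2 * cfg$spot_sigma^2))
        px[yy, xx, 1, fi] <- px[yy, xx, 1, fi] + cfg$spot_amplitude * g
      }
    }
    if (cfg$noise_sd > 0) px <- px + stats::rnorm(length(px), 0, cfg$noise_sd)
    image_stack(px, channel_names = "signal", pixel_size = cfg$pixel_size,
                frame_interval = frame_interval)
  })
}
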