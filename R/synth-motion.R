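#' Motion model configuration for simulated spot trajectories
#'
#' @param n_trajectories number of spots to simulate.
#' @param n_frames frames per trajectory (>= 2).
#' @param frame_interval seconds between frames (default 0.1, i.e. the
#'   100 ms/frame acquisition rate used for chromatin-mobility imaging).
#' @param diffusion_coefficient D in um^2/s (>= 0).
#' @param localization_sd static localization error sd in um, added
#'   independently per axis and frame to the observed coordinates.
#' @param motion_model `"brownian"` (free diffusion) or `"confined"`
#'   (diffusion reflected at `confinement_radius` around the start point).
#' @param confinement_radius um; required for the confined model.
#' @param seed integer seed; fully determines the output.
#' @return A validated `motion_config` list.
#' @export
motion_config <- function(n_trajectories = 50, n_frames = 100,
                          frame_interval = 0.1, diffusion_coefficient = 0.01,
                          localization_sd = 0.02,
                          motion_model = c("brownian", "confined"),
                          confinement_radius = NULL, seed = NULL) {
  motion_model <- match.arg(motion_model)
  stopifnot(n_trajectories >= 1, n_frames >= 2, frame_interval > 0,
            diffusion_coefficient >= 0, localization_sd >= 0)
  if (motion_model == "confined") {
    if (is.null(confinement_radius) || confinement_radius <= 0) {
      stop("confined motion requires confinement_radius > 0")
    }
  }
  structure(list(n_trajectories = as.integer(n_trajectories),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 diffusion_coefficient = diffusion_coefficient,
                 localization_sd = localization_sd,
                 motion_model = motion_model,
                 confinement_radius = confinement_radius, seed = seed),
            class = c("motion_config", "list"))
}

reflect_into <- function(x, radius) {
  # reflect a coordinate into [-radius, radius] (reflecting boundary)
  period <- 4 * radius
  x <- (x + radius) %% period
  x <- ifelse(x > 2 * radius, period - x, x)
  x - radius
}

#' Simulate diffusing spot trajectories
#'
#' Brownian motion draws independent per-axis Gaussian increments with
#' variance `2 * D * dt`; the confined model reflects each axis at
#' `confinement_radius` around the starting position. Observed coordinates
#' are the true positions plus independent Gaussian localization noise of sd
#' `localization_sd`, so the ensemble MSD converges to
#' `4 D tau + 4 localization_sd^2`.
#'
#' @param cfg a [motion_config()].
#' @param origin length-2 `(x, y)` um offset applied to all start points
#'   (start points are jittered around it).
#' @param start_spread um; sd of the start-point scatter around `origin`.
#' @return A list with `trajectories` (tibble: `trajectory_id`, `frame`,
#'   `t_s`, `x_um`, `y_um` — observed) and `truth` (same keys with
#'   `x_true_um`, `y_true_um` plus the generating `diffusion_coefficient`).
#' @export
#' @examples
#' sim <- simulate_trajectories(motion_config(n_trajectories = 2, seed = 1))
#' head(sim$trajectories)
simulate_trajectories <- function(cfg, origin = c(0, 0), start_spread = 0) {
  stopifnot(inherits(cfg, "motion_config"))
  if (cfg$n_frames < 2) stop("n_frames must be >= 2: no displacement computable")
  with_seed_local(cfg$seed, {
    n <- cfg$n_trajectories; nf <- cfg$n_frames
    step_sd <- sqrt(2 * cfg$diffusion_coefficient * cfg$frame_interval)
    sx <- origin[1] + stats::rnorm(n, 0, start_spread)
    sy <- origin[2] + stats::rnorm(n, 0, start_spread)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      dx <- c(0, stats::rnorm(nf - 1, 0, step_sd))
      dy <- c(0, stats::rnorm(nf - 1, 0, step_sd))
      xt <- cumsum(dx); yt <- cumsum(dy)
      if (cfg$motion_model == "confined") {
        xt <- reflect_into(xt, cfg$confinement_radius)
        yt <- reflect_into(yt, cfg$confinement_radius)
      }
      xt <- xt + sx[i]; yt <- yt + sy[i]
      out[[i]] <- tibble::tibble(
        trajectory_id = i, frame = seq_len(nf),
        t_s = (seq_len(nf) - 1) * cfg$frame_interval,
        x_true_um = xt, y_true_um = yt)
    }
    truth <- dplyr::bind_rows(out)
    truth$diffusion_coefficient <- cfg$diffusion_coefficient
    obs <- truth
    obs$x_um <- obs$x_true_um +
      stats::rnorm(nrow(obs), 0, cfg$localization_sd)
    obs$y_um <- obs$y_true_um +
      stats::rnorm(nrow(obs), 0, cfg$localization_sd)
    trajectories <- obs[, c("trajectory_id", "frame", "t_s", "x_um", "y_um")]
    attr(trajectories, "frame_interval") <- cfg$frame_interval
    list(trajectories = trajectories, truth = truth)
  })
}
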