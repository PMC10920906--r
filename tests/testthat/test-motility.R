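make_traj <- function(x, y, dt = 1) {
  tibble::tibble(trajectory_id = 1L, frame = seq_along(x),
                 t_s = (seq_along(x) - 1) * dt, x_um = x, y_um = y)
}

test_that("moving average matches hand arithmetic and its edge cases", {
  px <- array(0, dim = c(1, 1, 1, 6))
  px[1, 1, 1, ] <- 1:6
  mv <- image_stack(px, frame_interval = 0.1)
  out <- temporal_moving_average(mv, 5)
  expect_equal(as.vector(out$pixels[1, 1, 1, ]), c(3, 4))
  expect_equal(attr(out, "time_origin_shift_s"), 0.2)
  expect_identical(temporal_moving_average(mv, 1), mv)   # identity window
  const <- image_stack(array(4, dim = c(2, 2, 1, 8)), frame_interval = 0.1)
  expect_true(all(temporal_moving_average(const, 5)$pixels == 4))
  expect_error(temporal_moving_average(mv, 7), "between 1 and")
})

test_that("MSD matches closed forms on degenerate trajectories", {
  still <- make_traj(rep(1, 10), rep(2, 10))
  expect_true(all(compute_msd(still)$msd_um2 == 0))
  v <- 0.3
  ball <- make_traj(v * (0:9), rep(0, 10))
  msd <- compute_msd(ball)
  expect_equal(msd$msd_um2, v^2 * msd$lag_s^2, tolerance = 1e-12)
  # the hand-checked worked example
  ex <- make_traj(c(0, 1, 1, 2), c(0, 0, 1, 1))
  m <- compute_msd(ex)
  expect_equal(m$msd_um2[m$lag_s == 1], 1.0)
  expect_equal(m$msd_um2[m$lag_s == 2], 2.0)
  expect_equal(m$n_pairs, c(3L, 2L, 1L))
})

test_that("MSD equals the brute-force pair enumeration on random trajectories", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    tr <- make_traj(cumsum(rnorm(n)), cumsum(rnorm(n)), dt = 0.1)
    got <- compute_msd(tr)
    want <- msd_brute_force(tr$t_s, tr$x_um, tr$y_um, 0.1)
    expect_equal(got$msd_um2, want$msd, tolerance = 1e-12)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("MSD is invariant under translation and rotation", {
  set.seed(7)
  tr <- make_traj(cumsum(rnorm(25)), cumsum(rnorm(25)))
  base <- compute_msd(tr)$msd_um2
  shifted <- tr
  shifted$x_um <- shifted$x_um + 100; shifted$y_um <- shifted$y_um - 40
  expect_equal(compute_msd(shifted)$msd_um2, base, tolerance = 1e-12)
  th <- 0.7
  rot <- tr
  rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um
  rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um
  expect_equal(compute_msd(rot)$msd_um2, base, tolerance = 1e-9)
})

test_that("ensemble MSD pools pairs and omits empty lags", {
  t1 <- make_traj(c(0, 1, 2), c(0, 0, 0))
  t2 <- make_traj(c(0, 2), c(0, 0)); t2$trajectory_id <- 2L
  ens <- compute_msd(dplyr::bind_rows(t1, t2), mode = "ensemble")
  # lag 1: pairs (1,1) from t1 and (4) from t2 -> (1+1+4)/3
  expect_equal(ens$msd_um2[ens$lag_s == 1], 2)
  expect_equal(ens$n_pairs[ens$lag_s == 1], 3L)
  expect_equal(ens$msd_um2[ens$lag_s == 2], 4)   # only t1 contributes
  short <- make_traj(c(0, 1), c(0, 0))
  expect_false(any(compute_msd(short)$lag_s > 1))  # zero-pair lags omitted
})

test_that("the scaled-MAD filter reproduces its hand-worked example", {
  res <- scaled_mad_filter(c(1, 2, 3, 4, 100))
  expect_identical(res$value[res$outlier], 100)
  expect_identical(res$value[!res$outlier], c(1, 2, 3, 4))
  expect_false(any(scaled_mad_filter(rep(5, 4))$outlier))  # all equal: none
  expect_false(any(scaled_mad_filter(c(1, 2, 3, 4, 5))$outlier))
  # degenerate rule: zero MAD flags every value off the median
  res2 <- scaled_mad_filter(c(1, 1, 1, 1, 2))
  expect_identical(res2$value[res2$outlier], 2)
  expect_error(scaled_mad_filter(numeric()), "finite value")
})

test_that("tracking links well-separated drifting spots to the truth", {
  frames <- 1:20
  det <- dplyr::bind_rows(
    tibble::tibble(frame = frames, y_px = 10 + 0.2 * frames, x_px = 10),
    tibble::tibble(frame = frames, y_px = 50, x_px = 50 - 0.2 * frames))
  tr <- track_spots(det, max_displacement = 0.5, min_length = 10,
                    pixel_size = 0.1, frame_interval = 0.1)
  expect_equal(dplyr::n_distinct(tr$trajectory_id), 2)
  expect_equal(as.vector(table(tr$trajectory_id)), c(20L, 20L))
  # a spot disappearing mid-movie terminates (no gap closing)
  det2 <- tibble::tibble(frame = c(1:5, 9:12), y_px = 5, x_px = 5)
  tr2 <- track_spots(det2, max_displacement = 0.5, min_length = 2,
                     pixel_size = 0.1)
  expect_equal(dplyr::n_distinct(tr2$trajectory_id), 2)
  # single static spot: one trajectory of full length
  det3 <- tibble::tibble(frame = 1:15, y_px = 8, x_px = 8)
  tr3 <- track_spots(det3, max_displacement = 0.2, min_length = 15,
                     pixel_size = 0.1)
  expect_equal(dplyr::n_distinct(tr3$trajectory_id), 1)
})

test_that("detection + tracking on a rendered movie reconstructs the truth links", {
  cfg <- motion_config(n_trajectories = 2, n_frames = 25,
                       diffusion_coefficient = 0.002,
                       localization_sd = 0, seed = 23)
  sim <- simulate_trajectories(cfg, origin = c(2, 2), start_spread = 0)
  # separate the two spots widely before rendering
  traj <- sim$trajectories
  traj$x_um <- traj$x_um + ifelse(traj$trajectory_id == 2, 3, 0)
  scene <- scene_config(image_width = 80, image_height = 80, noise_sd = 0.5,
                        spot_amplitude = 200, seed = 3)
  movie <- render_movie(traj, scene)
  det <- detect_spots(movie, k = 5)
  tr <- track_spots(det, max_displacement = 0.5, min_length = 20,
                    pixel_size = scene$pixel_size, frame_interval = 0.1)
  expect_equal(dplyr::n_distinct(tr$trajectory_id), 2)
  lens <- table(tr$trajectory_id)
  expect_true(all(lens >= 0.95 * 25))
})

test_that("mobility scores report both 1-s readouts and exclude short tracks", {
  tr1 <- make_traj(0.1 * (0:20), rep(0, 21), dt = 0.1)        # ballistic
  tr2 <- make_traj(rep(0, 5), rep(0, 5), dt = 0.1)             # too short
  tr2$trajectory_id <- 2L
  mob <- mobility_summary(dplyr::bind_rows(tr1, tr2), lag_target = 1)
  expect_equal(mob$n_excluded_short, 1)
  expect_equal(nrow(mob$scores), 1)
  # ballistic: MSD(1 s) = (v*1)^2 with v = 1 um/s
  expect_equal(mob$scores$msd_at_1s, 1, tolerance = 1e-12)
  # mean over lags 0.1..1.0 of v^2 tau^2
  expect_equal(mob$scores$msd_mean_to_1s, mean((0.1 * (1:10))^2),
               tolerance = 1e-12)
})

test_that("sparse cultures score faster than dense in seeded replicates", {
  wins <- 0
  for (s in 1:10) {
    sp <- simulate_trajectories(motion_config(
      n_trajectories = 40, n_frames = 30, diffusion_coefficient = 0.010,
      seed = 100 + s))$trajectories
    dn <- simulate_trajectories(motion_config(
      n_trajectories = 40, n_frames = 30, diffusion_coefficient = 0.005,
      seed = 200 + s))$trajectories
    sp$condition <- "sparse"; dn$condition <- "dense"
    dn$trajectory_id <- dn$trajectory_id + 1000
    mob <- mobility_summary(dplyr::bind_rows(sp, dn), lag_target = 1)
    m <- tapply(mob$scores$msd_at_1s[!mob$scores$outlier],
                mob$scores$condition[!mob$scores$outlier], mean)
    if (m["sparse"] > m["dense"]) wins <- wins + 1
  }
  expect_gte(wins, 10 * 0.95)
})

test_that("diffusion fits recover parameters and flag negative slopes", {
  lin <- tibble::tibble(lag_s = (1:10) / 10, msd_um2 = 4 * 0.01 * (1:10) / 10)
  fit <- fit_diffusion(lin)
  expect_equal(fit$D, 0.01, tolerance = 1e-12)
  expect_equal(fit$offset, 0, tolerance = 1e-12)
  flat <- tibble::tibble(lag_s = (1:10) / 10, msd_um2 = rep(0.02, 10))
  expect_equal(fit_diffusion(flat)$D, 0, tolerance = 1e-12)
  dec <- tibble::tibble(lag_s = 1:3, msd_um2 = c(3, 2, 1))
  expect_warning(fit <- fit_diffusion(dec), "negative")
  expect_true(fit$negative_D)
  expect_lt(fit$D, 0)
  # parameter recovery at the documented simulation scale
  sim <- simulate_trajectories(motion_config(
    n_trajectories = 500, n_frames = 100, diffusion_coefficient = 0.01,
    localization_sd = 0.02, seed = 42))
  ens <- compute_msd(sim$trajectories, max_lag = 1, mode = "ensemble")
  fit <- fit_diffusion(ens)
  expect_equal(fit$D, 0.01, tolerance = 0.1)
  expect_equal(fit$offset, 4 * 0.02^2, tolerance = 0.25)
})

test_that("dropping the moving average leaves fitted D stable on clean data", {
  cfg <- motion_config(n_trajectories = 200, n_frames = 60,
                       diffusion_coefficient = 0.01, localization_sd = 0,
                       seed = 55)
  tr <- simulate_trajectories(cfg)$trajectories
  fit_raw <- fit_diffusion(compute_msd(tr, max_lag = 1, mode = "ensemble"))
  # 5-frame boxcar on coordinates emulates the movie-level moving average
  sm <- dplyr::group_modify(dplyr::group_by(tr, trajectory_id), ~ {
    .x$x_um <- as.numeric(stats::filter(.x$x_um, rep(1 / 5, 5), sides = 1))
    .x$y_um <- as.numeric(stats::filter(.x$y_um, rep(1 / 5, 5), sides = 1))
    .x[!is.na(.x$x_um), ]
  })
  fit_sm <- fit_diffusion(compute_msd(dplyr::ungroup(sm), max_lag = 1,
                                      mode = "ensemble"))
  expect_equal(fit_sm$D, fit_raw$D, tolerance = 0.25)
})
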