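test_that("max projection is the pixelwise maximum with slice-count checks", {
  px <- array(0, dim = c(8, 8, 1, 3))
  px[3, 4, 1, 2] <- 5
  st <- image_stack(px)
  expect_equal(max_project(st, 1, 3)[3, 4], 5)
  const <- image_stack(array(2, dim = c(4, 4, 1, 7)))
  expect_true(all(max_project(const) == 2))
  rnd <- image_stack(array(runif(8 * 8 * 1 * 5), dim = c(8, 8, 1, 5)))
  proj <- max_project(rnd)
  for (s in 1:5) expect_true(all(proj >= rnd$pixels[, , 1, s]))
  expect_error(max_project(st, 1, 4), "only 3")
})

test_that("segmentation finds discs with near-analytic areas and honours the border rule", {
  img <- disc_image(128, 128,
                    centers = rbind(c(30, 30), c(30, 90), c(90, 60)),
                    radius = 10, fg = 100, bg = 1)
  seg <- segment_nuclei(img, min_area = 100)
  expect_equal(nrow(seg$nuclei), 3)
  expect_equal(seg$nuclei$area_px, rep(pi * 100, 3), tolerance = 0.1)
  # a disc overlapping the border is excluded under the stated rule
  img2 <- disc_image(128, 128, centers = rbind(c(0, 60), c(64, 64)),
                     radius = 10, fg = 100, bg = 1)
  seg2 <- segment_nuclei(img2, min_area = 100, exclude_border = TRUE)
  expect_equal(nrow(seg2$nuclei), 1)
  seg2b <- segment_nuclei(img2, min_area = 100, exclude_border = FALSE)
  expect_equal(sum(seg2b$nuclei$touches_border), 1)
  # blank image: zero nuclei, not an error
  expect_equal(nrow(segment_nuclei(matrix(3, 64, 64))$nuclei), 0)
})

test_that("spot quantification does per-cell background subtraction exactly", {
  img <- disc_image(64, 64, centers = rbind(c(32, 32)), radius = 15,
                    fg = 100, bg = 1)
  seg <- segment_nuclei(img, min_area = 100)
  reporter <- matrix(0, 64, 64)
  reporter[seg$label_image == 1] <- 10              # nuclear background 10
  reporter[30:34, 30:34] <- 110                     # one spot region at 110
  q <- quantify_spots(seg$label_image, reporter)
  expect_equal(q$corrected_signal, 100)
  expect_equal(q$spot_count, 1L)
  expect_equal(q$spot_pixel_count, 25L)
  # uniform reporter: no pixel passes mean + k sd, record kept and flagged
  q0 <- quantify_spots(seg$label_image,
                       matrix(7, 64, 64))
  expect_equal(nrow(q0), 1)
  expect_true(is.na(q0$corrected_signal))
})

test_that("spot and background masks partition the nucleus; offsets cancel, gain scales", {
  sim <- simulate_nuclei_stack(scene_config(n_nuclei = 6, seed = 31))
  dna <- max_project(sim$stack, "dna")
  sig <- max_project(sim$stack, "signal")
  seg <- segment_nuclei(dna)
  q1 <- quantify_spots(seg$label_image, sig)
  q2 <- quantify_spots(seg$label_image, sig + 50)        # additive offset
  expect_equal(q2$corrected_signal, q1$corrected_signal, tolerance = 1e-10)
  q3 <- quantify_spots(seg$label_image, sig * 2)          # multiplicative gain
  expect_equal(q3$corrected_signal, 2 * q1$corrected_signal,
               tolerance = 1e-10)
  # partition identity per nucleus: spot pixels + background pixels = nucleus
  for (l in q1$nucleus_label) {
    n_nuc <- sum(seg$label_image == l)
    vals <- sig[seg$label_image == l]
    thr <- mean(vals) + 3 * sd(vals)
    expect_equal(sum(vals > thr) + sum(vals <= thr), n_nuc)
  }
})

test_that("segmentation recovers nearly all truth nuclei with sub-2px centroids", {
  cfg <- scene_config(image_width = 512, image_height = 512, n_nuclei = 30,
                      seed = 8)
  sim <- simulate_nuclei_stack(cfg)
  seg <- segment_nuclei(max_project(sim$stack, "dna"))
  truth <- sim$nuclei
  matched <- 0
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((seg$nuclei$y_px - truth$y_px[i])^2 +
              (seg$nuclei$x_px - truth$x_px[i])^2)
    if (length(d) && min(d) < 2) matched <- matched + 1
  }
  expect_gte(matched / nrow(truth), 0.95)
  # spot counts recovered within the documented 2-3 band on average
  q <- quantify_spots(seg$label_image, max_project(sim$stack, "signal"))
  expect_gte(mean(q$spot_count), 2)
  expect_lte(mean(q$spot_count), 3)
})

test_that("corrected signal increases monotonically with true spot amplitude", {
  amps <- c(50, 100, 200, 400)
  res <- vapply(amps, function(a) {
    cfg <- scene_config(n_nuclei = 4, noise_sd = 0, nucleus_brightness_cv = 0,
                        spot_amplitude = a, seed = 12)
    sim <- simulate_nuclei_stack(cfg)
    seg <- segment_nuclei(max_project(sim$stack, "dna"))
    q <- quantify_spots(seg$label_image, max_project(sim$stack, "signal"))
    mean(q$corrected_signal, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(res) > 0))
})

test_that("mean nuclear area is near-analytic on discs and calibration scales", {
  img <- disc_image(160, 160, centers = rbind(c(50, 50), c(100, 110)),
                    radius = 10, fg = 100, bg = 1)
  res <- mean_nuclear_area(list(img), pixel_size = 0.1, min_area = 100)
  expect_equal(res$mean_area_px, pi * 100, tolerance = 0.1)
  res2 <- mean_nuclear_area(list(img), pixel_size = 0.2, min_area = 100)
  expect_equal(res2$mean_area_px, res$mean_area_px)          # px unchanged
  expect_equal(res2$mean_area_um2, 4 * res$mean_area_um2)    # um^2 scales x4
  # all nuclei on the border: field skipped, empty summary with warning
  border <- disc_image(64, 64, centers = rbind(c(0, 32)), radius = 10,
                       fg = 100, bg = 1)
  expect_warning(
    expect_warning(out <- mean_nuclear_area(list(border), min_area = 50),
                   "no usable"),
    "no field contained")
  expect_equal(nrow(out), 0)
})

test_that("mean nuclear intensity is linear and recovers a 1.5x stain ratio", {
  img <- disc_image(64, 64, centers = rbind(c(32, 32)), radius = 12,
                    fg = 100, bg = 1)
  seg <- segment_nuclei(img, min_area = 100)
  uni <- matrix(7, 64, 64)
  expect_equal(mean_nuclear_intensity(seg$label_image, uni)$mean_intensity, 7)
  expect_equal(
    mean_nuclear_intensity(seg$label_image, uni + 3)$mean_intensity, 10)
  # paired synthetic fields: treated nuclei stained 1.5x
  cfg <- scene_config(n_nuclei = 8, spot_amplitude = 0,
                      nuclear_background = 100, seed = 77)
  mock <- simulate_nuclei_stack(cfg, preset = "none")
  trt <- simulate_nuclei_stack(cfg, preset = "bobcat_treated")
  m <- function(sim) {
    seg <- segment_nuclei(max_project(sim$stack, "dna"))
    mean(mean_nuclear_intensity(seg$label_image,
                                max_project(sim$stack, "signal"))$mean_intensity)
  }
  expect_equal(m(trt) / m(mock), 1.5, tolerance = 0.05)
})
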