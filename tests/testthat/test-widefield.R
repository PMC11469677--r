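test_that("binning pools means and rescales geometry", {
  raw <- array(runif(2 * 320 * 256), dim = c(2, 320, 256))
  out <- preprocess_movie(raw, 2, pixel_size_um = 31.25,
                          bregma_pixel = c(120, 128))
  expect_equal(dim(out$movie), c(2, 160, 128))
  expect_equal(out$pixel_size_um, 62.5)
  expect_equal(out$movie[1, 1, 1], mean(raw[1, 1:2, 1:2]))
  # constant image stays constant; checkerboard averages to 0.5
  cst <- array(3.7, dim = c(1, 8, 8))
  expect_true(all(preprocess_movie(cst, 2)$movie == 3.7))
  chk <- array(0, dim = c(1, 8, 8))
  chk[1, , ] <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_true(all(preprocess_movie(chk, 2)$movie == 0.5))
  # trailing rows that do not fill a bin are dropped with a warning
  odd <- array(1, dim = c(1, 9, 8))
  expect_warning(o2 <- preprocess_movie(odd, 2), "trailing")
  expect_equal(dim(o2$movie), c(1, 4, 4))
})

test_that("dF/F is zero for constant movies and exact for known steps", {
  times <- seq(-300, 400, by = 10)  # 100 Hz
  nf <- length(times)
  movie <- array(50, dim = c(2, nf, 6, 6))
  log <- data.frame(trial = 1:2, grid_point_id = 1L,
                    stim_ml_mm = 3, stim_ap_mm = -1.5)
  ses <- widefield_session(movie, times, log, 62.5, c(3, 3))
  dff <- compute_dff(ses)
  expect_true(all(dff$movie == 0))
  # at 100 Hz the 300 ms baseline uses 30 frames
  expect_equal(sum(times >= -300 & times < 0), 30L)
  # post-stimulus frames at 2*F0 give dF/F of exactly 1
  movie2 <- movie
  movie2[, times >= 0, , ] <- 100
  ses2 <- widefield_session(movie2, times, log, 62.5, c(3, 3))
  dff2 <- compute_dff(ses2)
  expect_true(all(dff2$movie[, times >= 0, , ] == 1))
  expect_error(compute_dff(widefield_session(
    movie[, times >= 0, , , drop = FALSE], times[times >= 0], log, 62.5,
    c(3, 3))), "baseline")
})

test_that("evoked maps average the window and scale linearly", {
  tr <- widefield_truth(image_shape = c(48L, 40L), bregma_pixel = c(36, 24),
                        resp_ml_mm = 0.5, amplitude = 0.04, noise_sd = 0,
                        ap_jitter_sd_mm = 0, trials_per_point = 2L)
  sim <- simulate_widefield_session(tr, frame_rate_hz = 50, seed = 4)
  dff <- compute_dff(sim$session)
  em <- evoked_map(dff, 2)
  expect_equal(em$n_trials, 2L)
  # noise-free session reproduces the generator's hotspot template
  ctr <- sim$truth$centers[2, ]
  template <- 0.04 * outer(
    exp(-(seq_len(48) - ctr$resp_row)^2 / (2 * tr$spread_px^2)),
    exp(-(seq_len(40) - ctr$resp_col)^2 / (2 * tr$spread_px^2)))
  expect_equal(em$data, template, tolerance = 1e-9)
  # doubling dF/F doubles the map
  dff2 <- dff; dff2$movie <- 2 * dff2$movie
  expect_equal(evoked_map(dff2, 2)$data, 2 * em$data, tolerance = 1e-12)
  expect_error(evoked_map(dff, 99), "no trials")
  expect_error(evoked_map(sim$session, 1), "compute_dff")
})

test_that("population averages weight maps by trial count", {
  mk <- function(val, n) structure(
    list(data = matrix(val, 4, 4), n_trials = n, grid_point_id = 1L,
         stim_ml_mm = 3, stim_ap_mm = -1.5, pixel_size_um = 62.5,
         bregma_pixel = c(2, 2), mouse_id = "m"), class = "evoked_map")
  avg <- population_average(list(mk(0, 1L), mk(4, 3L)))
  expect_true(all(avg$data == 3))
  expect_equal(avg$n_trials, 4L)
  expect_equal(population_average(list(mk(2, 5L)))$data,
               matrix(2, 4, 4))
  expect_equal(population_average(list(mk(1, 2L), mk(3, 2L)))$data,
               matrix(2, 4, 4))
  expect_error(population_average(list()), "at least one")
})

test_that("masked center of mass localizes responses in bregma mm", {
  geom <- list(pixel_size_um = 62.5, bregma_pixel = c(36, 24))
  mk <- function(data) structure(c(list(data = data), geom,
                                   list(n_trials = 1L)),
                                 class = "evoked_map")
  mask <- frontal_mask(c(36, 24), nrow = 20, ncol = 30, row_offset = -25,
                       col_offset = -19)
  # single-pixel impulse -> that pixel's coordinates
  z <- matrix(0, 48, 40); z[20, 16] <- 1
  cm <- frontal_center_of_mass(mk(z), mask)
  expect_equal(cm$ap_mm, (36 - 20) * 0.0625)
  expect_equal(cm$ml_mm, (16 - 24) * 0.0625)
  # uniform positive map -> geometric center of the mask
  u <- matrix(1, 48, 40)
  cmu <- frontal_center_of_mass(mk(u), mask)
  expect_equal(cmu$ap_mm, (36 - mean(mask$rows)) * 0.0625)
  expect_equal(cmu$ml_mm, (mean(mask$cols) - 24) * 0.0625)
  # symmetric Gaussian bump inside the mask -> its center within 0.2 px
  g <- outer(exp(-(seq_len(48) - 20.37)^2 / 18),
             exp(-(seq_len(40) - 15.58)^2 / 18))
  cmg <- frontal_center_of_mass(mk(g), mask)
  expect_lt(abs(36 - cmg$ap_mm / 0.0625 - 20.37), 0.2)
  expect_lt(abs(24 + cmg$ml_mm / 0.0625 - 15.58), 0.2)
  # all-non-positive mask -> no-response result
  cmn <- frontal_center_of_mass(mk(matrix(-1, 48, 40)), mask)
  expect_true(is.na(cmn$ap_mm))
  expect_error(frontal_center_of_mass(
    mk(z), list(rows = 0:10, cols = 1:5)), "outside")
})

test_that("functional regression pools mice and skips degenerate subsets", {
  pts <- data.frame(
    abs_ml_mm = c(3, 3.5, 4, 4.5, 3, 3.5, 4, 4.5, 3),
    ap_mm = c(0.75, 1, 1.25, 1.5, 0.75, 1, 1.25, 1.5, 0.75),
    mouse_id = c(rep("m1", 4), rep("m2", 4), "m3"))
  res <- fit_functional_topography(pts)
  expect_equal(res$fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(res$fit$r, 1, tolerance = 1e-12)
  expect_equal(res$fit$n, 9L)
  # m3 has one point: contributes to the pool but gets no per-mouse line
  expect_equal(sort(res$per_mouse$mouse_id), c("m1", "m2"))
  expect_equal(res$per_mouse$slope, c(0.5, 0.5), tolerance = 1e-12)
})
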