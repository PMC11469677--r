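#' Ground truth for a synthetic wide-field optogenetics session
#'
#' Describes a stimulation grid along the mediolateral axis of somatosensory
#' cortex and the functional mirror map the evoked responses obey: the
#' response center in frontal cortex sits at
#' \code{AP = intercept + slope * |stim ML|} at a fixed response ML. Evoked
#' responses are separable Gaussian-in-space, boxcar-in-time fractional
#' fluorescence bumps on top of a baseline image.
#'
#' @param grid_ml_mm |ML| positions of the stimulation points (default
#'   3.0-4.5 mm in 0.5 mm steps, the spacing of the stimulation grid).
#' @param grid_ap_mm AP of the stimulation points (default -1.5 mm).
#' @param intercept_mm,slope_mm_per_mm functional map parameters
#'   (defaults -0.75 and 0.5).
#' @param resp_ml_mm ML of the response center (default 1.0 mm, ipsilateral
#'   left, i.e. negative column offset).
#' @param amplitude peak fractional response dF/F (default 0.05).
#' @param spread_px response Gaussian spread in binned pixels (default 4).
#' @param onset_ms,duration_ms response boxcar (defaults 0 and 300 ms).
#' @param ap_jitter_sd_mm between-mouse SD of the map's AP offset; one
#'   offset is drawn per session (default 0.1 mm), emulating
#'   mouse-to-mouse variability of the functional map.
#' @param f0 baseline fluorescence (scalar or H x W image, default 100).
#' @param noise_sd additive per-pixel noise SD in raw fluorescence units
#'   (default 0.5, i.e. 0.5\% of the default baseline).
#' @param trials_per_point trials per stimulation point (default 3).
#' @param image_shape (rows, cols) of the binned frame; rows run AP
#'   (posterior down), cols run ML (right positive). Default 160 x 128
#'   (a 10 x 8 mm field of view binned to 62.5 um pixels).
#' @param pixel_size_um binned pixel size (default 62.5).
#' @param bregma_pixel (row, col) of bregma (default c(60, 64)).
#' @return list of class \code{widefield_truth}.
#' @export
widefield_truth <- function(grid_ml_mm = c(3, 3.5, 4, 4.5),
                            grid_ap_mm = -1.5,
                            intercept_mm = -0.75, slope_mm_per_mm = 0.5,
                            resp_ml_mm = 1.0,
                            amplitude = 0.05, spread_px = 4,
                            onset_ms = 0, duration_ms = 300,
                            ap_jitter_sd_mm = 0.1,
                            f0 = 100, noise_sd = 0.5,
                            trials_per_point = 3L,
                            image_shape = c(160L, 128L),
                            pixel_size_um = 62.5,
                            bregma_pixel = c(60, 64)) {
  if (amplitude < 0) stopf("amplitude must be non-negative")
  if (trials_per_point < 1) stopf("trials_per_point must be >= 1")
  structure(list(grid_ml_mm = grid_ml_mm, grid_ap_mm = grid_ap_mm,
                 intercept_mm = intercept_mm,
                 slope_mm_per_mm = slope_mm_per_mm,
                 resp_ml_mm = resp_ml_mm, amplitude = amplitude,
                 spread_px = spread_px, onset_ms = onset_ms,
                 duration_ms = duration_ms,
                 ap_jitter_sd_mm = ap_jitter_sd_mm,
                 f0 = f0, noise_sd = noise_sd,
                 trials_per_point = as.integer(trials_per_point),
                 image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 bregma_pixel = bregma_pixel),
            class = "widefield_truth")
}

#' Wide-field session container
#'
#' @param movie 4D array (trial, frame, row, col) of fluorescence.
#' @param frame_times_ms frame times relative to stimulation onset.
#' @param stim_log data.frame with columns \code{trial},
#'   \code{grid_point_id}, \code{stim_ml_mm}, \code{stim_ap_mm}.
#' @param pixel_size_um binned pixel size.
#' @param bregma_pixel (row, col) of bregma.
#' @param mouse_id,cre_line identifiers.
#' @return list of class \code{widefield_session}.
#' @export
widefield_session <- function(movie, frame_times_ms, stim_log,
                              pixel_size_um, bregma_pixel,
                              mouse_id = "m1", cre_line = "lineA") {
  if (length(dim(movie)) != 4L) stopf("movie must be (trial, frame, H, W)")
  if (dim(movie)[2] != length(frame_times_ms))
    stopf("frame_times_ms length must match frame count")
  if (is.unsorted(frame_times_ms, strictly = TRUE))
    stopf("frame_times_ms must be strictly increasing")
  if (!all(seq_len(dim(movie)[1]) %in% stim_log$trial))
    stopf("stim_log must cover every trial")
  structure(list(movie = movie, frame_times_ms = frame_times_ms,
                 stim_log = stim_log, pixel_size_um = pixel_size_um,
                 bregma_pixel = bregma_pixel, mouse_id = mouse_id,
                 cre_line = cre_line),
            class = "widefield_session")
}

#' Simulate a wide-field optogenetics session
#'
#' Per trial, the movie is \code{F0 * (1 + response(t, x, y)) + noise} with
#' the response a separable spatial Gaussian centered at the truth location
#' for the trial's stimulation point and a boxcar in time. Stimulation
#' points are interleaved in randomized order; the log records every trial.
#'
#' @param truth a \code{\link{widefield_truth}}.
#' @param frame_rate_hz sampling rate used to lay out frame times
#'   (default 100).
#' @param seed integer seed.
#' @param mouse_id,cre_line identifiers recorded in the session.
#' @param frame_times_ms optional explicit (possibly irregular) frame
#'   times; default is regular sampling from -320 ms to 470 ms.
#' @return list with elements \code{session}
#'   (\code{\link{widefield_session}}) and \code{truth} (the input truth
#'   plus the per-grid-point response centers in mm and pixels).
#' @export
simulate_widefield_session <- function(truth, frame_rate_hz = 100, seed = 1,
                                       mouse_id = "m1", cre_line = "lineA",
                                       frame_times_ms = NULL) {
  set.seed(seed)
  dt <- 1000 / frame_rate_hz
  times <- frame_times_ms %||% seq(-320, 470, by = dt)
  if (!any(times < 0)) stopf("frame times must include a pre-stimulus baseline")
  h <- truth$image_shape[1]; w <- truth$image_shape[2]
  f0 <- if (length(truth$f0) == 1L) matrix(truth$f0, h, w) else truth$f0
  px_mm <- truth$pixel_size_um / 1000
  npts <- length(truth$grid_ml_mm)
  centers <- data.frame(
    grid_point_id = seq_len(npts),
    stim_ml_mm = truth$grid_ml_mm,
    stim_ap_mm = rep(truth$grid_ap_mm, length.out = npts))
  ap_jitter <- rnorm(1, 0, truth$ap_jitter_sd_mm)
  centers$resp_ap_mm <- truth$intercept_mm + ap_jitter +
    truth$slope_mm_per_mm * abs(centers$stim_ml_mm)
  centers$resp_ml_mm <- -abs(truth$resp_ml_mm)  # ipsilateral (left) response
  centers$resp_row <- truth$bregma_pixel[1] - centers$resp_ap_mm / px_mm
  centers$resp_col <- truth$bregma_pixel[2] + centers$resp_ml_mm / px_mm

  point_seq <- rep(seq_len(npts), truth$trials_per_point)
  point_seq <- sample(point_seq)  # randomized interleaving
  ntrial <- length(point_seq)
  nfr <- length(times)
  t_on <- as.numeric(times >= truth$onset_ms &
                     times < truth$onset_ms + truth$duration_ms)
  movie <- array(0, dim = c(ntrial, nfr, h, w))
  spatial <- lapply(seq_len(npts), function(k) {
    outer(exp(-(seq_len(h) - centers$resp_row[k])^2 / (2 * truth$spread_px^2)),
          exp(-(seq_len(w) - centers$resp_col[k])^2 / (2 * truth$spread_px^2)))
  })
  for (tr in seq_len(ntrial)) {
    k <- point_seq[tr]
    resp <- truth$amplitude * spatial[[k]]
    for (fr in seq_len(nfr)) {
      frame <- f0 * (1 + t_on[fr] * resp)
      movie[tr, fr, , ] <- frame
    }
  }
  if (truth$noise_sd > 0)
    movie <- movie + array(rnorm(length(movie), sd = truth$noise_sd),
                           dim = dim(movie))
  stim_log <- data.frame(trial = seq_len(ntrial),
                         grid_point_id = point_seq,
                         stim_ml_mm = centers$stim_ml_mm[point_seq],
                         stim_ap_mm = centers$stim_ap_mm[point_seq])
  list(session = widefield_session(movie, times, stim_log,
                                   truth$pixel_size_um, truth$bregma_pixel,
                                   mouse_id, cre_line),
       truth = c(truth, list(centers = centers)))
}
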