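#' Spatially bin a raw wide-field movie
#'
#' Non-overlapping mean pooling of each frame (e.g. 320 x 256 pixels at
#' 31.25 um binned 2 x 2 to 160 x 128 at 62.5 um) to reduce data volume and
#' increase signal-to-noise. Trailing rows/columns not filling a complete
#' bin are dropped with a warning. The pixel size is multiplied by the bin
#' factor and the bregma pixel rescaled to the binned grid.
#'
#' @param raw 3D array (frame, row, col) of fluorescence.
#' @param bin_factor integer pooling factor (default 2).
#' @param pixel_size_um raw pixel size.
#' @param bregma_pixel raw (row, col) of bregma.
#' @return list with \code{movie} (binned frames), \code{pixel_size_um},
#'   \code{bregma_pixel}.
#' @export
preprocess_movie <- function(raw, bin_factor = 2L, pixel_size_um = 31.25,
                             bregma_pixel = c(120, 128)) {
  if (length(dim(raw)) != 3L) stopf("raw must be (frame, row, col)")
  b <- as.integer(bin_factor)
  d <- dim(raw)
  h <- (d[2] %/% b) * b
  w <- (d[3] %/% b) * b
  if (h < d[2] || w < d[3])
    warning(sprintf("dropping %d trailing row(s) and %d column(s) not filling a bin",
                    d[2] - h, d[3] - w), call. = FALSE)
  x <- raw[, seq_len(h), seq_len(w), drop = FALSE]
  out <- array(0, dim = c(d[1], h %/% b, w %/% b))
  for (i in seq_len(b)) for (j in seq_len(b)) {
    out <- out + x[, seq(i, h, by = b), seq(j, w, by = b), drop = FALSE]
  }
  list(movie = out / b^2,
       pixel_size_um = pixel_size_um * b,
       bregma_pixel = (bregma_pixel + (b - 1) / 2) / b)
}

#' Fractional fluorescence change of a session
#'
#' Per trial, the baseline image F0 is the average fluorescence over the
#' \code{baseline_ms} window before stimulation onset, selected by
#' timestamp (never by frame index, so irregular acquisition patterns are
#' handled); dF/F = (F - F0) / F0 pixel-wise. Pixels with non-positive F0
#' become \code{NA} and are tallied in the \code{n_bad_f0} field.
#'
#' @param session a \code{\link{widefield_session}}.
#' @param baseline_ms baseline window length before onset (default 300).
#' @return the session with \code{movie} replaced by dF/F values,
#'   \code{is_dff = TRUE} and \code{n_bad_f0} set.
#' @export
compute_dff <- function(session, baseline_ms = 300) {
  t <- session$frame_times_ms
  base <- which(t >= -baseline_ms & t < 0)
  if (!length(base)) stopf("no baseline frames in [-%g, 0) ms", baseline_ms)
  d <- dim(session$movie)
  out <- session$movie
  n_bad <- 0L
  for (tr in seq_len(d[1])) {
    trial <- session$movie[tr, , , , drop = FALSE]
    dim(trial) <- d[2:4]
    f0 <- apply(trial[base, , , drop = FALSE], c(2, 3), mean)
    bad <- f0 <= 0
    n_bad <- n_bad + sum(bad)
    f0[bad] <- NA_real_
    dff <- sweep(sweep(trial, c(2, 3), f0, `-`), c(2, 3), f0, `/`)
    out[tr, , , ] <- dff
  }
  session$movie <- out
  session$is_dff <- TRUE
  session$n_bad_f0 <- n_bad
  session
}

#' Trial-averaged evoked response map for one stimulation point
#'
#' Averages dF/F over the evoked time window (frames selected by
#' timestamp), then over the trials belonging to the stimulation grid
#' point.
#'
#' @param session a dF/F \code{\link{widefield_session}} (see
#'   \code{\link{compute_dff}}).
#' @param grid_point stimulation grid point id.
#' @param window_ms evoked window, default c(10, 260) ms post-onset.
#' @return An object of class \code{evoked_map}: list with \code{data}
#'   (H x W), \code{n_trials}, \code{grid_point_id}, \code{stim_ml_mm},
#'   \code{stim_ap_mm}, \code{pixel_size_um}, \code{bregma_pixel}.
#' @export
evoked_map <- function(session, grid_point, window_ms = c(10, 260)) {
  if (!isTRUE(session$is_dff))
    stopf("evoked_map expects a dF/F session; run compute_dff() first")
  t <- session$frame_times_ms
  win <- which(t >= window_ms[1] & t <= window_ms[2])
  if (!length(win)) stopf("no frames inside the evoked window")
  trials <- session$stim_log$trial[session$stim_log$grid_point_id == grid_point]
  if (!length(trials)) stopf("no trials for grid point %s", grid_point)
  d <- dim(session$movie)
  acc <- matrix(0, d[3], d[4])
  for (tr in trials) {
    trial <- session$movie[tr, win, , , drop = FALSE]
    dim(trial) <- c(length(win), d[3], d[4])
    acc <- acc + apply(trial, c(2, 3), mean)
  }
  sl <- session$stim_log[match(trials[1], session$stim_log$trial), ]
  structure(list(data = acc / length(trials), n_trials = length(trials),
                 grid_point_id = grid_point,
                 stim_ml_mm = sl$stim_ml_mm, stim_ap_mm = sl$stim_ap_mm,
                 pixel_size_um = session$pixel_size_um,
                 bregma_pixel = session$bregma_pixel,
                 mouse_id = session$mouse_id),
            class = "evoked_map")
}

#' Trial-weighted population average of evoked maps
#'
#' Mean of per-mouse evoked maps weighted by their trial counts; the output
#' carries the summed trial count.
#'
#' @param maps list of \code{evoked_map}s with identical geometry.
#' @return an \code{evoked_map}.
#' @export
population_average <- function(maps) {
  if (!length(maps)) stopf("need at least one evoked map")
  d <- dim(maps[[1]]$data)
  acc <- matrix(0, d[1], d[2])
  ntot <- 0L
  for (m in maps) {
    if (!all(dim(m$data) == d)) stopf("evoked map geometry mismatch")
    acc <- acc + m$n_trials * m$data
    ntot <- ntot + m$n_trials
  }
  out <- maps[[1]]
  out$data <- acc / ntot
  out$n_trials <- ntot
  out$mouse_id <- "population"
  out
}

#' Default frontal mask for center-of-mass localization
#'
#' A 40 x 25 binned-pixel rectangle (2.5 x 1.56 mm at 62.5 um pixels)
#' placed over frontal cortex relative to bregma.
#'
#' @param bregma_pixel binned (row, col) of bregma.
#' @param nrow,ncol mask extents in binned pixels.
#' @param row_offset,col_offset top-left corner relative to bregma.
#' @return list with \code{rows} and \code{cols} index vectors.
#' @export
frontal_mask <- function(bregma_pixel, nrow = 25L, ncol = 40L,
                         row_offset = -26L, col_offset = -35L) {
  r0 <- round(bregma_pixel[1]) + row_offset
  c0 <- round(bregma_pixel[2]) + col_offset
  list(rows = r0:(r0 + nrow - 1L), cols = c0:(c0 + ncol - 1L))
}

#' Center of mass of the evoked response within a frontal mask
#'
#' Within the mask, pixels at or above \code{frac} of the within-mask
#' maximum are selected and their value-weighted centroid computed,
#' converted to bregma-referenced millimetres. An all-non-positive mask
#' yields a no-response result (\code{NA} coordinates) that downstream
#' regressions drop.
#'
#' @param map an \code{evoked_map}.
#' @param mask a list with \code{rows}, \code{cols}
#'   (see \code{\link{frontal_mask}}); default places the standard mask
#'   from the map's bregma pixel.
#' @param frac threshold as a fraction of the within-mask maximum
#'   (default 0.8).
#' @return list with \code{ap_mm}, \code{ml_mm}, \code{peak},
#'   \code{n_pixels}, \code{threshold}.
#' @export
frontal_center_of_mass <- function(map, mask = NULL, frac = 0.8) {
  mask <- mask %||% frontal_mask(map$bregma_pixel)
  d <- dim(map$data)
  if (min(mask$rows) < 1 || max(mask$rows) > d[1] ||
      min(mask$cols) < 1 || max(mask$cols) > d[2])
    stopf("mask extends outside the frame")
  sub <- map$data[mask$rows, mask$cols]
  m <- max(sub, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    return(list(ap_mm = NA_real_, ml_mm = NA_real_, peak = m,
                n_pixels = 0L, threshold = NA_real_))
  thr <- frac * m
  sel <- which(!is.na(sub) & sub >= thr, arr.ind = TRUE)
  wts <- sub[sel]
  row <- sum(wts * (mask$rows[sel[, 1]])) / sum(wts)
  col <- sum(wts * (mask$cols[sel[, 2]])) / sum(wts)
  px_mm <- map$pixel_size_um / 1000
  list(ap_mm = (map$bregma_pixel[1] - row) * px_mm,
       ml_mm = (col - map$bregma_pixel[2]) * px_mm,
       peak = m, n_pixels = nrow(sel), threshold = thr)
}

#' Regression of evoked-response location on stimulation site
#'
#' Pools (|stim ML|, response-center AP) points across mice and fits the
#' population ordinary-least-squares line with Pearson correlation and
#' two-sided p-value; per-mouse lines are fit for every mouse contributing
#' at least two distinct stimulation positions.
#'
#' @param points data.frame with columns \code{abs_ml_mm},
#'   \code{ap_mm} and \code{mouse_id}; rows with \code{NA} (no-response)
#'   are dropped first.
#' @return list with \code{fit} (a \code{\link{fit_topography}} result on
#'   the pooled points) and \code{per_mouse} (data.frame of per-mouse
#'   slopes and intercepts).
#' @export
fit_functional_topography <- function(points) {
  pts <- points[is.finite(points$abs_ml_mm) & is.finite(points$ap_mm), ]
  pooled <- fit_topography(pts[, c("abs_ml_mm", "ap_mm")])
  per_mouse <- do.call(rbind, lapply(split(pts, pts$mouse_id), function(g) {
    if (nrow(g) < 2 || stats::sd(g$abs_ml_mm) == 0) return(NULL)
    co <- coef(lm(ap_mm ~ abs_ml_mm, data = g))
    data.frame(mouse_id = g$mouse_id[1], intercept = co[1], slope = co[2],
               n = nrow(g))
  }))
  if (!is.null(per_mouse)) rownames(per_mouse) <- NULL
  list(fit = pooled, per_mouse = per_mouse)
}
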