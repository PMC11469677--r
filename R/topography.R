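#' Horizontal sum map of motor-cortex axons
#'
#' Selects axons within the requested layers of the requested motor regions
#' (both hemispheres) and sum-projects the masked density along the DV axis
#' into a horizontal (AP x ML) view. The 2D total equals the masked 3D
#' total exactly.
#'
#' @param map a \code{\link{density_map}}.
#' @param annotation an \code{\link{annotation_volume}}.
#' @param graph a \code{\link{structure_graph}}.
#' @param regions region acronyms (default MOp, MOs).
#' @param layers layer suffixes (default \code{c("2/3", "5")}); resolved as
#'   \code{paste0(region, layer)} acronyms in the graph.
#' @return 2D matrix (AP x ML) of summed density.
#' @export
mo_axon_map <- function(map, annotation, graph,
                        regions = c("MOp", "MOs"), layers = c("2/3", "5")) {
  x <- if (inherits(map, "density_map")) map$data else map
  assert_array3(x, "map")
  if (!all(dim(x) == dim(annotation$id_grid)))
    stopf("map and annotation geometry differ")
  acr <- as.vector(outer(regions, layers, paste0))
  ids <- graph_id(graph, acr)  # errors on unresolvable acronyms
  masked <- x * (annotation$id_grid %in% ids)
  dim(masked) <- dim(x)
  d <- dim(x)
  out <- matrix(0, d[1], d[3])
  for (k in seq_len(d[2])) out <- out + masked[, k, ]
  out
}

#' Hotspot contour metrics of a horizontal axon map
#'
#' The map is Gaussian-filtered (sigma in pixels), thresholded at fractions
#' of its maximum (default 75\% and 95\%), and summarized: the area inside
#' the 75\% contour measures the horizontal spread of the innervation, the
#' unweighted centroid of the 95\% set localizes the densest innervation,
#' and the mean filtered density within a square ROI (default
#' 225 x 225 um = 9 x 9 pixels, clipped at borders) centered on the peak
#' pixel measures the peak innervation density per mm^2. Ties at the
#' maximum are resolved by first position in column-major scan order. An
#' all-zero map yields a no-hotspot result with \code{NA} metrics.
#'
#' @param map2d 2D (AP x ML) matrix, e.g. from \code{\link{mo_axon_map}}.
#' @param frame a \code{\link{coordinate_frame}} for converting the
#'   centroid to bregma mm (its voxel size is the pixel size).
#' @param sigma_px Gaussian filter sigma in pixels (default 4).
#' @param levels contour levels as fractions of max (default 0.75, 0.95).
#' @param roi_um ROI edge length in micrometres (default 225).
#' @return list with \code{filtered}, \code{contour75}/\code{contour95}
#'   (pixel index matrices), \code{area75_mm2}, \code{centroid95_ap_mm},
#'   \code{centroid95_ml_mm}, \code{peak_pixel}, \code{peak_roi_density}
#'   (axon voxels per mm^2 per cell), \code{has_hotspot}.
#' @export
hotspot_metrics <- function(map2d, frame, sigma_px = 4,
                            levels = c(0.75, 0.95), roi_um = 225) {
  if (!is.matrix(map2d)) stopf("map2d must be a matrix")
  px_um <- frame$voxel_size_um
  f <- gaussian_filter(map2d, sigma_px)
  m <- max(f)
  if (m <= 0) {
    return(list(filtered = f, contour75 = NULL, contour95 = NULL,
                area75_mm2 = NA_real_, centroid95_ap_mm = NA_real_,
                centroid95_ml_mm = NA_real_, peak_pixel = c(NA, NA),
                peak_roi_density = NA_real_, has_hotspot = FALSE))
  }
  set75 <- which(f >= levels[1] * m, arr.ind = TRUE)
  set95 <- which(f >= levels[2] * m, arr.ind = TRUE)
  cen <- colMeans(set95)  # unweighted centroid of all supra-level pixels
  cen_mm <- voxel_to_bregma_mm(c(cen[1], 1, cen[2]), frame)
  peak <- which.max(f)  # first in column-major scan order on ties
  pk <- arrayInd(peak, dim(f))[1, ]
  r <- floor((roi_um / px_um) / 2)  # 225/25 = 9 px ROI -> half-width 4
  rows <- max(1, pk[1] - r):min(nrow(f), pk[1] + r)
  cols <- max(1, pk[2] - r):min(ncol(f), pk[2] + r)
  px_area_mm2 <- (px_um / 1000)^2
  list(filtered = f,
       contour75 = set75, contour95 = set95,
       area75_mm2 = nrow(set75) * px_area_mm2,
       centroid95_ap_mm = unname(cen_mm[1, "ap_mm"]),
       centroid95_ml_mm = unname(cen_mm[1, "ml_mm"]),
       peak_pixel = unname(pk),
       peak_roi_density = mean(f[rows, cols]) / px_area_mm2,
       has_hotspot = TRUE)
}

#' Injection-location versus hotspot-location regression
#'
#' Ordinary least squares of the anteroposterior hotspot position on the
#' absolute mediolateral injection position, with Pearson correlation and
#' its two-sided p-value (n - 2 degrees of freedom). The slope is the
#' scaling of the mirror map in mm AP per mm |ML|.
#'
#' @param points data.frame (or matrix) whose first column is |ML| (mm) of
#'   the injection center and second column the AP (mm) of the hotspot
#'   centroid; non-finite rows (no-hotspot samples) are dropped.
#' @return list of class \code{topography_fit} with \code{r}, \code{p},
#'   \code{slope}, \code{intercept}, \code{n}, \code{ci95_slope}.
#' @export
fit_topography <- function(points) {
  pts <- as.data.frame(points)[, 1:2]
  names(pts) <- c("abs_ml_mm", "ap_mm")
  pts <- pts[is.finite(pts$abs_ml_mm) & is.finite(pts$ap_mm), ]
  if (nrow(pts) < 3) stopf("regression needs at least 3 finite points")
  if (stats::sd(pts$abs_ml_mm) == 0)
    stopf("zero variance in |ML| positions")
  fit <- lm(ap_mm ~ abs_ml_mm, data = pts)
  ct <- suppressWarnings(cor.test(pts$abs_ml_mm, pts$ap_mm,
                                  method = "pearson"))
  ci <- tryCatch(suppressWarnings(confint(fit, "abs_ml_mm", level = 0.95)),
                 error = function(e) matrix(NA_real_, 1, 2))
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = nrow(pts),
                 ci95_slope = as.numeric(ci)),
            class = "topography_fit")
}

#' @export
print.topography_fit <- function(x, ...) {
  cat(sprintf("topography_fit: slope %.3f mm/mm, intercept %.3f mm, r %.3f, p %.3g, n %d\n",
              x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}

#' Axis profiles of caudoputamen innervation
#'
#' Masks the density map to the caudoputamen, Gaussian-filters it, and
#' extracts 1D summed-density curves along the three anatomical axes in
#' bregma mm. The AP and DV curves use the hemisphere ipsilateral to the
#' injection only; the ML curve is bilateral. With \code{sigma = 0} the
#' curve integrals equal the masked totals per scope exactly.
#'
#' @param map a \code{\link{density_map}}.
#' @param annotation an \code{\link{annotation_volume}}.
#' @param graph a \code{\link{structure_graph}}.
#' @param frame a \code{\link{coordinate_frame}}.
#' @param injection_side \code{"left"} or \code{"right"}.
#' @param sigma_voxels Gaussian sigma (default 4).
#' @param region acronym of the masked structure (default \code{"CP"}).
#' @return list of three data.frames (\code{ap}, \code{dv}, \code{ml}) with
#'   columns \code{mm} and \code{density}, plus \code{scope} attributes.
#' @export
striatum_profiles <- function(map, annotation, graph, frame,
                              injection_side = c("left", "right"),
                              sigma_voxels = 4, region = "CP") {
  injection_side <- match.arg(injection_side)
  x <- if (inherits(map, "density_map")) map$data else map
  ids <- graph_descendants(graph, graph_id(graph, region))
  masked <- x * (annotation$id_grid %in% ids)
  dim(masked) <- dim(x)
  f <- gaussian_filter(masked, sigma_voxels)
  d <- dim(f)
  ml_idx <- seq_len(d[3])
  dml <- ml_idx - frame$midline_ml
  ipsi <- if (injection_side == "left") dml <= -0.5 else dml >= 0.5
  fi <- f[, , ipsi, drop = FALSE]
  s <- frame$voxel_size_um / 1000
  ap_curve <- apply(fi, 1, sum)
  dv_curve <- apply(fi, 2, sum)
  ml_curve <- apply(f, 3, sum)
  list(ap = data.frame(mm = (frame$bregma_voxel[1] - seq_len(d[1])) * s,
                       density = ap_curve),
       dv = data.frame(mm = (frame$bregma_voxel[2] - seq_len(d[2])) * s,
                       density = dv_curve),
       ml = data.frame(mm = (ml_idx - frame$midline_ml) * s,
                       density = ml_curve),
       scope = list(ap = "ipsi", dv = "ipsi", ml = "bilateral"))
}
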