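#' Ground-truth description of a tubular axon phantom
#'
#' Centerlines are polylines in native voxel coordinates; each carries a
#' tube radius (Gaussian profile standard deviation, in voxels) and a peak
#' brightness. Artifact blobs are bright spheres, typically placed near the
#' volume edges to emulate imaging artifacts at the brain border.
#'
#' @param centerlines list of n x 3 matrices of (x, y, z) voxel coordinates.
#' @param radius per-polyline tube radius in voxels (recycled, >= 0.5).
#' @param brightness per-polyline peak value (recycled).
#' @param blobs optional data.frame with columns \code{x}, \code{y},
#'   \code{z}, \code{radius}, \code{intensity}.
#' @return list of class \code{axon_truth}.
#' @export
axon_truth <- function(centerlines = list(), radius = 1, brightness = 1,
                       blobs = NULL) {
  if (any(radius < 0.5)) stopf("tube radius must be >= 0.5 voxel")
  structure(list(centerlines = centerlines,
                 radius = rep(radius, length.out = length(centerlines)),
                 brightness = rep(brightness, length.out = length(centerlines)),
                 blobs = blobs),
            class = "axon_truth")
}

# squared distance from points (m x 3) to segment a-b
dist2_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d <- sweep(p, 2, a)
    return(rowSums(d^2))
  }
  t <- pmin(pmax(as.vector(sweep(p, 2, a) %*% ab) / len2, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  rowSums((p - proj)^2)
}

#' Simulate a probability volume around known centerlines
#'
#' Emulates the output of a voxel-wise axon segmentation network: the sum of
#' Gaussian-profile tubes around the true centerlines, plus bright artifact
#' blobs, plus additive Gaussian noise, clipped to [0, 1]. Deterministic for
#' a fixed seed.
#'
#' @param truth an \code{\link{axon_truth}}.
#' @param shape volume dimensions (x, y, z).
#' @param noise_sd additive Gaussian noise standard deviation (default 0).
#' @param seed integer seed.
#' @param voxel_size_um native voxel size recorded in metadata.
#' @return numeric 3D array of probabilities in [0, 1] with attribute
#'   \code{voxel_size_um}.
#' @export
simulate_axon_probability <- function(truth, shape, noise_sd = 0, seed = 1,
                                      voxel_size_um = c(5.3, 5.3, 5)) {
  shape <- as.integer(shape)
  vol <- array(0, dim = shape)
  for (i in seq_along(truth$centerlines)) {
    cl <- truth$centerlines[[i]]
    if (any(cl < 1) || any(sweep(cl, 2, shape) > 0))
      stopf("centerline %d extends outside the volume", i)
    r <- truth$radius[i]
    pad <- ceiling(3 * r)
    for (s in seq_len(max(nrow(cl) - 1L, 1L))) {
      a <- cl[s, ]
      b <- cl[min(s + 1L, nrow(cl)), ]
      lo <- pmax(floor(pmin(a, b)) - pad, 1)
      hi <- pmin(ceiling(pmax(a, b)) + pad, shape)
      gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
      pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      d2 <- dist2_to_segment(pts, a, b)
      val <- truth$brightness[i] * exp(-d2 / (2 * r^2))
      box <- array(val, dim = c(length(gx), length(gy), length(gz)))
      cur <- vol[gx, gy, gz]
      vol[gx, gy, gz] <- pmax(cur, box)  # max over segments avoids double
                                         # counting at shared polyline joints
    }
  }
  if (!is.null(truth$blobs)) {
    for (i in seq_len(nrow(truth$blobs))) {
      b <- truth$blobs[i, ]
      lo <- pmax(floor(c(b$x, b$y, b$z) - b$radius), 1)
      hi <- pmin(ceiling(c(b$x, b$y, b$z) + b$radius), shape)
      gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
      pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      d2 <- rowSums(sweep(pts, 2, c(b$x, b$y, b$z))^2)
      box <- array(b$intensity * (d2 <= b$radius^2),
                   dim = c(length(gx), length(gy), length(gz)))
      vol[gx, gy, gz] <- pmax(vol[gx, gy, gz], box)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vol <- vol + array(rnorm(length(vol), sd = noise_sd), dim = shape)
  }
  vol <- pmin(pmax(vol, 0), 1)
  attr(vol, "voxel_size_um") <- voxel_size_um
  vol
}

#' Straight-tube phantom helper
#'
#' Builds an \code{\link{axon_truth}} with a single straight centerline
#' along the x axis at a given (y, z) position.
#'
#' @param shape volume dimensions.
#' @param y,z in-plane position of the tube.
#' @param radius tube radius in voxels.
#' @param brightness peak value.
#' @return an \code{\link{axon_truth}}.
#' @export
straight_tube_truth <- function(shape, y = NULL, z = NULL, radius = 1.5,
                                brightness = 1) {
  y <- y %||% ((shape[2] + 1) / 2)
  z <- z %||% ((shape[3] + 1) / 2)
  cl <- cbind(x = seq_len(shape[1]), y = y, z = z)
  axon_truth(centerlines = list(cl), radius = radius, brightness = brightness)
}
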