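#' Coordinate transforms from native to atlas space
#'
#' A transform chain is an ordered list of transforms applied to physical
#' (micrometre) coordinates, in the native-to-atlas direction. Each element
#' is either a 4 x 4 affine matrix acting on homogeneous micrometre
#' coordinates (\code{affine_transform}) or a dense displacement field
#' (\code{displacement_field}) adding a trilinearly interpolated offset.
#' Registration fitting is out of scope: chains are consumed, not estimated.
#'
#' @param matrix 4 x 4 affine matrix on micrometre coordinates.
#' @return transform objects usable in \code{\link{transform_chain}}.
#' @export
affine_transform <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4))) stopf("affine matrix must be 4 x 4")
  if (abs(det(matrix)) < 1e-12) stopf("affine matrix must be invertible")
  structure(list(matrix = matrix), class = c("affine_transform", "transform"))
}

#' @param offset 4D array (grid dims x 3) of micrometre offsets sampled on a
#'   regular grid.
#' @param spacing_um grid spacing in micrometres (length 3).
#' @param origin_um micrometre coordinates of the first grid sample.
#' @rdname affine_transform
#' @export
displacement_field <- function(offset, spacing_um, origin_um = c(0, 0, 0)) {
  if (length(dim(offset)) != 4L || dim(offset)[4] != 3L)
    stopf("offset must be a (d1, d2, d3, 3) array")
  structure(list(offset = offset, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um)),
            class = c("displacement_field", "transform"))
}

#' @param ... transforms, applied in order.
#' @rdname affine_transform
#' @export
transform_chain <- function(...) {
  tf <- list(...)
  if (length(tf) == 1L && is.list(tf[[1]]) && !inherits(tf[[1]], "transform"))
    tf <- tf[[1]]
  ok <- vapply(tf, inherits, logical(1), what = "transform")
  if (!all(ok)) stopf("all chain elements must be transforms")
  structure(list(transforms = tf), class = "transform_chain")
}

#' Identity chain mapping native voxels straight onto the atlas grid
#'
#' Convenience for phantoms generated directly in atlas space: scales native
#' voxel indices by the native voxel size only, so with equal native and
#' atlas voxel sizes coordinates map onto themselves.
#'
#' @return a \code{\link{transform_chain}} with a single identity affine.
#' @export
identity_chain <- function() transform_chain(affine_transform(diag(4)))

apply_transform <- function(tf, pts_um) UseMethod("apply_transform")

#' @export
apply_transform.affine_transform <- function(tf, pts_um) {
  out <- cbind(pts_um, 1) %*% t(tf$matrix)
  list(pts = out[, 1:3, drop = FALSE], clamped = 0L)
}

#' @export
apply_transform.displacement_field <- function(tf, pts_um) {
  g <- (sweep(pts_um, 2, tf$origin_um)) %*% diag(1 / tf$spacing_um)
  d <- dim(tf$offset)[1:3]
  clamped <- sum(apply(g < 0 | g > rep(d - 1L, each = nrow(g)), 1, any))
  # clamp to grid support; out-of-support points take nearest-edge offsets
  for (k in 1:3) g[, k] <- pmin(pmax(g[, k], 0), d[k] - 1L)
  lo <- floor(g)
  frac <- g - lo
  off <- matrix(0, nrow(g), 3)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- pmin(lo[, 1] + cx, d[1] - 1L)
    iy <- pmin(lo[, 2] + cy, d[2] - 1L)
    iz <- pmin(lo[, 3] + cz, d[3] - 1L)
    wt <- (ifelse(cx == 1, frac[, 1], 1 - frac[, 1]) *
           ifelse(cy == 1, frac[, 2], 1 - frac[, 2]) *
           ifelse(cz == 1, frac[, 3], 1 - frac[, 3]))
    base <- 1 + ix + d[1] * (iy + d[2] * iz)
    n3 <- prod(d)
    off[, 1] <- off[, 1] + wt * tf$offset[base]
    off[, 2] <- off[, 2] + wt * tf$offset[base + n3]
    off[, 3] <- off[, 3] + wt * tf$offset[base + 2 * n3]
  }
  list(pts = pts_um + off, clamped = as.integer(clamped))
}

#' Map native voxel coordinates into atlas voxel space
#'
#' Each 1-based native voxel index is converted to physical micrometres
#' (index 1 sits at 0 um), passed through the chain, and divided by the
#' atlas voxel size to give real-valued 1-based atlas voxel indices.
#' Coordinates falling outside a displacement field's support are mapped
#' with the nearest-edge displacement and counted in the
#' \code{"n_edge_clamped"} attribute.
#'
#' @param coords data.frame or matrix with native (x, y, z) voxel indices.
#' @param chain a \code{\link{transform_chain}}.
#' @param native_voxel_size_um length-3 native voxel size.
#' @param atlas_voxel_size_um atlas voxel size (default 25).
#' @return n x 3 numeric matrix of real atlas voxel indices with attribute
#'   \code{n_edge_clamped}.
#' @export
transform_coords <- function(coords, chain, native_voxel_size_um,
                             atlas_voxel_size_um = 25) {
  m <- as.matrix(coords[, 1:3, drop = FALSE])
  pts <- sweep(m - 1, 2, rep(native_voxel_size_um, length.out = 3), `*`)
  clamped <- 0L
  for (tf in chain$transforms) {
    res <- apply_transform(tf, pts)
    pts <- res$pts
    clamped <- clamped + res$clamped
  }
  out <- pts / atlas_voxel_size_um + 1
  colnames(out) <- c("ap", "dv", "ml")
  attr(out, "n_edge_clamped") <- clamped
  out
}

#' Invert a pure-affine chain
#'
#' @param chain a \code{\link{transform_chain}} containing only affine
#'   transforms.
#' @return the inverse \code{\link{transform_chain}}.
#' @export
invert_chain <- function(chain) {
  if (!all(vapply(chain$transforms, inherits, logical(1), "affine_transform")))
    stopf("only pure-affine chains can be inverted")
  inv <- lapply(rev(chain$transforms),
                function(tf) affine_transform(solve(tf$matrix)))
  transform_chain(inv)
}
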