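#' Skeletonize a binary 3D mask
#'
#' Medial-axis thinning on the voxel lattice with 26-connectivity for the
#' object and 6-connectivity for the background. Simple border voxels are
#' removed in six directional subiterations per pass with sequential
#' re-checking, so the result is deterministic and preserves topology;
#' endpoints (voxels with a single neighbor) are kept. Voxel anisotropy is
#' ignored during thinning and only carried in metadata.
#'
#' @param mask logical 3D array.
#' @return logical 3D array of the same shape containing the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  assert_array3(mask, "mask")
  storage.mode(mask) <- "logical"
  .skeletonize3d_cpp(mask)
}

#' Label 26-connected components of a binary 3D mask
#'
#' @param mask logical 3D array.
#' @return integer 3D array of component labels (0 = background), labeled in
#'   scan order.
#' @export
label_components <- function(mask) {
  assert_array3(mask, "mask")
  storage.mode(mask) <- "logical"
  .label_components26_cpp(mask)
}

#' Axon skeleton container
#'
#' Sparse voxel set with a per-voxel confidence weight (the sum of the
#' binarization thresholds at which the voxel appeared in a skeleton) and a
#' 26-connectivity component label. Downstream counting treats every
#' skeleton voxel as one axon-containing voxel regardless of weight; the
#' weight exists to rescue dim axons during construction and is retained as
#' metadata only.
#'
#' @param voxels integer n x 3 matrix of 1-based (x, y, z) native voxel
#'   indices.
#' @param weight numeric vector of per-voxel weights.
#' @param component integer vector of component labels.
#' @param dim dimensions of the source volume.
#' @param voxel_size_um length-3 native voxel size in micrometres.
#' @param provenance list of free-form processing metadata.
#' @return An object of class \code{axon_skeleton}.
#' @export
axon_skeleton <- function(voxels, weight, component, dim,
                          voxel_size_um = c(5.3, 5.3, 5), provenance = list()) {
  voxels <- matrix(as.integer(voxels), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  n <- nrow(voxels)
  if (length(weight) != n || length(component) != n)
    stopf("voxels, weight and component must have matching length")
  component <- as.integer(component)
  sizes <- if (n) table(component) else table(integer(0))
  structure(list(voxels = voxels, weight = as.numeric(weight),
                 component = component,
                 component_sizes = stats::setNames(as.integer(sizes),
                                                   names(sizes)),
                 dim = as.integer(dim),
                 voxel_size_um = voxel_size_um,
                 provenance = provenance),
            class = "axon_skeleton")
}

#' @export
print.axon_skeleton <- function(x, ...) {
  cat(sprintf("axon_skeleton: %d voxels, %d component(s), volume %s\n",
              nrow(x$voxels), length(x$component_sizes),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Multi-threshold weighted skeleton of a probability volume
#'
#' The probability volume is binarized at each threshold, each binary mask is
#' skeletonized independently, each skeleton is scaled by its threshold
#' value, and the scaled skeletons are summed. A voxel present in all eight
#' default skeletons therefore carries weight 0.2 + 0.3 + ... + 0.9 = 4.4.
#' Because the thresholds are increasing, the binary masks are nested; this
#' is asserted before thinning. Connected components are labeled on the
#' union support with 26-connectivity.
#'
#' @param prob numeric 3D array of axon probabilities in [0, 1].
#' @param thresholds strictly increasing thresholds in (0, 1)
#'   (default \code{seq(0.2, 0.9, by = 0.1)}).
#' @param voxel_size_um native voxel size in micrometres.
#' @return An \code{\link{axon_skeleton}}.
#' @export
weighted_skeleton <- function(prob, thresholds = seq(0.2, 0.9, by = 0.1),
                              voxel_size_um = c(5.3, 5.3, 5)) {
  assert_array3(prob, "prob")
  if (any(prob < 0 | prob > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie strictly inside (0, 1)")
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly increasing")
  w <- array(0, dim = dim(prob))
  prev_mask <- NULL
  for (t in thresholds) {
    mask <- prob >= t
    if (!is.null(prev_mask) && any(mask & !prev_mask))
      stopf("threshold masks are not nested")  # cannot happen for sorted t
    prev_mask <- mask
    if (!any(mask)) next
    w <- w + t * skeletonize_mask(mask)
  }
  support <- w > 0
  comp <- label_components(support)
  idx <- which(support)
  voxels <- arrayInd(idx, dim(prob))
  axon_skeleton(voxels, weight = w[idx], component = comp[idx],
                dim = dim(prob), voxel_size_um = voxel_size_um,
                provenance = list(thresholds = thresholds))
}

#' Remove small skeleton components
#'
#' Drops connected components with strictly fewer than \code{min_size}
#' voxels (artifacts), relabels the survivors by descending size (ties
#' broken by previous label), and reports the size and fate of every
#' component. The operation is idempotent.
#'
#' @param skel an \code{\link{axon_skeleton}}.
#' @param min_size minimum voxel count to keep a component (default 10000).
#' @return list with elements \code{skeleton} (filtered
#'   \code{axon_skeleton}) and \code{report} (data.frame with columns
#'   \code{component}, \code{size}, \code{kept}).
#' @export
filter_components <- function(skel, min_size = 10000) {
  sizes <- skel$component_sizes
  labels <- as.integer(names(sizes))
  kept <- sizes >= min_size
  report <- data.frame(component = labels, size = as.integer(sizes),
                       kept = as.vector(kept))
  report <- report[order(-report$size, report$component), ]
  rownames(report) <- NULL
  keep_labels <- report$component[report$kept]
  sel <- skel$component %in% keep_labels
  # relabel by descending size
  new_label <- match(skel$component[sel], keep_labels)
  out <- axon_skeleton(skel$voxels[sel, , drop = FALSE],
                       weight = skel$weight[sel],
                       component = new_label,
                       dim = skel$dim, voxel_size_um = skel$voxel_size_um,
                       provenance = c(skel$provenance,
                                      list(min_component_size = min_size)))
  list(skeleton = out, report = report)
}

#' Apply curation decisions to a skeleton
#'
#' Components are inspected (e.g. to preserve large axon chunks that became
#' disconnected and to eliminate artifacts) and kept or dropped by label.
#' Decisions and reasons are persisted in the output provenance.
#'
#' @param skel an \code{\link{axon_skeleton}}.
#' @param decisions data.frame with columns \code{component},
#'   \code{keep} (logical) and optionally \code{reason}.
#' @return curated \code{\link{axon_skeleton}}.
#' @export
apply_curation <- function(skel, decisions) {
  if (!all(c("component", "keep") %in% names(decisions)))
    stopf("decisions need columns 'component' and 'keep'")
  labels <- as.integer(names(skel$component_sizes))
  unknown <- setdiff(as.integer(decisions$component), labels)
  if (length(unknown))
    stopf("curation decision references unknown component: %s",
          paste(unknown, collapse = ", "))
  drop <- as.integer(decisions$component[!decisions$keep])
  sel <- !(skel$component %in% drop)
  axon_skeleton(skel$voxels[sel, , drop = FALSE],
                weight = skel$weight[sel],
                component = skel$component[sel],
                dim = skel$dim, voxel_size_um = skel$voxel_size_um,
                provenance = c(skel$provenance, list(curation = decisions)))
}

#' Export a skeleton as an ordered coordinate list
#'
#' One row per skeleton voxel, in deterministic lexicographic (x, y, z)
#' order, with the weight carried as an extra column.
#'
#' @param skel an \code{\link{axon_skeleton}}.
#' @return data.frame with columns \code{x}, \code{y}, \code{z},
#'   \code{weight}.
#' @export
skeleton_to_coords <- function(skel) {
  v <- skel$voxels
  ord <- order(v[, 1], v[, 2], v[, 3])
  out <- data.frame(x = v[ord, 1], y = v[ord, 2], z = v[ord, 3],
                    weight = skel$weight[ord])
  attr(out, "dim_native") <- skel$dim
  attr(out, "voxel_size_um") <- skel$voxel_size_um
  out
}
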