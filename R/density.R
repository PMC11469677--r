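#' Bin atlas-space coordinates onto the annotation grid
#'
#' Each real-valued atlas coordinate is rounded half-up per axis to an
#' integer voxel; in-bounds coordinates increment that voxel by one and
#' out-of-bounds coordinates are tallied, so that
#' grid total + out_of_bounds_count always equals the number of input
#' coordinates exactly. Every native axon voxel therefore contributes one
#' count to exactly one atlas voxel (no trilinear splatting), preserving
#' the number of axon-containing voxels through down-sampling.
#'
#' @param atlas_coords n x 3 matrix of real (AP, DV, ML) atlas voxel indices.
#' @param annotation an \code{\link{annotation_volume}} supplying the grid
#'   geometry.
#' @return An object of class \code{counts_volume}: list with \code{counts}
#'   (integer 3D array), \code{out_of_bounds_count} and
#'   \code{voxel_size_um}.
#' @export
bin_to_atlas <- function(atlas_coords, annotation) {
  d <- dim(annotation$id_grid)
  m <- round_half_up(as.matrix(atlas_coords[, 1:3, drop = FALSE]))
  inb <- m[, 1] >= 1 & m[, 1] <= d[1] &
         m[, 2] >= 1 & m[, 2] <= d[2] &
         m[, 3] >= 1 & m[, 3] <= d[3]
  counts <- array(0L, dim = d)
  if (any(inb)) {
    lin <- m[inb, 1] + d[1] * (m[inb, 2] - 1) + d[1] * d[2] * (m[inb, 3] - 1)
    tab <- tabulate(lin, nbins = prod(d))
    counts <- array(as.integer(tab), dim = d)
  }
  structure(list(counts = counts,
                 out_of_bounds_count = as.integer(sum(!inb)),
                 voxel_size_um = annotation$voxel_size_um),
            class = "counts_volume")
}

#' Normalize an axon-count volume per labeled neuron
#'
#' Divides every voxel by the number of fluorescently labeled cells at the
#' injection site, giving axon-containing native voxels per cell per atlas
#' voxel -- the unit all downstream analyses use.
#'
#' @param counts a \code{counts_volume} from \code{\link{bin_to_atlas}}, or
#'   a bare numeric 3D array.
#' @param n_cells positive integer count of labeled cells.
#' @param metadata named list (e.g. \code{cre_line},
#'   \code{injection_region}, \code{injection_center},
#'   \code{injection_side}).
#' @return An object of class \code{density_map}: list with \code{data}
#'   (numeric 3D array), \code{n_cells}, \code{voxel_size_um},
#'   \code{metadata}.
#' @export
normalize_per_cell <- function(counts, n_cells, metadata = list()) {
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells <= 0)
    stopf("n_cells must be a positive integer")
  if (inherits(counts, "counts_volume")) {
    grid <- counts$counts
    voxel <- counts$voxel_size_um
    metadata$out_of_bounds_count <- counts$out_of_bounds_count
  } else {
    grid <- counts
    voxel <- metadata$voxel_size_um %||% 25
  }
  assert_array3(grid, "counts")
  density_map(grid / n_cells, n_cells = as.integer(n_cells),
              voxel_size_um = voxel, metadata = metadata)
}

#' Density map container
#'
#' @param data numeric 3D array of axon voxels per cell per atlas voxel.
#' @param n_cells labeled-cell count used for normalization.
#' @param voxel_size_um atlas voxel size in micrometres.
#' @param metadata named list of sample metadata.
#' @return An object of class \code{density_map}.
#' @export
density_map <- function(data, n_cells = 1L, voxel_size_um = 25,
                        metadata = list()) {
  assert_array3(data, "data")
  structure(list(data = data, n_cells = n_cells,
                 voxel_size_um = voxel_size_um, metadata = metadata),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %s voxels at %g um, total %.4g, n_cells %s\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size_um,
              sum(x$data), paste(x$n_cells, collapse = "+")))
  invisible(x)
}

#' Injection-site quality control
#'
#' Computes the unweighted centroid of an injection-site mask, the fraction
#' of mask voxels whose annotation id is one of the target structures or any
#' of their descendants (e.g. cortical layers), the mask volume, and whether
#' the sample passes the inclusion rule: at least \code{min_fraction} of
#' injection-site voxels inside the target regions.
#'
#' @param mask logical 3D array on the annotation geometry.
#' @param annotation an \code{\link{annotation_volume}}.
#' @param graph a \code{\link{structure_graph}}.
#' @param target_acronyms acronyms of allowed injection regions
#'   (default SSp-bfd and SSs).
#' @param min_fraction inclusion threshold (default 0.8).
#' @return list with \code{center} (real (AP, DV, ML) voxel triple),
#'   \code{fraction_in_targets}, \code{included}, \code{volume_mm3},
#'   \code{n_voxels}.
#' @export
injection_qc <- function(mask, annotation, graph,
                         target_acronyms = c("SSp-bfd", "SSs"),
                         min_fraction = 0.8) {
  assert_array3(mask, "mask")
  if (!all(dim(mask) == dim(annotation$id_grid)))
    stopf("mask and annotation geometry differ")
  idx <- which(mask)
  if (!length(idx)) stopf("injection mask is empty")
  target_ids <- graph_descendants(graph, graph_id(graph, target_acronyms))
  ids <- annotation$id_grid[idx]
  fraction <- mean(ids %in% target_ids)
  pos <- arrayInd(idx, dim(mask))
  vox_mm <- annotation$voxel_size_um / 1000
  list(center = colMeans(pos),
       fraction_in_targets = fraction,
       included = fraction >= min_fraction,
       volume_mm3 = length(idx) * vox_mm^3,
       n_voxels = length(idx))
}

#' Voxel-wise group average of density maps
#'
#' @param maps list of \code{\link{density_map}} objects with identical
#'   geometry.
#' @return a \code{\link{density_map}} whose \code{n_cells} field lists the
#'   contributors' cell counts and whose metadata records the group size.
#' @export
group_average <- function(maps) {
  if (!length(maps)) stopf("need at least one map")
  d <- dim(maps[[1]]$data)
  acc <- array(0, dim = d)
  for (m in maps) {
    if (!all(dim(m$data) == d)) stopf("density map geometry mismatch")
    acc <- acc + m$data
  }
  density_map(acc / length(maps),
              n_cells = vapply(maps, function(m) m$n_cells[1], integer(1)),
              voxel_size_um = maps[[1]]$voxel_size_um,
              metadata = list(n_samples = length(maps)))
}

#' Sum projection of a volume along one anatomical axis
#'
#' @param map a \code{\link{density_map}} or numeric 3D array.
#' @param axis \code{"AP"}, \code{"DV"} or \code{"ML"}.
#' @param slab optional integer range of voxel indices along \code{axis} to
#'   restrict the projection (e.g. 5 planes for a 125 um slab at 25 um).
#' @return 2D matrix; its total equals the (slab-restricted) 3D total.
#' @export
sum_projection <- function(map, axis = c("AP", "DV", "ML"), slab = NULL) {
  axis <- match.arg(axis)
  x <- if (inherits(map, "density_map")) map$data else map
  assert_array3(x, "map")
  ax <- match(axis, c("AP", "DV", "ML"))
  if (!is.null(slab)) {
    if (!length(slab) || min(slab) < 1 || max(slab) > dim(x)[ax])
      stopf("slab out of bounds or empty")
    ind <- list(TRUE, TRUE, TRUE)
    ind[[ax]] <- slab
    x <- do.call(`[`, c(list(x), ind, list(drop = FALSE)))
  }
  apply(x, setdiff(1:3, ax), sum)
}
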