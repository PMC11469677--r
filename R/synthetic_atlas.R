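#' Specification of the symmetric toy atlas
#'
#' Describes a compact, mirror-symmetric parcellation used by the synthetic
#' generators: motor areas MOp and MOs and somatosensory areas SSp-bfd and
#' SSs as cortical cuboids carrying layer subregions (L1, L2/3, L5, L6
#' stacked along DV), plus the caudoputamen (CP) as a subcortical cuboid.
#' All placements are given for the left hemisphere in 1-based voxel index
#' ranges on the canonical (AP, DV, ML) grid and mirrored across the
#' midline. The grid spans roughly bregma +2.5 mm to -1.5 mm in AP at the
#' 25 um atlas resolution; sizes are deliberately modest so that full
#' cohorts can be simulated quickly.
#'
#' @param dim grid shape (AP, DV, ML).
#' @param voxel_size_um voxel size (default 25).
#' @param bregma_voxel bregma position in voxel indices.
#' @param layer_dv named list of DV index ranges for the cortical layers.
#' @param regions data.frame of cortical region cuboids (acronym, parent,
#'   ap_lo, ap_hi, ml_lo, ml_hi for the left hemisphere).
#' @param cp list describing the caudoputamen cuboid.
#' @return list of class \code{atlas_spec}.
#' @export
toy_atlas_spec <- function(dim = c(160L, 60L, 160L),
                           voxel_size_um = 25,
                           bregma_voxel = c(101, 0, 80.5),
                           layer_dv = list("1" = 1:3, "2/3" = 4:9,
                                           "5" = 10:17, "6" = 18:24),
                           regions = data.frame(
                             acronym = c("MOs", "MOp", "SSp-bfd", "SSs"),
                             parent = c("MO", "MO", "SS", "SS"),
                             ap_lo = c(21L, 21L, 61L, 61L),
                             ap_hi = c(60L, 60L, 120L, 120L),
                             ml_lo = c(53L, 25L, 29L, 5L),
                             ml_hi = c(80L, 52L, 56L, 28L)),
                           cp = list(ap = 61:120, dv = 30:50, ml = 35:70)) {
  structure(list(dim = as.integer(dim), voxel_size_um = voxel_size_um,
                 bregma_voxel = bregma_voxel,
                 midline_ml = (dim[3] + 1) / 2,
                 layer_dv = layer_dv, regions = regions, cp = cp),
            class = "atlas_spec")
}

toy_graph_nodes <- function(spec) {
  nodes <- data.frame(id = 1L, acronym = "root", name = "root brain",
                      parent_id = NA_integer_)
  nodes <- rbind(nodes,
    data.frame(id = 2L, acronym = "Isocortex", name = "isocortex",
               parent_id = 1L),
    data.frame(id = 3L, acronym = "MO", name = "somatomotor areas",
               parent_id = 2L),
    data.frame(id = 6L, acronym = "SS", name = "somatosensory areas",
               parent_id = 2L),
    data.frame(id = 9L, acronym = "STR", name = "striatum", parent_id = 1L),
    data.frame(id = 10L, acronym = "CP", name = "caudoputamen",
               parent_id = 9L))
  region_ids <- c(MOs = 5L, MOp = 4L, `SSp-bfd` = 7L, SSs = 8L)
  region_names <- c(MOs = "secondary motor area",
                    MOp = "primary motor area",
                    `SSp-bfd` = "primary somatosensory area, barrel field",
                    SSs = "supplemental somatosensory area")
  for (i in seq_len(nrow(spec$regions))) {
    acr <- spec$regions$acronym[i]
    rid <- region_ids[[acr]]
    parent <- if (spec$regions$parent[i] == "MO") 3L else 6L
    nodes <- rbind(nodes,
      data.frame(id = rid, acronym = acr, name = region_names[[acr]],
                 parent_id = parent))
    layers <- names(spec$layer_dv)
    for (j in seq_along(layers)) {
      nodes <- rbind(nodes,
        data.frame(id = rid * 10L + j,
                   acronym = paste0(acr, layers[j]),
                   name = paste0(region_names[[acr]], ", layer ", layers[j]),
                   parent_id = rid))
    }
  }
  nodes
}

#' Build the toy atlas
#'
#' Produces an annotation volume in which every region voxel carries its
#' leaf structure id (a cortical layer or CP), the companion structure
#' graph, and the coordinate frame. The annotation is exactly
#' mirror-symmetric: flipping the ML axis reproduces the grid.
#'
#' @param spec an \code{\link{toy_atlas_spec}}.
#' @return list with elements \code{annotation}
#'   (\code{\link{annotation_volume}}), \code{graph}
#'   (\code{\link{structure_graph}}), \code{frame}
#'   (\code{\link{coordinate_frame}}) and \code{spec}.
#' @export
make_toy_atlas <- function(spec = toy_atlas_spec()) {
  d <- spec$dim
  grid <- array(0L, dim = d)
  nodes <- toy_graph_nodes(spec)
  graph <- structure_graph(nodes)
  fill <- function(acr, ap, dv, ml) {
    id <- graph_id(graph, acr)
    mirror <- (d[3] + 1L) - rev(ml)
    for (mlr in list(ml, mirror)) {
      occupied <- grid[ap, dv, mlr] != 0L
      if (any(occupied)) {
        other <- unique(grid[ap, dv, mlr][occupied])
        stopf("overlapping region definitions: %s overlaps %s",
              acr, paste(graph_acronym(graph, other), collapse = ", "))
      }
      grid[ap, dv, mlr] <<- id
    }
  }
  for (i in seq_len(nrow(spec$regions))) {
    acr <- spec$regions$acronym[i]
    ap <- spec$regions$ap_lo[i]:spec$regions$ap_hi[i]
    ml <- spec$regions$ml_lo[i]:spec$regions$ml_hi[i]
    for (layer in names(spec$layer_dv))
      fill(paste0(acr, layer), ap, spec$layer_dv[[layer]], ml)
  }
  fill("CP", spec$cp$ap, spec$cp$dv, spec$cp$ml)
  list(annotation = annotation_volume(grid, spec$voxel_size_um, graph),
       graph = graph,
       frame = coordinate_frame(spec$bregma_voxel, spec$midline_ml,
                                spec$voxel_size_um),
       spec = spec)
}
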