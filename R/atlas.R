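#' Structure graph of brain regions
#'
#' A structure graph is the hierarchy (forest) of brain structures used to
#' assign voxels to anatomical regions and to roll layer-level counts up to
#' their parent region. Each node has an integer \code{id}, a short unique
#' \code{acronym}, a full \code{name} and a \code{parent_id} (\code{NA} for
#' roots), mirroring the fields of the Allen-style structure-graph JSON.
#'
#' @param nodes data.frame with columns \code{id}, \code{acronym},
#'   \code{name}, \code{parent_id} (\code{NA} for root nodes).
#' @return An object of class \code{structure_graph}.
#' @export
structure_graph <- function(nodes) {
  required <- c("id", "acronym", "name", "parent_id")
  if (!all(required %in% names(nodes)))
    stopf("structure graph needs columns: %s", paste(required, collapse = ", "))
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$id))
    stopf("duplicate structure id: %s",
          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (anyDuplicated(nodes$acronym))
    stopf("duplicate acronym: %s",
          paste(unique(nodes$acronym[duplicated(nodes$acronym)]), collapse = ", "))
  dangling <- setdiff(nodes$parent_id[!is.na(nodes$parent_id)], nodes$id)
  if (length(dangling))
    stopf("parent_id not present in node set: %s", paste(dangling, collapse = ", "))
  # cycle check: walk each node to a root, path length bounded by node count
  idx <- match(nodes$parent_id, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    j <- i
    for (step in seq_len(nrow(nodes) + 1L)) {
      j <- idx[j]
      if (is.na(j)) break
      if (j == i)
        stopf("cycle in structure graph involving id %d (%s)",
              nodes$id[i], nodes$acronym[i])
      if (step > nrow(nodes)) stopf("cycle in structure graph")
    }
  }
  structure(list(nodes = nodes[, required]), class = "structure_graph")
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("structure_graph: %d nodes, %d root(s), %d leaves\n",
              nrow(x$nodes), sum(is.na(x$nodes$parent_id)),
              length(graph_leaves(x))))
  invisible(x)
}

#' Read / write a structure graph as JSON
#'
#' The on-disk format is a JSON list of objects
#' \code{{id, acronym, name, parent_id}} with \code{parent_id} null for
#' roots (a subset of the Allen structure-graph dialect).
#'
#' @param path file path.
#' @return \code{load_structure_graph} returns a validated
#'   \code{\link{structure_graph}}.
#' @export
load_structure_graph <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pid <- if (is.null(raw$parent_id)) rep(NA_integer_, nrow(raw)) else raw$parent_id
  if (is.list(pid))
    pid <- vapply(pid, function(v) if (is.null(v)) NA_integer_ else as.integer(v),
                  integer(1))
  raw$parent_id <- suppressWarnings(as.integer(pid))
  structure_graph(as.data.frame(raw))
}

#' @param graph a \code{\link{structure_graph}}.
#' @rdname load_structure_graph
#' @export
write_structure_graph <- function(graph, path) {
  jsonlite::write_json(graph$nodes, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Structure graph queries
#'
#' @param graph a \code{\link{structure_graph}}.
#' @param ids integer structure ids.
#' @param include_self include the query ids themselves in the result.
#' @return integer vector of structure ids.
#' @export
graph_descendants <- function(graph, ids, include_self = TRUE) {
  ids <- as.integer(ids)
  unknown <- setdiff(ids, graph$nodes$id)
  if (length(unknown)) stopf("unknown structure id: %s", paste(unknown, collapse = ", "))
  out <- ids
  frontier <- ids
  repeat {
    kids <- graph$nodes$id[graph$nodes$parent_id %in% frontier]
    kids <- setdiff(kids, out)
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  if (!include_self) out <- setdiff(out, ids)
  sort(out)
}

#' @rdname graph_descendants
#' @export
graph_leaves <- function(graph) {
  sort(setdiff(graph$nodes$id, graph$nodes$parent_id))
}

#' @param levels number of steps towards the root (capped at the root).
#' @rdname graph_descendants
#' @export
graph_ancestor <- function(graph, ids, levels = 1L) {
  ids <- as.integer(ids)
  unknown <- setdiff(ids, graph$nodes$id)
  if (length(unknown)) stopf("unknown structure id: %s", paste(unknown, collapse = ", "))
  idx <- match(ids, graph$nodes$id)
  for (k in seq_len(levels)) {
    parent <- graph$nodes$parent_id[idx]
    pidx <- match(parent, graph$nodes$id)
    idx <- ifelse(is.na(pidx), idx, pidx)  # roots stay put
  }
  graph$nodes$id[idx]
}

#' @param acronyms character acronyms to resolve.
#' @rdname graph_descendants
#' @export
graph_id <- function(graph, acronyms) {
  idx <- match(acronyms, graph$nodes$acronym)
  if (anyNA(idx))
    stopf("unknown acronym: %s", paste(acronyms[is.na(idx)], collapse = ", "))
  graph$nodes$id[idx]
}

#' @rdname graph_descendants
#' @export
graph_acronym <- function(graph, ids) {
  out <- graph$nodes$acronym[match(as.integer(ids), graph$nodes$id)]
  out[is.na(out) & ids == 0L] <- "unassigned"
  out
}

#' Annotation volume
#'
#' A 3D grid of non-negative integer structure ids on the canonical
#' (AP, DV, ML) axis order, 0 meaning outside the brain, with its voxel size.
#'
#' @param id_grid 3D integer array of structure ids.
#' @param voxel_size_um voxel edge length in micrometres (default 25).
#' @param graph optional \code{\link{structure_graph}}; if supplied, every
#'   nonzero id must be present in it.
#' @return An object of class \code{annotation_volume}.
#' @export
annotation_volume <- function(id_grid, voxel_size_um = 25, graph = NULL) {
  assert_array3(id_grid, "id_grid")
  if (voxel_size_um <= 0) stopf("voxel_size_um must be positive")
  if (any(id_grid < 0)) stopf("structure ids must be non-negative")
  if (!is.null(graph)) {
    present <- setdiff(unique(as.vector(id_grid)), 0L)
    missing <- setdiff(present, graph$nodes$id)
    if (length(missing))
      stopf("annotation ids absent from structure graph: %s",
            paste(missing, collapse = ", "))
  }
  structure(list(id_grid = id_grid, voxel_size_um = voxel_size_um),
            class = "annotation_volume")
}

#' Coordinate frame of an atlas grid
#'
#' Relates integer (1-based) voxel indices on the canonical (AP, DV, ML) grid
#' to bregma-referenced millimetre coordinates. Anterior, dorsal and right
#' are positive.
#'
#' @param bregma_voxel real (AP, DV, ML) voxel indices of bregma.
#' @param midline_ml real ML voxel index of the sagittal midplane.
#' @param voxel_size_um voxel size in micrometres.
#' @return An object of class \code{coordinate_frame}.
#' @export
coordinate_frame <- function(bregma_voxel, midline_ml, voxel_size_um = 25) {
  if (length(bregma_voxel) != 3L) stopf("bregma_voxel must have length 3")
  if (voxel_size_um <= 0) stopf("voxel_size_um must be positive")
  structure(list(bregma_voxel = as.numeric(bregma_voxel),
                 midline_ml = as.numeric(midline_ml),
                 voxel_size_um = as.numeric(voxel_size_um)),
            class = "coordinate_frame")
}

#' Convert voxel indices to bregma-referenced millimetres (and back)
#'
#' \code{voxel_to_bregma_mm} maps real-valued (AP, DV, ML) voxel indices to
#' (AP_mm, DV_mm, ML_mm) with anterior, dorsal and right positive;
#' \code{bregma_mm_to_voxel} is its exact inverse. Both are pure affine maps
#' and accept coordinates outside the grid.
#'
#' @param coords numeric vector of length 3 or an n x 3 matrix of
#'   (AP, DV, ML) voxel indices (or mm for the inverse).
#' @param frame a \code{\link{coordinate_frame}}.
#' @return n x 3 matrix with columns \code{ap_mm}, \code{dv_mm},
#'   \code{ml_mm} (or voxel indices for the inverse).
#' @export
voxel_to_bregma_mm <- function(coords, frame) {
  m <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  s <- frame$voxel_size_um / 1000
  out <- cbind(ap_mm = (frame$bregma_voxel[1] - m[, 1]) * s,
               dv_mm = (frame$bregma_voxel[2] - m[, 2]) * s,
               ml_mm = (m[, 3] - frame$midline_ml) * s)
  out
}

#' @rdname voxel_to_bregma_mm
#' @export
bregma_mm_to_voxel <- function(coords, frame) {
  m <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  s <- frame$voxel_size_um / 1000
  cbind(ap = frame$bregma_voxel[1] - m[, 1] / s,
        dv = frame$bregma_voxel[2] - m[, 2] / s,
        ml = frame$midline_ml + m[, 3] / s)
}

#' Hemisphere assignment relative to an injection side
#'
#' Voxels within half a voxel of the sagittal midplane are reported as
#' \code{"midline"} and kept in a separate bucket so that ipsi + contra +
#' midline always partitions a total exactly.
#'
#' @param coords numeric vector of length 3 or n x 3 matrix of (AP, DV, ML)
#'   voxel indices.
#' @param frame a \code{\link{coordinate_frame}}.
#' @param injection_side \code{"left"} or \code{"right"}.
#' @return character vector: \code{"ipsi"}, \code{"contra"} or
#'   \code{"midline"}.
#' @export
hemisphere_of <- function(coords, frame, injection_side = c("left", "right")) {
  injection_side <- match.arg(injection_side)
  m <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  d <- m[, 3] - frame$midline_ml
  side <- ifelse(abs(d) < 0.5, "midline", ifelse(d < 0, "left", "right"))
  out <- ifelse(side == "midline", "midline",
                ifelse(side == injection_side, "ipsi", "contra"))
  out
}
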