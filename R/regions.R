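#' Per-region, per-hemisphere quantification of a density map
#'
#' Accrues every voxel's density value to its annotation structure id and
#' hemisphere (relative to the injection side). Voxels with id 0 go to an
#' "unassigned" row and voxels within half a voxel of the midline to the
#' "midline" hemisphere bucket, so the table rows always partition the map
#' total exactly. Every leaf structure is present (with zeros) in the ipsi
#' and contra hemispheres.
#'
#' @param map a \code{\link{density_map}} (or \code{counts_volume}).
#' @param annotation an \code{\link{annotation_volume}} with matching
#'   geometry.
#' @param graph a \code{\link{structure_graph}}.
#' @param frame a \code{\link{coordinate_frame}}.
#' @param injection_side \code{"left"} or \code{"right"}.
#' @return An object of class \code{region_table}: data.frame with columns
#'   \code{structure_id}, \code{acronym}, \code{hemisphere},
#'   \code{axon_total}, \code{voxel_count}, plus attributes
#'   \code{injection_side} and \code{rollup_level}.
#' @export
quantify_by_region <- function(map, annotation, graph, frame,
                               injection_side = c("left", "right")) {
  injection_side <- match.arg(injection_side)
  x <- if (inherits(map, "density_map")) map$data else
       if (inherits(map, "counts_volume")) map$counts else map
  assert_array3(x, "map")
  if (!all(dim(x) == dim(annotation$id_grid)))
    stopf("map and annotation geometry differ")
  d <- dim(x)
  idx <- which(x != 0)
  universe <- expand.grid(structure_id = c(graph_leaves(graph), 0L),
                          hemisphere = c("ipsi", "contra", "midline"),
                          stringsAsFactors = FALSE)
  if (length(idx)) {
    pos <- arrayInd(idx, d)
    hemi <- hemisphere_of(pos, frame, injection_side)
    ids <- annotation$id_grid[idx]
    key <- paste(ids, hemi)
    tot <- rowsum(x[idx], key)
    cnt <- rowsum(rep(1L, length(idx)), key)
    agg <- data.frame(key = rownames(tot), axon_total = tot[, 1],
                      voxel_count = as.integer(cnt[, 1]))
  } else {
    agg <- data.frame(key = character(), axon_total = numeric(),
                      voxel_count = integer())
  }
  universe$key <- paste(universe$structure_id, universe$hemisphere)
  mi <- match(universe$key, agg$key)
  out <- data.frame(structure_id = universe$structure_id,
                    acronym = graph_acronym(graph, universe$structure_id),
                    hemisphere = universe$hemisphere,
                    axon_total = ifelse(is.na(mi), 0, agg$axon_total[mi]),
                    voxel_count = ifelse(is.na(mi), 0L, agg$voxel_count[mi]))
  # any density sitting on a non-leaf id (not produced by the toy atlas, but
  # legal in a real annotation) is appended so the partition stays exact
  extra <- setdiff(agg$key, universe$key)
  if (length(extra)) {
    ei <- match(extra, agg$key)
    parts <- strsplit(extra, " ")
    eid <- as.integer(vapply(parts, `[`, "", 1))
    out <- rbind(out, data.frame(structure_id = eid,
                                 acronym = graph_acronym(graph, eid),
                                 hemisphere = vapply(parts, `[`, "", 2),
                                 axon_total = agg$axon_total[ei],
                                 voxel_count = agg$voxel_count[ei]))
  }
  out <- out[order(out$structure_id, out$hemisphere), ]
  rownames(out) <- NULL
  attr(out, "injection_side") <- injection_side
  attr(out, "rollup_level") <- 0L
  class(out) <- c("region_table", "data.frame")
  out
}

#' Roll layer-level rows up the structure hierarchy
#'
#' Replaces each row's structure by its ancestor \code{levels} steps up
#' (capped at the root) and sums rows that share the resulting
#' (ancestor, hemisphere) pair, e.g. summing individual cortical layers into
#' their region. Totals are conserved exactly; the unassigned (id 0) bucket
#' is left untouched.
#'
#' @param table a \code{region_table}.
#' @param graph a \code{\link{structure_graph}}.
#' @param levels non-negative integer number of steps up (default 1).
#' @return a \code{region_table} at the coarser level.
#' @export
rollup_layers <- function(table, graph, levels = 1L) {
  if (levels < 0) stopf("levels must be non-negative")
  if (levels == 0) return(table)
  ids <- table$structure_id
  known <- ids == 0L | ids %in% graph$nodes$id
  if (!all(known))
    stopf("unknown structure_id: %s", paste(unique(ids[!known]), collapse = ", "))
  anc <- ids
  anc[ids != 0L] <- graph_ancestor(graph, ids[ids != 0L], levels = levels)
  key <- paste(anc, table$hemisphere)
  tot <- rowsum(table$axon_total, key)
  cnt <- rowsum(table$voxel_count, key)
  parts <- strsplit(rownames(tot), " ")
  sid <- as.integer(vapply(parts, `[`, "", 1))
  out <- data.frame(structure_id = sid,
                    acronym = graph_acronym(graph, sid),
                    hemisphere = vapply(parts, `[`, "", 2),
                    axon_total = tot[, 1],
                    voxel_count = as.integer(cnt[, 1]))
  out <- out[order(out$structure_id, out$hemisphere), ]
  rownames(out) <- NULL
  attr(out, "injection_side") <- attr(table, "injection_side")
  attr(out, "rollup_level") <- (attr(table, "rollup_level") %||% 0L) + levels
  class(out) <- c("region_table", "data.frame")
  out
}

#' Rank regions by mean innervation density across groups
#'
#' Per region (acronym), the mean of axon totals over all group tables and
#' both the ipsi and contra hemispheres is computed; regions are sorted in
#' descending order, ties broken by acronym, and the list truncated to
#' \code{top_n}. Midline and unassigned buckets are excluded from ranking.
#'
#' @param group_tables list of \code{region_table}s rolled up to the same
#'   level.
#' @param top_n number of regions to keep (default 75).
#' @return data.frame with columns \code{acronym}, \code{mean_density},
#'   \code{rank}.
#' @export
rank_regions <- function(group_tables, top_n = 75L) {
  if (!length(group_tables)) stopf("need at least one table")
  rows <- do.call(rbind, lapply(group_tables, function(t)
    as.data.frame(t)[t$hemisphere %in% c("ipsi", "contra") &
                     t$structure_id != 0L,
                     c("acronym", "hemisphere", "axon_total")]))
  # mean over groups x hemispheres: every (group, hemisphere) cell counts,
  # including zeros, so the denominator is 2 x number of groups
  tot <- rowsum(rows$axon_total, rows$acronym)
  denom <- 2 * length(group_tables)
  out <- data.frame(acronym = rownames(tot), mean_density = tot[, 1] / denom)
  out <- out[order(-out$mean_density, out$acronym), ]
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
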