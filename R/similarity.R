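#' Canonical sample ordering for correlation matrices
#'
#' Samples are ordered first by their transgenic line in a configured
#' canonical order, then by the absolute mediolateral position of the
#' injection-site center with the most medial injection first. The sort is
#' stable, so the ordering is invariant to the input permutation.
#'
#' @param metadata data.frame with columns \code{sample_id},
#'   \code{cre_line} and \code{ml_mm} (signed ML of the injection center).
#' @param line_order character vector giving the canonical line order;
#'   defaults to the order of first appearance.
#' @return character vector of sample ids in canonical order.
#' @export
order_samples <- function(metadata, line_order = NULL) {
  need <- c("sample_id", "cre_line", "ml_mm")
  if (!all(need %in% names(metadata)))
    stopf("metadata needs columns: %s", paste(need, collapse = ", "))
  if (anyNA(metadata$cre_line) || anyNA(metadata$ml_mm))
    stopf("missing cre_line or ml_mm in sample metadata")
  if (is.null(line_order)) line_order <- unique(metadata$cre_line)
  li <- match(metadata$cre_line, line_order)
  if (anyNA(li))
    stopf("cre_line not in canonical order: %s",
          paste(unique(metadata$cre_line[is.na(li)]), collapse = ", "))
  metadata$sample_id[order(li, abs(metadata$ml_mm), metadata$sample_id)]
}

pearson_matrix <- function(vectors, labels, method, params) {
  mat <- do.call(cbind, vectors)
  colnames(mat) <- labels
  sds <- apply(mat, 2, stats::sd)
  degenerate <- labels[sds == 0]
  r <- suppressWarnings(cor(mat, method = "pearson"))
  if (length(degenerate)) {
    r[degenerate, ] <- NA_real_
    r[, degenerate] <- NA_real_
    warning(sprintf("zero-variance sample(s): %s (correlations set to NA)",
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  diag(r) <- ifelse(labels %in% degenerate, NA_real_, 1)
  structure(list(r = r, labels = labels, method = method, params = params,
                 degenerate = degenerate),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (%s): %d samples\n", x$method,
              length(x$labels)))
  print(round(x$r, 3))
  invisible(x)
}

#' Categorical (region-level) correlation across injections
#'
#' Each sample is summarized as the vector of per-region axon totals at the
#' finest parcellation level, with the ipsi and contra hemispheres kept as
#' separate entries, and pairwise Pearson correlations are computed between
#' samples. Rows missing from a table are treated as zero. Samples whose
#' vector has zero variance get \code{NA} correlations and a warning rather
#' than a silent zero.
#'
#' @param tables named list of \code{region_table}s at the finest level
#'   (names = sample ids).
#' @param order character vector of sample ids giving the matrix order
#'   (e.g. from \code{\link{order_samples}}); defaults to list order.
#' @return An object of class \code{correlation_matrix}.
#' @export
categorical_correlation <- function(tables, order = names(tables)) {
  if (is.null(names(tables))) names(tables) <- paste0("s", seq_along(tables))
  if (is.null(order)) order <- names(tables)
  tables <- tables[order]
  keys <- sort(unique(unlist(lapply(tables, function(t)
    paste(t$structure_id, t$hemisphere)[t$hemisphere %in% c("ipsi", "contra")]))))
  vectors <- lapply(tables, function(t) {
    sel <- t$hemisphere %in% c("ipsi", "contra")
    v <- stats::setNames(rep(0, length(keys)), keys)
    k <- paste(t$structure_id, t$hemisphere)[sel]
    v[k] <- t$axon_total[sel]
    v
  })
  pearson_matrix(vectors, order, "categorical", list())
}

#' Spatial (voxel-wise) correlation across injections
#'
#' Each density map is filtered with an isotropic 3D Gaussian
#' (reflect boundary), flattened, and pairwise Pearson correlations are
#' computed between the flattened arrays. With \code{sigma = 0} this is the
#' raw voxel-wise correlation.
#'
#' @param maps named list of \code{\link{density_map}}s with identical
#'   geometry.
#' @param sigma_voxels Gaussian standard deviation in voxels (default 4).
#' @param order sample id order for the matrix; defaults to list order.
#' @return An object of class \code{correlation_matrix}.
#' @export
spatial_correlation <- function(maps, sigma_voxels = 4, order = names(maps)) {
  if (is.null(names(maps))) names(maps) <- paste0("s", seq_along(maps))
  if (is.null(order)) order <- names(maps)
  maps <- maps[order]
  d <- dim(maps[[1]]$data)
  vectors <- lapply(maps, function(m) {
    if (!all(dim(m$data) == d)) stopf("density map geometry mismatch")
    as.vector(gaussian_filter(m$data, sigma_voxels))
  })
  pearson_matrix(vectors, order, "spatial",
                 list(sigma_voxels = sigma_voxels, boundary = "reflect"))
}
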