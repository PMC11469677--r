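#' Read and write 3D volumes as multi-page TIFF with a JSON sidecar
#'
#' Volumes are stored on the canonical (AP, DV, ML) axis order as one TIFF
#' page per AP plane, with a JSON sidecar (\code{<path>.json}) recording the
#' grid geometry: \code{kind} ("float" or "uint16"), \code{dim},
#' \code{voxel_size_um}, \code{axis_order} and optionally
#' \code{bregma_voxel} / \code{midline_ml}. Integer volumes (e.g.
#' annotations) round-trip exactly; float volumes within single precision.
#'
#' @param x 3D numeric array. For \code{kind = "uint16"} values must be
#'   integers in [0, 65535]; for \code{"float"} values must lie in [0, 1]
#'   (probability volumes).
#' @param path output path (\code{.tif}).
#' @param kind \code{"float"} or \code{"uint16"}.
#' @param voxel_size_um voxel size recorded in the sidecar.
#' @param sidecar named list of extra geometry fields.
#' @return \code{write_volume} returns the path; \code{read_volume} a list
#'   with \code{data} (3D array) and \code{sidecar}.
#' @export
write_volume <- function(x, path, kind = c("float", "uint16"),
                         voxel_size_um = 25, sidecar = list()) {
  kind <- match.arg(kind)
  assert_array3(x, "x")
  d <- dim(x)
  if (kind == "uint16") {
    if (any(x < 0 | x > 65535) || any(x != floor(x)))
      stopf("uint16 volumes must hold integers in [0, 65535]")
    pages <- lapply(seq_len(d[1]), function(i) x[i, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    if (any(x < 0 | x > 1)) stopf("float volumes must lie in [0, 1]")
    pages <- lapply(seq_len(d[1]), function(i) x[i, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  meta <- c(list(kind = kind, dim = d, voxel_size_um = voxel_size_um,
                 axis_order = c("AP", "DV", "ML")), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stopf("missing geometry sidecar: %s", sc_path)
  meta <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (meta$kind == "uint16"))
  d <- c(length(pages), dim(pages[[1]]))
  x <- array(0, dim = d)
  for (i in seq_along(pages)) x[i, , ] <- pages[[i]]
  if (meta$kind == "uint16") storage.mode(x) <- "integer"
  list(data = x, sidecar = meta)
}

#' Write / read a region table as CSV
#'
#' @param table a \code{region_table}.
#' @param path CSV path.
#' @return the path / the table.
#' @export
write_region_table <- function(table, path) {
  df <- as.data.frame(table)
  df$injection_side <- attr(table, "injection_side")
  df$rollup_level <- attr(table, "rollup_level") %||% 0L
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side <- df$injection_side[1]
  lvl <- df$rollup_level[1]
  df$injection_side <- NULL
  df$rollup_level <- NULL
  attr(df, "injection_side") <- side
  attr(df, "rollup_level") <- lvl
  class(df) <- c("region_table", "data.frame")
  df
}

#' Write a coordinate list as CSV (and read it back)
#'
#' @param coords data.frame from \code{\link{skeleton_to_coords}}.
#' @param path CSV path.
#' @export
write_coords <- function(coords, path) {
  write.csv(coords, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coords
#' @export
read_coords <- function(path) read.csv(path)

#' Write a correlation matrix as CSV plus JSON metadata
#'
#' @param cm a \code{correlation_matrix}.
#' @param path CSV path (metadata goes to \code{<path>.json}).
#' @export
write_correlation <- function(cm, path) {
  df <- as.data.frame(cm$r)
  df <- cbind(sample = rownames(cm$r), df)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(method = cm$method, params = cm$params,
                            degenerate = cm$degenerate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
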