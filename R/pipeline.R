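#' Pipeline configuration with study defaults
#'
#' Collects every stage parameter in one validated list. All defaults are
#' the study values: 8 binarization thresholds 0.2-0.9, 10,000-voxel
#' component filter, 80\% injection-site inclusion rule, Gaussian sigma 4
#' for spatial correlation / hotspot / caudoputamen filtering, 75\%/95\%
#' contours with a 225 um peak ROI, top-75 ranking one hierarchy level up,
#' 300 ms dF/F baseline, 10-260 ms evoked window, 40 x 25 pixel frontal
#' mask with the 80\%-of-max threshold, and trial-weighted population
#' averaging. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above (see
#'   \code{pipeline_defaults()}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    # synthetic cohort
    n_samples = 7L,
    topography = list(intercept_mm = 0.9, slope_mm_per_mm = 0.5,
                      sigma_spot_px = 6, ap_noise_sd_mm = 0.1,
                      cells_range = c(200L, 1200L),
                      axon_voxels_per_cell = 80, spot_ml_mm = 0.9,
                      injection_side = "left", cre_line = "lineA"),
    # density / QC
    qc_targets = c("SSp-bfd", "SSs"),
    qc_min_fraction = 0.8,
    # region quantification
    rollup_levels = 1L,
    top_n = 75L,
    # correlations
    correlation_sigma = 4,
    line_order = NULL,
    # hotspot topography
    hotspot_regions = c("MOp", "MOs"),
    hotspot_layers = c("2/3", "5"),
    hotspot_sigma = 4,
    contour_levels = c(0.75, 0.95),
    roi_um = 225,
    # wide-field stage
    run_widefield = TRUE,
    n_mice = 3L,
    widefield = list(image_shape = c(96L, 80L), bregma_pixel = c(44, 40),
                     trials_per_point = 3L, slope_mm_per_mm = 0.5,
                     intercept_mm = -0.75),
    dff_baseline_ms = 300,
    evoked_window_ms = c(10, 260),
    com_frac = 0.8)
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the toy atlas and an injection cohort, applies injection-site
#' QC, quantifies regions (finest level and rolled up), ranks regions,
#' computes categorical and spatial correlation matrices, measures
#' motor-cortex hotspots and fits the anatomical topography regression on
#' QC-included samples with a hotspot, and (optionally) simulates wide-field
#' sessions and fits the functional topography. All tabular outputs are
#' written as CSV/JSON under \code{out_dir} together with a manifest
#' (configuration, seed, package version, output checksums); re-running
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory results
#'   (\code{cohort}, \code{qc}, \code{hotspots}, \code{anatomical_fit},
#'   \code{functional_fit}, \code{ranking}, \code{correlations},
#'   \code{manifest_path}).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- make_toy_atlas()

  topo <- do.call(topography_spec, config$topography)
  cohort <- simulate_injection_cohort(topo, atlas, config$n_samples,
                                      seed = stage_seed(config$seed, "cohort"))

  # injection QC ------------------------------------------------------------
  qc_rows <- lapply(seq_len(nrow(cohort$injections)), function(i) {
    inj <- cohort$injections[i, ]
    qc <- injection_qc(injection_mask(inj, atlas$annotation),
                       atlas$annotation, atlas$graph,
                       target_acronyms = config$qc_targets,
                       min_fraction = config$qc_min_fraction)
    mm <- voxel_to_bregma_mm(qc$center, atlas$frame)
    data.frame(sample_id = inj$sample_id, cre_line = inj$cre_line,
               injection_region = inj$injection_region,
               n_cells = inj$n_cells,
               center_ap_mm = mm[1, "ap_mm"], center_ml_mm = mm[1, "ml_mm"],
               abs_ml_mm = abs(mm[1, "ml_mm"]),
               fraction_in_targets = qc$fraction_in_targets,
               volume_mm3 = qc$volume_mm3, included = qc$included)
  })
  qc <- do.call(rbind, qc_rows)

  # region tables -----------------------------------------------------------
  side <- topo$injection_side
  tables <- lapply(cohort$maps, quantify_by_region, atlas$annotation,
                   atlas$graph, atlas$frame, injection_side = side)
  rolled <- lapply(tables, rollup_layers, atlas$graph,
                   levels = config$rollup_levels)
  included_ids <- qc$sample_id[qc$included]
  grp <- group_average(cohort$maps[included_ids])
  grp_table <- rollup_layers(
    quantify_by_region(grp, atlas$annotation, atlas$graph, atlas$frame,
                       injection_side = side),
    atlas$graph, levels = config$rollup_levels)
  ranking <- rank_regions(list(grp_table), top_n = config$top_n)

  # correlations ------------------------------------------------------------
  meta <- data.frame(sample_id = qc$sample_id, cre_line = qc$cre_line,
                     ml_mm = qc$center_ml_mm)
  ord <- order_samples(meta, line_order = if (length(config$line_order))
    config$line_order else NULL)
  cat_cm <- categorical_correlation(tables, order = ord)
  spa_cm <- spatial_correlation(cohort$maps, config$correlation_sigma,
                                order = ord)

  # hotspot topography ------------------------------------------------------
  hot_rows <- lapply(qc$sample_id, function(sid) {
    hm <- mo_axon_map(cohort$maps[[sid]], atlas$annotation, atlas$graph,
                      regions = config$hotspot_regions,
                      layers = config$hotspot_layers)
    hs <- hotspot_metrics(hm, atlas$frame, sigma_px = config$hotspot_sigma,
                          levels = config$contour_levels,
                          roi_um = config$roi_um)
    data.frame(sample_id = sid,
               area75_mm2 = hs$area75_mm2,
               centroid95_ap_mm = hs$centroid95_ap_mm,
               centroid95_ml_mm = hs$centroid95_ml_mm,
               peak_roi_density = hs$peak_roi_density,
               has_hotspot = hs$has_hotspot)
  })
  hotspots <- merge(qc[, c("sample_id", "abs_ml_mm", "included")],
                    do.call(rbind, hot_rows), by = "sample_id", sort = TRUE)
  use <- hotspots$included & hotspots$has_hotspot
  anatomical_fit <- fit_topography(hotspots[use, c("abs_ml_mm",
                                                   "centroid95_ap_mm")])

  # wide-field stage --------------------------------------------------------
  functional_fit <- NULL
  com <- NULL
  if (isTRUE(config$run_widefield)) {
    wf_truth <- do.call(widefield_truth, config$widefield)
    com_rows <- list()
    for (mi in seq_len(config$n_mice)) {
      sim <- simulate_widefield_session(
        wf_truth, seed = stage_seed(config$seed, paste0("widefield", mi)),
        mouse_id = sprintf("m%02d", mi), cre_line = topo$cre_line)
      dff <- compute_dff(sim$session, baseline_ms = config$dff_baseline_ms)
      for (gp in sort(unique(dff$stim_log$grid_point_id))) {
        em <- evoked_map(dff, gp, window_ms = config$evoked_window_ms)
        cm <- frontal_center_of_mass(em, frac = config$com_frac)
        com_rows[[length(com_rows) + 1L]] <- data.frame(
          mouse_id = dff$mouse_id, grid_point_id = gp,
          abs_ml_mm = abs(em$stim_ml_mm), ap_mm = cm$ap_mm,
          ml_mm = cm$ml_mm, n_trials = em$n_trials)
      }
    }
    com <- do.call(rbind, com_rows)
    functional_fit <- fit_functional_topography(com)
  }

  # outputs -----------------------------------------------------------------
  paths <- character()
  wr <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    paths <<- c(paths, p)
  }
  wcsv <- function(obj, p) write.csv(obj, p, row.names = FALSE)
  wjson <- function(obj, p)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wr(qc, "injection_qc.csv", wcsv)
  wr(hotspots, "hotspots.csv", wcsv)
  wr(ranking, "region_ranking.csv", wcsv)
  all_regions <- do.call(rbind, lapply(names(rolled), function(sid) {
    df <- as.data.frame(rolled[[sid]])
    cbind(sample_id = sid, df)
  }))
  wr(all_regions, "region_tables.csv", wcsv)
  wr(cat_cm, "correlation_categorical.csv", write_correlation)
  wr(spa_cm, "correlation_spatial.csv", write_correlation)
  wr(unclass(anatomical_fit), "anatomical_fit.json", wjson)
  if (!is.null(functional_fit)) {
    wr(com, "functional_com.csv", wcsv)
    wr(c(unclass(functional_fit$fit),
         list(per_mouse = functional_fit$per_mouse)),
       "functional_fit.json", wjson)
  }
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("axonmapr")),
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(sort(paths))),
                     basename(sort(paths)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, qc = qc, hotspots = hotspots,
                 anatomical_fit = anatomical_fit,
                 functional_fit = functional_fit,
                 ranking = ranking,
                 correlations = list(categorical = cat_cm, spatial = spa_cm),
                 manifest_path = manifest_path))
}

#' Re-run a pipeline from its manifest
#'
#' The manifest records the complete configuration and seed, so it alone
#' suffices to reproduce a run.
#'
#' @param manifest_path path to a \code{manifest.json} written by
#'   \code{\link{run_pipeline}}.
#' @param out_dir output directory for the re-run.
#' @return as \code{\link{run_pipeline}}.
#' @export
run_pipeline_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  for (k in c("topography", "widefield"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.list(cfg[[k]])
  run_pipeline(pipeline_config(cfg), out_dir)
}
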