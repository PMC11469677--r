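#' Specification of a synthetic injection cohort's topography
#'
#' Encodes the mirror map the cohort should obey: the anteroposterior
#' position of each sample's motor-cortex hotspot is
#' \code{AP = intercept + slope * |ML|} of the injection site, plus Gaussian
#' noise. The default slope of 0.5 mm AP per mm |ML| is in the range of
#' measured somatosensory-to-motor map slopes (roughly 0.5-0.65).
#'
#' @param intercept_mm AP of the hotspot for a (hypothetical) midline
#'   injection (default 0.9 mm).
#' @param slope_mm_per_mm mm AP per mm |ML|; positive = more lateral
#'   injection maps to more anterior hotspot (default 0.5).
#' @param sigma_spot_px hotspot Gaussian spread in 25 um pixels (default 6,
#'   i.e. 150 um).
#' @param ap_noise_sd_mm per-sample AP noise standard deviation
#'   (default 0.1 mm).
#' @param abs_ml_mm per-sample |ML| injection positions; default
#'   \code{NULL} spreads \code{n_samples} evenly over 0.75-1.85 mm
#'   (covering the toy SSp-bfd and SSs bands).
#' @param cells_range labeled-cell count range per injection
#'   (default 200-1200, matching the order of magnitude of real cohorts).
#' @param axon_voxels_per_cell mean axon-voxel budget per labeled cell
#'   (default 80).
#' @param spot_ml_mm |ML| of the hotspot center in MO (default 0.9,
#'   placed ipsilaterally).
#' @param injection_side hemisphere of the injections (default left).
#' @param cre_line transgenic line label attached to the samples.
#' @return list of class \code{topography_spec}.
#' @export
topography_spec <- function(intercept_mm = 0.9, slope_mm_per_mm = 0.5,
                            sigma_spot_px = 6, ap_noise_sd_mm = 0.1,
                            abs_ml_mm = NULL, cells_range = c(200L, 1200L),
                            axon_voxels_per_cell = 80,
                            spot_ml_mm = 0.9,
                            injection_side = "left",
                            cre_line = "lineA") {
  if (sigma_spot_px <= 0) stopf("sigma_spot_px must be positive")
  if (ap_noise_sd_mm < 0) stopf("ap_noise_sd_mm must be non-negative")
  structure(list(intercept_mm = intercept_mm,
                 slope_mm_per_mm = slope_mm_per_mm,
                 sigma_spot_px = sigma_spot_px,
                 ap_noise_sd_mm = ap_noise_sd_mm,
                 abs_ml_mm = abs_ml_mm,
                 cells_range = as.integer(cells_range),
                 axon_voxels_per_cell = axon_voxels_per_cell,
                 spot_ml_mm = spot_ml_mm,
                 injection_side = injection_side,
                 cre_line = cre_line),
            class = "topography_spec")
}

#' Simulate an injection cohort with known mirror-map topography
#'
#' For each sample: an injection-site mask is placed in SSp-bfd or SSs at
#' the requested |ML|, a labeled-cell count is drawn, and an integer budget
#' of axon voxels is sampled (multinomially) from a Gaussian hotspot of
#' spread \code{sigma_spot_px} restricted to layers 2/3 and 5 of MOp/MOs,
#' centered at \code{AP = intercept + slope * |ML| + noise}. The density
#' map is the sampled counts divided by the cell count, so density total
#' times cell count reproduces the drawn budget exactly. Ground truth
#' (including every generated hotspot center) is returned alongside.
#'
#' @param topo a \code{\link{topography_spec}}.
#' @param atlas a toy atlas from \code{\link{make_toy_atlas}}.
#' @param n_samples number of injections (>= 3 recommended; 2 warns,
#'   fewer errors).
#' @param seed integer seed.
#' @return list with elements \code{maps} (named list of
#'   \code{\link{density_map}}s), \code{injections} (data.frame of
#'   injection metadata incl. mask extents), \code{truth} (data.frame of
#'   generated hotspot centers and budgets).
#' @export
simulate_injection_cohort <- function(topo, atlas, n_samples = 7L, seed = 1) {
  if (n_samples < 2) stopf("n_samples must be >= 2 (regression needs >= 3)")
  if (n_samples == 2)
    warning("n_samples = 2: downstream regression needs >= 3 samples",
            call. = FALSE)
  set.seed(seed)
  ann <- atlas$annotation
  frame <- atlas$frame
  graph <- atlas$graph
  d <- dim(ann$id_grid)
  vox_mm <- frame$voxel_size_um / 1000
  abs_ml <- topo$abs_ml_mm %||% seq(0.75, 1.85, length.out = n_samples)
  if (length(abs_ml) != n_samples)
    stopf("abs_ml_mm must have length n_samples")
  side_sign <- if (topo$injection_side == "left") -1 else 1
  mo_ids <- graph_id(graph, c("MOp2/3", "MOp5", "MOs2/3", "MOs5"))
  ss_ids <- graph_descendants(graph, graph_id(graph, c("SSp-bfd", "SSs")))
  ss_ap_mid <- round(mean(atlas$spec$regions$ap_lo[3]:atlas$spec$regions$ap_hi[3]))
  inj_dv <- range(c(atlas$spec$layer_dv[["2/3"]], atlas$spec$layer_dv[["5"]]))

  n_cells <- as.integer(round(runif(n_samples, topo$cells_range[1],
                                    topo$cells_range[2])))
  ap_noise <- rnorm(n_samples, 0, topo$ap_noise_sd_mm)

  maps <- list()
  inj_rows <- list()
  truth_rows <- list()
  for (i in seq_len(n_samples)) {
    sid <- sprintf("s%02d", i)
    ml_v <- frame$midline_ml + side_sign * abs_ml[i] / vox_mm
    ml_c <- as.integer(round_half_up(ml_v))
    inj_id <- ann$id_grid[ss_ap_mid, inj_dv[1], ml_c]
    if (!(inj_id %in% ss_ids))
      stopf("injection |ML| %.2f mm falls outside SSp-bfd/SSs", abs_ml[i])
    region <- graph_acronym(graph, graph_ancestor(graph, inj_id, 1L))

    # cuboid injection mask centered on (AP mid of SS band, cortex, ml)
    ap_rng <- (ss_ap_mid - 3L):(ss_ap_mid + 3L)
    ml_rng <- (ml_c - 3L):(ml_c + 3L)
    dv_rng <- inj_dv[1]:inj_dv[2]

    # hotspot center
    ap_mm <- topo$intercept_mm + topo$slope_mm_per_mm * abs_ml[i] + ap_noise[i]
    ml_mm <- side_sign * topo$spot_ml_mm
    ap_v <- frame$bregma_voxel[1] - ap_mm / vox_mm
    spot_ml_v <- frame$midline_ml + ml_mm / vox_mm

    # Gaussian weights over a local box restricted to MO layers 2/3 and 5
    s <- topo$sigma_spot_px
    box_ap <- max(1, floor(ap_v - 4 * s)):min(d[1], ceiling(ap_v + 4 * s))
    box_ml <- max(1, floor(spot_ml_v - 4 * s)):min(d[3], ceiling(spot_ml_v + 4 * s))
    box_dv <- dv_rng
    w <- outer(exp(-(box_ap - ap_v)^2 / (2 * s^2)), rep(1, length(box_dv)))
    w <- outer(w, exp(-(box_ml - spot_ml_v)^2 / (2 * s^2)))
    inside <- array(ann$id_grid[box_ap, box_dv, box_ml] %in% mo_ids,
                    dim = dim(w))
    w <- w * inside
    if (sum(w) <= 0) stopf("hotspot center falls outside MO layers 2/3 and 5")
    budget <- as.integer(round(n_cells[i] * topo$axon_voxels_per_cell))
    counts_box <- array(as.integer(rmultinom(1, budget, as.vector(w))),
                        dim = dim(w))
    counts <- array(0, dim = d)
    counts[box_ap, box_dv, box_ml] <- counts_box

    maps[[sid]] <- normalize_per_cell(
      counts, n_cells[i],
      metadata = list(sample_id = sid, cre_line = topo$cre_line,
                      injection_region = region,
                      injection_side = topo$injection_side,
                      injection_center = c(ss_ap_mid, mean(dv_rng), ml_v),
                      voxel_size_um = frame$voxel_size_um))
    inj_rows[[i]] <- data.frame(
      sample_id = sid, cre_line = topo$cre_line, injection_region = region,
      ml_mm = side_sign * abs_ml[i], abs_ml_mm = abs_ml[i],
      n_cells = n_cells[i],
      ap_lo = ap_rng[1], ap_hi = ap_rng[length(ap_rng)],
      dv_lo = dv_rng[1], dv_hi = dv_rng[length(dv_rng)],
      ml_lo = ml_rng[1], ml_hi = ml_rng[length(ml_rng)])
    truth_rows[[i]] <- data.frame(
      sample_id = sid, abs_ml_mm = abs_ml[i],
      center_ap_mm = ap_mm, center_ml_mm = ml_mm,
      n_cells = n_cells[i], axon_budget = budget)
  }
  list(maps = maps,
       injections = do.call(rbind, inj_rows),
       truth = do.call(rbind, truth_rows))
}

#' Build an injection-site mask from cohort metadata
#'
#' @param injection one row of the \code{injections} data.frame returned by
#'   \code{\link{simulate_injection_cohort}}.
#' @param annotation the cohort's \code{\link{annotation_volume}}.
#' @return logical 3D array.
#' @export
injection_mask <- function(injection, annotation) {
  m <- array(FALSE, dim = dim(annotation$id_grid))
  m[injection$ap_lo:injection$ap_hi,
    injection$dv_lo:injection$dv_hi,
    injection$ml_lo:injection$ml_hi] <- TRUE
  m
}
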