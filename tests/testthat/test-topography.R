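test_that("motor-cortex maps select only layers 2/3 and 5 and conserve totals", {
  atlas <- toy()
  coh <- simulate_injection_cohort(topography_spec(), atlas, 3, seed = 15)
  m <- coh$maps[[1]]
  hm <- mo_axon_map(m, atlas$annotation, atlas$graph)
  mo_ids <- graph_id(atlas$graph, c("MOp2/3", "MOp5", "MOs2/3", "MOs5"))
  expect_equal(sum(hm),
               sum(m$data[atlas$annotation$id_grid %in% mo_ids]),
               tolerance = 1e-9)
  # axons only in MOp layer 6 yield an all-zero map
  x <- array(0, dim = dim(atlas$annotation$id_grid))
  x[atlas$annotation$id_grid == graph_id(atlas$graph, "MOp6")] <- 1
  expect_equal(sum(mo_axon_map(density_map(x), atlas$annotation,
                               atlas$graph)), 0)
  expect_error(mo_axon_map(m, atlas$annotation, atlas$graph,
                           regions = "NOPE"), "NOPE")
})

test_that("hotspot metrics match analytic Gaussian contour geometry", {
  frame <- coordinate_frame(c(101, 0, 80.5), 80.5, 25)
  s0 <- 6; cx <- 60.3; cy <- 70.6
  g <- outer(exp(-(seq_len(120) - cx)^2 / (2 * s0^2)),
             exp(-(seq_len(140) - cy)^2 / (2 * s0^2)))
  hs <- hotspot_metrics(g, frame, sigma_px = 4)
  # centroid within 0.5 px of the true center (effective spread sqrt(s0^2+16))
  cen_vox <- bregma_mm_to_voxel(c(hs$centroid95_ap_mm, 0,
                                  hs$centroid95_ml_mm), frame)
  expect_lt(abs(cen_vox[1, "ap"] - cx), 0.5)
  expect_lt(abs(cen_vox[1, "ml"] - cy), 0.5)
  # area within 5% of the closed form 2*pi*(s0^2+16)*ln(4/3) px^2,
  # itself verified against a brute-force dense-grid threshold count
  s_eff2 <- s0^2 + 16
  analytic_px <- 2 * pi * s_eff2 * log(4 / 3)
  xs <- seq(0.5, 120.5, by = 0.05); ys <- seq(0.5, 140.5, by = 0.05)
  gg <- outer(exp(-(xs - cx)^2 / (2 * s_eff2)),
              exp(-(ys - cy)^2 / (2 * s_eff2)))
  dense_px <- sum(gg >= 0.75 * max(gg)) * 0.05^2
  expect_equal(dense_px, analytic_px, tolerance = 0.01)
  area_px <- hs$area75_mm2 / (0.025^2)
  expect_lt(abs(area_px - dense_px) / dense_px, 0.05)
  # 95% set nested in 75% set
  expect_true(all(paste(hs$contour95[, 1], hs$contour95[, 2]) %in%
                  paste(hs$contour75[, 1], hs$contour75[, 2])))
  # peak ROI: 225 um at 25 um pixels is a 9 x 9 window
  expect_equal(hs$peak_pixel, c(60, 71))
  # translation equivariance away from borders
  g2 <- outer(exp(-(seq_len(120) - cx - 7)^2 / (2 * s0^2)),
              exp(-(seq_len(140) - cy + 5)^2 / (2 * s0^2)))
  hs2 <- hotspot_metrics(g2, frame, sigma_px = 4)
  expect_equal(hs2$centroid95_ap_mm, hs$centroid95_ap_mm - 7 * 0.025,
               tolerance = 1e-6)
  expect_equal(hs2$centroid95_ml_mm, hs$centroid95_ml_mm - 5 * 0.025,
               tolerance = 1e-6)
  expect_equal(hs2$area75_mm2, hs$area75_mm2, tolerance = 1e-9)
  expect_equal(hs2$peak_roi_density, hs$peak_roi_density, tolerance = 1e-9)
  # all-zero map -> no-hotspot result
  hz <- hotspot_metrics(matrix(0, 30, 30), frame)
  expect_false(hz$has_hotspot)
  expect_true(is.na(hz$area75_mm2))
})

test_that("topography regression recovers exact lines and rejects bad input", {
  fit <- fit_topography(data.frame(ml = c(3, 3.5, 4), ap = c(1, 1.25, 1.5)))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$n, 3L)
  expect_error(fit_topography(data.frame(ml = c(3, 3.5), ap = c(1, 2))),
               "at least 3")
  expect_error(fit_topography(data.frame(ml = rep(3, 4), ap = 1:4)),
               "variance")
  # no-hotspot samples (NA) are dropped before fitting
  fit2 <- fit_topography(data.frame(ml = c(3, 3.5, 4, 5),
                                    ap = c(1, 1.25, 1.5, NA)))
  expect_equal(fit2$n, 3L)
})

test_that("caudoputamen profiles respect hemisphere scopes", {
  atlas <- toy()
  d <- dim(atlas$annotation$id_grid)
  cp_id <- graph_id(atlas$graph, "CP")
  # axons only in the contralateral (right) CP for a left injection
  x <- array(0, dim = d)
  vox <- which(atlas$annotation$id_grid == cp_id, arr.ind = TRUE)
  right <- vox[vox[, 3] > atlas$frame$midline_ml, , drop = FALSE]
  x[right[1:50, ]] <- 1
  pr <- striatum_profiles(density_map(x), atlas$annotation, atlas$graph,
                          atlas$frame, injection_side = "left",
                          sigma_voxels = 0)
  expect_equal(sum(pr$ap$density), 0)
  expect_equal(sum(pr$dv$density), 0)
  expect_equal(sum(pr$ml$density), 50)
  expect_true(all(pr$ml$density[pr$ml$mm < 0] == 0))
  # impulse at a known ipsilateral CP voxel, sigma 0 -> unit impulses
  left <- vox[vox[, 3] < atlas$frame$midline_ml, , drop = FALSE]
  v <- left[7, ]
  x2 <- array(0, dim = d); x2[matrix(v, 1)] <- 1
  pr2 <- striatum_profiles(density_map(x2), atlas$annotation, atlas$graph,
                           atlas$frame, injection_side = "left",
                           sigma_voxels = 0)
  expect_equal(sum(pr2$ap$density > 0), 1L)
  expect_equal(pr2$ap$mm[pr2$ap$density > 0],
               unname((atlas$frame$bregma_voxel[1] - v[1]) * 0.025))
  expect_equal(sum(pr2$dv$density), 1)
  expect_equal(sum(pr2$ml$density), 1)
  expect_error(striatum_profiles(density_map(x2), atlas$annotation,
                                 atlas$graph, atlas$frame, "left",
                                 region = "XX"), "XX")
})
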