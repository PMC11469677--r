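test_that("region tables partition the map total exactly", {
  atlas <- toy()
  topo <- topography_spec(ap_noise_sd_mm = 0)
  coh <- simulate_injection_cohort(topo, atlas, n_samples = 3, seed = 8)
  m <- coh$maps[[1]]
  # sprinkle density outside the brain and on the midline to fill buckets
  m$data[1, 1, 1] <- 0.5                       # id 0 -> unassigned
  mid <- (dim(m$data)[3] + 1) / 2
  m$data[40, 5, floor(mid)] <- 0               # midline stays clean here
  tab <- quantify_by_region(m, atlas$annotation, atlas$graph, atlas$frame,
                            injection_side = "left")
  expect_equal(sum(tab$axon_total), sum(m$data), tolerance = 1e-9)
  # every leaf appears in ipsi and contra, zeros included
  leaves <- graph_leaves(atlas$graph)
  expect_true(all(paste(rep(leaves, each = 2), c("ipsi", "contra")) %in%
                  paste(tab$structure_id, tab$hemisphere)))
  expect_true(any(tab$structure_id == 0L & tab$axon_total > 0))
  expect_error(quantify_by_region(
    density_map(array(0, dim = c(2, 2, 2))), atlas$annotation, atlas$graph,
    atlas$frame), "differ")
})

test_that("an isolated left MOp-L5 deposit lands in a single ipsi row", {
  atlas <- toy()
  x <- array(0, dim = dim(atlas$annotation$id_grid))
  id5 <- graph_id(atlas$graph, "MOp5")
  vox <- which(atlas$annotation$id_grid == id5, arr.ind = TRUE)
  vox <- vox[vox[, 3] < atlas$frame$midline_ml, , drop = FALSE]
  x[vox[1:20, ]] <- 2
  tab <- quantify_by_region(density_map(x), atlas$annotation, atlas$graph,
                            atlas$frame, injection_side = "left")
  nz <- tab[tab$axon_total > 0, ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$acronym, "MOp5")
  expect_equal(nz$hemisphere, "ipsi")
  expect_equal(nz$axon_total, 40)
  expect_equal(nz$voxel_count, 20L)
})

test_that("layer rollup conserves totals and composes", {
  atlas <- toy()
  coh <- simulate_injection_cohort(topography_spec(), atlas, 3, seed = 12)
  tab <- quantify_by_region(coh$maps[[2]], atlas$annotation, atlas$graph,
                            atlas$frame, injection_side = "left")
  expect_identical(rollup_layers(tab, atlas$graph, 0L), tab)
  r1 <- rollup_layers(tab, atlas$graph, 1L)
  expect_equal(sum(r1$axon_total), sum(tab$axon_total), tolerance = 1e-12)
  # parent totals equal child sums
  mop_children <- graph_descendants(atlas$graph, graph_id(atlas$graph, "MOp"),
                                    include_self = FALSE)
  for (h in c("ipsi", "contra")) {
    expect_equal(
      r1$axon_total[r1$acronym == "MOp" & r1$hemisphere == h],
      sum(tab$axon_total[tab$structure_id %in% mop_children &
                         tab$hemisphere == h]),
      tolerance = 1e-12)
  }
  # rollup(rollup(t,1),1) = rollup(t,2)
  r11 <- rollup_layers(r1, atlas$graph, 1L)
  r2 <- rollup_layers(tab, atlas$graph, 2L)
  expect_equal(r11$axon_total, r2$axon_total, tolerance = 1e-12)
  expect_equal(r11$structure_id, r2$structure_id)
  bad <- tab; bad$structure_id[1] <- 999L
  expect_error(rollup_layers(bad, atlas$graph), "999")
})

test_that("region ranking matches an independent recomputation", {
  atlas <- toy()
  coh <- simulate_injection_cohort(topography_spec(), atlas, 4, seed = 30)
  tabs <- lapply(coh$maps, function(m)
    rollup_layers(quantify_by_region(m, atlas$annotation, atlas$graph,
                                     atlas$frame, "left"), atlas$graph, 1L))
  rk <- rank_regions(tabs, top_n = 75)
  # spreadsheet-style recompute: mean over (groups x hemispheres)
  long <- do.call(rbind, lapply(tabs, as.data.frame))
  long <- long[long$hemisphere %in% c("ipsi", "contra") &
               long$structure_id != 0L, ]
  means <- tapply(long$axon_total, long$acronym, sum) / (2 * length(tabs))
  means <- sort(means, decreasing = TRUE)
  expect_equal(rk$acronym[1], names(means)[1])
  expect_equal(rk$mean_density, as.vector(means[rk$acronym]),
               tolerance = 1e-12)
  expect_true(all(diff(rk$mean_density) <= 1e-12))
  # permutation invariance and deterministic ties
  rk2 <- rank_regions(rev(tabs), top_n = 75)
  expect_equal(rk, rk2)
  # top_n larger than region count returns everything; ties break by acronym
  t1 <- tabs[[1]]
  t1$axon_total[] <- 1
  rk3 <- rank_regions(list(t1), top_n = 1000)
  expect_equal(rk3$acronym, sort(rk3$acronym))
  expect_equal(nrow(rk3), length(unique(t1$acronym[t1$structure_id != 0L])))
})
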