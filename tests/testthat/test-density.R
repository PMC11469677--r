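test_that("coordinate transforms match hand-computed affine products", {
  # identity chain with native voxels equal to atlas voxels
  co <- data.frame(x = c(1L, 10L, 40L), y = c(2L, 5L, 7L), z = c(3L, 8L, 9L))
  out <- transform_coords(co, identity_chain(), native_voxel_size_um = 25)
  expect_equal(unname(out[, 1:3]), unname(as.matrix(co)), ignore_attr = TRUE)
  # +250 um AP translation at 25 um atlas voxels shifts AP index by 10
  tl <- diag(4); tl[1, 4] <- 250
  out2 <- transform_coords(co, transform_chain(affine_transform(tl)), 25)
  expect_equal(out2[, "ap"], co$x + 10)
  # anisotropic scale-only: hand-computed matrix product oracle
  co3 <- data.frame(x = 101L, y = 101L, z = 101L)
  out3 <- transform_coords(co3, identity_chain(),
                           native_voxel_size_um = c(5.3, 5.3, 5),
                           atlas_voxel_size_um = 25)
  # 100 * 5.3 / 25 = 21.2 native steps -> +1 for 1-based indexing
  expect_equal(unname(out3[1, ]), c(22.2, 22.2, 21), tolerance = 1e-12)
  # invertible affine chains are bijective on random point sets
  A <- diag(4); A[1:3, 1:3] <- matrix(c(0.9, 0.1, 0, -0.2, 1.1, 0.05,
                                        0, 0.03, 0.97), 3, 3)
  A[1:3, 4] <- c(120, -40, 60)
  ch <- transform_chain(affine_transform(A))
  set.seed(5)
  pts <- matrix(runif(150, 1, 200), ncol = 3)
  fwd <- transform_coords(pts, ch, 25)
  back <- transform_coords(fwd, invert_chain(ch), 25)
  expect_equal(unname(back[, 1:3]), unname(pts), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("displacement fields interpolate trilinearly and clamp at edges", {
  # constant +50 um offset along AP everywhere
  off <- array(0, dim = c(4, 4, 4, 3)); off[, , , 1] <- 50
  df <- displacement_field(off, spacing_um = c(100, 100, 100))
  ch <- transform_chain(df)
  out <- transform_coords(data.frame(x = 3, y = 2, z = 2), ch,
                          native_voxel_size_um = 25)
  expect_equal(out[1, "ap"], c(ap = 3 + 2), tolerance = 1e-12)
  expect_equal(attr(out, "n_edge_clamped"), 0L)
  # a point outside the grid support is clamped and tallied
  out2 <- transform_coords(data.frame(x = 100, y = 2, z = 2), ch, 25)
  expect_equal(attr(out2, "n_edge_clamped"), 1L)
  expect_equal(out2[1, "ap"], c(ap = 100 + 2), tolerance = 1e-12)
})

test_that("atlas binning conserves counts exactly", {
  atlas <- toy()
  set.seed(7)
  n <- 5000
  co <- cbind(runif(n, 0.51, dim(atlas$annotation$id_grid)[1] + 0.49),
              runif(n, 0.51, dim(atlas$annotation$id_grid)[2] + 0.49),
              runif(n, 0.51, dim(atlas$annotation$id_grid)[3] + 0.49))
  cv <- bin_to_atlas(co, atlas$annotation)
  expect_equal(sum(cv$counts) + cv$out_of_bounds_count, n)
  expect_equal(cv$out_of_bounds_count, 0L)
  # 8 coordinates into one voxel
  cv8 <- bin_to_atlas(matrix(rep(c(10.1, 9.9, 10.2), each = 8) +
                               runif(24, -0.2, 0.2), ncol = 3),
                      atlas$annotation)
  expect_equal(max(cv8$counts), 8L)
  # one coordinate just outside the grid edge
  d <- dim(atlas$annotation$id_grid)
  cv1 <- bin_to_atlas(rbind(c(d[1] + 0.6, 5, 5), c(5, 5, 5)),
                      atlas$annotation)
  expect_equal(cv1$out_of_bounds_count, 1L)
  expect_equal(sum(cv1$counts), 1L)
  # rounding rule: half-up per axis
  cvh <- bin_to_atlas(matrix(c(2.5, 2.49, 3.5, 2, 2, 2, 2, 2, 2), ncol = 3),
                      atlas$annotation)
  expect_equal(which(cvh$counts > 0, arr.ind = TRUE)[, 1],
               sort(c(3L, 2L, 4L)), ignore_attr = TRUE)
})

test_that("per-cell normalization divides exactly and validates n_cells", {
  counts <- array(0L, dim = c(4, 4, 4)); counts[1:10] <- 100L
  cv <- structure(list(counts = counts, out_of_bounds_count = 0L,
                       voxel_size_um = 25), class = "counts_volume")
  dm <- normalize_per_cell(cv, 100)
  expect_equal(sum(dm$data), 10)
  expect_equal(normalize_per_cell(cv, 1)$data, counts * 1.0, ignore_attr = TRUE)
  expect_error(normalize_per_cell(cv, 0), "positive")
})

test_that("injection QC applies the 80 percent inclusion rule at the boundary", {
  atlas <- toy()
  ann <- atlas$annotation
  # a mask fully inside SSp-bfd: fraction 1, center = cube center
  m <- array(FALSE, dim = dim(ann$id_grid))
  m[85:95, 5:9, 35:45] <- TRUE
  qc <- injection_qc(m, ann, atlas$graph)
  expect_equal(qc$fraction_in_targets, 1.0)
  expect_true(qc$included)
  expect_equal(qc$center, c(90, 7, 40))
  expect_equal(qc$volume_mm3, sum(m) * (0.025)^3)
  # constructed fractions exactly at and below the threshold
  base <- which(ann$id_grid == graph_id(atlas$graph, "SSp-bfd2/3"))[1:80]
  outside <- which(ann$id_grid == 0L)[1:20]
  m2 <- array(FALSE, dim = dim(ann$id_grid)); m2[c(base, outside)] <- TRUE
  qc2 <- injection_qc(m2, ann, atlas$graph)
  expect_equal(qc2$fraction_in_targets, 0.8)
  expect_true(qc2$included)   # "at least 80%" is inclusive
  m3 <- array(FALSE, dim = dim(ann$id_grid))
  m3[c(base[1:79], outside)] <- TRUE
  qc3 <- injection_qc(m3, ann, atlas$graph)
  expect_lt(qc3$fraction_in_targets, 0.8)
  expect_false(qc3$included)
  expect_error(injection_qc(array(FALSE, dim(ann$id_grid)), ann,
                            atlas$graph), "empty")
})

test_that("group averages and sum projections are conservative and linear", {
  a <- density_map(array(runif(27), dim = c(3, 3, 3)), n_cells = 10L)
  b <- density_map(array(0, dim = c(3, 3, 3)), n_cells = 20L)
  b$data[1, 1, 1] <- 3
  avg <- group_average(list(a, b))
  expect_equal(sum(avg$data), (sum(a$data) + sum(b$data)) / 2)
  expect_equal(group_average(list(a))$data, a$data)
  expect_error(group_average(list(a, density_map(array(0, dim = c(2, 3, 3))))),
               "mismatch")
  # projections conserve totals; a 125 um slab at 25 um is 5 planes
  x <- array(runif(8 * 6 * 7), dim = c(8, 6, 7))
  expect_equal(sum(sum_projection(x, "DV")), sum(x))
  expect_equal(sum(sum_projection(x, "AP", slab = 2:6)), sum(x[2:6, , ]))
  expect_equal(dim(sum_projection(x, "ML")), c(8, 6))
  imp <- array(0, dim = c(5, 5, 5)); imp[2, 3, 4] <- 1
  pr <- sum_projection(imp, "DV")
  expect_equal(which(pr > 0, arr.ind = TRUE), cbind(row = 2L, col = 4L),
               ignore_attr = TRUE)
  expect_error(sum_projection(x, "AP", slab = 9:10), "out of bounds")
  # project-then-average equals average-then-project
  avg_proj <- sum_projection(avg, "ML")
  proj_avg <- (sum_projection(a, "ML") + sum_projection(b, "ML")) / 2
  expect_equal(avg_proj, proj_avg, tolerance = 1e-9)
})
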