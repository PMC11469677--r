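test_that("weighted skeleton sums per-threshold skeletons scaled by threshold", {
  # an isolated high-probability voxel survives every threshold: weight 4.4
  pv <- array(0, dim = c(9, 9, 9))
  pv[5, 5, 5] <- 0.95
  sk <- weighted_skeleton(pv)
  expect_equal(nrow(sk$voxels), 1L)
  expect_equal(sk$weight, sum(seq(0.2, 0.9, by = 0.1)))
  expect_equal(sk$weight, 4.4)
  # all-zero volume -> empty skeleton, not an error
  empty <- weighted_skeleton(array(0, dim = c(6, 6, 6)))
  expect_equal(nrow(empty$voxels), 0L)
  # invalid thresholds rejected
  expect_error(weighted_skeleton(pv, thresholds = c(0.5, 1.2)), "inside")
  expect_error(weighted_skeleton(pv, thresholds = c(0.5, 0.3)), "increasing")
})

test_that("weighted skeleton equals the brute-force per-threshold oracle", {
  shape <- c(50L, 30L, 30L)
  tr <- axon_truth(
    centerlines = list(cbind(5:45, 10, 10),
                       cbind(5:45, 20, round(seq(8, 22, length.out = 41)))),
    radius = c(1.5, 1), brightness = c(1, 0.85),
    blobs = data.frame(x = 4, y = 4, z = 4, radius = 2.5, intensity = 0.9))
  pv <- simulate_axon_probability(tr, shape, noise_sd = 0.05, seed = 21)
  sk <- weighted_skeleton(pv)
  oracle <- brute_force_weighted(pv)
  dense <- array(0, dim = shape)
  dense[sk$voxels] <- sk$weight
  expect_equal(dense, oracle, tolerance = 1e-12)
  # per-threshold masks are nested
  thr <- seq(0.2, 0.9, by = 0.1)
  for (i in seq_len(length(thr) - 1))
    expect_true(all(which(pv >= thr[i + 1]) %in% which(pv >= thr[i])))
  # weights are subset-sums of the threshold set, bounded by 4.4
  expect_true(all(sk$weight <= 4.4 + 1e-12))
  subset_sums <- unique(as.vector(
    sapply(0:(2^8 - 1), function(m) sum(thr[bitwAnd(m, 2^(0:7)) > 0]))))
  expect_true(all(vapply(sk$weight, function(w)
    any(abs(subset_sums - w) < 1e-9), logical(1))))
})

test_that("skeleton voxels track the true centerline on clean tubes", {
  shape <- c(60L, 24L, 24L)
  tr <- straight_tube_truth(shape, y = 12, z = 12, radius = 1.5)
  pv <- simulate_axon_probability(tr, shape, noise_sd = 0, seed = 1)
  sk <- weighted_skeleton(pv)
  d <- sqrt((sk$voxels[, 2] - 12)^2 + (sk$voxels[, 3] - 12)^2)
  expect_gte(mean(d <= 1), 0.95)
})

test_that("component filtering is strictly 'less than' and idempotent", {
  sk <- snake_skeleton(c(9999L, 10000L))
  expect_equal(unname(sk$component_sizes), c(9999L, 10000L))
  res <- filter_components(sk, min_size = 10000)
  expect_equal(length(res$skeleton$component_sizes), 1L)
  expect_equal(unname(res$skeleton$component_sizes), 10000L)
  expect_equal(nrow(res$report), 2L)
  expect_equal(res$report$kept, c(TRUE, FALSE))  # sorted by descending size
  # idempotent
  again <- filter_components(res$skeleton, min_size = 10000)
  expect_equal(again$skeleton$voxels, res$skeleton$voxels)
  expect_equal(again$skeleton$component, res$skeleton$component)
  # empty skeleton passes through
  e <- axon_skeleton(matrix(integer(0), ncol = 3), numeric(0), integer(0),
                     dim = c(5L, 5L, 5L))
  res_e <- filter_components(e)
  expect_equal(nrow(res_e$skeleton$voxels), 0L)
  expect_equal(nrow(res_e$report), 0L)
  # survivors relabeled by descending size
  sk3 <- snake_skeleton(c(50L, 12000L, 11000L))
  res3 <- filter_components(sk3, min_size = 10000)
  sizes <- res3$skeleton$component_sizes
  expect_equal(unname(sizes[order(as.integer(names(sizes)))]),
               c(12000L, 11000L))
})

test_that("curation drops exactly the requested components", {
  sk <- snake_skeleton(c(300L, 200L, 100L))
  keep_all <- data.frame(component = 1:3, keep = TRUE)
  expect_equal(apply_curation(sk, keep_all)$voxels, sk$voxels)
  dec <- data.frame(component = 2L, keep = FALSE, reason = "artifact")
  cur <- apply_curation(sk, dec)
  expect_equal(nrow(cur$voxels), nrow(sk$voxels) - 200L)
  expect_false(2L %in% cur$component)
  expect_error(apply_curation(sk, data.frame(component = 9L, keep = FALSE)),
               "9")
})

test_that("coordinate lists are unique, sorted and CSV round-trippable", {
  sk <- snake_skeleton(c(500L))
  co <- skeleton_to_coords(sk)
  expect_equal(nrow(co), 500L)
  expect_false(any(duplicated(co[, 1:3])))
  ord <- order(co$x, co$y, co$z)
  expect_equal(ord, seq_len(nrow(co)))
  path <- tempfile(fileext = ".csv")
  write_coords(co, path)
  back <- read_coords(path)
  expect_equal(back$x, co$x)
  expect_equal(back$weight, co$weight)
})
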