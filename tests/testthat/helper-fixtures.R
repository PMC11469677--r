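# shared fixtures and independent oracles, built in code at test time

# minimal 3-node chain graph: root -> A -> A1
chain_graph <- function() {
  structure_graph(data.frame(
    id = c(1L, 2L, 3L),
    acronym = c("root", "A", "A1"),
    name = c("root", "area A", "area A layer 1"),
    parent_id = c(NA, 1L, 2L)))
}

# toy atlas shared across tests (built once; ~1.5M voxels)
toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_atlas()
    cache
  }
})

# independent per-threshold brute-force accumulation: binarize, skeletonize,
# scale, accumulate, with no shared state with weighted_skeleton()
brute_force_weighted <- function(prob, thresholds = seq(0.2, 0.9, by = 0.1)) {
  acc <- array(0, dim = dim(prob))
  for (t in thresholds) {
    mask <- prob >= t
    sk <- skeletonize_mask(mask)
    acc <- acc + as.numeric(t) * (sk * 1)
  }
  acc
}

# direct two-pass Pearson correlation (textbook formula)
brute_force_pearson <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# direct dense convolution with a truncated Gaussian and reflect boundary
brute_force_gaussian3d <- function(x, sigma, truncate = 4) {
  r <- as.integer(ceiling(truncate * sigma))
  w <- dnorm(-r:r, sd = sigma); w <- w / sum(w)
  d <- dim(x)
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    j <- ifelse(j < 0, j + 2L * n, j)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  out <- x
  for (ax in 1:3) {
    nxt <- array(0, dim = d)
    n <- d[ax]
    for (k in -r:r) {
      idx <- refl(seq_len(n) + k, n)
      sl <- switch(ax, out[idx, , , drop = FALSE],
                   out[, idx, , drop = FALSE], out[, , idx, drop = FALSE])
      nxt <- nxt + w[k + r + 1L] * sl
    }
    out <- nxt
  }
  out
}

# skeleton built directly from voxel coordinates (one snake per component)
snake_skeleton <- function(sizes, dim = c(120L, 120L, length(sizes) * 2L)) {
  vox <- NULL; comp <- NULL
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    # boustrophedon path through a 2D plane: consecutive voxels 26-connected
    rows <- ceiling(n / dim[1])
    xy <- do.call(rbind, lapply(seq_len(rows), function(r) {
      xs <- seq_len(dim[1]); if (r %% 2 == 0) xs <- rev(xs)
      cbind(xs, r)
    }))[seq_len(n), , drop = FALSE]
    vox <- rbind(vox, cbind(xy[, 1], xy[, 2], 2L * k - 1L))
    comp <- c(comp, rep(k, n))
  }
  axon_skeleton(vox, weight = rep(0.2, nrow(vox)), component = comp,
                dim = dim)
}
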