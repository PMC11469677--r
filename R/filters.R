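#' Separable Gaussian filtering of 2D/3D arrays
#'
#' Convolves an array with an isotropic Gaussian kernel, one axis at a time.
#' The kernel is truncated at 4 standard deviations and renormalized to unit
#' sum; boundaries are handled by half-sample reflection ("reflect"), which
#' avoids edge attenuation. \code{sigma = 0} returns the input unchanged.
#'
#' @param x numeric array (2D or 3D).
#' @param sigma standard deviation in pixels/voxels.
#' @param truncate kernel half-width in units of sigma (default 4).
#' @return filtered array of the same shape.
#' @export
gaussian_filter <- function(x, sigma, truncate = 4) {
  if (sigma < 0) stopf("sigma must be non-negative")
  if (sigma == 0) return(x)
  r <- as.integer(ceiling(truncate * sigma))
  w <- dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    x <- convolve_axis1(aperm_to_front(x, ax), w, r)
    x <- aperm_from_front(x, ax, d)
  }
  x
}

# reflect (half-sample symmetric) index folding: ... c b a | a b c ... | c b a
reflect_index <- function(i, n) {
  # map arbitrary integer positions onto 1..n
  period <- 2L * n
  j <- ((i - 1L) %% period)
  j <- ifelse(j < 0, j + period, j)
  ifelse(j < n, j + 1L, period - j)
}

# convolve along the first axis of an array flattened to a matrix
convolve_axis1 <- function(x, w, r) {
  d <- dim(x)
  n <- d[1]
  m <- matrix(x, nrow = n)
  padded <- m[reflect_index(seq(1L - r, n + r), n), , drop = FALSE]
  acc <- matrix(0, nrow = n, ncol = ncol(m))
  for (k in seq_along(w)) {
    acc <- acc + w[k] * padded[k:(k + n - 1L), , drop = FALSE]
  }
  array(acc, dim = d)
}

aperm_to_front <- function(x, ax) {
  nd <- length(dim(x))
  if (ax == 1L) return(x)
  aperm(x, c(ax, setdiff(seq_len(nd), ax)))
}

aperm_from_front <- function(x, ax, orig_dim) {
  nd <- length(orig_dim)
  if (ax == 1L) return(x)
  perm <- c(ax, setdiff(seq_len(nd), ax))
  aperm(x, order(perm))
}
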