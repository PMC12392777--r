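# Separable Gaussian convolution on matrices with reflective borders.
#
# The 1-D operator is built as an n x n matrix whose columns each sum to 1
# (out-of-range kernel taps are folded back by reflection), so convolution
# conserves the total exactly - the property the pre-blur step relies on.

conv_matrix_1d <- function(n, sigma_bins) {
  if (sigma_bins <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_bins))
  taps <- (-half):half
  k <- exp(-0.5 * (taps / sigma_bins)^2)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  reflect <- function(idx) {
    # fold about the half-sample borders until inside [1, n]
    while (any(idx < 1 | idx > n)) {
      idx <- ifelse(idx < 1, 1 - idx, idx)
      idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    }
    idx
  }
  for (j in seq_len(n)) {
    idx <- reflect(j + taps)
    for (t in seq_along(idx)) K[idx[t], j] <- K[idx[t], j] + k[t]
  }
  K
}

# 2-D Gaussian blur; sigma in bins, possibly different per axis
gauss_blur2d <- function(mat, sigma_bins) {
  if (length(sigma_bins) == 1L) sigma_bins <- rep(sigma_bins, 2L)
  if (all(sigma_bins <= 0)) return(mat)
  Kr <- conv_matrix_1d(nrow(mat), sigma_bins[1])
  Kc <- conv_matrix_1d(ncol(mat), sigma_bins[2])
  Kr %*% mat %*% t(Kc)
}

# bilinear interpolation of a matrix field sampled at (gx along cols,
# gy along rows); query points clamped to the grid hull
bilinear <- function(M, gy, gx, y, x) {
  ny <- length(gy); nx <- length(gx)
  fy <- (y - gy[1]) / (gy[2] - gy[1])
  fx <- (x - gx[1]) / (gx[2] - gx[1])
  fy <- pmin(pmax(fy, 0), ny - 1 - 1e-9)
  fx <- pmin(pmax(fx, 0), nx - 1 - 1e-9)
  i0 <- floor(fy); j0 <- floor(fx)
  dy <- fy - i0; dx <- fx - j0
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L
  M[cbind(i0, j0)] * (1 - dy) * (1 - dx) +
    M[cbind(i0 + 1L, j0)] * dy * (1 - dx) +
    M[cbind(i0, j0 + 1L)] * (1 - dy) * dx +
    M[cbind(i0 + 1L, j0 + 1L)] * dy * dx
}
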