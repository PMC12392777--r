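#' Rebin a raw projection onto the preconditioned grid
#'
#' Sums raw bins into the enclosing preconditioned pixel, per DOI layer.
#' This is the "no preconditioning" reference path: same pixel size as the
#' deconvolved projections but with all detector pathologies left in.
#'
#' @param raw a `raw_projection`.
#' @return a `precond_projection` (values are plain rebinned counts;
#'   `n_iter = 0`).
#' @export
rebin_to_precond <- function(raw) {
  spec <- raw$spec
  xs <- raw_centers(spec, 2); ys <- raw_centers(spec, 1)
  pc <- pmin(pmax(floor(xs / spec$precond_pitch) + 1L, 1L),
             spec$precond_grid[2])
  pr <- pmin(pmax(floor(ys / spec$precond_pitch) + 1L, 1L),
             spec$precond_grid[1])
  nl <- dim(raw$counts)[1]
  vals <- array(0, c(nl, spec$precond_grid[1], spec$precond_grid[2]))
  for (m in seq_len(nl)) {
    layer <- raw$counts[m, , ]
    agg <- rowsum(layer, pr)
    agg <- t(rowsum(t(agg), pc))
    vals[m, as.integer(rownames(agg)), as.integer(colnames(agg))] <- agg
  }
  structure(list(values = vals, spec = spec, n_iter = 0L,
                 ll_trace = NULL, final_ll = NA_real_,
                 precond_grid = spec$precond_grid,
                 meta = c(raw$meta, list(rebinned = TRUE))),
            class = "precond_projection")
}

#' Autocorrelation of an image or volume at a metric lag
#'
#' Mean-detrended autocorrelation along one axis, evaluated at an arbitrary
#' (non-integer) lag by linear interpolation between the integer-lag
#' autocorrelation values pooled over all lines. Used to detect the
#' anode-pitch square-grid periodicity.
#'
#' @param x 2-D or 3-D numeric array.
#' @param axis axis (1, 2 or 3) along which to correlate.
#' @param lag_mm lag in mm.
#' @param step_mm sample spacing along the axis, mm.
#' @param mask optional logical array: lines are restricted to masked
#'   samples (a line's masked-out samples are dropped).
#' @return the pooled autocorrelation coefficient at the requested lag.
#' @export
autocorrelation_at <- function(x, axis, lag_mm, step_mm, mask = NULL) {
  n <- dim(x)[axis]
  perm <- c(axis, setdiff(seq_along(dim(x)), axis))
  lines <- matrix(aperm(x, perm), nrow = n)
  if (!is.null(mask)) {
    mm <- matrix(aperm(mask, perm), nrow = n)
    keep <- colSums(mm) == n
    lines <- lines[, keep, drop = FALSE]
  }
  lines <- sweep(lines, 2, colMeans(lines))
  acf_at <- function(k) {
    if (k >= n - 1) return(0)
    a <- lines[1:(n - k), , drop = FALSE]
    b <- lines[(k + 1):n, , drop = FALSE]
    den <- sqrt(sum(a * a) * sum(b * b))
    if (den == 0) return(0)
    sum(a * b) / den
  }
  lag <- lag_mm / step_mm
  k0 <- floor(lag); w <- lag - k0
  (1 - w) * acf_at(as.integer(k0)) + w * acf_at(as.integer(k0) + 1L)
}
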