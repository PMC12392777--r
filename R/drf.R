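#' Sheet-beam scan set
#'
#' Bundles the layer-summed raw-grid responses to the two orthogonal scan
#' series: one image `R_a` per preconditioned row `a` (row scans, beam
#' narrow in y) and one image `C_b` per preconditioned column `b` (column
#' scans, narrow in x). Scans are pooled over DOI layers: the distortion
#' pattern is consistent across depths, so a single response serves all
#' layers, and pooling maximizes counting statistics.
#'
#' @param row_scans list of raw-grid matrices, one per preconditioned row.
#' @param col_scans list of raw-grid matrices, one per preconditioned column.
#' @param row_positions,col_positions scan-line centers, mm.
#' @param beam_width beam width, mm.
#' @export
sheet_beam_scan_set <- function(row_scans, col_scans,
                                row_positions, col_positions,
                                beam_width = 0.5) {
  stopifnot(length(row_scans) == length(row_positions),
            length(col_scans) == length(col_positions))
  for (im in c(row_scans, col_scans))
    if (any(im < 0)) stop("scan images must be non-negative")
  structure(list(row_scans = row_scans, col_scans = col_scans,
                 row_positions = row_positions,
                 col_positions = col_positions,
                 beam_width = beam_width),
            class = "sheet_beam_scan_set")
}

#' Build a scan set by running the simulator over both axes
#'
#' Convenience wrapper: scans every preconditioned row and column center
#' with [simulate_sheet_beam_scan()] and pools DOI layers.
#'
#' @inheritParams simulate_sheet_beam_scan
#' @export
simulate_scan_set <- function(spec, beam_width = 0.5, counts_per_position,
                              field = NULL, boundary = NULL, gain = NULL,
                              seed = 1L) {
  ypos <- precond_centers(spec, 1)
  xpos <- precond_centers(spec, 2)
  cols <- simulate_sheet_beam_scan(spec, "x", xpos, beam_width,
                                   counts_per_position, field, boundary,
                                   gain, seed)
  rows <- simulate_sheet_beam_scan(spec, "y", ypos, beam_width,
                                   counts_per_position, field, boundary,
                                   gain, seed + length(xpos))
  sheet_beam_scan_set(lapply(rows, layer_sum), lapply(cols, layer_sum),
                      ypos, xpos, beam_width)
}

#' Outer-product approximation of a pencil-beam response
#'
#' The raw response to a (virtual) pencil beam at the intersection of
#' preconditioned row `a` and column `b` is approximated by the element-wise
#' product of the two sheet-beam responses.
#'
#' @param R_a raw-grid response to the row scan.
#' @param C_b raw-grid response to the column scan.
#' @return non-negative matrix of the same dimensions.
#' @export
outer_product_response <- function(R_a, C_b) {
  if (!all(dim(R_a) == dim(C_b))) stop("scan image shapes do not match")
  R_a * C_b
}

#' Build the detector response function from a sheet-beam scan set
#'
#' Column `l` of the response matrix `P` (dimensions M raw bins by N
#' preconditioned pixels) is the flattened outer-product response for the
#' (row, column) pair of preconditioned pixel `l`; entries below
#' `sparsity_threshold` times the column maximum are zeroed before storage.
#' The sensitivity `s_l` is the column sum of the stored (sparsified) `P`.
#' Response values are stored un-normalized; the uniformity-correction step
#' absorbs the global scale.
#'
#' @param scans a [sheet_beam_scan_set()].
#' @param spec the [detector_spec()] the scans were acquired on.
#' @param sparsity_threshold fraction of each column's maximum below which
#'   entries are dropped.
#' @return object of class `drf_matrix`: sparse `P`
#'   (\code{\link[Matrix]{sparseMatrix}}), sensitivity `s`, grid dims,
#'   logical `active` (`s > 0`) and per-column retained mass.
#' @export
build_drf <- function(scans, spec, sparsity_threshold = 1e-3) {
  nr <- spec$precond_grid[1]; nc <- spec$precond_grid[2]
  if (length(scans$row_scans) != nr || length(scans$col_scans) != nc)
    stop(sprintf("scan set incomplete: need %d row and %d column scans, got %d and %d",
                 nr, nc, length(scans$row_scans), length(scans$col_scans)))
  M <- prod(spec$raw_grid)
  N <- nr * nc
  # precompute the support of each scan to keep the products cheap
  row_sup <- lapply(scans$row_scans, function(im) which(rowSums(im) > 0))
  col_sup <- lapply(scans$col_scans, function(im) which(colSums(im) > 0))
  ii <- vector("list", N); vv <- vector("list", N)
  retained <- numeric(N)
  for (b in seq_len(nc)) {
    C_b <- scans$col_scans[[b]]
    jc <- col_sup[[b]]
    for (a in seq_len(nr)) {
      l <- (b - 1L) * nr + a          # column-major precond index
      jr <- row_sup[[a]]
      if (!length(jr) || !length(jc)) next
      sub <- scans$row_scans[[a]][jr, jc, drop = FALSE] *
        C_b[jr, jc, drop = FALSE]
      mx <- max(sub)
      if (mx <= 0) next
      keep <- which(sub >= sparsity_threshold * mx & sub > 0)
      if (!length(keep)) next
      retained[l] <- sum(sub[keep]) / sum(sub)
      kr <- (keep - 1L) %% length(jr) + 1L
      kc <- (keep - 1L) %/% length(jr) + 1L
      ii[[l]] <- jr[kr] + (jc[kc] - 1L) * spec$raw_grid[1]
      vv[[l]] <- sub[keep]
    }
  }
  nnz <- lengths(ii)
  P <- Matrix::sparseMatrix(
    i = unlist(ii), j = rep.int(seq_len(N), nnz), x = unlist(vv),
    dims = c(M, N))
  s <- compute_sensitivity(P)
  structure(list(P = P, s = s, raw_grid = spec$raw_grid,
                 precond_grid = spec$precond_grid,
                 sparsity_threshold = sparsity_threshold,
                 active = s > 0, retained_mass = retained),
            class = "drf_matrix")
}

#' Sensitivity of a response matrix
#'
#' `s_l` is the column sum of `P`: the (unnormalized) probability that a
#' gamma ray reaching preconditioned pixel `l` is detected anywhere on the
#' raw grid. Columns with `s_l = 0` are inactive pixels.
#'
#' @param P matrix or sparse Matrix, raw bins by preconditioned pixels.
#' @export
compute_sensitivity <- function(P) {
  as.numeric(Matrix::colSums(P))
}

#' Construct a `drf_matrix` from an explicit response matrix
#'
#' Mainly for toy problems and tests.
#'
#' @param P matrix (dense or sparse), M raw bins by N precond pixels.
#' @param raw_grid,precond_grid grid dimensions; defaults treat both as
#'   one-dimensional.
#' @export
drf_from_matrix <- function(P, raw_grid = c(nrow(P), 1L),
                            precond_grid = c(ncol(P), 1L)) {
  P <- methods::as(methods::as(Matrix::Matrix(P, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(P@x < 0)) stop("response matrix must be non-negative")
  s <- compute_sensitivity(P)
  structure(list(P = P, s = s, raw_grid = as.integer(raw_grid),
                 precond_grid = as.integer(precond_grid),
                 sparsity_threshold = 0,
                 active = s > 0, retained_mass = rep(1, ncol(P))),
            class = "drf_matrix")
}

#' @export
print.drf_matrix <- function(x, ...) {
  cat(sprintf("<drf_matrix> %d x %d (raw bins x precond pixels), %d nonzeros, %d inactive pixels\n",
              nrow(x$P), ncol(x$P), Matrix::nnzero(x$P), sum(!x$active)))
  invisible(x)
}
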