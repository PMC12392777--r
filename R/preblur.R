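#' Partition the anode-pixel unit cell into filter regions
#'
#' The pixel-boundary artifact clusters events near anode-cell borders, so
#' different smoothing strengths are applied to the cell interior, the edge
#' bands and the corner patches. The default scheme has three labels:
#' 1 = interior, 2 = edge band, 3 = corner band.
#'
#' @param subbins_per_pixel raw subbins per anode pixel per axis.
#' @param band_width width of the boundary band in subbins (0 collapses the
#'   partition to a single interior region).
#' @return integer label matrix of dim `subbins x subbins` tiling one cell.
#' @export
partition_unit_cell <- function(subbins_per_pixel, band_width = 2L) {
  n <- as.integer(subbins_per_pixel)
  b <- as.integer(band_width)
  stopifnot(n >= 1L, b >= 0L, 2L * b <= n)
  idx <- seq_len(n)
  near <- idx <= b | idx > n - b
  in_x <- matrix(near, n, n, byrow = TRUE)
  in_y <- matrix(near, n, n)
  lab <- matrix(1L, n, n)
  lab[in_x | in_y] <- 2L
  lab[in_x & in_y] <- 3L
  lab
}

# label every raw bin of the detector by its position inside the anode cell:
# 1 interior, 2 edge band, 3 corner band; band half-width in mm
region_labels_full <- function(spec, band_halfwidth_mm) {
  p <- spec$anode_pitch
  xb <- raw_centers(spec, 2); yb <- raw_centers(spec, 1)
  dxb <- pmin(xb %% p, p - xb %% p)
  dyb <- pmin(yb %% p, p - yb %% p)
  in_x <- matrix(dxb <= band_halfwidth_mm, spec$raw_grid[1],
                 spec$raw_grid[2], byrow = TRUE)
  in_y <- matrix(dyb <= band_halfwidth_mm, spec$raw_grid[1], spec$raw_grid[2])
  lab <- matrix(1L, spec$raw_grid[1], spec$raw_grid[2])
  lab[in_x | in_y] <- 2L
  lab[in_x & in_y] <- 3L
  lab
}

#' Region-wise Gaussian blur filter set
#'
#' One Gaussian width per region per DOI layer. Layers differ in artifact
#' strength, so their filters are independent.
#'
#' @param sigma matrix `[layer, region]` of Gaussian sigmas in mm (may be 0).
#' @param band_halfwidth_mm half-width of the boundary band, mm.
#' @param objective optional per-layer objective values from the optimizer.
#' @export
blur_filter_set <- function(sigma, band_halfwidth_mm = 0.2,
                            objective = NULL) {
  sigma <- as.matrix(sigma)
  if (any(sigma < 0)) stop("sigma values must be non-negative")
  structure(list(sigma = sigma, band_halfwidth_mm = band_halfwidth_mm,
                 objective = objective),
            class = "blur_filter_set")
}

# region partition-of-unity weights on the raw grid: indicator masks lightly
# smoothed and renormalized so they sum to 1 everywhere (seamless blending)
region_weights <- function(spec, band_halfwidth_mm, n_regions,
                           seam_sigma_bins = 1) {
  lab <- region_labels_full(spec, band_halfwidth_mm)
  w <- lapply(seq_len(n_regions), function(r)
    gauss_blur2d((lab == r) * 1, seam_sigma_bins))
  tot <- Reduce(`+`, w)
  lapply(w, function(m) m / tot)
}

#' Apply region-wise Gaussian pre-blur to a raw projection
#'
#' For each DOI layer the counts are split by the region partition-of-unity
#' weights, each part is convolved with its region's Gaussian (normalized
#' kernel, reflective borders), and the parts are summed. Total counts are
#' conserved exactly up to floating error.
#'
#' @param A a `raw_projection`.
#' @param filters a [blur_filter_set()].
#' @return a `raw_projection` with real-valued counts.
#' @export
apply_blur <- function(A, filters) {
  spec <- A$spec
  n_regions <- ncol(filters$sigma)
  if (nrow(filters$sigma) != spec$n_layers)
    stop("filter set does not match the projection's layer count")
  w <- region_weights(spec, filters$band_halfwidth_mm, n_regions)
  out <- array(0, dim(A$counts))
  for (m in seq_len(spec$n_layers)) {
    layer <- A$counts[m, , ]
    acc <- matrix(0, nrow(layer), ncol(layer))
    for (r in seq_len(n_regions)) {
      sig_bins <- filters$sigma[m, r] / spec$raw_pitch
      acc <- acc + gauss_blur2d(w[[r]] * layer, sig_bins)
    }
    out[m, , ] <- acc
  }
  res <- A
  res$counts <- out
  res$meta$blurred <- TRUE
  res
}

# indices of complete anode tiles along each axis plus subbin phase
tile_phase <- function(spec) {
  p <- spec$anode_pitch
  phase <- function(axis) {
    cb <- raw_centers(spec, axis)
    cell <- floor(cb / p)
    full <- as.numeric(names(which(table(cell) == max(table(cell)))))
    sub <- floor((cb %% p) / spec$raw_pitch) + 1L
    list(sel = cell %in% full, sub = sub)
  }
  list(y = phase(1), x = phase(2),
       n_sub = max(phase(1)$sub))
}

# fold a detector layer into the anode unit cell: per-subbin mean over all
# complete tiles, normalized by the overall mean. Tile averaging makes the
# template robust to Poisson noise while preserving the systematic
# boundary pattern.
fold_unit_cell <- function(layer, spec) {
  tp <- tile_phase(spec)
  sel <- outer(tp$y$sel, tp$x$sel, "&")
  ys <- tp$y$sub[tp$y$sel]; xs <- tp$x$sub[tp$x$sel]
  sub <- layer[tp$y$sel, tp$x$sel, drop = FALSE]
  tmpl <- rowsum(t(rowsum(sub, ys)), xs)     # x-sub in rows now
  cnt <- rowsum(t(rowsum((sub * 0 + 1), ys)), xs)
  t(tmpl / cnt) / mean(sub)
}

# per-region normalized grand means of the folded template (relative to
# the template mean); regions labeled by distance to the cell boundary
region_grand_means <- function(layer, spec, band_halfwidth_mm) {
  tmpl <- fold_unit_cell(layer, spec)
  n_sub <- nrow(tmpl)
  b <- max(0L, min(round(band_halfwidth_mm / spec$raw_pitch),
                   floor(n_sub / 2)))
  lab <- partition_unit_cell(n_sub, b)
  mu <- tapply(as.numeric(tmpl), as.numeric(lab), mean)
  mu / mean(tmpl)
}

#' Optimize region-wise blur filters on a flood acquisition
#'
#' Per DOI layer, finds the Gaussian widths that flatten the count
#' variation across the anode-cell regions. The blurred flood is folded
#' into the 1.9 mm unit cell (per-subbin mean over all complete anode
#' tiles, which averages Poisson noise away while preserving the
#' systematic boundary pattern); the objective is the variance of the
#' normalized folded template, accumulated per region, plus a small ridge
#' penalty on sigma that prefers the weakest filter achieving flatness.
#' Layers are optimized independently. Bounded quasi-Newton search from
#' several seeded starts; the best objective wins.
#'
#' @param flood a `raw_projection` from a flood acquisition.
#' @param band_halfwidth_mm boundary band half-width, mm.
#' @param n_regions number of regions (3 = interior/edge/corner).
#' @param sigma_bounds `(lower, upper)` bounds on sigma, mm.
#' @param layers layers to optimize (default all).
#' @param n_starts number of seeded restarts.
#' @param ridge weight of the sigma penalty (keeps sigma at the lower bound
#'   when only counting noise, not structure, would be smoothed).
#' @param seed integer seed for the restarts.
#' @return a [blur_filter_set()] with the per-layer objective values.
#' @export
optimize_blur_filters <- function(flood, band_halfwidth_mm = 0.2,
                                  n_regions = 3L,
                                  sigma_bounds = c(0, 0.8),
                                  layers = NULL, n_starts = 3L,
                                  ridge = 3e-3, seed = 1L) {
  spec <- flood$spec
  if (sum(flood$counts) == 0) stop("flood projection is degenerate (all zeros)")
  if (is.null(layers)) layers <- seq_len(spec$n_layers)
  w <- region_weights(spec, band_halfwidth_mm, n_regions)
  n_anode <- prod(floor(precond_span(spec) / spec$anode_pitch))
  sigma <- matrix(0, spec$n_layers, n_regions)
  objective <- rep(NA_real_, spec$n_layers)
  set.seed(as.integer(seed))
  starts <- matrix(stats::runif(n_starts * n_regions, sigma_bounds[1],
                                sigma_bounds[2]), n_starts, n_regions)
  starts[1, ] <- sigma_bounds[1] + 0.1 * diff(sigma_bounds)
  for (m in layers) {
    layer <- flood$counts[m, , ]
    if (mean(layer) * prod(spec$raw_grid) / max(n_anode, 1) < 100)
      warning(sprintf("layer %d flood statistics are low (< 100 counts per anode pixel)", m))
    obj <- function(sig) {
      sig <- pmin(pmax(sig, sigma_bounds[1]), sigma_bounds[2])
      acc <- matrix(0, nrow(layer), ncol(layer))
      for (r in seq_len(n_regions))
        acc <- acc + gauss_blur2d(w[[r]] * layer, sig[r] / spec$raw_pitch)
      tmpl <- fold_unit_cell(acc, spec)
      mean((tmpl - mean(tmpl))^2) / mean(tmpl)^2 +
        ridge * mean((sig / max(sigma_bounds[2], 1e-9))^2)
    }
    best <- NULL
    for (k in seq_len(n_starts)) {
      fit <- stats::optim(starts[k, ], obj, method = "L-BFGS-B",
                          lower = sigma_bounds[1], upper = sigma_bounds[2],
                          control = list(maxit = 60, factr = 1e10))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    sigma[m, ] <- pmin(pmax(best$par, sigma_bounds[1]), sigma_bounds[2])
    objective[m] <- best$value
  }
  blur_filter_set(sigma, band_halfwidth_mm, objective)
}
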