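#' Synthetic detector: distortion field
#'
#' Generates a smooth, seeded 2-D displacement field on the detector plane,
#' emulating the systematic event-positioning distortion of large-volume
#' position-sensitive detectors. The field is low-pass-filtered white noise:
#' node values are i.i.d. Gaussian, smoothed with a Gaussian kernel of width
#' `correlation_length`, then scaled so the RMS displacement magnitude over
#' the detector equals `amplitude`; displacements are clipped at
#' `3 * amplitude`.
#'
#' @param spec a [detector_spec()].
#' @param amplitude target RMS displacement magnitude in mm (0 gives the
#'   identically-zero field).
#' @param correlation_length smoothing length in mm; must be positive.
#' @param seed integer seed; the field is deterministic given the seed.
#' @return object of class `distortion_field` with components `dx`, `dy`
#'   (node matrices, mm), node coordinates and the generating parameters.
#' @export
make_distortion_field <- function(spec, amplitude, correlation_length, seed) {
  if (correlation_length <= 0) stop("correlation_length must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  span <- precond_span(spec)
  h <- correlation_length / 3
  # extend one correlation length beyond the plane so edges are well defined
  gy <- seq(-correlation_length, span[1] + correlation_length, by = h)
  gx <- seq(-correlation_length, span[2] + correlation_length, by = h)
  set.seed(as.integer(seed))
  smooth_noise <- function() {
    z <- matrix(stats::rnorm(length(gy) * length(gx)), length(gy), length(gx))
    gauss_blur2d(z, correlation_length / h)
  }
  dx <- smooth_noise(); dy <- smooth_noise()
  if (amplitude == 0) {
    dx[] <- 0; dy[] <- 0
  } else {
    inside <- outer(gy >= 0 & gy <= span[1], gx >= 0 & gx <= span[2], "&")
    rms <- sqrt(mean(dx[inside]^2 + dy[inside]^2))
    sc <- amplitude / rms
    dx <- dx * sc; dy <- dy * sc
    mag <- sqrt(dx^2 + dy^2)
    over <- mag > 3 * amplitude
    if (any(over)) {
      f <- ifelse(over, 3 * amplitude / mag, 1)
      dx <- dx * f; dy <- dy * f
    }
  }
  structure(list(dx = dx, dy = dy, gy = gy, gx = gx,
                 amplitude = amplitude,
                 correlation_length = correlation_length, seed = seed),
            class = "distortion_field")
}

#' Evaluate a distortion field at detector coordinates
#'
#' @param field a `distortion_field` (or `NULL` for no distortion).
#' @param x,y coordinates in mm (vectors of equal length).
#' @return list with numeric vectors `dx` and `dy` (mm).
#' @export
displacement_at <- function(field, x, y) {
  if (is.null(field)) return(list(dx = numeric(length(x)), dy = numeric(length(x))))
  list(dx = bilinear(field$dx, field$gy, field$gx, y, x),
       dy = bilinear(field$dy, field$gy, field$gx, y, x))
}

#' Synthetic detector: pixel-boundary artifact model
#'
#' Events whose true position falls within `capture_halfwidth` of an
#' anode-pixel boundary are, with probability `misplacement_fraction`,
#' snapped onto the boundary line, reproducing the square-grid clustering
#' pattern seen in flood images of pixelated detectors.
#'
#' @param capture_halfwidth half-width of the band around each boundary, mm.
#' @param misplacement_fraction snap probability in `[0, 1]`.
#' @param grid_pitch anode-pixel pitch, mm.
#' @export
boundary_artifact_model <- function(capture_halfwidth = 0.35,
                                    misplacement_fraction = 0.45,
                                    grid_pitch = 1.9) {
  stopifnot(misplacement_fraction >= 0, misplacement_fraction <= 1,
            capture_halfwidth >= 0, grid_pitch > 0)
  if (capture_halfwidth >= grid_pitch / 2)
    stop("capture_halfwidth must be smaller than half the grid pitch")
  structure(list(capture_halfwidth = capture_halfwidth,
                 misplacement_fraction = misplacement_fraction,
                 grid_pitch = grid_pitch),
            class = "boundary_artifact_model")
}

#' Synthetic detector: multiplicative gain map
#'
#' Smooth per-raw-bin, per-DOI-layer detection-efficiency map with mean
#' exactly 1 per layer. Events are thinned in proportion to the local gain,
#' emulating crystal nonuniformity.
#'
#' @param spec a [detector_spec()].
#' @param sd relative standard deviation of the gain fluctuation.
#' @param correlation_length smoothing length of the fluctuation, mm.
#' @param seed integer seed.
#' @return object of class `gain_map`: array `[layer, row, col]` plus params.
#' @export
make_gain_map <- function(spec, sd = 0.05, correlation_length = 3, seed = 1L) {
  stopifnot(sd >= 0, correlation_length > 0)
  set.seed(as.integer(seed))
  g <- array(1, c(spec$n_layers, spec$raw_grid[1], spec$raw_grid[2]))
  sig_bins <- correlation_length / spec$raw_pitch
  for (m in seq_len(spec$n_layers)) {
    z <- matrix(stats::rnorm(prod(spec$raw_grid)), spec$raw_grid[1], spec$raw_grid[2])
    z <- gauss_blur2d(z, sig_bins)
    z <- z / stats::sd(z)
    layer <- pmax(1 + sd * z, 0)
    g[m, , ] <- layer / mean(layer)
  }
  structure(list(gain = g, sd = sd,
                 correlation_length = correlation_length, seed = seed),
            class = "gain_map")
}

#' Construct a gain map from an explicit array
#'
#' @param spec a [detector_spec()].
#' @param gain array `[layer, row, col]` of non-negative efficiencies.
#' @export
gain_map_from_array <- function(spec, gain) {
  stopifnot(all(dim(gain) == c(spec$n_layers, spec$raw_grid)))
  if (any(gain < 0)) stop("gain values must be non-negative")
  structure(list(gain = gain, sd = NA, correlation_length = NA, seed = NA),
            class = "gain_map")
}

new_raw_projection <- function(spec, counts, energy_window = c(120, 124),
                               meta = list()) {
  structure(list(counts = counts, spec = spec,
                 energy_window = energy_window, meta = meta),
            class = "raw_projection")
}

#' @export
print.raw_projection <- function(x, ...) {
  cat(sprintf("<raw_projection> %d layers x %dx%d bins, %d counts\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$counts)))
  invisible(x)
}

# sample interaction depths (mm from the irradiated front face) and bin them
# into DOI layers; density ~ mu_pe * exp(-mu_total * x) truncated to the
# crystal thickness. Front layer is m = n, anode layer m = 1.
sample_layers <- function(spec, n) {
  L <- spec$n_layers * spec$layer_thickness
  u <- stats::runif(n)
  x <- -log1p(-u * (1 - exp(-spec$mu_total * L))) / spec$mu_total
  m <- spec$n_layers - floor(x / spec$layer_thickness)
  pmax(pmin(m, spec$n_layers), 1L)
}

# core event engine: takes true planar positions, applies pathologies,
# histograms to the raw grid. Callers have already seeded the RNG.
sim_core <- function(spec, x, y, field = NULL, boundary = NULL, gain = NULL,
                     energy_window = c(120, 124), meta = list()) {
  n <- length(x)
  m <- sample_layers(spec, n)
  d <- displacement_at(field, x, y)
  ax <- x + d$dx
  ay <- y + d$dy
  if (!is.null(boundary) && boundary$misplacement_fraction > 0 &&
      boundary$capture_halfwidth > 0) {
    p <- boundary$grid_pitch
    bx <- round(ax / p) * p
    by <- round(ay / p) * p
    inb_x <- abs(ax - bx) <= boundary$capture_halfwidth
    inb_y <- abs(ay - by) <= boundary$capture_halfwidth
    snap <- (inb_x | inb_y) &
      (stats::runif(n) < boundary$misplacement_fraction)
    ax[snap & inb_x] <- bx[snap & inb_x]
    ay[snap & inb_y] <- by[snap & inb_y]
  }
  idx <- raw_bin_index(spec, ax, ay)
  keep <- !is.na(idx$row)
  n_out <- sum(!keep)
  n_rej <- 0L
  if (!is.null(gain)) {
    gmax <- max(gain$gain)
    acc <- rep(FALSE, n)
    ii <- which(keep)
    if (length(ii)) {
      p_acc <- gain$gain[cbind(m[ii], idx$row[ii], idx$col[ii])] / gmax
      acc[ii] <- stats::runif(length(ii)) < p_acc
    }
    n_rej <- sum(keep & !acc)
    keep <- acc
  }
  dims <- c(spec$n_layers, spec$raw_grid[1], spec$raw_grid[2])
  counts <- array(0L, dims)
  if (any(keep)) {
    lin <- m[keep] + dims[1] * (idx$row[keep] - 1L) +
      dims[1] * dims[2] * (idx$col[keep] - 1L)
    counts <- array(tabulate(lin, nbins = prod(dims)), dims)
  }
  meta <- utils::modifyList(
    list(n_generated = n, n_rejected_gain = n_rej, n_out_of_grid = n_out),
    meta)
  new_raw_projection(spec, counts, energy_window, meta)
}

#' Simulate detector events from a planar fluence map
#'
#' Draws `n_events` true interaction positions from `fluence` (an intensity
#' map on the raw grid, uniform within each bin), samples an interaction
#' depth from the exponential-attenuation profile, applies the spatial
#' distortion field, the pixel-boundary snap and gain thinning, then
#' histograms apparent positions on the raw grid.
#'
#' @param spec a [detector_spec()].
#' @param fluence non-negative matrix of dim `raw_grid`; relative intensity.
#' @param n_events number of events to generate.
#' @param field optional [make_distortion_field()] result.
#' @param boundary optional [boundary_artifact_model()].
#' @param gain optional [make_gain_map()] result.
#' @param seed integer seed.
#' @param energy_window keV pair recorded in the output metadata.
#' @return a `raw_projection`; `meta` records the exact event bookkeeping
#'   (`n_generated = sum(counts) + n_rejected_gain + n_out_of_grid`).
#' @export
simulate_events <- function(spec, fluence, n_events, field = NULL,
                            boundary = NULL, gain = NULL, seed = 1L,
                            energy_window = c(120, 124)) {
  stopifnot(n_events >= 0)
  if (!all(dim(fluence) == spec$raw_grid))
    stop("fluence must be a matrix on the raw grid")
  if (any(fluence < 0) || sum(fluence) <= 0)
    stop("fluence must be non-negative with at least one positive entry")
  set.seed(as.integer(seed))
  bins <- sample.int(length(fluence), n_events, replace = TRUE,
                     prob = as.vector(fluence))
  row <- (bins - 1L) %% nrow(fluence) + 1L
  col <- (bins - 1L) %/% nrow(fluence) + 1L
  org <- raw_origin(spec)
  x <- org[2] + (col - 1 + stats::runif(n_events)) * spec$raw_pitch
  y <- org[1] + (row - 1 + stats::runif(n_events)) * spec$raw_pitch
  sim_core(spec, x, y, field, boundary, gain, energy_window,
           meta = list(kind = "events", seed = seed))
}

#' Simulate a pencil-beam acquisition
#'
#' Point fluence at `position` (or a small uniform square spot of side
#' `spot_size`, which emulates illuminating one preconditioned pixel); the
#' resulting histogram directly images the local detector response.
#'
#' @inheritParams simulate_events
#' @param position `(x, y)` in mm; must lie on the preconditioned plane.
#' @param spot_size side of the uniform square spot in mm (0 = ideal
#'   point).
#' @export
simulate_pencil_beam <- function(spec, position, n_events, field = NULL,
                                 boundary = NULL, gain = NULL, seed = 1L,
                                 energy_window = c(120, 124),
                                 spot_size = 0) {
  span <- precond_span(spec)
  if (position[1] < 0 || position[1] > span[2] ||
      position[2] < 0 || position[2] > span[1])
    stop("pencil-beam position lies outside the detector plane")
  set.seed(as.integer(seed))
  x <- rep(position[1], n_events)
  y <- rep(position[2], n_events)
  if (spot_size > 0) {
    x <- x + stats::runif(n_events, -spot_size / 2, spot_size / 2)
    y <- y + stats::runif(n_events, -spot_size / 2, spot_size / 2)
  }
  sim_core(spec, x, y, field, boundary, gain, energy_window,
           meta = list(kind = "pencil", position = position, seed = seed))
}

#' Simulate a flood-field acquisition
#'
#' Uniform irradiation of the preconditioned plane.
#'
#' @inheritParams simulate_events
#' @export
simulate_flood <- function(spec, n_events, field = NULL, boundary = NULL,
                           gain = NULL, seed = 1L,
                           energy_window = c(120, 124)) {
  span <- precond_span(spec)
  set.seed(as.integer(seed))
  x <- stats::runif(n_events, 0, span[2])
  y <- stats::runif(n_events, 0, span[1])
  sim_core(spec, x, y, field, boundary, gain, energy_window,
           meta = list(kind = "flood", seed = seed))
}

#' Simulate a sheet-beam scan set along one axis
#'
#' One acquisition per scan position. The beam is a uniform band of width
#' `beam_width` centered on the scan line: for `axis = "x"` the band is
#' narrow in x (a column scan), for `axis = "y"` narrow in y (a row scan);
#' the perpendicular coordinate is uniform over the plane.
#'
#' @inheritParams simulate_events
#' @param axis `"x"` or `"y"`: the coordinate the scan steps through.
#' @param positions strictly increasing scan-line centers, mm.
#' @param beam_width full beam width, mm; must be positive.
#' @param counts_per_position events per scan position.
#' @return list of `raw_projection`, with attribute `positions`.
#' @export
simulate_sheet_beam_scan <- function(spec, axis = c("x", "y"), positions,
                                     beam_width, counts_per_position,
                                     field = NULL, boundary = NULL,
                                     gain = NULL, seed = 1L,
                                     energy_window = c(120, 124)) {
  axis <- match.arg(axis)
  if (beam_width <= 0) stop("beam_width must be positive")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  span <- precond_span(spec)
  out <- vector("list", length(positions))
  for (k in seq_along(positions)) {
    set.seed(as.integer(seed) + k - 1L)
    narrow <- stats::runif(counts_per_position,
                           positions[k] - beam_width / 2,
                           positions[k] + beam_width / 2)
    if (axis == "x") {
      x <- narrow
      y <- stats::runif(counts_per_position, 0, span[1])
    } else {
      y <- narrow
      x <- stats::runif(counts_per_position, 0, span[2])
    }
    out[[k]] <- sim_core(spec, x, y, field, boundary, gain, energy_window,
                         meta = list(kind = "sheet_scan", axis = axis,
                                     position = positions[k],
                                     seed = seed + k - 1L))
  }
  attr(out, "positions") <- positions
  attr(out, "axis") <- axis
  attr(out, "beam_width") <- beam_width
  out
}

# layer-summed 2-D image of a raw projection
layer_sum <- function(proj) {
  apply(proj$counts, c(2, 3), sum)
}
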