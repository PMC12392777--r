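#' Detector geometry specification
#'
#' Describes the two planar grids of a 3-D position-sensitive detector: the
#' fine *raw* grid on which the subpixel positioning algorithm histograms
#' events, and the coarser *preconditioned* grid onto which raw projections
#' are deconvolved. Depth of interaction (DOI) is discretized into
#' `n_layers` slabs of `layer_thickness` mm; layer `m = 1` sits at the anode
#' (rear) side and layer `m = n_layers` at the irradiated cathode (front)
#' side. Attenuation inside the crystal is characterized by the total and
#' photoelectric linear attenuation coefficients at the working energy.
#'
#' Coordinates are in mm with the origin at the lower-left corner of the
#' preconditioned grid; bins are half-open `[k*w, (k+1)*w)`. The raw grid is
#' centered on the preconditioned grid (their spans need not be equal).
#'
#' @param raw_grid integer pair, raw bins per axis (rows, cols).
#' @param raw_pitch raw bin pitch in mm.
#' @param precond_grid integer pair, preconditioned pixels per axis.
#' @param precond_pitch preconditioned pixel pitch in mm.
#' @param anode_pitch pitch of the coarse anode-pixel readout grid in mm.
#' @param n_layers number of DOI layers.
#' @param layer_thickness thickness of each DOI layer in mm.
#' @param mu_total total linear attenuation coefficient, 1/mm.
#' @param mu_pe photoelectric linear attenuation coefficient, 1/mm.
#' @return an object of class `detector_spec`.
#' @examples
#' spec <- detector_spec()            # full-size detector
#' toy  <- toy_detector_spec(16)      # 16x16 preconditioned toy
#' @export
detector_spec <- function(raw_grid = c(440L, 440L), raw_pitch = 0.095,
                          precond_grid = c(88L, 88L), precond_pitch = 0.5,
                          anode_pitch = 1.9, n_layers = 5L,
                          layer_thickness = 2.0,
                          mu_total = 0.23, mu_pe = 0.18) {
  raw_grid <- as.integer(raw_grid)
  precond_grid <- as.integer(precond_grid)
  if (length(raw_grid) == 1L) raw_grid <- rep(raw_grid, 2L)
  if (length(precond_grid) == 1L) precond_grid <- rep(precond_grid, 2L)
  stopifnot(
    length(raw_grid) == 2L, all(raw_grid >= 1L),
    length(precond_grid) == 2L, all(precond_grid >= 1L),
    raw_pitch > 0, precond_pitch > 0, anode_pitch > 0,
    n_layers >= 1L, layer_thickness > 0
  )
  if (!(mu_total >= mu_pe && mu_pe > 0))
    stop("attenuation coefficients must satisfy mu_total >= mu_pe > 0")
  structure(list(
    raw_grid = raw_grid, raw_pitch = raw_pitch,
    precond_grid = precond_grid, precond_pitch = precond_pitch,
    anode_pitch = anode_pitch, n_layers = as.integer(n_layers),
    layer_thickness = layer_thickness,
    mu_total = mu_total, mu_pe = mu_pe
  ), class = "detector_spec")
}

#' @rdname detector_spec
#' @param n preconditioned pixels per axis of the toy.
#' @param raw_per_precond raw bins per preconditioned pixel per axis.
#' @export
toy_detector_spec <- function(n = 16L, raw_per_precond = 5L, ...) {
  n <- as.integer(n)
  detector_spec(raw_grid = c(n, n) * raw_per_precond,
                raw_pitch = 0.5 / raw_per_precond,
                precond_grid = c(n, n), ...)
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf(
    "<detector_spec> raw %dx%d @ %.3f mm | precond %dx%d @ %.2f mm | %d DOI layers x %.1f mm\n",
    x$raw_grid[1], x$raw_grid[2], x$raw_pitch,
    x$precond_grid[1], x$precond_grid[2], x$precond_pitch,
    x$n_layers, x$layer_thickness))
  cat(sprintf("  anode pitch %.2f mm; mu_total %.3f /mm, mu_pe %.3f /mm\n",
              x$anode_pitch, x$mu_total, x$mu_pe))
  invisible(x)
}

# span of the preconditioned plane (mm), per axis (rows=y, cols=x)
precond_span <- function(spec) spec$precond_grid * spec$precond_pitch

# lower-left corner of the raw grid in detector coordinates: the raw grid is
# centered on the precond grid, whose corner is the origin
raw_origin <- function(spec) {
  (precond_span(spec) - spec$raw_grid * spec$raw_pitch) / 2
}

# bin-center coordinates along one axis: axis 1 = y (rows), 2 = x (cols)
raw_centers <- function(spec, axis) {
  raw_origin(spec)[axis] + (seq_len(spec$raw_grid[axis]) - 0.5) * spec$raw_pitch
}

precond_centers <- function(spec, axis) {
  (seq_len(spec$precond_grid[axis]) - 0.5) * spec$precond_pitch
}

# map continuous (x, y) mm to raw bin indices; NA outside the grid
raw_bin_index <- function(spec, x, y) {
  org <- raw_origin(spec)
  col <- floor((x - org[2]) / spec$raw_pitch) + 1
  row <- floor((y - org[1]) / spec$raw_pitch) + 1
  bad <- col < 1 | col > spec$raw_grid[2] | row < 1 | row > spec$raw_grid[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}
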