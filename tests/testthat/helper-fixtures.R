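# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# 16x16 toy detector with all three pathologies, scans and DRF
toy_ctx <- function() cached("toy_ctx", function() {
  spec <- toy_detector_spec(16)
  field <- make_distortion_field(spec, 0.5, 6, seed = 101)
  boundary <- boundary_artifact_model()
  gain <- make_gain_map(spec, 0.05, 3, seed = 102)
  scans <- simulate_scan_set(spec, 0.5, 20000, field = field,
                             boundary = boundary, gain = gain, seed = 105)
  drf <- build_drf(scans, spec, 1e-3)
  list(spec = spec, field = field, boundary = boundary, gain = gain,
       scans = scans, drf = drf)
})

# distortion-only 16x16 toy (no boundary snap, no gain)
distort_ctx <- function() cached("distort_ctx", function() {
  spec <- toy_detector_spec(16)
  field <- make_distortion_field(spec, 0.5, 6, seed = 7)
  scans <- simulate_scan_set(spec, 0.5, 20000, field = field, seed = 8)
  drf <- build_drf(scans, spec, 1e-3)
  list(spec = spec, field = field, scans = scans, drf = drf)
})

# hand-built separable distortion field: dx depends on x only, dy on y only
separable_field <- function(spec, amp = 0.3) {
  span <- precond_span(spec)
  gy <- seq(-1, span[1] + 1, by = 0.25)
  gx <- seq(-1, span[2] + 1, by = 0.25)
  fx <- amp * sin(2 * pi * gx / span[2])
  fy <- amp * cos(2 * pi * gy / span[1])
  structure(list(dx = matrix(fx, length(gy), length(gx), byrow = TRUE),
                 dy = matrix(fy, length(gy), length(gx)),
                 gy = gy, gx = gx, amplitude = amp,
                 correlation_length = NA, seed = NA),
            class = "distortion_field")
}

# random sparse non-negative toy response matrix with positive column sums
random_toy_drf <- function(M = 40L, N = 12L, seed = 1L, density = 0.3) {
  set.seed(seed)
  P <- matrix(stats::runif(M * N) *
                (stats::runif(M * N) < density), M, N)
  for (l in which(colSums(P) == 0)) P[sample.int(M, 1), l] <- stats::runif(1)
  drf_from_matrix(P)
}

# raw projection filled with given per-layer matrices
raw_from_layers <- function(spec, layers) {
  counts <- array(0, c(spec$n_layers, spec$raw_grid[1], spec$raw_grid[2]))
  for (m in seq_along(layers)) counts[m, , ] <- layers[[m]]
  spectdecon:::new_raw_projection(spec, counts)
}
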