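test_that("distortion field: zero amplitude, determinism, RMS scaling", {
  spec <- toy_detector_spec(16)
  f0 <- make_distortion_field(spec, 0, 5, seed = 1)
  expect_true(all(f0$dx == 0) && all(f0$dy == 0))

  f1 <- make_distortion_field(spec, 0.5, 5, seed = 1)
  f2 <- make_distortion_field(spec, 0.5, 5, seed = 1)
  expect_identical(f1, f2)

  xs <- seq(0.05, 7.95, by = 0.1)
  g <- expand.grid(x = xs, y = xs)
  d <- displacement_at(f1, g$x, g$y)
  rms <- sqrt(mean(d$dx^2 + d$dy^2))
  expect_gt(rms, 0.25)
  expect_lt(rms, 0.75)
  expect_lte(max(sqrt(d$dx^2 + d$dy^2)), 3 * 0.5 + 1e-9)

  expect_error(make_distortion_field(spec, 0.5, 0, seed = 1),
               "correlation_length")
})

test_that("simulate_events: zero events, empty fluence, exact bookkeeping", {
  spec <- toy_detector_spec(8)
  flu <- matrix(1, spec$raw_grid[1], spec$raw_grid[2])
  p0 <- simulate_events(spec, flu, 0, seed = 1)
  expect_true(all(p0$counts == 0))
  expect_error(simulate_events(spec, flu * 0, 10, seed = 1), "positive")

  gain <- make_gain_map(spec, 0.2, 2, seed = 3)
  field <- make_distortion_field(spec, 0.5, 4, seed = 2)
  p <- simulate_events(spec, flu, 50000, field = field, gain = gain, seed = 4)
  expect_identical(p$meta$n_generated,
                   sum(p$counts) + p$meta$n_rejected_gain +
                     p$meta$n_out_of_grid)
})

test_that("depth sampling follows the exponential-attenuation layer fractions", {
  spec <- toy_detector_spec(8)
  flu <- matrix(1, spec$raw_grid[1], spec$raw_grid[2])
  p <- simulate_events(spec, flu, 1e6, seed = 5)
  obs <- apply(p$counts, 1, sum)
  # oracle: numerical integration of the attenuation density per layer
  dens <- function(x) spec$mu_pe * exp(-spec$mu_total * x)
  t <- spec$layer_thickness; n <- spec$n_layers
  ints <- vapply(seq_len(n), function(m)
    stats::integrate(dens, (n - m) * t, (n - m + 1) * t)$value, 0)
  expected <- sum(obs) * ints / sum(ints)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.99, df = n - 1))
})

test_that("boundary artifact produces the 1.9 mm square-grid autocorrelation peak", {
  spec <- toy_detector_spec(16)
  bd <- boundary_artifact_model(0.35, 0.3, 1.9)
  fl <- simulate_flood(spec, 1e6, boundary = bd, seed = 3)
  img <- spectdecon:::layer_sum(fl)
  on_peak <- autocorrelation_at(img, 2, 1.9, spec$raw_pitch)
  off_peak <- autocorrelation_at(img, 2, 1.2, spec$raw_pitch)
  expect_gt(on_peak, 0.3)
  expect_gt(on_peak, off_peak + 0.2)
  # both axes
  expect_gt(autocorrelation_at(img, 1, 1.9, spec$raw_pitch), 0.3)
})

test_that("boundary model validates its parameters", {
  expect_error(boundary_artifact_model(1.0, 0.3, 1.9), "halfwidth")
  expect_error(boundary_artifact_model(0.2, 1.3, 1.9))
})

test_that("sheet-beam scans: geometry, count and band support", {
  spec <- toy_detector_spec(8)
  # full-size detector scans one position per precond pixel per axis
  full <- detector_spec()
  expect_identical(length(precond_centers(full, 1)), 88L)
  expect_equal(diff(precond_centers(full, 1))[1], 0.5)
  expect_identical(2L * length(precond_centers(full, 1)), 176L)

  pos <- precond_centers(spec, 2)
  scans <- simulate_sheet_beam_scan(spec, "x", pos, 0.5, 5000, seed = 2)
  expect_length(scans, length(pos))
  # single clean position: support confined to the band +- one bin
  one <- simulate_sheet_beam_scan(spec, "x", 2.25, 0.5, 5000, seed = 3)[[1]]
  img <- spectdecon:::layer_sum(one)
  hit <- which(colSums(img) > 0)
  xs <- raw_centers(spec, 2)
  expect_true(all(xs[hit] > 2.0 - spec$raw_pitch &
                    xs[hit] < 2.5 + spec$raw_pitch))
  expect_error(simulate_sheet_beam_scan(spec, "x", c(2, 1), 0.5, 10),
               "increasing")
  expect_error(simulate_sheet_beam_scan(spec, "x", 2, 0, 10), "beam_width")
})

test_that("scan centroids track the distortion field", {
  ctx <- distort_ctx()
  spec <- ctx$spec
  pos <- c(2.25, 4.25, 6.25)
  scans <- simulate_sheet_beam_scan(spec, "x", pos, 0.5, 40000,
                                    field = ctx$field, seed = 11)
  xs <- raw_centers(spec, 2)
  dev <- vapply(seq_along(pos), function(k) {
    prof <- colSums(spectdecon:::layer_sum(scans[[k]]))
    sum(prof * xs) / sum(prof) - pos[k]
  }, 0)
  # oracle: band-averaged x-displacement of the field along each scan line
  yy <- seq(0.05, 7.95, by = 0.05)
  expect_dev <- vapply(pos, function(p) {
    mean(displacement_at(ctx$field, rep(p, length(yy)), yy)$dx)
  }, 0)
  rmse <- sqrt(mean((dev - expect_dev)^2))
  expect_lt(rmse, 0.3 * sqrt(mean(expect_dev^2)) + 0.05)
})

test_that("pencil beam: bin placement, displacement lookup, separability", {
  spec <- toy_detector_spec(8)
  p <- simulate_pencil_beam(spec, c(1.62, 2.97), 500, seed = 1)
  img <- spectdecon:::layer_sum(p)
  expect_identical(sum(img > 0), 1L)
  idx <- which(img > 0, arr.ind = TRUE)
  expect_identical(as.integer(idx),
                   c(spectdecon:::raw_bin_index(spec, 1.62, 2.97)$row,
                     spectdecon:::raw_bin_index(spec, 1.62, 2.97)$col))

  field <- make_distortion_field(spec, 0.4, 4, seed = 9)
  d <- displacement_at(field, 2.05, 2.05)
  p2 <- simulate_pencil_beam(spec, c(2.05, 2.05), 2000, field = field,
                             seed = 2)
  wc <- weighting_center(p2)
  expect_lt(abs(wc["x"] - (2.05 + d$dx)), spec$raw_pitch)
  expect_lt(abs(wc["y"] - (2.05 + d$dy)), spec$raw_pitch)

  expect_error(simulate_pencil_beam(spec, c(-1, 2), 10), "outside")

  # separable pathologies: histogram equals outer product of its marginals
  sf <- separable_field(spec, amp = 0.3)
  p3 <- simulate_pencil_beam(spec, c(2.05, 2.05), 2e5, field = sf,
                             seed = 3, spot_size = 0.5)
  img3 <- spectdecon:::layer_sum(p3)
  img3 <- img3 / sum(img3)
  outer_m <- outer(rowSums(img3), colSums(img3))
  expect_lt(max(abs(img3 - outer_m)), 0.02)
})

test_that("flood is Poisson-flat without pathologies", {
  spec <- toy_detector_spec(8)
  fl <- simulate_flood(spec, 4e5, seed = 6)
  img <- spectdecon:::layer_sum(fl)
  # rebin 5x5 for counts, chi-square against a flat mean
  reb <- rebin_to_precond(fl)
  v <- apply(reb$values, c(2, 3), sum)
  chi2 <- sum((v - mean(v))^2 / mean(v))
  expect_lt(chi2, qchisq(0.999, df = length(v) - 1))
})

test_that("gain map has unit mean and thins events proportionally", {
  spec <- toy_detector_spec(8)
  g <- make_gain_map(spec, 0.1, 2, seed = 4)
  expect_equal(mean(g$gain[1, , ]), 1, tolerance = 1e-10)
  expect_true(all(g$gain >= 0))
  # a half-efficiency stripe shows up in the flood at half intensity
  arr <- array(1, c(spec$n_layers, spec$raw_grid))
  arr[, , 11:20] <- 0.5
  gm <- gain_map_from_array(spec, arr)
  fl <- simulate_flood(spec, 4e5, gain = gm, seed = 5)
  img <- spectdecon:::layer_sum(fl)
  ratio <- mean(img[, 11:20]) / mean(img[, 21:40])
  expect_equal(ratio, 0.5, tolerance = 0.05)
})
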