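test_that("layer counts match quadrature and behave in limits", {
  m <- attenuation_model(0.23, 0.18, 2, 5, c0 = 2)
  # closed form vs numerical quadrature
  for (k in 1:5) {
    num <- stats::integrate(function(x) 2 * 0.18 * exp(-0.23 * x),
                            (5 - k) * 2, (5 - k + 1) * 2,
                            rel.tol = 1e-12)$value
    expect_equal(layer_count(m, k), num, tolerance = 1e-10)
  }
  # flat limit: mu_total -> 0 gives c0 * mu_pe * t for every layer
  flat <- attenuation_model(1e-9, 1e-9, 2, 5, c0 = 2)
  expect_equal(layer_count(flat, 1), 2 * 1e-9 * 2, tolerance = 1e-6)
  expect_equal(layer_count(flat, 1), layer_count(flat, 5), tolerance = 1e-12)
  # strictly increasing toward the irradiated front
  expect_true(all(diff(layer_count(m, 1:5)) > 0))
  expect_error(layer_count(m, 6), "range")
})

test_that("layer ratios are normalized, monotone and match integration", {
  m <- attenuation_model(0.23, 0.18, 2, 5)
  expect_identical(layer_ratio(m, 5), 1)
  expect_true(all(diff(layer_ratio(m, 1:5)) > 0))
  # oracle: ratio of numerically integrated layer counts
  num <- vapply(1:5, function(k)
    stats::integrate(function(x) exp(-0.23 * x), (5 - k) * 2,
                     (5 - k + 1) * 2)$value, 0)
  expect_equal(layer_ratio(m, 3), num[3] / num[5], tolerance = 1e-10)
  expect_equal(layer_ratio(m, 3), 0.398, tolerance = 2e-3)
  expect_error(layer_ratio(m, 0), "range")
  # the front-layer normalization cancels in ratio-of-ratios
  unnorm <- function(k) exp(-0.23 * (5 - k) * 2) - exp(-0.23 * (5 - k + 1) * 2)
  for (k in 1:5)
    expect_equal(layer_ratio(m, k) / layer_ratio(m, 5),
                 unnorm(k) / unnorm(5), tolerance = 1e-12)
})

test_that("correction factors: flat flood gives unit factors, stripes invert", {
  # identity-response detector: raw grid coincides with the precond grid
  spec <- detector_spec(raw_grid = c(8, 8), raw_pitch = 0.5,
                        precond_grid = c(8, 8))
  drf <- drf_from_matrix(diag(64), raw_grid = c(8L, 8L),
                         precond_grid = c(8L, 8L))
  model <- attenuation_from_spec(spec)
  ratios <- layer_ratio(model, 1:5)
  base <- 400
  layers <- lapply(1:5, function(mm) matrix(base * ratios[mm], 8, 8))
  flood <- raw_from_layers(spec, layers)
  CF <- compute_correction_factors(flood, drf, blur = NULL, model = model,
                                   n_iter = 40)
  expect_equal(max(abs(CF$CF - 1)), 0, tolerance = 1e-6)

  # halve the flood on one column -> CF doubles there relative to the rest
  layers2 <- lapply(layers, function(l) { l[, 4] <- l[, 4] / 2; l })
  CF2 <- compute_correction_factors(raw_from_layers(spec, layers2), drf,
                                    blur = NULL, model = model, n_iter = 200)
  expect_equal(mean(CF2$CF[5, , 4]) / mean(CF2$CF[5, , c(1:3, 5:8)]), 2,
               tolerance = 1e-6)
  expect_equal(mean(CF2$CF[5, , 1:3]), 1, tolerance = 0.1)
})

test_that("full pipeline with unit factors reduces to blur + deconvolution", {
  ctx <- distort_ctx()
  fl <- simulate_flood(ctx$spec, 3e5, field = ctx$field, seed = 51)
  CF1 <- list(CF = array(1, c(5, 16, 16)))
  class(CF1) <- "correction_factors"
  a <- apply_full_pipeline(fl, ctx$drf, blur = NULL, CF = CF1, n_iter = 10)
  b <- precondition(fl, ctx$drf, n_iter = 10)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("pathology-free pipeline output is statistically plain binning", {
  spec <- toy_detector_spec(8)
  scans <- simulate_scan_set(spec, 0.5, 30000, seed = 52)
  drf <- build_drf(scans, spec, 1e-3)
  fl <- simulate_flood(spec, 5e5, seed = 53)
  pc <- precondition(fl, drf, n_iter = 10)
  reb <- rebin_to_precond(fl)
  # compare the mean-normalized distribution of layer-5 interior pixel
  # values (KS, alpha = 0.01); the response absorbs the scan-derived scale
  inner <- 2:7
  a <- as.numeric(pc$values[5, inner, inner]); a <- a / mean(a)
  b <- as.numeric(reb$values[5, inner, inner]); b <- b / mean(b)
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})
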