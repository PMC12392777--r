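test_that("weighting center: single bin, symmetry, direct formula", {
  img <- matrix(0, 6, 6); img[3, 5] <- 7
  wc <- weighting_center(img, pitch = 0.5)
  expect_equal(unname(wc), c((5 - 0.5) * 0.5, (3 - 0.5) * 0.5))

  sym <- outer(dnorm(seq(-2, 2, length.out = 21)),
               dnorm(seq(-2, 2, length.out = 21)))
  wcs <- weighting_center(sym, pitch = 1)
  expect_equal(unname(wcs), c(10.5, 10.5), tolerance = 1e-9)

  set.seed(3)
  r <- matrix(runif(30), 5, 6)
  wr <- weighting_center(r, pitch = 1)
  xs <- (1:6) - 0.5; ys <- (1:5) - 0.5
  expect_equal(unname(wr["x"]), sum(t(r) * xs) / sum(r), tolerance = 1e-12)
  expect_equal(unname(wr["y"]), sum(r * ys) / sum(r), tolerance = 1e-12)
  expect_error(weighting_center(matrix(0, 3, 3)), "empty")
})

test_that("forward model: axis source, unit magnification, oracle chain", {
  spec <- detector_spec()
  alpha <- default_geometry(90, 90, radius = 0, spec = spec)
  angles <- seq(0, 315, by = 45)
  cen <- forward_centers(alpha, angles, rep(0, 8))
  expect_lt(max(dist(cen)), 1e-9)   # on-axis source: all views identical

  # equal distances: image offset magnitude equals source offset (mag 1)
  alpha6 <- default_geometry(90, 90, radius = 6, spec = spec)
  cen6 <- forward_centers(alpha6, 0, 0)
  cen0 <- forward_centers(alpha, 0, 0)
  expect_equal(sqrt(sum((cen6 - cen0)^2)), 6, tolerance = 1e-9)

  # independent homogeneous-transform implementation
  oracle_centers <- function(alpha, angles, translations) {
    a <- as.numeric(alpha)
    d2r <- function(x) x * pi / 180
    Rx <- function(t) rbind(c(1, 0, 0), c(0, cos(t), -sin(t)),
                            c(0, sin(t), cos(t)))
    Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                            c(0, 0, 1))
    Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                            c(-sin(t), 0, cos(t)))
    Rdet <- Rz(d2r(a[6])) %*% Ry(d2r(a[5])) %*% Rx(d2r(a[4]))
    u <- as.numeric(Rz(d2r(a[11])) %*% Rx(d2r(a[10])) %*% c(0, 1, 0))
    u <- u / sqrt(sum(u^2))
    w0 <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u; w0 <- w0 / sqrt(sum(w0^2))
    wp <- c(u[2] * w0[3] - u[3] * w0[2], u[3] * w0[1] - u[1] * w0[3],
            u[1] * w0[2] - u[2] * w0[1])
    cc <- c(a[12], 0, a[17]); p <- a[7:9]
    v <- a[14:16] / sqrt(sum(a[14:16]^2))
    d0 <- a[1:3]; e1 <- Rdet[, 1]; e2 <- Rdet[, 2]; e3 <- Rdet[, 3]
    t(vapply(seq_along(angles), function(k) {
      th <- d2r(angles[k])
      S <- cc + a[13] * (cos(th) * w0 + sin(th) * wp) + translations[k] * v
      dir <- p - S
      tt <- sum((d0 - p) * e3) / sum(e3 * dir)
      X <- p + tt * dir
      c(sum((X - d0) * e1), sum((X - d0) * e2))
    }, numeric(2)))
  }
  set.seed(11)
  a_rand <- as.numeric(default_geometry(85, 95, 5.5, spec))
  a_rand[c(1:6, 10:12, 17)] <- a_rand[c(1:6, 10:12, 17)] +
    rnorm(10, 0, c(rep(1, 3), rep(2, 3), 1, 1, 1, 1))
  ang <- runif(6, 0, 360); tr <- runif(6, -5, 5)
  expect_equal(forward_centers(geometry_params(a_rand), ang, tr),
               oracle_centers(a_rand, ang, tr), tolerance = 1e-9)
})

test_that("stage-frame equivariance of the forward model", {
  spec <- detector_spec()
  alpha <- default_geometry(90, 90, 6, spec)
  geo <- spectdecon:::parse_geometry(alpha)
  ang <- c(10, 100, 250); tr <- c(-5, 0, 5); delta <- 37
  # rotating the source by delta about the axis equals shifting the angles
  S1 <- spectdecon:::source_positions(geo, ang + delta, tr)
  S0 <- spectdecon:::source_positions(geo, ang, tr)
  off0 <- S0 - geo$c - outer(geo$v, tr)
  S0rot <- spectdecon:::rotate_about(off0, geo$u, delta * pi / 180) +
    geo$c + outer(geo$v, tr)
  expect_equal(S1, S0rot, tolerance = 1e-9)
  # angle periodicity carries through to the projected centers
  expect_equal(forward_centers(alpha, ang, tr),
               forward_centers(alpha, ang + 360, tr), tolerance = 1e-9)
})

tilted_truth <- function(spec) {
  # a rotation axis slightly tilted w.r.t. the detector columns spreads the
  # projection centers in both plane directions, which makes the detector
  # orientation identifiable (with a perfectly aligned axis the centers sit
  # on three rows and a detector tilt about x cannot be distinguished from
  # a plane shift)
  alpha <- default_geometry(90, 90, 6, spec)
  alpha[10] <- 4; alpha[11] <- 3
  v <- c(0.05, 0.99, 0.08)
  alpha[14:16] <- v / sqrt(sum(v^2))
  geometry_params(alpha)
}

test_that("calibration recovers the geometry from 24 noiseless views", {
  spec <- detector_spec()
  alpha <- tilted_truth(spec)
  angles <- rep(seq(0, 315, by = 45), times = 3)
  trans <- rep(c(-10, 0, 10), each = 8)
  centers <- forward_centers(alpha, angles, trans)
  acq <- calibration_acquisition(centers, angles, trans)
  expect_identical(nrow(acq$centers), 24L)

  set.seed(21)
  init <- as.numeric(alpha)
  free <- setdiff(1:19, spectdecon:::default_fixed_components())
  init[free] <- init[free] * (1 + runif(length(free), -0.02, 0.02)) +
    runif(length(free), -0.3, 0.3)
  cal <- calibrate_geometry(acq, geometry_params(init), n_starts = 2,
                            seed = 1)
  expect_identical(length(cal$per_view_residuals), 24L)
  err <- as.numeric(cal$alpha) - as.numeric(alpha)
  expect_lt(max(abs(err[c(1:3, 13, 17)])), 0.05)  # positions, mm
  expect_lt(max(abs(err[4:6])), 0.1)              # orientations, deg
  expect_lt(max(abs(err[14:16])), 2e-3)           # unit direction
  expect_lt(cal$residual_rms, 1e-3)
})

test_that("calibration tolerates measurement noise without bias", {
  spec <- detector_spec()
  alpha <- tilted_truth(spec)
  angles <- rep(seq(0, 315, by = 45), times = 3)
  trans <- rep(c(-10, 0, 10), each = 8)
  centers <- forward_centers(alpha, angles, trans)
  free <- setdiff(1:19, spectdecon:::default_fixed_components())
  set.seed(31)
  n_rep <- 6
  noises <- lapply(seq_len(n_rep), function(r)
    matrix(rnorm(length(centers), 0, 0.1), ncol = 2))
  jitters <- lapply(seq_len(n_rep), function(r)
    rnorm(length(free), 0, 0.2))
  ests <- vapply(seq_len(n_rep), function(r) {
    acq <- calibration_acquisition(centers + noises[[r]], angles, trans)
    init <- as.numeric(alpha)
    init[free] <- init[free] + jitters[[r]]
    cal <- calibrate_geometry(acq, geometry_params(init), n_starts = 2,
                              seed = r)
    c(cal$residual_rms, as.numeric(cal$alpha)[c(1, 2, 13)])
  }, numeric(4))
  expect_lt(mean(ests[1, ]), 0.2)      # residual at the noise scale
  truth <- as.numeric(alpha)[c(1, 2, 13)]
  est <- ests[-1, , drop = FALSE]
  bias <- abs(rowMeans(est) - truth)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(bias < pmax(0.05, 3 * se)))
})

test_that("degenerate acquisitions are rejected", {
  spec <- detector_spec()
  alpha <- default_geometry(90, 90, 6, spec)
  cen <- forward_centers(alpha, c(0, 45, 90), rep(0, 3))
  acq1 <- calibration_acquisition(cen, c(0, 45, 90), rep(0, 3))
  expect_error(calibrate_geometry(acq1, alpha), "axial")
  expect_error(calibration_acquisition(cen, c(0, 45, 361), rep(0, 3)),
               "angles")
})
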