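test_that("log-likelihood matches term-by-term evaluation", {
  # degenerate cases
  P <- diag(4)
  drf <- drf_from_matrix(P)
  expect_identical(log_likelihood(rep(0, 4), rep(0, 4), drf), 0)
  P1 <- matrix(1, 1, 1)
  expect_equal(log_likelihood(1, 1, drf_from_matrix(P1)), -1)

  # random small instance vs direct sum
  toy <- random_toy_drf(25, 6, seed = 3)
  set.seed(4)
  f <- runif(6); fhat <- rpois(25, as.numeric(toy$P %*% f))
  lam <- as.numeric(as.matrix(toy$P) %*% f)
  direct <- sum(ifelse(lam > 0, fhat * log(lam), 0) - lam - lgamma(fhat + 1))
  expect_equal(log_likelihood(f, fhat, toy), direct, tolerance = 1e-12)

  # counts where the model is zero: -Inf, flagged
  P0 <- diag(3); P0[2, 2] <- 0; P0[1, 2] <- 1
  d0 <- drf_from_matrix(P0)
  ll <- log_likelihood(c(0, 1, 0), c(0, 5, 0), d0)
  expect_identical(as.numeric(ll), -Inf)
  expect_identical(attr(ll, "zero_model_bins"), 2L)
})

test_that("MLEM update: identity response, conservation, coverage error", {
  fhat <- c(3, 9, 1, 0, 7)
  drf <- drf_from_matrix(diag(5))
  f1 <- mlem_update(rep(1, 5), fhat, drf)
  expect_equal(f1, fhat)

  toy <- random_toy_drf(40, 12, seed = 5)
  set.seed(6)
  f <- runif(12, 0.1, 2)
  fhat <- rpois(40, as.numeric(toy$P %*% f))
  ft <- rep(sum(fhat) / sum(toy$s), 12)
  for (i in 1:5) {
    ft <- mlem_update(ft, fhat, toy)
    expect_equal(sum(toy$s * ft), sum(fhat), tolerance = 1e-9)
    expect_true(all(ft >= 0))
  }

  P <- diag(3); P[1, 1] <- 0; P[2, 1] <- 1
  bad <- drf_from_matrix(P)
  expect_error(mlem_update(c(0, 1, 1), c(5, 0, 0), bad), "coverage")
})

test_that("log-likelihood is non-decreasing along MLEM iterations", {
  toy <- random_toy_drf(9, 3, seed = 7)
  set.seed(8)
  f_true <- runif(3, 0.5, 3)
  fhat <- rpois(9, as.numeric(toy$P %*% f_true))
  f <- rep(sum(fhat) / sum(toy$s), 3)
  ll <- numeric(50)
  for (t in 1:50) {
    f <- mlem_update(f, fhat, toy)
    ll[t] <- log_likelihood(f, fhat, toy)
  }
  expect_true(all(diff(ll) > -1e-8))
})

test_that("noiseless data reaches the true fluence as a fixed point", {
  toy <- random_toy_drf(30, 8, seed = 9)
  set.seed(10)
  f_true <- runif(8, 0.5, 2)
  fhat <- as.numeric(toy$P %*% f_true)   # noiseless
  f <- rep(sum(fhat) / sum(toy$s), 8)
  for (t in 1:500) f <- mlem_update(f, fhat, toy)
  resid <- sum(abs(as.numeric(toy$P %*% f) - fhat)) / sum(fhat)
  expect_lt(resid, 1e-6)
})

test_that("precondition: iteration count, determinism, masking bookkeeping", {
  ctx <- distort_ctx()
  sb <- simulate_sheet_beam_scan(ctx$spec, "x", 4.25, 0.5, 30000,
                                 field = ctx$field, seed = 41)[[1]]
  p0 <- precondition(sb, ctx$drf, n_iter = 0)
  expect_identical(p0$n_iter, 0L)
  expect_true(all(p0$values[5, , ][matrix(ctx$drf$active, 16, 16)] > 0))

  pa <- precondition(sb, ctx$drf, n_iter = 20)
  pb <- precondition(sb, ctx$drf, n_iter = 20)
  expect_identical(pa$values, pb$values)
  expect_true(all(diff(pa$ll_trace[, 5]) > -1e-6))
  # inactive pixels stay exactly zero
  expect_true(all(pa$values[5, , ][!matrix(ctx$drf$active, 16, 16)] == 0))
})

test_that("deconvolved sheet beam is straight on the preconditioned plane", {
  ctx <- distort_ctx()
  spec <- ctx$spec
  sb <- simulate_sheet_beam_scan(spec, "x", 4.25, 0.5, 50000,
                                 field = ctx$field, seed = 42)[[1]]
  pc <- precondition(sb, ctx$drf, n_iter = 50)
  img <- apply(pc$values, c(2, 3), sum)
  xs <- precond_centers(spec, 2)
  rows <- which(rowSums(img) > 0.2 * max(rowSums(img)))
  cen <- vapply(rows, function(r) sum(img[r, ] * xs) / sum(img[r, ]), 0)
  expect_lt(sd(cen), 0.3 * spec$precond_pitch)
})

test_that("flood through a scan-derived response deconvolves to a flat plane", {
  ctx <- distort_ctx()
  fl <- simulate_flood(ctx$spec, 1e6, field = ctx$field, seed = 43)
  pc <- precondition(fl, ctx$drf, n_iter = 30)
  act <- matrix(ctx$drf$active, 16, 16)
  act[c(1, 16), ] <- FALSE; act[, c(1, 16)] <- FALSE  # edge pixels clip
  cv <- normalized_std(pc$values[5, , ], act)
  mean_counts <- mean(pc$values[5, , ][act])
  poisson_floor <- 1 / sqrt(mean_counts)
  expect_lt(cv, 3 * poisson_floor)
})
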