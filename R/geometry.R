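#' System geometry parameter vector
#'
#' The single-pinhole tomograph is described by a 19-component vector
#' `alpha` in a global frame whose conventions are documented below.
#' Components (mm and degrees):
#'
#' 1-3   detector local-frame origin `d0`
#' 4-6   detector orientation Euler angles (about global x, y, z)
#' 7-9   pinhole position `p`
#' 10-11 rotation-stage axis tilt angles (about x and z; the axis is the
#'       global y direction when both are 0)
#' 12    axis point x-offset: the axis crosses the plane y = 0 at
#'       `(alpha[12], 0, alpha[17])`
#' 13    rotation radius (source offset from the axis)
#' 14-16 translation-stage direction (normalized internally)
#' 17    axis point z-offset (first reserved slot, used as the axis depth)
#' 18-19 reserved, fixed at 0
#'
#' The global frame is anchored by convention (gauge fixing): the axis tilt
#' and x-crossing (components 10, 11, 12) and the pinhole position (7-9)
#' are held fixed during calibration by default, which removes the six
#' rigid-motion degrees of freedom of the setup as a whole; the reserved
#' slots 18-19 are always fixed.
#'
#' @param alpha numeric vector of length 19.
#' @export
geometry_params <- function(alpha) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != 19) stop("alpha must have 19 components")
  structure(alpha, class = "geometry_params")
}

#' @rdname geometry_params
#' @param detector_distance pinhole-to-detector distance, mm.
#' @param object_distance pinhole-to-axis distance, mm.
#' @param radius source rotation radius, mm.
#' @param spec optional [detector_spec()]; when given, the detector origin
#'   is placed so the optical axis hits the center of the precond plane.
#' @export
default_geometry <- function(detector_distance = 90, object_distance = 90,
                             radius = 6, spec = NULL) {
  a <- numeric(19)
  corner <- if (is.null(spec)) c(0, 0) else -rev(precond_span(spec)) / 2
  a[1:3] <- c(corner, -detector_distance)  # detector origin behind the pinhole
  a[7:9] <- c(0, 0, 0)                   # pinhole at the global origin
  a[12] <- 0; a[17] <- object_distance   # axis crosses (0, 0, z_obj)
  a[13] <- radius
  a[14:16] <- c(0, 1, 0)                 # vertical translation stage
  geometry_params(a)
}

deg2rad <- function(d) d * pi / 180

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# Rodrigues rotation of the columns of X (3 x n) about unit axis u
rotate_about <- function(X, u, theta) {
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, uz, -uy, -uz, 0, ux, uy, -ux, 0), 3, 3)
  R <- diag(3) * ct + st * K + (1 - ct) * (u %o% u)
  R %*% X
}

# unpack alpha into frame objects used by the forward model
parse_geometry <- function(alpha) {
  alpha <- as.numeric(alpha)
  Rdet <- rot_z(deg2rad(alpha[6])) %*% rot_y(deg2rad(alpha[5])) %*%
    rot_x(deg2rad(alpha[4]))
  u <- rotate_about(rotate_about(matrix(c(0, 1, 0)), c(1, 0, 0),
                                 deg2rad(alpha[10])),
                    c(0, 0, 1), deg2rad(alpha[11]))[, 1]
  u <- u / sqrt(sum(u^2))
  w0 <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  w0 <- w0 / sqrt(sum(w0^2))
  v <- alpha[14:16]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("translation direction is degenerate")
  list(d0 = alpha[1:3], e1 = Rdet[, 1], e2 = Rdet[, 2], e3 = Rdet[, 3],
       p = alpha[7:9], u = u, w0 = w0, c = c(alpha[12], 0, alpha[17]),
       r = alpha[13], v = v / nv, vnorm = nv)
}

# project global points (3 x n) through the pinhole onto the detector
# plane; returns 2 x n in-plane mm coordinates
pinhole_project <- function(geo, S) {
  dir <- geo$p - S                       # ray directions through the pinhole
  denom <- as.numeric(crossprod(geo$e3, dir))
  tnum <- sum((geo$d0 - geo$p) * geo$e3)
  tt <- tnum / denom
  X <- geo$p + sweep(dir, 2, tt, "*")
  rel <- X - geo$d0
  rbind(as.numeric(crossprod(geo$e1, rel)), as.numeric(crossprod(geo$e2, rel)))
}

# global source positions for given stage angles (deg) and translations (mm)
source_positions <- function(geo, angles, translations) {
  th <- deg2rad(angles)
  w_perp <- c(geo$u[2] * geo$w0[3] - geo$u[3] * geo$w0[2],
              geo$u[3] * geo$w0[1] - geo$u[1] * geo$w0[3],
              geo$u[1] * geo$w0[2] - geo$u[2] * geo$w0[1])
  S <- geo$c + geo$r * (outer(geo$w0, cos(th)) + outer(w_perp, sin(th)))
  S + outer(geo$v, translations)
}

#' Predict point-source projection centers
#'
#' Places the calibration point source at each (rotation angle, axial
#' translation) pose and projects it through the pinhole onto the detector
#' plane, returning in-plane (x, y) coordinates in mm on the preconditioned
#' plane.
#'
#' @param alpha a [geometry_params()] vector.
#' @param angles rotation angles, degrees (one per view).
#' @param translations axial stage translations, mm (one per view).
#' @param source_offset optional override of the rotation radius, mm.
#' @return matrix `n_views x 2` of predicted centers.
#' @export
forward_centers <- function(alpha, angles, translations,
                            source_offset = NULL) {
  stopifnot(length(angles) == length(translations))
  geo <- parse_geometry(alpha)
  if (!is.null(source_offset)) geo$r <- source_offset
  S <- source_positions(geo, angles, translations)
  t(pinhole_project(geo, S))
}

#' Intensity-weighted center of a projection
#'
#' Layer-summed intensity-weighted centroid, in mm on the projection's
#' plane (preconditioned plane for `precond_projection`, raw plane for
#' `raw_projection`).
#'
#' @param proj a `raw_projection`, `precond_projection`, or a matrix (then
#'   `pitch`/`origin` locate the bins).
#' @param pitch,origin bin geometry when `proj` is a bare matrix.
#' @return numeric `(x, y)` in mm.
#' @export
weighting_center <- function(proj, pitch = 1, origin = c(0, 0)) {
  if (inherits(proj, "raw_projection")) {
    img <- layer_sum(proj)
    xs <- raw_centers(proj$spec, 2); ys <- raw_centers(proj$spec, 1)
  } else if (inherits(proj, "precond_projection")) {
    img <- apply(proj$values, c(2, 3), sum)
    xs <- precond_centers(proj$spec, 2); ys <- precond_centers(proj$spec, 1)
  } else {
    img <- proj
    xs <- origin[1] + (seq_len(ncol(img)) - 0.5) * pitch
    ys <- origin[2] + (seq_len(nrow(img)) - 0.5) * pitch
  }
  tot <- sum(img)
  if (tot <= 0) stop("cannot take the weighting center of an empty image")
  c(x = sum(colSums(img) * xs) / tot, y = sum(rowSums(img) * ys) / tot)
}

#' Calibration acquisition
#'
#' Measured weighting centers of the point-source projections with their
#' known stage poses.
#'
#' @param centers matrix `n_views x 2` of measured centers, mm.
#' @param angles rotation angles, degrees, in `[0, 360)`.
#' @param translations axial translations, mm.
#' @param counts optional per-view total counts.
#' @export
calibration_acquisition <- function(centers, angles, translations,
                                    counts = NULL) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, nrow(centers) == length(angles),
            length(angles) == length(translations))
  if (any(angles < 0 | angles >= 360))
    stop("angles must lie in [0, 360)")
  structure(list(centers = centers, angles = angles,
                 translations = translations, counts = counts),
            class = "calibration_acquisition")
}

# default gauge-fixed / reserved components (see geometry_params docs)
default_fixed_components <- function() c(7L, 8L, 9L, 10L, 11L, 12L, 18L, 19L)

#' Calibrate the system geometry from point-source projections
#'
#' Minimizes the squared discrepancy between measured and predicted
#' weighting centers over the free components of `alpha`, under box bounds,
#' with several seeded multi-starts (the landscape has local minima when
#' the initial guess is poor). A small penalty pins the translation-stage
#' direction to unit norm, removing its scale redundancy.
#'
#' @param acq a [calibration_acquisition()].
#' @param init initial [geometry_params()] guess.
#' @param bounds optional `19 x 2` matrix of lower/upper bounds (default:
#'   init +/- 20 mm or +/- 10 degrees).
#' @param fixed indices of `alpha` held at `init` (default: the gauge and
#'   reserved components).
#' @param n_starts number of seeded restarts.
#' @param seed integer seed for the restart jitter.
#' @return list: `alpha` (the estimate), `residual_rms` (mm),
#'   `per_view_residuals`, `objective`, `convergence`, `fixed`.
#' @export
calibrate_geometry <- function(acq, init, bounds = NULL,
                               fixed = default_fixed_components(),
                               n_starts = 8L, seed = 1L) {
  n_views <- nrow(acq$centers)
  free <- setdiff(seq_len(19L), fixed)
  if (length(unique(acq$translations)) < 2 ||
      length(unique(acq$angles)) < 3)
    stop("acquisition must span >= 2 axial positions and >= 3 angles")
  if (2 * n_views < length(free))
    stop("fewer measurements than free parameters")
  init <- as.numeric(init)
  if (is.null(bounds)) {
    half <- ifelse(seq_len(19L) %in% c(4:6, 10:11), 10, 20)
    bounds <- cbind(init - half, init + half)
  }
  residual <- function(par) {
    a <- init; a[free] <- par
    pred <- tryCatch(forward_centers(a, acq$angles, acq$translations),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred)))
      return(rep(1e6, 2 * n_views + 1))
    nv <- sqrt(sum(a[14:16]^2))
    c(as.numeric(pred - acq$centers), 0.1 * (nv - 1))
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (k in seq_len(n_starts)) {
    start <- init[free]
    if (k > 1) {
      jitter <- 0.02 * (k - 1) / (n_starts - 1) *
        (bounds[free, 2] - bounds[free, 1])
      start <- start + stats::rnorm(length(free), 0, jitter)
      start <- pmin(pmax(start, bounds[free, 1]), bounds[free, 2])
    }
    fit <- minpack.lm::nls.lm(start, lower = bounds[free, 1],
                              upper = bounds[free, 2], fn = residual,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-15,
                                ptol = 1e-15, gtol = 0))
    fit$value <- sum(fit$fvec^2)
    better <- is.null(best) || fit$value < best$value - 1e-12 ||
      (abs(fit$value - best$value) <= 1e-12 &&
         sum(fit$par^2) < sum(best$par^2))
    if (better) best <- fit
  }
  alpha_hat <- init; alpha_hat[free] <- best$par
  alpha_hat[14:16] <- alpha_hat[14:16] / sqrt(sum(alpha_hat[14:16]^2))
  pred <- forward_centers(alpha_hat, acq$angles, acq$translations)
  res <- sqrt(rowSums((pred - acq$centers)^2))
  list(alpha = geometry_params(alpha_hat),
       residual_rms = sqrt(mean(res^2)),
       per_view_residuals = res,
       objective = best$value,
       convergence = best$info,
       fixed = fixed)
}
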