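#' Source voxel grid
#'
#' Cubic voxel grid carrying the activity distribution `Q`, defined in the
#' rotation-stage frame (x, y in the rotation plane, z along the rotation
#' axis) and centered on the axis.
#'
#' @param dim integer triple of voxel counts (default `c(64, 64, 64)`).
#' @param voxel voxel size, mm (default 0.5).
#' @param Q optional non-negative activity array of dim `dim`.
#' @export
source_grid <- function(dim = c(64L, 64L, 64L), voxel = 0.5, Q = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel > 0)
  if (is.null(Q)) Q <- array(0, dim)
  if (any(Q < 0)) stop("activity must be non-negative")
  stopifnot(all(dim(Q) == dim))
  structure(list(Q = Q, dim = dim, voxel = voxel), class = "source_grid")
}

# stage-frame voxel center coordinates, 3 x n_vox (grid centered on origin)
voxel_centers <- function(sg) {
  ax <- lapply(sg$dim, function(n) (seq_len(n) - (n + 1) / 2) * sg$voxel)
  g <- expand.grid(ix = ax[[1]], iy = ax[[2]], iz = ax[[3]])
  t(as.matrix(g))
}

#' Digital rod/sphere phantom
#'
#' Uniform cylinder of activity (axis along the stage z axis) with optional
#' cold rods drilled through it; a synthetic stand-in for a physical
#' image-quality phantom.
#'
#' @param dim,voxel grid geometry, as in [source_grid()].
#' @param radius cylinder radius, mm.
#' @param hole_centers matrix `k x 2` of rod (x, y) centers, mm.
#' @param hole_radius rod radius, mm.
#' @param value activity in the warm background.
#' @export
digital_rod_phantom <- function(dim = c(32L, 32L, 12L), voxel = 0.5,
                                radius = 6, hole_centers = NULL,
                                hole_radius = 1, value = 1) {
  sg <- source_grid(dim, voxel)
  ax <- lapply(sg$dim, function(n) (seq_len(n) - (n + 1) / 2) * voxel)
  X <- outer(ax[[1]], rep(1, dim[2])); Y <- outer(rep(1, dim[1]), ax[[2]])
  slice <- (X^2 + Y^2 <= radius^2) * value
  if (!is.null(hole_centers)) {
    hole_centers <- as.matrix(hole_centers)
    for (k in seq_len(nrow(hole_centers)))
      slice[(X - hole_centers[k, 1])^2 + (Y - hole_centers[k, 2])^2 <=
              hole_radius^2] <- 0
  }
  for (iz in seq_len(dim[3])) sg$Q[, , iz] <- slice
  sg
}

#' Voxel-driven system response for a pinhole tomograph
#'
#' For every source voxel and view angle, rotates the voxel center with the
#' stage, projects it through the pinhole onto the detector plane, and
#' deposits a Gaussian aperture footprint on the preconditioned grid,
#' weighted by the inverse-square distance and the incidence cosine. The
#' response is distributed over DOI layers with the normalized
#' exponential-attenuation layer fractions. Detector voxels are ordered
#' layer-fastest, matching `as.vector()` of a `precond_projection`'s
#' `values` array.
#'
#' @param alpha a [geometry_params()] vector (typically calibrated).
#' @param spec a [detector_spec()].
#' @param angles view angles, degrees.
#' @param sg a [source_grid()] (only its geometry is used).
#' @param model an [attenuation_model()]; default from `spec`.
#' @param pinhole_diameter aperture diameter, mm.
#' @param translations per-view axial translations, mm (default 0).
#' @param footprint half-width of the deposited footprint in precond
#'   pixels.
#' @return object of class `system_response`: list `A` of per-view sparse
#'   matrices (detector-voxels x source-voxels), sensitivity `g`, and the
#'   geometry actually used. Voxels never seen by any view have `g = 0`
#'   and are flagged in `outside_fov`.
#' @export
build_srf <- function(alpha, spec, angles, sg, model = NULL,
                      pinhole_diameter = 1, translations = NULL,
                      footprint = 1L) {
  if (is.null(model)) model <- attenuation_from_spec(spec)
  if (is.null(translations)) translations <- rep(0, length(angles))
  stopifnot(length(translations) == length(angles))
  geo <- parse_geometry(alpha)
  frac <- layer_count(model, seq_len(model$n))
  frac <- frac / sum(frac)
  nl <- model$n
  nr <- spec$precond_grid[1]; nc <- spec$precond_grid[2]
  Npix <- nr * nc
  V <- voxel_centers(sg)
  n_vox <- ncol(V)
  w_perp <- c(geo$u[2] * geo$w0[3] - geo$u[3] * geo$w0[2],
              geo$u[3] * geo$w0[1] - geo$u[1] * geo$w0[3],
              geo$u[1] * geo$w0[2] - geo$u[2] * geo$w0[1])
  B <- cbind(geo$w0, w_perp, geo$u)     # stage frame -> global
  offs <- as.matrix(expand.grid(dr = -footprint:footprint,
                                dc = -footprint:footprint))
  A <- vector("list", length(angles))
  g <- numeric(n_vox)
  # detector-plane offset: alpha d0 is the plane anchor; precond-plane
  # coordinates are measured from the plane's lower-left corner, i.e. the
  # in-plane projection already is in precond mm
  for (k in seq_along(angles)) {
    th <- deg2rad(angles[k])
    Vg <- geo$c + rotate_about(B %*% V, geo$u, th) +
      outer(geo$v, rep(translations[k], n_vox))
    uv <- pinhole_project(geo, Vg)
    d2 <- colSums((Vg - geo$p)^2)
    ray <- geo$p - Vg
    cosi <- abs(as.numeric(crossprod(geo$e3, ray))) / sqrt(colSums(ray^2))
    wgt <- cosi^3 / d2
    # magnification-projected aperture blur (FWHM = D * (mag + 1) / 2)
    ddet <- abs(sum((geo$p - geo$d0) * geo$e3))
    mag <- ddet / pmax(sqrt(d2), 1e-6)
    sig <- pinhole_diameter * (mag + 1) / 2 / (2 * sqrt(2 * log(2)))
    # nearest precond pixel of the projection point
    pc <- uv[1, ] / spec$precond_pitch + 0.5   # fractional col index
    pr <- uv[2, ] / spec$precond_pitch + 0.5   # fractional row index
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    base_r <- floor(pr + 0.5); base_c <- floor(pc + 0.5)
    for (o in seq_len(nrow(offs))) {
      r <- base_r + offs[o, 1]; cc <- base_c + offs[o, 2]
      inside <- r >= 1 & r <= nr & cc >= 1 & cc <= nc
      if (!any(inside)) next
      dist2 <- ((r - pr) * spec$precond_pitch)^2 +
        ((cc - pc) * spec$precond_pitch)^2
      wk <- exp(-0.5 * dist2 / sig^2) * wgt
      sel <- which(inside & wk > 0)
      if (!length(sel)) next
      ii <- c(ii, (r[sel] - 1L) + (cc[sel] - 1L) * nr)
      jj <- c(jj, sel)
      xx <- c(xx, wk[sel])
    }
    # expand over DOI layers, layer index fastest
    nrep <- length(ii)
    li <- rep(seq_len(nl), times = nrep)
    ii_full <- rep(ii, each = nl) * nl + li
    jj_full <- rep(jj, each = nl)
    xx_full <- rep(xx, each = nl) * frac[li]
    A[[k]] <- Matrix::sparseMatrix(i = ii_full, j = jj_full, x = xx_full,
                                   dims = c(Npix * nl, n_vox))
    g <- g + as.numeric(Matrix::colSums(A[[k]]))
  }
  structure(list(A = A, g = g, angles = angles,
                 translations = translations, alpha = alpha, spec = spec,
                 sg_dim = sg$dim, voxel = sg$voxel, model = model,
                 pinhole_diameter = pinhole_diameter,
                 outside_fov = g == 0),
            class = "system_response")
}

#' @export
print.system_response <- function(x, ...) {
  cat(sprintf("<system_response> %d views, %d detector-voxels x %d source-voxels, %d voxels outside FOV\n",
              length(x$A), nrow(x$A[[1]]), ncol(x$A[[1]]),
              sum(x$outside_fov)))
  invisible(x)
}

# forward-project a source grid through the SRF: expected counts per view
# as arrays [layer, precond row, precond col]
project_views <- function(sg, srf) {
  q <- as.numeric(sg$Q)
  nl <- srf$model$n
  nr <- srf$spec$precond_grid[1]; nc <- srf$spec$precond_grid[2]
  lapply(srf$A, function(Ak)
    array(as.numeric(Ak %*% q), c(nl, nr, nc)))
}

#' MLEM tomographic reconstruction
#'
#' Joint MLEM over all views: `Q_l <- (Q_l / g_l) * sum_jk a_jl D_j /
#' (A Q)_j`, with data bins the model cannot see (forward projection 0)
#' ignored. Deterministic; activity stays non-negative and voxels outside
#' the field of view stay 0.
#'
#' @param views list of `precond_projection` objects (or arrays
#'   `[layer, row, col]`), one per view, ordered as `srf$angles`.
#' @param srf a [build_srf()] result.
#' @param n_iter number of iterations.
#' @param snapshots optional integer vector of iterations at which to store
#'   intermediate volumes (returned in attribute `snapshots`, a named list
#'   of activity arrays), e.g. to match iterations across series by
#'   resolution.
#' @return a [source_grid()] with attributes `ll_trace` (Poisson
#'   log-likelihood per iteration, up to data-factorial constants) and
#'   `n_iter`.
#' @export
mlem_reconstruct <- function(views, srf, n_iter = 15L, snapshots = NULL) {
  stopifnot(length(views) == length(srf$A))
  D <- lapply(views, function(v) {
    if (inherits(v, "precond_projection")) as.numeric(v$values)
    else as.numeric(v)
  })
  n_vox <- ncol(srf$A[[1]])
  q <- numeric(n_vox)
  tot <- sum(unlist(D))
  act <- !srf$outside_fov
  q[act] <- if (tot > 0) tot / sum(srf$g[act]) else 0
  ll <- numeric(n_iter)
  snaps <- list()
  if (tot > 0 && n_iter > 0) for (t in seq_len(n_iter)) {
    back <- numeric(n_vox)
    llt <- 0
    for (k in seq_along(srf$A)) {
      lam <- as.numeric(srf$A[[k]] %*% q)
      pos <- lam > 0
      ratio <- numeric(length(lam))
      ratio[pos] <- D[[k]][pos] / lam[pos]
      back <- back + as.numeric(Matrix::crossprod(srf$A[[k]], ratio))
      llt <- llt + sum(D[[k]][pos] * log(lam[pos])) - sum(lam)
    }
    qn <- numeric(n_vox)
    qn[act] <- q[act] / srf$g[act] * back[act]
    q <- qn
    ll[t] <- llt
    if (t %in% snapshots)
      snaps[[as.character(t)]] <- array(q, srf$sg_dim)
  }
  out <- source_grid(srf$sg_dim, srf$voxel,
                     array(q, srf$sg_dim))
  attr(out, "ll_trace") <- ll
  attr(out, "n_iter") <- n_iter
  if (length(snaps)) attr(out, "snapshots") <- snaps
  out
}

#' Match iterations across two reconstruction series by rod resolution
#'
#' Given fitted rod FWHMs along two iteration series, selects for each
#' series the iteration whose FWHM is closest to the target, so images at
#' comparable resolution are compared.
#'
#' @param fwhm_a,fwhm_b numeric vectors of fitted rod FWHM per iteration
#'   (mm); `NA` marks iterations where the rods could not be fitted.
#' @param rod_fwhm_target target FWHM, mm.
#' @return integer pair `(iteration_a, iteration_b)`.
#' @export
match_iterations_by_resolution <- function(fwhm_a, fwhm_b,
                                           rod_fwhm_target) {
  pick <- function(f) {
    if (all(is.na(f))) stop("no iteration has a fitted rod FWHM")
    which.min(abs(f - rod_fwhm_target))
  }
  c(pick(fwhm_a), pick(fwhm_b))
}

#' Simulate a multi-angle pinhole acquisition of a phantom
#'
#' Forward-projects the phantom through an ideal system response to obtain
#' per-view expected fluence on the preconditioned plane, upsamples it to
#' the raw grid, and runs the event simulator with the requested detector
#' pathologies. The per-view event count is Poisson around
#' `events_per_view`.
#'
#' @param spec a [detector_spec()].
#' @param sg phantom [source_grid()].
#' @param srf ideal [build_srf()] for the acquisition geometry.
#' @param events_per_view expected detected events per view.
#' @inheritParams simulate_events
#' @return list of `raw_projection`, one per view.
#' @export
simulate_pinhole_acquisition <- function(spec, sg, srf, events_per_view,
                                         field = NULL, boundary = NULL,
                                         gain = NULL, seed = 1L,
                                         energy_window = c(136, 144)) {
  lam <- project_views(sg, srf)
  # map each raw bin to its enclosing precond pixel for upsampling
  xs <- raw_centers(spec, 2); ys <- raw_centers(spec, 1)
  pc <- pmin(pmax(floor(xs / spec$precond_pitch) + 1L, 1L),
             spec$precond_grid[2])
  pr <- pmin(pmax(floor(ys / spec$precond_pitch) + 1L, 1L),
             spec$precond_grid[1])
  out <- vector("list", length(lam))
  for (k in seq_along(lam)) {
    img <- apply(lam[[k]], c(2, 3), sum)
    fluence <- img[pr, pc]
    set.seed(as.integer(seed) + 1000L + k)
    nk <- stats::rpois(1, events_per_view)
    out[[k]] <- simulate_events(spec, fluence, nk, field, boundary, gain,
                                seed = seed + k, energy_window = energy_window)
  }
  out
}
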