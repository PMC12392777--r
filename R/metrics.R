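# local extrema of a 1-D profile; plateaus collapse to their center
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- sign(diff(v))
  # carry the last nonzero slope through plateaus
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  turn <- diff(d)
  list(max = which(turn < 0) + 1L, min = which(turn > 0) + 1L)
}

#' Fit multi-Gaussian line profiles
#'
#' Collapses a 2-D image onto one axis and fits a sum of `expected_peaks`
#' Gaussians plus a constant baseline by nonlinear least squares. Peaks are
#' seeded from smoothed local maxima; an error lists the detected peaks if
#' fewer than requested are found.
#'
#' @param image 2-D array of counts.
#' @param axis `"x"` (profile along columns) or `"y"` (along rows).
#' @param expected_peaks number of Gaussians to fit.
#' @param pitch bin pitch along the profile, mm.
#' @param origin coordinate of the lower edge of the first bin, mm.
#' @return data.frame with one row per peak, sorted by position: `centroid`
#'   (mm), `fwhm` (mm), `amplitude`, `residual` (RMS of the fit residuals,
#'   identical across rows).
#' @export
fit_line_profiles <- function(image, axis = c("x", "y"), expected_peaks,
                              pitch = 1, origin = 0) {
  axis <- match.arg(axis)
  prof <- if (axis == "x") colSums(image) else rowSums(image)
  pos <- origin + (seq_along(prof) - 0.5) * pitch
  fit_profile_peaks(prof, pos, expected_peaks)
}

#' @rdname fit_line_profiles
#' @param profile 1-D numeric profile.
#' @param positions bin-center coordinates of the profile, mm.
#' @export
fit_profile_peaks <- function(profile, positions, expected_peaks) {
  sm <- stats::filter(profile, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- profile[is.na(sm)]
  ex <- local_extrema(as.numeric(sm))
  cand <- ex$max[order(sm[ex$max], decreasing = TRUE)]
  # enforce a minimal separation between seeds
  sel <- integer(0)
  min_sep <- max(2, length(profile) / (6 * expected_peaks))
  for (i in cand) {
    if (all(abs(i - sel) >= min_sep)) sel <- c(sel, i)
    if (length(sel) == expected_peaks) break
  }
  if (length(sel) < expected_peaks)
    stop(sprintf("found %d peak(s) at {%s} but expected %d",
                 length(sel),
                 paste(signif(positions[sel], 4), collapse = ", "),
                 expected_peaks))
  sel <- sort(sel)
  pitch <- stats::median(diff(positions))
  base0 <- stats::quantile(profile, 0.1, names = FALSE)
  start <- list(b = base0)
  for (k in seq_len(expected_peaks)) {
    start[[paste0("a", k)]] <- max(profile[sel[k]] - base0, 1e-6)
    start[[paste0("m", k)]] <- positions[sel[k]]
    start[[paste0("s", k)]] <- 1.5 * pitch
  }
  model_terms <- paste0("a", seq_len(expected_peaks),
                        " * exp(-0.5 * ((x - m", seq_len(expected_peaks),
                        ") / s", seq_len(expected_peaks), ")^2)",
                        collapse = " + ")
  fml <- stats::as.formula(paste("y ~ b +", model_terms))
  dat <- data.frame(x = positions, y = as.numeric(profile))
  fit <- minpack.lm::nlsLM(fml, data = dat, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  res <- sqrt(mean(stats::resid(fit)^2))
  out <- data.frame(
    centroid = cf[paste0("m", seq_len(expected_peaks))],
    fwhm = 2 * sqrt(2 * log(2)) * abs(cf[paste0("s", seq_len(expected_peaks))]),
    amplitude = cf[paste0("a", seq_len(expected_peaks))],
    residual = res)
  out <- out[order(out$centroid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intrinsic resolution by quadrature subtraction
#'
#' Removes the finite beam width from a measured FWHM:
#' `sqrt(fwhm^2 - beam^2)`.
#'
#' @param fwhm_measured measured FWHM, mm; must be at least `beam_width`.
#' @param beam_width beam FWHM reaching the detector, mm.
#' @export
quadrature_intrinsic <- function(fwhm_measured, beam_width) {
  if (any(fwhm_measured < beam_width))
    stop("measured FWHM must not be smaller than the beam width")
  sqrt(fwhm_measured^2 - beam_width^2)
}

#' Beam width at the detector from slit geometry
#'
#' Geometric divergence of a slit beam:
#' `slit_width * (slit_thickness + slit_to_detector) / slit_thickness`.
#'
#' @param slit_width slit opening, mm.
#' @param slit_thickness collimator thickness, mm.
#' @param slit_to_detector slit-to-detector distance, mm.
#' @export
beam_width_at_detector <- function(slit_width, slit_thickness,
                                   slit_to_detector) {
  stopifnot(slit_thickness > 0, slit_to_detector >= 0)
  slit_width * (slit_thickness + slit_to_detector) / slit_thickness
}

#' Root-mean-square centroid error
#'
#' @param fitted fitted peak centroids, mm.
#' @param commanded true (commanded) positions, mm.
#' @export
centroid_rmse <- function(fitted, commanded) {
  stopifnot(length(fitted) == length(commanded))
  sqrt(mean((fitted - commanded)^2))
}

#' Normalized standard deviation within a mask
#'
#' `sd / mean` of the masked values; scale-free uniformity measure.
#'
#' @param image numeric array.
#' @param mask logical array of the same shape (default: everything).
#' @export
normalized_std <- function(image, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(image) else as.numeric(image[mask])
  if (mean(v) == 0) stop("masked region has zero mean")
  stats::sd(v) / mean(v)
}

#' Peak-to-valley ratios along a profile
#'
#' Finds interior local minima flanked by local maxima and returns, for each
#' valley, the ratio of the *lower* flanking peak to the valley value.
#'
#' @param profile numeric vector.
#' @return numeric vector of ratios, one per valley (left to right).
#' @export
peak_to_valley <- function(profile) {
  ex <- local_extrema(as.numeric(profile))
  ratios <- numeric(0)
  for (v in ex$min) {
    left <- ex$max[ex$max < v]
    right <- ex$max[ex$max > v]
    if (!length(left) || !length(right)) next
    lower_peak <- min(profile[max(left)], profile[min(right)])
    ratios <- c(ratios, lower_peak / profile[v])
  }
  ratios
}
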