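#' Depth-layer attenuation model
#'
#' Exponential attenuation of a normally incident beam through a crystal of
#' `n` DOI layers of thickness `t` mm: the expected photoelectric count in
#' layer `m` (m = 1 at the rear/anode, m = n at the irradiated front) is
#' `c(m) = c0 * (mu_pe/mu_total) * (exp(-mu_total*(n-m)*t) -
#' exp(-mu_total*(n-m+1)*t))`.
#'
#' @param mu_total total linear attenuation coefficient, 1/mm.
#' @param mu_pe photoelectric linear attenuation coefficient, 1/mm.
#' @param t layer thickness, mm.
#' @param n number of DOI layers.
#' @param c0 event rate at the front surface (arbitrary units).
#' @export
attenuation_model <- function(mu_total = 0.23, mu_pe = 0.18, t = 2, n = 5L,
                              c0 = 1) {
  if (!(mu_total >= mu_pe && mu_pe > 0)) stop("need mu_total >= mu_pe > 0")
  stopifnot(t > 0, n >= 1)
  structure(list(mu_total = mu_total, mu_pe = mu_pe, t = t,
                 n = as.integer(n), c0 = c0),
            class = "attenuation_model")
}

#' @rdname attenuation_model
#' @param spec a [detector_spec()] to take the parameters from.
#' @export
attenuation_from_spec <- function(spec, c0 = 1) {
  attenuation_model(spec$mu_total, spec$mu_pe, spec$layer_thickness,
                    spec$n_layers, c0)
}

#' Expected count in one DOI layer
#'
#' Closed-form integral of the attenuation density over the layer's depth
#' interval.
#'
#' @param model an [attenuation_model()].
#' @param m layer index in `1..n`.
#' @export
layer_count <- function(model, m) {
  if (any(m < 1 | m > model$n)) stop("layer index out of range 1..n")
  mu <- model$mu_total; t <- model$t; n <- model$n
  model$c0 * (model$mu_pe / mu) *
    (exp(-mu * (n - m) * t) - exp(-mu * (n - m + 1) * t))
}

#' Layer count ratio relative to the front layer
#'
#' `ratio_m = c(m)/c(n)`; by construction `ratio_n = 1` exactly. Front
#' layers see more flux, so the ratio increases with `m`.
#'
#' @inheritParams layer_count
#' @export
layer_ratio <- function(model, m) {
  if (any(m < 1 | m > model$n)) stop("layer index out of range 1..n")
  mu <- model$mu_total; t <- model$t; n <- model$n
  (exp(-mu * (n - m) * t) - exp(-mu * (n - m + 1) * t)) / (1 - exp(-mu * t))
}

#' Flood-based uniformity correction factors
#'
#' From a flood acquisition, computes the per-pixel, per-layer correction
#' factor: the target count of every active preconditioned pixel at layer
#' `m` is `ratio_m * sum(flood counts at layer n) / (number of active
#' pixels)` - i.e. uniform in plane, with layer totals following the
#' attenuation ratios referenced to the front layer. The factor is the
#' element-wise quotient of the target by the blurred-and-deconvolved flood;
#' active pixels where the flood deconvolves to zero are flagged dead
#' (factor 0, with a warning).
#'
#' @param flood a `raw_projection` flood acquisition.
#' @param drf a `drf_matrix`.
#' @param blur a [blur_filter_set()] (or `NULL` to skip pre-blur).
#' @param model an [attenuation_model()]; defaults to the flood's spec.
#' @param n_iter MLEM iterations used to deconvolve the flood.
#' @return object of class `correction_factors`: array `CF`
#'   `[layer, row, col]` plus provenance.
#' @export
compute_correction_factors <- function(flood, drf, blur = NULL, model = NULL,
                                       n_iter = 50L) {
  spec <- flood$spec
  if (is.null(model)) model <- attenuation_from_spec(spec)
  if (model$n != spec$n_layers)
    stop("attenuation model layer count does not match the detector")
  sm <- if (is.null(blur)) flood else apply_blur(flood, blur)
  pf <- precondition(sm, drf, n_iter = n_iter)
  n_active <- sum(drf$active)
  total_n <- sum(flood$counts[spec$n_layers, , ])
  active_mat <- matrix(drf$active, drf$precond_grid[1], drf$precond_grid[2])
  CF <- array(0, dim(pf$values))
  n_dead <- 0L
  for (m in seq_len(spec$n_layers)) {
    target <- layer_ratio(model, m) * total_n / n_active
    layer <- pf$values[m, , ]
    cf <- matrix(0, nrow(layer), ncol(layer))
    ok <- active_mat & layer > 0
    cf[ok] <- target / layer[ok]
    n_dead <- n_dead + sum(active_mat & layer <= 0)
    CF[m, , ] <- cf
  }
  if (n_dead > 0)
    warning(sprintf("%d active pixels had zero deconvolved flood counts; flagged dead (CF = 0)", n_dead))
  structure(list(CF = CF, model = model, n_iter = n_iter,
                 flood_meta = flood$meta, n_dead = n_dead),
            class = "correction_factors")
}

#' Full preconditioning pipeline for one raw projection
#'
#' Composes pre-blur, maximum-likelihood deconvolution and uniformity
#' correction: `B_m = CF_m * deconvolve(blur_m(A_m))` per DOI layer.
#'
#' @param A a `raw_projection`.
#' @param drf a `drf_matrix`.
#' @param blur a [blur_filter_set()] or `NULL`.
#' @param CF a `correction_factors` object or `NULL` (skip correction).
#' @param n_iter MLEM iterations.
#' @return a `precond_projection` (the final projection `B`).
#' @export
apply_full_pipeline <- function(A, drf, blur = NULL, CF = NULL,
                                n_iter = 50L) {
  sm <- if (is.null(blur)) A else apply_blur(A, blur)
  pf <- precondition(sm, drf, n_iter = n_iter)
  if (!is.null(CF)) {
    for (m in seq_len(dim(pf$values)[1]))
      pf$values[m, , ] <- pf$values[m, , ] * CF$CF[m, , ]
    pf$meta$uniformity_corrected <- TRUE
  }
  pf
}
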