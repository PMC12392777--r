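---
title: "Maximum-likelihood preconditioning of position-sensitive detector projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood preconditioning of position-sensitive detector projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectdecon)
```

## The problem

Large-volume 3-D position-sensitive gamma-ray detectors (pixelated CZT
modules with subpixel positioning and depth-of-interaction readout) deliver
sub-millimeter spatial resolution, but their event-position estimates carry
three systematic pathologies:

1. **Pixel-boundary clustering.** Interactions near an anode-pixel border
   cannot be positioned reliably by the subpixel algorithm and pile up on
   the borders, imprinting a square-grid pattern at the anode pitch
   (1.9 mm here) on every projection.
2. **Spatial distortion.** Crystal inhomogeneity and electrode effects bend
   the mapping from true to reported position by a smooth, detector-specific
   field of a few tenths of a millimeter.
3. **Gain nonuniformity.** Detection efficiency varies across the crystal
   and with depth.

`spectdecon` implements a data-domain remedy: instead of correcting each
event, it treats the recorded projection as the output of a linear detector
response applied to an ideal projection, and recovers the ideal projection
by Poisson maximum likelihood. The corrected ("preconditioned") projections
then feed ordinary tomographic calibration and reconstruction.

## The model

Counts `f̂_j` in raw detector bin `j` (the fine grid on which events are
histogrammed, 440×440 at 0.095 mm by default) are modeled as independent
Poisson variables with mean `λ_j = Σ_l P_jl f_l`, where `f` lives on the
coarser *preconditioned* plane (88×88 at 0.5 mm) and `P` is the detector
response function (DRF): column `l` is the raw-grid image produced by
illuminating preconditioned pixel `l`. The log-likelihood
`Σ_j [f̂_j log λ_j − λ_j − log f̂_j!]` is maximized by the standard MLEM
fixed-point iteration

```
f_l <- (f_l / s_l) * Σ_j P_jl f̂_j / λ_j ,   s_l = Σ_j P_jl ,
```

which preserves `Σ_l s_l f_l = Σ_j f̂_j` at every step and never decreases
the likelihood. Both properties are asserted numerically in the test suite.
Raw bins outside the support of `P` have zero model probability for any
`f`; `precondition()` masks their counts (reporting how many) rather than
failing, since with measured scans such bins are inevitable.

Iteration count is fixed (default 50) rather than tolerance-based: MLEM
likelihood is monotone, the trace is returned, and the appropriate stopping
point is application-dependent. Initialization is flat on active pixels at
`sum(f̂)/sum(s)`, which makes the first iterate already count-matched.

## Measuring the response: sheet-beam scans

A pencil-beam scan of every preconditioned pixel would measure `P` exactly
but needs N acquisitions per layer. The package instead uses two orthogonal
sheet-beam scan sets — one narrow beam per preconditioned row and per
column (88 + 88 positions at the 0.5 mm pitch) — and approximates column
`l = (a, b)` as the element-wise product `R_a ∘ C_b` of the row and column
responses. The approximation is exact when the detector response is
separable in x and y; the test suite verifies per-column cosine similarity
≥ 0.99 against a simulated pencil-beam oracle on a separable toy detector.
Entries below `1e-3` of each column's maximum are dropped (configurable);
retained column mass is reported.

Response values are stored **unnormalized**. Scan-intensity nonuniformity
and the product's quadratic scale are deliberately left in `P` and absorbed
later by the flood-based correction factors, so no beam-profile calibration
is needed. A single DRF serves all DOI layers and energies: the distortion
pattern is depth- and energy-stable, while the high-frequency detail the
approximation loses would have required per-layer scans anyway. Scans are
pooled over layers for statistics.

## Pre-blur: suppressing the boundary grid

The outer-product DRF cannot represent the ~0.2 mm boundary clustering, so
projections are smoothed before deconvolution with region-wise Gaussian
filters: the anode unit cell is partitioned into interior, edge band and
corner band (`partition_unit_cell()`), and each region gets its own sigma
per DOI layer (the artifact differs across depths, so layers are optimized
independently).

`apply_blur()` splits the counts by smooth partition-of-unity region
weights, convolves each part with its region's normalized kernel
(reflective borders), and sums. Splitting the *input* rather than blending
the *outputs* makes total counts exactly conserved — the convolution
operator's columns each sum to one.

`optimize_blur_filters()` needs an objective that sees the artifact but not
the Poisson noise. The blurred flood is folded into the 1.9 mm unit cell
(per-subbin average over all complete anode tiles), which averages noise
down by the tile count while preserving the systematic boundary pattern;
the objective is the variance of the normalized folded template plus a
small ridge penalty on sigma (`3e-3` at the upper bound). The ridge is
calibrated to exceed the noise-variance reduction that smoothing alone can
buy on an artifact-free flood — so a clean detector drives sigma to the
lower bound — while staying orders of magnitude below the template variance
a real boundary artifact produces. Optimization is bounded quasi-Newton
from seeded multi-starts.

The filters trade resolution for artifact suppression, exactly as a
physical implementation does: in the bundled end-to-end study the
preconditioned reconstruction converges to a coarser resolution floor than
an artifact-free one would, and comparisons across processing paths are
therefore made at iterations matched by fitted rod FWHM
(`match_iterations_by_resolution()`).

## Uniformity correction and the full pipeline

For a flood exposure the expected counts in DOI layer `m` (layer `n` at the
irradiated front face, layer 1 at the anode) follow the attenuation
integral

```
c(m) = c0 ∫ μ_PE exp(−μ_total x) dx   over x ∈ [(n−m)t, (n−m+1)t] ,
```

with `t = 2 mm`, `n = 5`, and CZT coefficients at ~122 keV
(`μ_total = 0.23 /mm`, `μ_PE = 0.18 /mm` by default; `μ_PE` cancels from
every ratio). The ratio `c(m)/c(n)` is implemented with the front-layer
denominator restored so that `ratio_n = 1` exactly; only ratio-of-ratios
enters the correction, so this normalization choice is verifiable —
`layer_ratio(model, 3) ≈ 0.3985 ≈ 0.4` for the default stack — and
harmless. With these defaults the layer-3 to layer-5 count ratio is the
familiar "layer 3 records ~0.4 of the front layer" rule of thumb.

`compute_correction_factors()` deconvolves a blurred flood and forms, per
layer, the element-wise quotient of the target (uniform in plane, layer
totals following the ratios, referenced to the measured front-layer total
divided by the number of active pixels `Σ sgn(s_l)`) by the deconvolved
flood. Active pixels where the flood deconvolves to zero are flagged dead
with factor 0 and a warning. The full pipeline is then

```
B_m = CF_m ∘ MLEM( blur_m(A_m) )
```

per layer. Correction factors are energy-specific by construction (they
come from a flood in a given window); distinct filter/factor sets should be
fitted per emission energy.

## The synthetic detector

All tests run against `sim_detector`-module acquisitions, which emulate:

- a seeded, band-limited smooth displacement field with a target RMS
  amplitude (0.5 mm in the bundled studies, clipped at 3×RMS);
- probabilistic snap-to-boundary event misplacement within a capture band
  around the 1.9 mm anode grid;
- a smooth multiplicative gain map (unit mean per layer) applied by event
  thinning, with exact bookkeeping
  (`generated = kept + thinned + off-grid`);
- depth sampling from the truncated exponential attenuation profile,
  binned into the 5 DOI layers.

The boundary model's two parameters are phenomenological; the defaults
(capture half-width 0.35 mm, misplacement fraction 0.45) were chosen so the
raw-path nonuniformity at the 0.5 mm analysis pitch is of the order
reported for real hardware of this class (normalized standard deviation
~0.2), rather than from first principles. The simulator does **not** model
charge transport, charge sharing, energy spectra, Compton multi-site
events, or inter-module gaps — so passing tests demonstrate the
*self-consistency* of the correction chain under the stated artifact
models, not detector physics fidelity. Notably the simulator has no
intrinsic PSF: a pencil beam without pathologies lands in a single raw bin,
which is why response-oracle comparisons illuminate a full 0.5 mm pixel
(`spot_size`).

## Geometry and reconstruction

The single-pinhole tomograph is described by a 19-component vector:
detector frame origin and orientation (6), pinhole position (3), rotation
stage axis direction, crossing and radius (4), translation-stage direction
(3), and 3 reserved components (two fixed spares and the axis depth). Six
of the components are a *gauge*: a rigid motion of the whole setup changes
nothing measurable, so by convention the pinhole position and the axis tilt
and x-crossing are fixed during calibration. Point-source weighting centers
from 8 angles × 3 axial translations (24 views) are fitted by bounded
Levenberg–Marquardt with seeded multi-starts (the problem has narrow curved
valleys in which quasi-Newton methods stall; the residual formulation is
essential). A small penalty pins the translation direction to unit norm.

One identifiability caveat surfaced during development and is worth knowing
when designing a calibration acquisition: if the rotation axis is exactly
parallel to the detector columns and the translation stage moves along it,
the 24 centers lie on three rows of the detector plane, and a detector tilt
about the in-plane x axis is indistinguishable from a plane shift — the fit
is perfect and the parameters are wrong. A few degrees of axis tilt (or any
acquisition that spreads the centers in both plane directions) restores
identifiability to ≲0.03 mm / 0.03°. The bundled calibration tests use such
a tilted-axis truth.

The voxel-driven system response projects each source voxel through the
pinhole per view, deposits a Gaussian aperture footprint (FWHM
`= diameter × (magnification + 1)/2`, truncated at ±1 preconditioned pixel
and renormalized implicitly by MLEM's count conservation), weights by
inverse-square distance and incidence cosine, and distributes the response
over DOI layers with the normalized attenuation layer fractions at normal
incidence — oblique path-length corrections are ignored at these small cone
angles. Reconstruction is joint MLEM over all views with the same
conservation and monotonicity guarantees, checked by inverse-crime tests.

## Problem sizes and numerical choices

The packaged studies use scaled-down detectors — 16×16 to 20×20
preconditioned pixels (5 raw bins per pixel, so the raw grid is 80×80 to
100×100) instead of 88×88, floods of 1.5–3 million events, scans of
20,000–250,000 events per position, and reconstruction grids of 24×24×16
half-millimeter voxels over 24 views. These sizes keep every property of
interest measurable (the anode pitch spans ~4–5 preconditioned pixels
either way) while the full suite runs in minutes; all operators accept the
full-size geometry unchanged. Other numerical conventions: lengths in mm
with the origin at the lower-left corner of the preconditioned plane,
half-open bins, R's native column-major 1-based array indexing throughout,
angles in degrees at every interface, and one explicit integer seed per
stochastic call (calling a simulator function reseeds R's RNG).

## Limitations

- The outer-product response is exact only for separable distortion; real
  fields are locally but not globally separable, and the residual error
  appears as mild extra blur in the deconvolved plane.
- Pre-blur mitigates but does not remove the boundary artifact; a weak
  residual grid persists in preconditioned reconstructions, measurable by
  the same autocorrelation contrast the acceptance study uses.
- Correction factors equalize *expected* counts; absolute activity
  quantification needs an external sensitivity calibration.
- The calibration model treats the pinhole as a point; aperture size enters
  only the reconstruction response as a Gaussian blur.
- At the bundled study scale the cold rods (1.6 mm) are close to the
  reconstructed resolution (1–1.5 mm FWHM), so the peak-to-valley contrast
  comparison between processing paths sits near the detectability limit:
  the uniformity and grid-periodicity comparisons are the robust
  discriminators here, while peak-to-valley depends on the convergence
  stage and realization. A full-size detector with proportionally larger
  phantom features would separate the paths more decisively.
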