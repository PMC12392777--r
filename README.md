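# spectdecon

Maximum-likelihood data preconditioning for 3-D position-sensitive
gamma-ray imaging detectors, with geometric calibration and MLEM
reconstruction for a single-pinhole tomograph — exercised end to end on a
bundled synthetic detector simulator.

## Who this is for

Large-volume pixelated semiconductor detectors (e.g. CZT modules with
1.9 mm anode pixels, subpixel positioning and 5 depth-of-interaction
layers) suffer from three systematic projection artifacts: event clustering
on anode-pixel boundaries (a square-grid pattern at the anode pitch),
smooth spatial distortion of a few tenths of a millimeter, and gain
nonuniformity. This package is for instrumentation and preclinical-imaging
groups who want to remove those artifacts *in the data domain* — without
access to the detector's internal signals — before feeding projections to
tomographic reconstruction.

## The method

Raw counts `f̂` on the fine detector grid (440×440 bins of 0.095 mm by
default) are modeled as Poisson with mean `P f`, where `f` lives on a
coarser preconditioned plane (88×88 pixels of 0.5 mm) and `P` is the
detector response function (DRF). The preconditioned projection is the
maximum-likelihood estimate, found by the MLEM iteration

    f_l ← (f_l / s_l) Σ_j P_jl f̂_j / (P f)_j ,   s_l = Σ_j P_jl ,

which conserves total counts and has monotone likelihood. `P` is measured
by two orthogonal sheet-beam scan sets (one 0.5 mm beam per preconditioned
row and column) and assembled by the outer-product approximation
`P[, (a,b)] ≈ vec(R_a ∘ C_b)`. Because the scan-derived response cannot
capture the sub-pixel boundary artifact, projections are first smoothed
with region-wise Gaussian filters optimized on a flood field
(`optimize_blur_filters`), and a flood-based per-pixel, per-layer
correction factor restores in-plane uniformity and the exponential
attenuation depth profile `c(m) ∝ e^(−μ(n−m)t) − e^(−μ(n−m+1)t)`
(`compute_correction_factors`). The full chain per DOI layer `m` is

    B_m = CF_m ∘ MLEM( S_m(A_m) ) .

The package also calibrates a single-pinhole tomograph's 19-parameter
geometry from point-source projections (Levenberg–Marquardt on weighting
centers; 8 angles × 3 translations) and reconstructs activity on a voxel
grid by MLEM with a voxel-driven system response that includes the DOI
layer fractions and a Gaussian aperture model.

A synthetic detector (`simulate_flood`, `simulate_sheet_beam_scan`,
`simulate_pencil_beam`, `simulate_pinhole_acquisition`) generates all three
pathologies with exact event bookkeeping and drives the test suite.

## Worked example

A 16×16-pixel toy detector with 0.5 mm RMS distortion and the boundary
artifact; the response is scanned, filters and correction factors are
fitted from a flood, and a sheet beam commanded at x = 4.25 mm is imaged
raw and preconditioned:

```r
library(spectdecon)
spec  <- toy_detector_spec(16)
field <- make_distortion_field(spec, amplitude = 0.5, correlation_length = 6, seed = 1)
bnd   <- boundary_artifact_model()
scans <- simulate_scan_set(spec, beam_width = 0.5, counts_per_position = 20000,
                           field = field, boundary = bnd, seed = 2)
drf   <- build_drf(scans, spec)
drf
#> <drf_matrix> 6400 x 256 (raw bins x precond pixels), 8563 nonzeros, 7 inactive pixels

flood <- simulate_flood(spec, 1e6, field, bnd, seed = 3)
blur  <- optimize_blur_filters(flood, band_halfwidth_mm = 0.35, sigma_bounds = c(0, 0.6))
CF    <- compute_correction_factors(flood, drf, blur, n_iter = 30)

sb <- simulate_sheet_beam_scan(spec, "x", 4.25, beam_width = 0.5,
                               counts_per_position = 50000,
                               field = field, boundary = bnd, seed = 4)[[1]]
B  <- apply_full_pipeline(sb, drf, blur, CF, n_iter = 30)
round(c(commanded = 4.25,
        raw   = weighting_center(rebin_to_precond(sb))["x"],
        final = weighting_center(B)["x"]), 3)
#> commanded       raw     final
#>     4.250     4.721     4.248
```

The distortion displaces the raw beam centroid by ~0.47 mm; after
preconditioning it sits within 2 µm of the commanded position. The
attenuation depth profile used by the uniformity step (layer 5 is the
irradiated front face):

```r
round(layer_ratio(attenuation_from_spec(spec), 1:5), 3)
#> [1] 0.159 0.252 0.399 0.631 1.000
```

Layer 3 records ≈0.4 of the front-layer counts, the expected ratio for
2 mm CZT layers at ~122 keV.

## Package layout

| Area | Functions |
| --- | --- |
| Simulator | `toy_detector_spec`, `make_distortion_field`, `boundary_artifact_model`, `make_gain_map`, `simulate_*` |
| Response | `simulate_scan_set`, `outer_product_response`, `build_drf`, `compute_sensitivity` |
| Preconditioning | `partition_unit_cell`, `optimize_blur_filters`, `apply_blur`, `precondition`, `log_likelihood`, `mlem_update` |
| Uniformity | `attenuation_model`, `layer_count`, `layer_ratio`, `compute_correction_factors`, `apply_full_pipeline` |
| Metrics | `fit_line_profiles`, `quadrature_intrinsic`, `beam_width_at_detector`, `centroid_rmse`, `normalized_std`, `peak_to_valley`, `autocorrelation_at` |
| Tomograph | `geometry_params`, `forward_centers`, `weighting_center`, `calibrate_geometry`, `build_srf`, `mlem_reconstruct`, `match_iterations_by_resolution`, `digital_rod_phantom` |
| I/O & pipeline | `read_projection`, `write_projection`, `read_blur_filters`, `write_blur_filters`, `run_pipeline`, `default_run_config` |
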