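# geldiff

Quantitative analysis of drug transport in hydrogel chip reservoirs from
fluorescence time-lapse microscopy, for labs characterising drug
penetration through biomimetic extracellular-matrix gels (e.g. agarose
vs fibrin/collagen "cirrhotic" matrices) and drug uptake by tumour cells
embedded in them.

A chip reservoir holds a ~3 mm gel column between a drug donor solution
and a receiver solution. The drug (doxorubicin, intrinsically
fluorescent) diffuses in, and the evolving axial fluorescence profile
`I(y, t)` is imaged. `geldiff` estimates:

* the **apparent diffusion coefficient** `D_app` (µm²/s), by fitting the
  1D diffusion equation `∂C/∂t = D ∂²C/∂y²` — solved with a
  Crank–Nicolson scheme (Δy = 12.50339 µm = 10 pixels, Δt = 30 s), zero
  initial condition, a sink condition at the receiver end and a
  data-driven donor-side boundary
  `I_LB(t) = I_LB,∞ (1 − e^(−βt))` (exactly through the first two
  measured boundary values, linear spline afterwards) — to two measured
  baseline-corrected profiles with a Levenberg–Marquardt iteration in
  `log D` (relative SSE convergence < 10⁻⁶);
* **single-cell uptake kinetics**: nuclei segmented from the
  nuclear-stain channel (max projection → Otsu → dilation → watershed →
  particle filter), per-cell traces converted to concentration via a
  linear calibration, aggregated into 250 µm zones; per-zone uptake
  rates (µM/min), the transport rate constant `k_cell` (min⁻¹, slope of
  uptake vs available gel concentration) and the apparent cell
  permeability `P_cell = k_cell · r / (3·60)` µm/s;
* **statistical comparisons** of fitted coefficients across gel
  conditions (Shapiro–Wilk and F-test gates choosing pooled t, Welch t
  or rank-based tests; Kruskal–Wallis + Dunn against a control);
* fully **ground-truthed synthetic chip experiments** (three-channel
  16-bit TIFF stacks rendered from a fine-grid forward model) so the
  entire pipeline is testable without laboratory data.

The methods vignette (`vignettes/gel-chip-diffusion.Rmd`) documents the
model, the estimator conventions and the validation studies in detail.

## Worked example

```r
library(geldiff)

# render a synthetic chip: D = 300 um^2/s, 20 cells, k_cell = 0.016/min
params <- simulation_params(D_true = 300, k_cell_true = 0.016,
                            n_cells = 20, seed = 1)
sim <- simulate_experiment(params)

conc <- seq(1, 25, length.out = 5)
curve <- fit_calibration(conc, 50 * conc + 100)   # 50 a.u./uM over 100 a.u.
res <- analyze_chip(sim$series, curve)

res$diffusion
#> <diffusion_fit> D_app = 308.3 um^2/s (SSE 3458, 4 iterations, converged)
#>   fitted at t = 900, 1500 s, boundary mode exp_then_spline
res$uptake
#> <uptake_result> k_cell = 0.01531 +/- 0.0003 1/min, P_cell = 0.0009071 um/s (r = 10.7 um)
#>   7 zones, uptake rates 0.0755 .. 0.279 uM/min
```

`D_app` lands within ~3% of the simulated 300 µm²/s (the residual is the
two-point exponential approximation of the diffusion-delayed boundary
trace); all 20 cells are found; `k_cell` recovers the programmed
0.016 min⁻¹ to ~4% here and to within ~20% across seeds
(segmentation-mask overhang and the regression conventions discussed in
the vignette). `P_cell` follows `k_cell · r/180` exactly.

Useful entry points: `simulate_experiment()`, `read_image_series()`,
`detect_gel_boundaries()`, `extract_profile()`, `baseline_correct()`,
`estimate_diffusion()`, `detect_nuclei()`, `measure_cell_intensities()`,
`uptake_analysis()`, `compare_two_groups()`, `stokes_einstein_scale()`.

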