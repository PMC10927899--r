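#' Full chip-experiment analysis
#'
#' Convenience driver running the complete analysis on an image series:
#' gel-geometry detection from the DIC channel, nucleus segmentation,
#' axial profile extraction on the drug channel (cell pixels excluded
#' from the transverse average), baseline correction, diffusion-coefficient
#' estimation, per-cell trace measurement and the zone uptake /
#' permeability analysis.
#'
#' @param series An [image_series].
#' @param curve A [calibration_curve] mapping intensity to concentration.
#' @param geometry_overrides Optional geometry overrides (see
#'   [detect_gel_boundaries()]).
#' @param baseline_mode Baseline-correction mode (default `"far_segment"`).
#' @param fit_times Optional explicit pair of fit times (s).
#' @param uptake_times_min Times (min) for the k_cell regression
#'   (default 60, 120, 180).
#' @param roi_width_um Profile ROI width (µm, default 100).
#' @return List with `geometry`, `cells`, `profiles` (corrected a.u.),
#'   `profiles_uM` (uncorrected, concentration units), `diffusion`
#'   (a `diffusion_fit`), `traces`, and `uptake` (an `uptake_result`, or
#'   `NULL` when no cells are detected).
#' @export
analyze_chip <- function(series, curve, geometry_overrides = NULL,
                         baseline_mode = "far_segment", fit_times = NULL,
                         uptake_times_min = c(60, 120, 180),
                         roi_width_um = 100) {
  validate_calibration(curve)
  geometry <- detect_gel_boundaries(series, geometry_overrides)
  cells <- detect_nuclei(series)
  mask <- attr(cells, "label_mask") > 0
  raw <- extract_profile(series, geometry, "dox",
                         roi_width_um = roi_width_um,
                         exclude_mask = if (any(mask)) mask else NULL)
  corrected <- baseline_correct(raw, baseline_mode)
  fit <- estimate_diffusion(corrected, geometry, times = fit_times)
  profiles_uM <- profiles_to_concentration(raw, curve)
  traces <- NULL
  uptake <- NULL
  if (nrow(cells) > 0) {
    traces <- measure_cell_intensities(series, cells)
    uptake <- uptake_analysis(cells, traces, profiles_uM, curve,
                              eval_times_min = uptake_times_min)
  }
  list(geometry = geometry, cells = cells, profiles = corrected,
       profiles_uM = profiles_uM, diffusion = fit, traces = traces,
       uptake = uptake)
}
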