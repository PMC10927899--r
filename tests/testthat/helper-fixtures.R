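# shared fixtures: all synthetic, built in code at test time

# exact calibration curve through noiseless standards
make_curve <- function(slope = 50, intercept = 100, cmax = 25) {
  conc <- seq(1, cmax, length.out = 5)
  fit_calibration(conc, slope * conc + intercept)
}

# small, fast simulation settings for imaging / cells tests
small_params <- function(...) {
  defaults <- list(gel_length = 600, gel_width = 250, n_frames = 3,
                   frame_interval = 300, t_lag = 60, n_cells = 0,
                   noise_sd = 0)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

# noiseless measured profiles + geometry for recovery studies; the fit
# interval starts 25 um (20 px) from the simulated donor boundary so the
# exponential boundary model is well-specified (see the methods vignette)
recovery_setup <- function(D, n_frames = 19, params = NULL) {
  p <- if (is.null(params)) {
    simulation_params(D_true = D, noise_sd = 0, n_cells = 0,
                      n_frames = n_frames)
  } else params
  ny <- round(p$gel_length / p$pixel_size) + 1
  length_eff <- (ny - 1) * p$pixel_size
  times <- p$t_lag + (0:(p$n_frames - 1)) * p$frame_interval
  ps <- simulate_profiles(p, times)
  prof <- profile_series(ps$y_um, times, attr(ps, "intensity"),
                         units = "a.u.", pixel_size = p$pixel_size)
  geom <- gel_geometry(0, length_eff, y_lower_boundary = 25,
                       pixel_size = p$pixel_size)
  list(params = p, profiles = prof, geometry = geom, times = times)
}

# add multiplicative Gaussian noise to a profile series, fixed seed
perturb_profiles <- function(prof, frac, seed) {
  set.seed(seed)
  v <- prof$values * matrix(stats::rnorm(length(prof$values), 1, frac),
                            nrow(prof$values))
  profile_series(prof$y_um, prof$times_s, v, units = prof$units,
                 baseline_mode = prof$baseline_mode,
                 pixel_size = prof$pixel_size)
}

erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
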