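#' Parameters of a synthetic chip experiment
#'
#' Defaults emulate the study conditions of the chip assay: a 3 mm gel
#' reservoir (1 mm wide) imaged at 1.250339 µm/pixel every 10 min for
#' 0-180 min, a 20 µM donor solution whose interface intensity saturates
#' exponentially, a receiver acting as a perfect sink, and tumour cells of
#' about 9.9 µm radius taking up drug at a rate proportional to the local
#' gel concentration.
#'
#' @param D_true True diffusion coefficient (µm²/s).
#' @param boundary_I_inf Plateau intensity of the donor interface (a.u.);
#'   the default corresponds to 20 µM through the default calibration.
#' @param boundary_beta Saturation rate of the donor interface (1/s).
#' @param gel_length Gel reservoir length (µm).
#' @param gel_width Gel reservoir width (µm).
#' @param pixel_size Pixel size (µm).
#' @param frame_interval Imaging interval (s).
#' @param n_frames Number of acquired frames.
#' @param t_lag Lag between drug addition and first frame (s).
#' @param noise_sd Additive Gaussian detector noise sd (a.u.).
#' @param n_cells Number of cells placed in the reservoir.
#' @param cell_radius_mean,cell_radius_sd Cell radius distribution (µm).
#' @param k_cell_true True cellular transport rate constant (1/min).
#' @param nucblue_decay_coupling Nuclear-stain decay coupling (fraction
#'   per µM·min of accumulated cellular drug exposure).
#' @param nucblue_peak Peak nuclear-stain intensity at t = 0 (a.u.).
#' @param calibration_slope,calibration_intercept Linear calibration
#'   (a.u. per µM; a.u.).
#' @param seed Integer seed; identical seeds reproduce identical outputs.
#' @return Validated object of class `simulation_params`.
#' @export
simulation_params <- function(D_true = 300,
                              boundary_I_inf = 1100,
                              boundary_beta = 1 / 600,
                              gel_length = 3000,
                              gel_width = 1000,
                              pixel_size = 1.250339,
                              frame_interval = 600,
                              n_frames = 19,
                              t_lag = 300,
                              noise_sd = 20,
                              n_cells = 20,
                              cell_radius_mean = 9.9,
                              cell_radius_sd = 0.7,
                              k_cell_true = 0.0163,
                              nucblue_decay_coupling = 1.8e-4,
                              nucblue_peak = 20000,
                              calibration_slope = 50,
                              calibration_intercept = 100,
                              seed = 1L) {
  p <- list(D_true = D_true, boundary_I_inf = boundary_I_inf,
            boundary_beta = boundary_beta, gel_length = gel_length,
            gel_width = gel_width, pixel_size = pixel_size,
            frame_interval = frame_interval, n_frames = n_frames,
            t_lag = t_lag, noise_sd = noise_sd, n_cells = n_cells,
            cell_radius_mean = cell_radius_mean,
            cell_radius_sd = cell_radius_sd, k_cell_true = k_cell_true,
            nucblue_decay_coupling = nucblue_decay_coupling,
            nucblue_peak = nucblue_peak,
            calibration_slope = calibration_slope,
            calibration_intercept = calibration_intercept,
            seed = as.integer(seed))
  if (p$D_true <= 0) stop("D_true must be positive")
  if (p$gel_length <= 0 || p$gel_width <= 0) stop("gel dimensions must be positive")
  if (p$frame_interval <= 0) stop("frame_interval must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  if (p$n_cells < 0) stop("n_cells must be non-negative")
  if (p$t_lag <= 0) stop("t_lag must be positive")
  structure(p, class = "simulation_params")
}

# Fine-grid geometry shared by the generator: image rows sit on the pixel
# lattice, so the realised gel length is the nearest lattice multiple.
sim_lattice <- function(params) {
  ny <- round(params$gel_length / params$pixel_size) + 1L
  list(ny = ny,
       nx = max(3L, round(params$gel_width / params$pixel_size)),
       y = (seq_len(ny) - 1) * params$pixel_size,
       length_eff = (ny - 1) * params$pixel_size)
}

#' Simulate drug concentration profiles on a fine grid
#'
#' Forward model for data generation: solves the 1D diffusion problem with
#' donor boundary `C(0, t) = C_inf * (1 - exp(-beta t))`, sink condition
#' at the far end and zero initial condition, on a grid substantially
#' finer than the fitting grid (node spacing one pixel; time step
#' `min(frame_interval / 40, 7.5 s)`), so the inverse fit never sees its
#' own discretisation. `beta = Inf` is accepted and gives a step boundary.
#'
#' @param params A [simulation_params].
#' @param times Output times (s since drug addition), sorted, positive.
#' @return A [profile_series] in µM over the full reservoir. The matching
#'   intensity values (via the calibration line) are attached as attribute
#'   `intensity`.
#' @export
simulate_profiles <- function(params, times) {
  if (any(diff(times) <= 0)) stop("times must be sorted increasing")
  if (any(times < 0)) stop("times must be non-negative")
  lat <- sim_lattice(params)
  C_inf <- (params$boundary_I_inf - params$calibration_intercept) /
    params$calibration_slope
  beta <- params$boundary_beta
  g <- if (is.infinite(beta)) {
    function(t) ifelse(t > 0, C_inf, C_inf)   # step boundary, on at t = 0+
  } else {
    function(t) C_inf * (1 - exp(-beta * t))
  }
  dt_fine <- min(params$frame_interval / 40, 7.5)
  vals <- cn_march(params$D_true, params$pixel_size, lat$ny, dt_fine,
                   max(times), g, times)
  ps <- profile_series(lat$y, times, vals, units = "uM",
                       pixel_size = params$pixel_size)
  attr(ps, "intensity") <- params$calibration_slope * vals +
    params$calibration_intercept
  ps
}

# cellular drug exposure: C_cell(t) = (k_cell/60) * integral_0^t C_gel dt
# evaluated by trapezoid on a 60 s grid at the cell's axial pixel.
cell_exposure <- function(params, cell_rows, t_end) {
  lat <- sim_lattice(params)
  tt <- seq(0, t_end, by = 60)
  if (tt[length(tt)] < t_end) tt <- c(tt, t_end)
  prof <- simulate_profiles(params, tt[-1])   # t = 0 field is identically 0
  cg <- rbind(0, t(prof$values[cell_rows, , drop = FALSE]))  # time x cell
  dtv <- diff(tt)
  # cumulative trapezoid over time, seconds -> minutes inside the rate
  inc <- (cg[-1, , drop = FALSE] + cg[-nrow(cg), , drop = FALSE]) / 2 * dtv
  cum <- apply(inc, 2, cumsum)
  cum <- rbind(0, cum)
  list(times = tt, C_cell = params$k_cell_true * cum / 60, C_gel = cg)
}

#' Simulate a full chip experiment
#'
#' Renders a three-channel 16-bit image stack from the fine-grid forward
#' model. The drug channel holds the diffusing gradient (uniform across
#' the width) plus, for each cell, a uniform nuclear disk of added
#' intensity tracking `dC_cell/dt = k_cell * C_gel(y, t)`. The
#' nuclear-stain channel renders each nucleus with a Gaussian radial
#' falloff (sigma = r/2) whose amplitude decays exponentially with the
#' accumulated cellular drug exposure. The DIC channel encodes the gel
#' interfaces as dark lines. I.i.d. Gaussian noise of sd `noise_sd` is
#' added per pixel and the result is rounded and clipped to [0, 65535].
#'
#' @param params A [simulation_params].
#' @param cells Optional data frame (`y_um`, `x_um`, `radius_um`)
#'   overriding random cell placement (for controlled scenarios).
#' @param out_dir Optional directory; when given, per-channel TIFF stacks,
#'   `manifest.json` (ground truth) and `profiles_true.csv` are written.
#' @return List with `series` (an [image_series]) and `truth` (a list:
#'   the parameters, the realised cell table, the realised boundary trace
#'   and the noiseless concentration profiles).
#' @export
simulate_experiment <- function(params, cells = NULL, out_dir = NULL) {
  set.seed(params$seed)
  lat <- sim_lattice(params)
  px <- params$pixel_size
  timestamps <- params$t_lag + (seq_len(params$n_frames) - 1) *
    params$frame_interval
  if (is.null(cells)) {
    cells <- place_cells(params, lat)
  } else {
    cells <- data.frame(id = seq_len(nrow(cells)), cells)
  }
  if (nrow(cells)) {
    if (any(cells$y_um < cells$radius_um |
            cells$y_um > lat$length_eff - cells$radius_um |
            cells$x_um < cells$radius_um |
            cells$x_um > (lat$nx - 1) * px - cells$radius_um)) {
      stop("cells cannot be placed without exceeding gel bounds")
    }
  }
  prof <- simulate_profiles(params, timestamps)
  conc <- prof$values                               # ny x nt, uM
  # per-cell kinetics on a fine time grid
  if (nrow(cells)) {
    rows <- pmin(lat$ny, pmax(1L, round(cells$y_um / px) + 1L))
    expo <- cell_exposure(params, rows, max(timestamps))
    # interpolate to frame times
    C_cell <- vapply(seq_len(nrow(cells)), function(i) {
      stats::approx(expo$times, expo$C_cell[, i], xout = timestamps)$y
    }, numeric(length(timestamps)))               # nt x ncell
    C_cell <- matrix(C_cell, nrow = length(timestamps))
    exposure_int <- vapply(seq_len(nrow(cells)), function(i) {
      # integral of C_cell dt (uM * min), trapezoid on the fine grid
      cc <- expo$C_cell[, i]
      cumsum(c(0, (cc[-1] + cc[-length(cc)]) / 2 * diff(expo$times) / 60))
    }, numeric(length(expo$times)))
    exposure_frames <- vapply(seq_len(nrow(cells)), function(i) {
      stats::approx(expo$times, exposure_int[, i], xout = timestamps)$y
    }, numeric(length(timestamps)))
    exposure_frames <- matrix(exposure_frames, nrow = length(timestamps))
  }
  slope <- params$calibration_slope
  icpt <- params$calibration_intercept
  nb_bg <- 50
  dic_bg <- 20000
  nt <- length(timestamps)
  dox <- array(0L, dim = c(lat$ny, lat$nx, nt))
  nb <- array(0L, dim = c(lat$ny, lat$nx, nt))
  dic <- array(0L, dim = c(lat$ny, lat$nx, nt))
  # precompute per-cell pixel footprints
  foot <- lapply(seq_len(nrow(cells)), function(i) {
    r <- cells$radius_um[i]
    rw <- ceiling((2 * r) / px)   # half-width in px, covers 2 sigma of the stain
    cy <- round(cells$y_um[i] / px) + 1L
    cx <- round(cells$x_um[i] / px) + 1L
    ys <- max(1L, cy - rw):min(lat$ny, cy + rw)
    xs <- max(1L, cx - rw):min(lat$nx, cx + rw)
    dy <- (ys - 1) * px - cells$y_um[i]
    dx <- (xs - 1) * px - cells$x_um[i]
    rho2 <- outer(dy^2, dx^2, `+`)
    list(ys = ys, xs = xs,
         disk = rho2 <= r^2,
         gauss = exp(-rho2 / (2 * (r / 2)^2)))
  })
  for (k in seq_len(nt)) {
    dox_f <- matrix(slope * conc[, k] + icpt, lat$ny, lat$nx)
    nb_f <- matrix(nb_bg, lat$ny, lat$nx)
    dic_f <- matrix(dic_bg, lat$ny, lat$nx)
    dic_f[c(1, lat$ny), ] <- 0.1 * dic_bg
    for (i in seq_along(foot)) {
      f <- foot[[i]]
      dox_f[f$ys, f$xs] <- dox_f[f$ys, f$xs] + f$disk * slope * C_cell[k, i]
      decay <- exp(-params$nucblue_decay_coupling * exposure_frames[k, i])
      nb_f[f$ys, f$xs] <- nb_f[f$ys, f$xs] +
        f$gauss * params$nucblue_peak * decay
    }
    if (params$noise_sd > 0) {
      npx <- lat$ny * lat$nx
      dox_f <- dox_f + stats::rnorm(npx, sd = params$noise_sd)
      nb_f <- nb_f + stats::rnorm(npx, sd = params$noise_sd)
      dic_f <- dic_f + stats::rnorm(npx, sd = params$noise_sd)
    }
    clip <- function(m) {
      m <- round(m)
      m[m < 0] <- 0
      m[m > 65535] <- 65535
      storage.mode(m) <- "integer"
      m
    }
    dox[, , k] <- clip(dox_f)
    nb[, , k] <- clip(nb_f)
    dic[, , k] <- clip(dic_f)
  }
  series <- image_series(list(nucblue = nb, dox = dox, dic = dic),
                         pixel_size = px, timestamps = timestamps,
                         t_lag = params$t_lag)
  boundary_trace <- data.frame(
    time_s = timestamps,
    intensity = slope * conc[1, ] + icpt,
    concentration_uM = conc[1, ])
  truth <- list(params = unclass(params), cells = cells,
                boundary_trace = boundary_trace,
                profiles_true = prof,
                gel_length_eff = lat$length_eff)
  if (!is.null(out_dir)) {
    write_image_series(series, out_dir)
    man <- truth
    man$profiles_true <- NULL
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    df <- as.data.frame(prof)
    names(df)[3] <- "concentration_uM"
    df$units <- NULL
    df$intensity <- slope * df$concentration_uM + icpt
    utils::write.csv(df, file.path(out_dir, "profiles_true.csv"),
                     row.names = FALSE)
  }
  list(series = series, truth = truth)
}

# random, non-overlapping-free placement of cells inside the gel bounds
place_cells <- function(params, lat) {
  n <- params$n_cells
  if (n == 0) {
    return(data.frame(id = integer(0), y_um = numeric(0),
                      x_um = numeric(0), radius_um = numeric(0)))
  }
  r <- stats::rnorm(n, params$cell_radius_mean, params$cell_radius_sd)
  r <- pmax(r, 3)
  xmax <- (lat$nx - 1) * params$pixel_size
  if (any(2 * r >= lat$length_eff) || any(2 * r >= xmax)) {
    stop("cells cannot be placed without exceeding gel bounds")
  }
  # keep nuclei separated so the ground-truth count is unambiguous
  y <- numeric(n); x <- numeric(n)
  for (i in seq_len(n)) {
    for (attempt in 1:200) {
      yi <- stats::runif(1, r[i], lat$length_eff - r[i])
      xi <- stats::runif(1, r[i], xmax - r[i])
      if (i == 1 || all(sqrt((y[seq_len(i - 1)] - yi)^2 +
                             (x[seq_len(i - 1)] - xi)^2) >
                        (r[seq_len(i - 1)] + r[i] + 5))) {
        y[i] <- yi; x[i] <- xi
        break
      }
      if (attempt == 200) stop("cells cannot be placed without exceeding gel bounds")
    }
  }
  data.frame(id = seq_len(n), y_um = y, x_um = x, radius_um = r)
}
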