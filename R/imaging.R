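#' Multi-channel time-lapse image series
#'
#' Container for the three acquisition channels of a chip experiment:
#' the nuclear stain (`nucblue`), the drug fluorescence (`dox`) and the
#' transmitted-light channel (`dic`). Each channel is a 3D integer array
#' `[y, x, t]`; rows run along the gel axis. Timestamps are absolute
#' seconds since drug addition, so the first frame is at `t_lag`.
#'
#' @param channels Named list of 3D arrays (any of `nucblue`, `dox`,
#'   `dic`), all with identical dimensions.
#' @param pixel_size Pixel size (µm/pixel).
#' @param timestamps Acquisition times (s since drug addition), strictly
#'   increasing, first `>= t_lag`.
#' @param t_lag Lag (s) between drug addition and the first acquisition.
#' @return An object of class `image_series`.
#' @export
image_series <- function(channels, pixel_size, timestamps, t_lag) {
  stopifnot(is.list(channels), length(channels) >= 1)
  dims <- lapply(channels, dim)
  d0 <- dims[[1]]
  for (nm in names(dims)) {
    if (!identical(dims[[nm]], d0)) {
      stop(sprintf("channel '%s' has dimensions %s; expected %s",
                   nm, paste(dims[[nm]], collapse = "x"),
                   paste(d0, collapse = "x")))
    }
  }
  if (length(timestamps) != d0[3]) {
    stop("number of timestamps must equal the number of frames")
  }
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  if (t_lag <= 0) stop("t_lag must be positive")
  if (timestamps[1] < t_lag - 1e-9) stop("timestamps[1] must be >= t_lag")
  structure(list(channels = channels, pixel_size = pixel_size,
                 timestamps = as.numeric(timestamps), t_lag = t_lag),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_series> %d x %d px, %d frames, channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel %.6g um, t = %.0f .. %.0f s (t_lag %.0f s)\n",
              x$pixel_size, x$timestamps[1],
              x$timestamps[length(x$timestamps)], x$t_lag))
  invisible(x)
}

#' Write an image series as per-channel multi-page TIFF
#'
#' Each channel becomes `<name>.tif` with one 16-bit page per time point,
#' plus a `series_meta.json` holding pixel size, timestamps and t_lag.
#'
#' @param series An [image_series].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_image_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(series$channels)) {
    arr <- series$channels[[nm]]
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) arr[, , k] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  }
  meta <- list(pixel_size = series$pixel_size,
               timestamps = series$timestamps, t_lag = series$t_lag)
  jsonlite::write_json(meta, file.path(dir, "series_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multi-channel TIFF time series
#'
#' Reads per-channel multi-page TIFF stacks into an [image_series].
#'
#' @param path Directory containing the stacks (and optionally
#'   `series_meta.json` written by [write_image_series()]).
#' @param channel_map Named character vector mapping channel names
#'   (`nucblue`, `dox`, `dic`) to TIFF file names within `path`. Missing
#'   channels (e.g. no DIC) are permitted.
#' @param metadata List with `pixel_size` (µm), `t_lag` (s) and either
#'   `timestamps` (s) or `frame_interval` (s). Values found in
#'   `series_meta.json` are used as defaults.
#' @return An [image_series].
#' @export
read_image_series <- function(path,
                              channel_map = c(nucblue = "nucblue.tif",
                                              dox = "dox.tif",
                                              dic = "dic.tif"),
                              metadata = list()) {
  meta_path <- file.path(path, "series_meta.json")
  if (file.exists(meta_path)) {
    stored <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    for (nm in names(stored)) {
      if (is.null(metadata[[nm]])) metadata[[nm]] <- stored[[nm]]
    }
  }
  channels <- list()
  for (nm in names(channel_map)) {
    f <- file.path(path, channel_map[[nm]])
    if (!file.exists(f)) next
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      stop(sprintf("channel '%s': page %d is %dx%d, expected %dx%d",
                   nm, bad, dims[1, bad], dims[2, bad],
                   dims[1, 1], dims[2, 1]))
    }
    arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 65535)
    channels[[nm]] <- arr
  }
  if (!length(channels)) stop("no channel stacks found under ", path)
  nt <- dim(channels[[1]])[3]
  ts <- metadata$timestamps
  if (is.null(ts)) {
    if (is.null(metadata$frame_interval)) {
      stop("metadata must provide timestamps or frame_interval")
    }
    if (is.null(metadata$t_lag)) stop("metadata must provide t_lag")
    ts <- metadata$t_lag + (seq_len(nt) - 1) * metadata$frame_interval
  }
  image_series(channels, pixel_size = metadata$pixel_size,
               timestamps = ts, t_lag = metadata$t_lag)
}

#' Gel geometry along the reservoir axis
#'
#' Locations (µm, image frame: zero at the top image row) of the donor and
#' acceptor gel interfaces, and the lower/upper boundaries of the interval
#' used for diffusion fitting. The donor interface sits at low y.
#'
#' @param y_donor_interface,y_acceptor_interface Gel interfaces (µm).
#' @param y_lower_boundary,y_upper_boundary Fit interval (µm); defaults:
#'   150 µm inside the donor interface, and the acceptor interface.
#' @param pixel_size Pixel size (µm) used to snap values to the lattice.
#' @return An object of class `gel_geometry`.
#' @export
gel_geometry <- function(y_donor_interface, y_acceptor_interface,
                         y_lower_boundary = NULL, y_upper_boundary = NULL,
                         pixel_size = 1.250339) {
  snap <- function(v) round(v / pixel_size) * pixel_size
  y_donor_interface <- snap(y_donor_interface)
  y_acceptor_interface <- snap(y_acceptor_interface)
  if (is.null(y_lower_boundary)) y_lower_boundary <- y_donor_interface + 150
  if (is.null(y_upper_boundary)) y_upper_boundary <- y_acceptor_interface
  y_lower_boundary <- snap(y_lower_boundary)
  y_upper_boundary <- snap(y_upper_boundary)
  if (!(y_donor_interface < y_lower_boundary &&
        y_lower_boundary < y_upper_boundary &&
        y_upper_boundary <= y_acceptor_interface + 1e-9)) {
    stop("require donor < lower boundary < upper boundary <= acceptor")
  }
  structure(list(y_donor_interface = y_donor_interface,
                 y_acceptor_interface = y_acceptor_interface,
                 y_lower_boundary = y_lower_boundary,
                 y_upper_boundary = y_upper_boundary,
                 pixel_size = pixel_size),
            class = "gel_geometry")
}

#' @export
print.gel_geometry <- function(x, ...) {
  cat(sprintf("<gel_geometry> donor %.1f um, acceptor %.1f um; fit [%.1f, %.1f] um\n",
              x$y_donor_interface, x$y_acceptor_interface,
              x$y_lower_boundary, x$y_upper_boundary))
  invisible(x)
}

#' Locate the gel interfaces from the DIC channel
#'
#' The physical gel boundaries appear as dark lines in the transmitted
#' light (DIC) channel. The time-averaged DIC image is averaged across the
#' transverse direction, and the first and last rows falling well below
#' the background level are taken as the donor and acceptor interfaces.
#'
#' @param series An [image_series].
#' @param overrides Optional list with `y_donor_interface` and
#'   `y_acceptor_interface` (µm); when both are given they are used
#'   verbatim (no DIC needed) along with optional `y_lower_boundary`,
#'   `y_upper_boundary`.
#' @return A [gel_geometry].
#' @export
detect_gel_boundaries <- function(series, overrides = NULL) {
  if (!is.null(overrides) &&
      !is.null(overrides$y_donor_interface) &&
      !is.null(overrides$y_acceptor_interface)) {
    return(gel_geometry(overrides$y_donor_interface,
                        overrides$y_acceptor_interface,
                        overrides$y_lower_boundary,
                        overrides$y_upper_boundary,
                        pixel_size = series$pixel_size))
  }
  if (is.null(series$channels$dic)) {
    stop("no DIC channel and no geometry overrides; supply y_donor_interface and y_acceptor_interface manually")
  }
  dic <- series$channels$dic
  rowmean <- apply(dic, 1, mean)
  bg <- stats::median(rowmean)
  drop <- bg - rowmean
  thr <- 0.5 * max(drop)
  if (max(drop) < 0.05 * bg) {
    stop("gel boundary detection failed (no dark lines in DIC); supply geometry overrides")
  }
  dark <- which(drop > thr)
  donor_row <- min(dark)
  acceptor_row <- max(dark)
  if ((acceptor_row - donor_row) < 0.5 * length(rowmean)) {
    stop("gel boundary detection not confident; supply geometry overrides")
  }
  gel_geometry((donor_row - 1) * series$pixel_size,
               (acceptor_row - 1) * series$pixel_size,
               pixel_size = series$pixel_size)
}

#' Extract the axial fluorescence profile
#'
#' Reproduces the line-ROI measurement: for each time point, the mean
#' intensity across the transverse (x) direction over a stripe of width
#' `roi_width_um`, for every axial (y) pixel between the donor and
#' acceptor interfaces. The returned profile uses y = 0 at the donor
#' interface.
#'
#' @param series An [image_series].
#' @param geometry A [gel_geometry].
#' @param channel Channel name (default `"dox"`).
#' @param roi_width_um Stripe width (µm, default 100). The stripe is
#'   centred transversely unless `roi_center_x_um` is given.
#' @param roi_center_x_um Optional transverse centre of the stripe (µm).
#' @param exclude_mask Optional logical matrix (image dimensions); `TRUE`
#'   pixels (e.g. cell masks) are excluded from the transverse average.
#' @return A [profile_series] in intensity units.
#' @export
extract_profile <- function(series, geometry, channel = "dox",
                            roi_width_um = 100, roi_center_x_um = NULL,
                            exclude_mask = NULL) {
  arr <- series$channels[[channel]]
  if (is.null(arr)) stop(sprintf("channel '%s' absent", channel))
  d <- dim(arr)
  px <- series$pixel_size
  width_px <- max(1L, round(roi_width_um / px))
  if (width_px > d[2]) stop("ROI width exceeds image width")
  cx <- if (is.null(roi_center_x_um)) (d[2] + 1) / 2 else roi_center_x_um / px + 1
  x0 <- max(1L, round(cx - width_px / 2))
  x1 <- min(d[2], x0 + width_px - 1L)
  r0 <- round(geometry$y_donor_interface / px) + 1L
  r1 <- round(geometry$y_acceptor_interface / px) + 1L
  r1 <- min(r1, d[1])
  rows <- r0:r1
  nt <- d[3]
  vals <- matrix(NA_real_, length(rows), nt)
  keep <- NULL
  if (!is.null(exclude_mask)) keep <- !exclude_mask[rows, x0:x1, drop = FALSE]
  for (k in seq_len(nt)) {
    sub <- arr[rows, x0:x1, k, drop = FALSE]
    dim(sub) <- dim(sub)[1:2]
    if (is.null(keep)) {
      vals[, k] <- rowMeans(sub)
    } else {
      s <- rowSums(sub * keep)
      n <- rowSums(keep)
      vals[, k] <- ifelse(n > 0, s / n, rowMeans(sub))
    }
  }
  profile_series((rows - r0) * px, series$timestamps, vals,
                 units = "a.u.", pixel_size = px)
}

#' Baseline-correct a profile series
#'
#' Two correction modes, both referenced to the first acquired frame
#' (t = t_lag): `far_segment` subtracts a single scalar, the mean of the
#' first profile over the final 100 µm of gel furthest from the donor;
#' `full_profile` subtracts the entire first profile point-wise from every
#' profile. Negative values are retained.
#'
#' @param profiles A [profile_series] whose first time is the reference
#'   frame.
#' @param mode `"far_segment"` or `"full_profile"`.
#' @return A corrected [profile_series] (baseline_mode tag set).
#' @export
baseline_correct <- function(profiles, mode = c("far_segment", "full_profile")) {
  mode <- match.arg(mode)
  v <- profiles$values
  first <- v[, 1]
  if (mode == "far_segment") {
    ymax <- max(profiles$y_um)
    sel <- profiles$y_um >= ymax - 100
    v <- v - mean(first[sel])
  } else {
    v <- v - first
  }
  profile_series(profiles$y_um, profiles$times_s, v,
                 units = profiles$units, baseline_mode = mode,
                 pixel_size = profiles$pixel_size)
}

#' Fit a linear fluorescence calibration curve
#'
#' Ordinary least squares of intensity on concentration over the standard
#' series (the assay uses 1-20 µM standards, within the linear range of
#' the drug's fluorescence; self-quenching causes deviations above about
#' 25 µM, hence the valid-range flagging in [to_concentration()]).
#'
#' @param concentrations Standard concentrations (µM), at least 3 distinct.
#' @param intensities Measured intensities (a.u.).
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared` and `valid_range`.
#' @export
fit_calibration <- function(concentrations, intensities) {
  if (length(concentrations) < 3) stop("need at least 3 calibration points")
  if (length(unique(concentrations)) < 2 ||
      stats::var(concentrations) == 0) {
    stop("calibration concentrations must vary")
  }
  fit <- stats::lm(intensities ~ concentrations)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 valid_range = range(concentrations)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> I = %.4g * C + %.4g (R^2 = %.4f), valid %g-%g uM\n",
              x$slope, x$intercept, x$r_squared,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Check a calibration curve against the linearity acceptance criterion
#'
#' The pipeline only accepts calibration curves with R^2 above 0.97
#' (linear-range fluorescence); anything poorer indicates quenching or a
#' failed standard series.
#'
#' @param curve A [calibration_curve].
#' @param min_r_squared Minimum acceptable R^2 (default 0.97).
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_calibration <- function(curve, min_r_squared = 0.97) {
  if (curve$r_squared < min_r_squared) {
    stop(sprintf("calibration R^2 = %.3f below the acceptance criterion %.2f",
                 curve$r_squared, min_r_squared))
  }
  invisible(TRUE)
}

#' Convert intensity to concentration
#'
#' Inverts the linear calibration, `C = (I - intercept) / slope`. Values
#' outside the calibrated concentration range are returned but flagged via
#' the `out_of_range` attribute (fluorescence self-quenching makes the
#' relation nonlinear at high concentrations).
#'
#' @param intensity Intensities (a.u.), vectorised.
#' @param curve A [calibration_curve].
#' @return Concentrations (µM) with logical attribute `out_of_range`.
#' @export
to_concentration <- function(intensity, curve) {
  if (curve$slope <= 0) stop("calibration slope must be positive")
  conc <- (intensity - curve$intercept) / curve$slope
  oor <- conc < curve$valid_range[1] - 1e-12 |
         conc > curve$valid_range[2] + 1e-12
  attr(conc, "out_of_range") <- oor
  conc
}

#' Convert a profile series to concentration units
#'
#' @param profiles A [profile_series] in intensity units.
#' @param curve A [calibration_curve].
#' @return A [profile_series] in µM.
#' @export
profiles_to_concentration <- function(profiles, curve) {
  conc <- to_concentration(profiles$values, curve)
  attr(conc, "out_of_range") <- NULL
  profile_series(profiles$y_um, profiles$times_s, conc,
                 units = "uM", baseline_mode = profiles$baseline_mode,
                 pixel_size = profiles$pixel_size)
}
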