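#' Axial fluorescence profile series
#'
#' A `profile_series` holds one intensity (or concentration) vector per
#' imaging time point, sampled on the axial pixel lattice of the gel
#' reservoir. The axial coordinate `y` is zero at the donor-side gel
#' interface and increases toward the acceptor (receiver) interface.
#'
#' @param y_um Numeric vector of axial positions (µm), uniformly spaced at
#'   the pixel size.
#' @param times_s Numeric vector of acquisition times in seconds since drug
#'   addition (absolute times, i.e. including the lag time `t_lag`).
#' @param values Numeric matrix, `length(y_um)` rows by `length(times_s)`
#'   columns.
#' @param units Either `"a.u."` (fluorescence intensity) or `"uM"`
#'   (concentration).
#' @param baseline_mode Baseline-correction tag: `"none"`, `"far_segment"`
#'   or `"full_profile"`.
#' @param pixel_size Axial pixel size in µm (optional; inferred from
#'   `y_um` when omitted).
#' @return An object of class `profile_series`.
#' @export
profile_series <- function(y_um, times_s, values,
                           units = c("a.u.", "uM"),
                           baseline_mode = "none",
                           pixel_size = NULL) {
  units <- match.arg(units)
  y_um <- as.numeric(y_um)
  times_s <- as.numeric(times_s)
  values <- as.matrix(values)
  if (nrow(values) != length(y_um) || ncol(values) != length(times_s)) {
    stop("values must be a length(y_um) x length(times_s) matrix")
  }
  if (length(times_s) > 1 && any(diff(times_s) <= 0)) {
    stop("times_s must be strictly increasing")
  }
  if (length(y_um) > 1) {
    dy <- diff(y_um)
    if (max(abs(dy - dy[1])) > 1e-6 * abs(dy[1])) {
      stop("y_um must be uniformly spaced")
    }
    if (is.null(pixel_size)) pixel_size <- dy[1]
  }
  structure(
    list(y_um = y_um, times_s = times_s, values = values,
         units = units, baseline_mode = baseline_mode,
         pixel_size = pixel_size),
    class = "profile_series")
}

#' @export
print.profile_series <- function(x, ...) {
  cat(sprintf("<profile_series> %d y-positions x %d times [%s], baseline: %s\n",
              length(x$y_um), length(x$times_s), x$units, x$baseline_mode))
  cat(sprintf("  y: %.1f .. %.1f um, t: %.0f .. %.0f s\n",
              min(x$y_um), max(x$y_um), min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' @export
as.data.frame.profile_series <- function(x, ...) {
  data.frame(
    time_s = rep(x$times_s, each = length(x$y_um)),
    y_um = rep(x$y_um, times = length(x$times_s)),
    value = as.vector(x$values),
    units = x$units)
}

#' Profile at a single time
#'
#' Returns the profile vector at time `t`, linearly interpolating between
#' the two bracketing frames when `t` falls between acquisitions.
#'
#' @param profiles A [profile_series].
#' @param t Time in seconds.
#' @return Numeric vector over `profiles$y_um`.
#' @export
profile_at_time <- function(profiles, t) {
  ts <- profiles$times_s
  if (t < min(ts) - 1e-9 || t > max(ts) + 1e-9) {
    stop(sprintf("time %.1f s outside measured range [%.1f, %.1f]",
                 t, min(ts), max(ts)))
  }
  j <- which(abs(ts - t) < 1e-9)
  if (length(j) == 1) return(profiles$values[, j])
  hi <- which(ts > t)[1]
  lo <- hi - 1
  w <- (t - ts[lo]) / (ts[hi] - ts[lo])
  (1 - w) * profiles$values[, lo] + w * profiles$values[, hi]
}

# subset a profile_series to selected times (by index)
subset_times <- function(profiles, idx) {
  profile_series(profiles$y_um, profiles$times_s[idx],
                 profiles$values[, idx, drop = FALSE],
                 units = profiles$units,
                 baseline_mode = profiles$baseline_mode,
                 pixel_size = profiles$pixel_size)
}

#' Write a profile series to tidy CSV
#'
#' Columns are `time_s`, `y_um` and either `intensity` or `conc_uM`
#' depending on the units tag.
#'
#' @param profiles A [profile_series].
#' @param path Output CSV file.
#' @return Invisibly, the path.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- as.data.frame(profiles)
  names(df)[3] <- if (profiles$units == "uM") "conc_uM" else "intensity"
  df$units <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a profile series from tidy CSV
#'
#' Inverse of [write_profiles_csv()].
#'
#' @param path CSV with columns `time_s`, `y_um`, and `intensity` or
#'   `conc_uM`.
#' @return A [profile_series].
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  vcol <- intersect(c("intensity", "conc_uM"), names(df))[1]
  if (is.na(vcol)) stop("no intensity or conc_uM column in ", path)
  times <- sort(unique(df$time_s))
  ys <- sort(unique(df$y_um))
  m <- matrix(NA_real_, length(ys), length(times))
  m[cbind(match(df$y_um, ys), match(df$time_s, times))] <- df[[vcol]]
  profile_series(ys, times, m,
                 units = if (vcol == "conc_uM") "uM" else "a.u.")
}
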