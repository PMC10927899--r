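#' Time-dependent lower boundary condition
#'
#' The donor-side Dirichlet condition for the diffusion solver is built
#' from the measured intensities at the lower fit boundary. In
#' `exp_then_spline` mode the interval from drug addition up to the second
#' measurement follows the saturating exponential
#' `I(t) = I_inf * (1 - exp(-beta * t))`, anchored at `I(0) = 0`, and later
#' intervals follow a linear spline through the measured values. In
#' `all_spline` mode a linear spline from the origin through all measured
#' values is used. Evaluation beyond the last knot holds the last value.
#'
#' @param mode `"exp_then_spline"` or `"all_spline"`.
#' @param I_inf,beta Exponential plateau (a.u.) and rate (1/s); required in
#'   `exp_then_spline` mode.
#' @param knots Data frame with columns `time_s`, `value`: the measured
#'   boundary intensities used as spline knots. In `exp_then_spline` mode
#'   the spline covers times from the second measurement onward.
#' @param t_switch Time (s) at which the exponential hands over to the
#'   spline (the second measurement time); `exp_then_spline` mode only.
#' @return An object of class `boundary_function`.
#' @export
boundary_function <- function(mode = c("exp_then_spline", "all_spline"),
                              I_inf = NULL, beta = NULL,
                              knots = NULL, t_switch = NULL) {
  mode <- match.arg(mode)
  if (mode == "exp_then_spline") {
    if (is.null(I_inf) || is.null(beta)) {
      stop("exp_then_spline mode requires I_inf and beta")
    }
    if (is.null(t_switch)) {
      t_switch <- if (!is.null(knots) && nrow(knots)) min(knots$time_s) else Inf
    }
  }
  if (!is.null(knots)) {
    knots <- knots[order(knots$time_s), , drop = FALSE]
  }
  structure(list(mode = mode, I_inf = I_inf, beta = beta,
                 knots = knots, t_switch = t_switch),
            class = "boundary_function")
}

#' Evaluate a boundary function
#'
#' @param bf A [boundary_function].
#' @param t Times in seconds (vectorised).
#' @return Boundary intensity at `t`; zero at `t = 0` in both modes.
#' @export
boundary_eval <- function(bf, t) {
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    if (bf$mode == "exp_then_spline" && ti <= bf$t_switch) {
      return(bf$I_inf * (1 - exp(-bf$beta * ti)))
    }
    kn <- bf$knots
    if (bf$mode == "all_spline") {
      kn <- rbind(data.frame(time_s = 0, value = 0), kn)
    }
    if (is.null(kn) || nrow(kn) == 0) {
      # exponential segment with no later knots: extend the exponential
      return(bf$I_inf * (1 - exp(-bf$beta * ti)))
    }
    if (ti >= kn$time_s[nrow(kn)]) return(kn$value[nrow(kn)])
    stats::approx(kn$time_s, kn$value, xout = ti)$y
  }, numeric(1))
}

#' @export
print.boundary_function <- function(x, ...) {
  cat(sprintf("<boundary_function> mode: %s\n", x$mode))
  if (x$mode == "exp_then_spline") {
    cat(sprintf("  I_inf = %.4g a.u., beta = %.4g 1/s, switch at %.0f s\n",
                x$I_inf, x$beta, x$t_switch))
  }
  if (!is.null(x$knots)) cat(sprintf("  %d spline knots\n", nrow(x$knots)))
  invisible(x)
}

#' Noise-reduced boundary intensity
#'
#' The boundary value used for the condition at the lower fit boundary is
#' the 11-point mean of the measured profile: the pixel at `y_lb` together
#' with the 5 pixels on either side.
#'
#' @param profiles A [profile_series].
#' @param y_lb Lower-boundary position (µm, profile frame).
#' @param time Measurement time (s); must match a profile time.
#' @return Scalar mean intensity.
#' @export
boundary_value <- function(profiles, y_lb, time) {
  j <- which(abs(profiles$times_s - time) < 1e-6)
  if (length(j) != 1) stop("time does not match a measured profile")
  i <- which.min(abs(profiles$y_um - y_lb))
  n <- length(profiles$y_um)
  if (i <= 5 || i > n - 5) {
    stop("y_lb within 5 pixels of the profile edge; cannot form 11-point mean")
  }
  mean(profiles$values[(i - 5):(i + 5), j])
}

#' Classify the early boundary-intensity shape
#'
#' Decides whether the boundary intensity grows concavely from zero over
#' the first two measurements (saturating-exponential regime) or linearly /
#' convexly (linear-spline regime). Growth is concave when
#' `I2/I1 < t2/t1`; ties break toward the spline.
#'
#' @param t1,I1 First measurement time (s) and boundary intensity.
#' @param t2,I2 Second measurement time and intensity.
#' @return `"exp_then_spline"` or `"all_spline"`.
#' @export
classify_boundary_shape <- function(t1, I1, t2, I2) {
  stopifnot(t1 > 0, t2 > t1)
  if (I1 <= 0 || I2 <= 0) {
    warning("non-positive boundary intensities; exponential form unfittable, using linear spline")
    return("all_spline")
  }
  if (I2 / I1 < t2 / t1) "exp_then_spline" else "all_spline"
}

#' Two-point fit of the saturating-exponential boundary model
#'
#' Solves `I = I_inf * (1 - exp(-beta * t))` exactly through the two first
#' boundary measurements, with the implicit anchor `I(0) = 0`. When
#' `t2 = 2 t1` the closed form `exp(-beta t1) = I2/I1 - 1` is used;
#' otherwise beta is found by bisection on `[1e-8, 1]` 1/s to a relative
#' tolerance of 1e-10.
#'
#' @param t1,I1,t2,I2 The two measurements (times in s, intensities a.u.).
#' @return List with `I_inf` and `beta`.
#' @export
fit_eq1 <- function(t1, I1, t2, I2) {
  stopifnot(t1 > 0, t2 > t1, I1 > 0, I2 > 0)
  ratio <- I2 / I1
  if (ratio <= 1) {
    # saturated by the first measurement: beta at the top of the bracket
    warning("boundary already saturated at the first measurement; beta capped")
    beta <- 1
    return(list(I_inf = I1 / (1 - exp(-beta * t1)), beta = beta))
  }
  if (abs(t2 - 2 * t1) < 1e-9 * t1) {
    x <- ratio - 1          # exp(-beta * t1)
    if (x >= 1) stop("growth not concave; exponential model does not apply")
    beta <- -log(x) / t1
    return(list(I_inf = I1 / (1 - x), beta = beta))
  }
  # g(beta) = I1 * (1 - exp(-beta t2)) - I2 * (1 - exp(-beta t1)) = 0
  g <- function(b) I1 * (1 - exp(-b * t2)) - I2 * (1 - exp(-b * t1))
  lo <- 1e-8; hi <- 1
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0) stop("no root for beta in [1e-8, 1] 1/s")
  while ((hi - lo) / hi > 1e-10) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) * glo <= 0) hi <- mid else lo <- mid
  }
  beta <- 0.5 * (lo + hi)
  list(I_inf = I1 / (1 - exp(-beta * t1)), beta = beta)
}

#' Build the lower boundary condition from measured profiles
#'
#' Computes the 11-point boundary intensity at each measured time, decides
#' the early-time functional form from the first two values, and assembles
#' the full boundary condition: a saturating exponential on the interval up
#' to the second measurement (when the growth is concave) followed by a
#' linear spline through the remaining values, or a linear spline
#' throughout.
#'
#' @param profiles Baseline-corrected [profile_series].
#' @param geometry A [gel_geometry]; its `y_lower_boundary` locates the
#'   boundary pixel.
#' @return A [boundary_function].
#' @export
build_boundary_function <- function(profiles, geometry) {
  times <- profiles$times_s
  if (length(times) < 2) stop("need at least 2 measured time points")
  y_lb <- geometry$y_lower_boundary - geometry$y_donor_interface
  vals <- vapply(times, function(t) boundary_value(profiles, y_lb, t),
                 numeric(1))
  mode <- classify_boundary_shape(times[1], vals[1], times[2], vals[2])
  knots <- data.frame(time_s = times, value = vals)
  if (mode == "exp_then_spline") {
    p <- fit_eq1(times[1], vals[1], times[2], vals[2])
    boundary_function("exp_then_spline", I_inf = p$I_inf, beta = p$beta,
                      knots = knots[-1, , drop = FALSE], t_switch = times[2])
  } else {
    boundary_function("all_spline", knots = knots)
  }
}
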