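#' Select the two profiles used for diffusion fitting
#'
#' Out of the candidate acquisition times, a time point qualifies when
#' (i) the sink end is still essentially drug-free: the mean
#' baseline-corrected intensity over the final 100 µm of the fit interval
#' is below `sink_frac` of that profile's maximum within the interval; and
#' (ii) the gradient has advanced far enough for a well-conditioned fit:
#' the intensity exceeds `reach_frac` of the profile maximum somewhere
#' beyond `reach_um` from the lower fit boundary. The earliest two
#' qualifying times are returned, so fast matrices are fitted on early
#' frames and slow matrices on later ones.
#'
#' @param profiles Baseline-corrected [profile_series].
#' @param geometry A [gel_geometry].
#' @param sink_frac Sink-end threshold (default 0.02).
#' @param reach_frac Penetration threshold (default 0.05).
#' @param reach_um Penetration distance from the lower boundary (default
#'   1000 µm).
#' @return Numeric vector `c(t_a, t_b)` (s). Errors when fewer than two
#'   times qualify, listing the failed criterion per time.
#' @export
select_fit_timepoints <- function(profiles, geometry,
                                  sink_frac = 0.02, reach_frac = 0.05,
                                  reach_um = 1000) {
  y <- profiles$y_um
  y_lb <- geometry$y_lower_boundary - geometry$y_donor_interface
  y_ub <- geometry$y_upper_boundary - geometry$y_donor_interface
  infit <- y >= y_lb - 1e-9 & y <= y_ub + 1e-9
  tail_sel <- infit & y >= y_ub - 100
  reach_sel <- infit & y > y_lb + reach_um
  report <- character(0)
  ok_times <- numeric(0)
  for (j in seq_along(profiles$times_s)) {
    v <- profiles$values[, j]
    vmax <- max(v[infit])
    if (vmax <= 0) {
      report <- c(report, sprintf("t=%.0f s: no signal", profiles$times_s[j]))
      next
    }
    sink_ok <- mean(v[tail_sel]) < sink_frac * vmax
    reach_ok <- any(v[reach_sel] > reach_frac * vmax)
    if (sink_ok && reach_ok) {
      ok_times <- c(ok_times, profiles$times_s[j])
    } else {
      why <- c(if (!sink_ok) "sink end not drug-free",
               if (!reach_ok) sprintf("profile shorter than %g um", reach_um))
      report <- c(report, sprintf("t=%.0f s: %s", profiles$times_s[j],
                                  paste(why, collapse = "; ")))
    }
  }
  if (length(ok_times) < 2) {
    stop("fewer than two time points qualify for fitting:\n  ",
         paste(report, collapse = "\n  "))
  }
  ok_times[1:2]
}

#' Sample measured profiles onto the fit grid
#'
#' Restricts a profile series to the fit-grid nodes (every 10th pixel
#' between the fit boundaries) at the selected times.
#'
#' @param profiles Baseline-corrected [profile_series].
#' @param geometry A [gel_geometry].
#' @param grid A [fit_grid].
#' @param times The two selected times (s).
#' @return A [profile_series] on the grid nodes.
#' @export
profiles_on_grid <- function(profiles, geometry, grid, times) {
  y_img <- profiles$y_um + geometry$y_donor_interface
  idx <- vapply(grid$y_nodes, function(yn) {
    i <- which.min(abs(y_img - yn))
    if (abs(y_img[i] - yn) > grid$pixel_size / 2 + 1e-6) {
      stop("fit-grid node off the measured pixel lattice")
    }
    i
  }, integer(1))
  jt <- vapply(times, function(t) {
    j <- which(abs(profiles$times_s - t) < 1e-6)
    if (length(j) != 1) stop("selected time not among measured times")
    j
  }, integer(1))
  profile_series(grid$y_nodes - grid$y_nodes[1], times,
                 profiles$values[idx, jt, drop = FALSE],
                 units = profiles$units,
                 baseline_mode = profiles$baseline_mode,
                 pixel_size = grid$dy)
}

# sum of squared residuals between CN prediction and the two measured
# profiles; residuals are taken at interior nodes (both boundary nodes are
# prescribed by the Dirichlet data). Both time points weighted equally.
cn_sse <- function(D, boundary, grid, measured, solve_times) {
  pred <- solve_crank_nicolson(D, boundary, grid, max(solve_times),
                               output_times = solve_times)
  n <- length(grid$y_nodes)
  r <- measured$values[2:(n - 1), ] - pred$values[2:(n - 1), ]
  list(sse = sum(r^2), resid = as.vector(r))
}

#' Fit the apparent diffusion coefficient
#'
#' Minimises the joint sum of squared differences between
#' Crank-Nicolson-predicted and measured baseline-corrected profiles at
#' two time points, over the single free parameter D (optimised as log D
#' to enforce positivity) with a Levenberg-Marquardt iteration: damping
#' starts at 1e-3, is multiplied by 10 on a rejected step and divided by
#' 10 on an accepted one; convergence is declared when the relative change
#' in SSE between consecutive accepted iterations falls below 1e-6.
#' Measurement times are rounded to the nearest solver step (30 s).
#'
#' @param measured [profile_series] at exactly two times, already sampled
#'   on the fit grid (see [profiles_on_grid()]).
#' @param boundary A [boundary_function].
#' @param grid A [fit_grid].
#' @param D0 Initial guess (µm²/s). Default: penetration-depth heuristic
#'   `D0 = x50^2 / (4 t_a)` where `x50` is the half-maximum position of
#'   the first fitted profile.
#' @param max_iter Iteration cap (default 200); non-convergence is flagged,
#'   not an error.
#' @param sse_tol Relative SSE convergence tolerance (default 1e-6).
#' @return An object of class `diffusion_fit` with `D_app`, `sse`,
#'   `n_iterations`, `converged`, `times_used`, `time_rounding_s`,
#'   `boundary`, `grid`.
#' @export
fit_diffusion_coefficient <- function(measured, boundary, grid, D0 = NULL,
                                      max_iter = 200L, sse_tol = 1e-6) {
  if (ncol(measured$values) != 2) stop("measured must hold exactly two times")
  if (all(abs(measured$values) < 1e-12)) {
    stop("degenerate all-zero measurement; nothing to fit")
  }
  times <- measured$times_s
  solve_times <- round(times / grid$dt) * grid$dt
  if (any(solve_times <= 0)) stop("fit times round to t <= 0")
  if (is.null(D0)) {
    v <- measured$values[, 1]
    half <- 0.5 * max(v)
    below <- which(v <= half)
    x50 <- if (length(below)) measured$y_um[below[1]] else max(measured$y_um)
    x50 <- max(x50, grid$dy)
    D0 <- x50^2 / (4 * times[1])
  }
  p <- log(D0)
  ev <- cn_sse(exp(p), boundary, grid, measured, solve_times)
  sse <- ev$sse
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  h <- 1e-4
  while (iter < max_iter) {
    iter <- iter + 1L
    ev_h <- cn_sse(exp(p + h), boundary, grid, measured, solve_times)
    # Jacobian of the residual vector wrt p (residual = measured - model)
    jac <- (ev_h$resid - ev$resid) / h
    g <- sum(jac * ev$resid)          # -(1/2) dSSE/dp
    H <- sum(jac * jac)
    if (H <= 0) break
    repeat {
      delta <- -g / (H * (1 + lambda))
      ev_new <- cn_sse(exp(p + delta), boundary, grid, measured, solve_times)
      if (ev_new$sse <= sse) {
        rel <- abs(sse - ev_new$sse) / max(sse, .Machine$double.eps)
        p <- p + delta
        ev <- ev_new
        sse <- ev_new$sse
        lambda <- max(lambda / 10, 1e-12)
        if (rel < sse_tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (converged || lambda > 1e12) break
  }
  structure(list(D_app = exp(p), sse = sse, n_iterations = iter,
                 converged = converged, times_used = times,
                 time_rounding_s = max(abs(times - solve_times)),
                 boundary = boundary, grid = grid,
                 baseline_mode = measured$baseline_mode),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D_app = %.4g um^2/s (SSE %.4g, %d iterations, %s)\n",
              x$D_app, x$sse, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  fitted at t = %s s, boundary mode %s\n",
              paste(round(x$times_used), collapse = ", "), x$boundary$mode))
  invisible(x)
}

#' Full diffusion-coefficient estimation from measured profiles
#'
#' Pipeline driver: builds the fit grid between the configured boundaries,
#' constructs the data-driven lower boundary condition, selects the two
#' fit time points, samples the measurements onto the grid and runs the
#' Levenberg-Marquardt fit.
#'
#' @param profiles Baseline-corrected [profile_series] (>= 4 times:
#'   boundary knots come from all of them).
#' @param geometry A [gel_geometry].
#' @param times Optional explicit pair of fit times (s); default
#'   [select_fit_timepoints()].
#' @param D0 Optional initial guess (µm²/s).
#' @param ... Passed to [select_fit_timepoints()].
#' @return A [fit_diffusion_coefficient()] result.
#' @export
estimate_diffusion <- function(profiles, geometry, times = NULL, D0 = NULL,
                               ...) {
  grid <- fit_grid(geometry$y_lower_boundary, geometry$y_upper_boundary,
                   pixel_size = geometry$pixel_size)
  # re-express grid nodes in the profile frame (y = 0 at donor interface)
  boundary <- build_boundary_function(profiles, geometry)
  if (is.null(times)) times <- select_fit_timepoints(profiles, geometry, ...)
  measured <- profiles_on_grid(profiles, geometry, grid, times)
  fit_diffusion_coefficient(measured, boundary, grid, D0 = D0)
}

#' Write a diffusion fit as JSON
#'
#' @param fit A `diffusion_fit`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_diffusion_fit <- function(fit, path) {
  jsonlite::write_json(
    list(D_app_um2_per_s = fit$D_app, sse = fit$sse,
         n_iterations = fit$n_iterations, converged = fit$converged,
         times_used_s = fit$times_used,
         time_rounding_s = fit$time_rounding_s,
         boundary_mode = fit$boundary$mode,
         baseline_mode = fit$baseline_mode),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
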