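#' Fit grid for diffusion-coefficient estimation
#'
#' The inverse fit operates on a coarsened lattice: one node every 10
#' pixels (12.50339 µm at the native 1.250339 µm pixel size) between the
#' lower and upper fit boundaries, with a 30 s solver time step. Nodes are
#' snapped to the pixel lattice.
#'
#' @param y_lower_um,y_upper_um Fit-interval boundaries (µm, gel frame).
#' @param pixel_size Axial pixel size (µm).
#' @param stride Pixels per node (default 10).
#' @param dt_s Solver time step in seconds (default 30).
#' @return An object of class `fit_grid` with fields `y_nodes`, `dy`, `dt`.
#' @export
fit_grid <- function(y_lower_um, y_upper_um, pixel_size = 1.250339,
                     stride = 10L, dt_s = 30) {
  if (y_upper_um <= y_lower_um) stop("y_upper_um must exceed y_lower_um")
  # snap boundaries to the pixel lattice
  i0 <- round(y_lower_um / pixel_size)
  i1 <- floor(y_upper_um / pixel_size + 1e-9)
  idx <- seq(i0, i1, by = stride)
  if (length(idx) < 3) stop("fit grid needs at least 3 nodes")
  structure(
    list(y_nodes = idx * pixel_size, dy = stride * pixel_size,
         dt = dt_s, pixel_size = pixel_size, stride = as.integer(stride)),
    class = "fit_grid")
}

# Precomputed Thomas (tridiagonal LU) factorisation for a constant
# symmetric system with diagonal b and off-diagonal a, m unknowns.
thomas_factor <- function(b, a, m) {
  cp <- numeric(m)
  denom <- numeric(m)
  denom[1] <- b
  cp[1] <- a / b
  if (m > 1) {
    for (i in 2:m) {
      denom[i] <- b - a * cp[i - 1]
      cp[i] <- a / denom[i]
    }
  }
  list(cp = cp, denom = denom, a = a)
}

thomas_solve <- function(fac, d) {
  m <- length(d)
  dp <- numeric(m)
  dp[1] <- d[1] / fac$denom[1]
  if (m > 1) {
    for (i in 2:m) dp[i] <- (d[i] - fac$a * dp[i - 1]) / fac$denom[i]
  }
  x <- numeric(m)
  x[m] <- dp[m]
  if (m > 1) {
    for (i in (m - 1):1) x[i] <- dp[i] - fac$cp[i] * x[i + 1]
  }
  x
}

# Core theta-scheme stepper on a uniform node set (theta = 1/2 except for
# a short damped startup when the boundary data are discontinuous at t = 0,
# where two backward-Euler steps suppress the spurious Crank-Nicolson
# oscillations excited by the jump).
# g_lower: function(t) giving the Dirichlet value at the first node;
# upper boundary held at zero (sink). Zero initial condition at t = 0.
# Returns the field (all nodes, including boundaries) at output_times.
cn_march <- function(D, dy, n_nodes, dt, t_end, g_lower, output_times) {
  if (n_nodes < 3) stop("grid with fewer than 3 nodes")
  if (D <= 0) stop("diffusion coefficient must be positive")
  m <- n_nodes - 2L
  # step sequence: regular dt, with extra break points at the output times
  # (the final step is shortened if t_end is not a multiple of dt)
  tseq <- sort(unique(c(seq(0, t_end, by = dt),
                        output_times[output_times <= t_end + 1e-9], t_end)))
  tseq <- tseq[tseq <= t_end + 1e-9]
  # drop near-duplicate break points
  tseq <- tseq[c(TRUE, diff(tseq) > 1e-9)]
  facs <- list()   # factorisation cache keyed by (step length, theta)
  u <- numeric(n_nodes)           # zero initial condition
  u[1] <- g_lower(0)
  n_startup_ie <- 0L
  if (abs(u[1]) > 0 && length(tseq) >= 3) {
    # Rannacher startup: the first two steps are each split into two
    # backward-Euler half-steps, damping the high-frequency modes the
    # discontinuous datum excites without losing second-order accuracy
    # away from t = 0
    mids <- c((tseq[1] + tseq[2]) / 2, (tseq[2] + tseq[3]) / 2)
    tseq <- sort(unique(c(tseq, mids)))
    n_startup_ie <- 4L
  }
  out <- matrix(NA_real_, n_nodes, length(output_times))
  oi <- 1L
  record <- function(t_now, u) {
    while (oi <= length(output_times) && output_times[oi] <= t_now + 1e-9) {
      out[, oi] <<- u
      oi <<- oi + 1L
    }
  }
  record(0, u)
  if (length(tseq) >= 2) {
    for (k in 2:length(tseq)) {
      h <- tseq[k] - tseq[k - 1]
      theta <- if (k - 1 <= n_startup_ie) 1 else 0.5
      s <- D * h / dy^2
      key <- sprintf("%.9g_%g", h, theta)
      if (is.null(facs[[key]])) {
        facs[[key]] <- thomas_factor(1 + 2 * theta * s, -theta * s, m)
      }
      fac <- facs[[key]]
      g_new <- g_lower(tseq[k])
      ui <- u[2:(n_nodes - 1)]
      om <- (1 - theta) * s
      d <- (1 - 2 * om) * ui + om * (u[1:(n_nodes - 2)] + u[3:n_nodes])
      d[1] <- d[1] + theta * s * g_new
      ui_new <- thomas_solve(fac, d)
      u <- c(g_new, ui_new, 0)
      record(tseq[k], u)
    }
  }
  out
}

#' Solve the 1D diffusion equation by Crank-Nicolson
#'
#' Integrates `dC/dt = D d2C/dy2` with a theta = 1/2 (Crank-Nicolson)
#' finite-difference scheme on the fit grid, zero initial condition,
#' time-dependent Dirichlet condition at the lower (donor-side) boundary
#' and a zero Dirichlet (sink) condition at the upper boundary. The
#' boundary function is evaluated at both theta levels of every step.
#'
#' @param D Diffusion coefficient (µm²/s), must be positive.
#' @param boundary A [boundary_function] (or any function of time in
#'   seconds) giving the lower-boundary value.
#' @param grid A [fit_grid].
#' @param t_end Final integration time (s). If not a multiple of the grid
#'   time step, the last step is shortened.
#' @param output_times Times (s) at which to return the field; defaults to
#'   `t_end` only. Times are snapped to step boundaries internally.
#' @return A [profile_series] over the grid nodes at `output_times`.
#' @export
solve_crank_nicolson <- function(D, boundary, grid, t_end,
                                 output_times = t_end) {
  g <- if (inherits(boundary, "boundary_function")) {
    function(t) boundary_eval(boundary, t)
  } else if (is.function(boundary)) {
    boundary
  } else {
    stop("boundary must be a boundary_function or a function of time")
  }
  output_times <- sort(output_times)
  if (any(output_times > t_end + 1e-9)) stop("output_times beyond t_end")
  vals <- cn_march(D, grid$dy, length(grid$y_nodes), grid$dt, t_end,
                   g, output_times)
  profile_series(grid$y_nodes - grid$y_nodes[1], output_times, vals,
                 units = "a.u.", pixel_size = grid$dy)
}
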