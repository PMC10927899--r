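# diffusion: boundary construction, Crank-Nicolson solver, LM inverse fit

test_that("the 11-point boundary average behaves on flat, ramp and edge cases", {
  y <- 0:99
  flat <- profile_series(y, 600, matrix(40, 100, 1))
  expect_equal(boundary_value(flat, 50, 600), 40)
  ramp <- profile_series(y, 600, matrix(as.numeric(y), 100, 1))
  expect_equal(boundary_value(ramp, 50, 600), 50)  # symmetric window
  expect_error(boundary_value(flat, 2, 600), "edge")
  expect_error(boundary_value(flat, 50, 999), "time")
})

test_that("boundary shape classification follows the concavity criterion", {
  expect_equal(classify_boundary_shape(600, 50, 1200, 75), "exp_then_spline")
  expect_equal(classify_boundary_shape(600, 50, 1200, 100), "all_spline")  # tie
  expect_equal(classify_boundary_shape(600, 50, 1200, 120), "all_spline")
  expect_warning(out <- classify_boundary_shape(600, -1, 1200, 10),
                 "non-positive")
  expect_equal(out, "all_spline")
})

test_that("the two-point exponential boundary fit is exact", {
  p <- fit_eq1(600, 50, 1200, 75)
  expect_equal(p$I_inf, 100)
  expect_equal(p$beta, log(2) / 600, tolerance = 1e-12)
  # bisection branch (t2 != 2 t1) reproduces the data to 1e-8 relative
  truth <- list(I_inf = 80, beta = 1 / 900)
  I <- function(t) truth$I_inf * (1 - exp(-truth$beta * t))
  q <- fit_eq1(500, I(500), 1300, I(1300))
  expect_equal(q$I_inf * (1 - exp(-q$beta * 500)) / I(500), 1,
               tolerance = 1e-8)
  expect_equal(q$I_inf * (1 - exp(-q$beta * 1300)) / I(1300), 1,
               tolerance = 1e-8)
  expect_equal(q$beta, truth$beta, tolerance = 1e-6)
  expect_warning(sat <- fit_eq1(600, 50, 1200, 50), "saturated")
  expect_equal(sat$beta, 1)
})

test_that("the assembled boundary function matches its exponential and spline segments", {
  pxs <- 1.250339
  y <- (0:159) * pxs
  times <- c(600, 1200, 1800, 2400)
  Ib <- function(t) 100 * (1 - 2^(-t / 600))
  vals <- matrix(rep(Ib(times), each = length(y)), length(y))
  prof <- profile_series(y, times, vals, pixel_size = pxs)
  geom <- gel_geometry(0, max(y), y_lower_boundary = 100, pixel_size = pxs)
  bf <- build_boundary_function(prof, geom)
  expect_equal(bf$mode, "exp_then_spline")
  expect_equal(boundary_eval(bf, 300), 100 * (1 - 2^(-0.5)), tolerance = 1e-9)
  expect_equal(boundary_eval(bf, 0), 0)
  # beyond the last knot the last value is held
  expect_equal(boundary_eval(bf, 9000), Ib(2400))
  # strictly linear boundary values -> all_spline reproducing the line
  lin_vals <- matrix(rep(0.05 * times, each = length(y)), length(y))
  lprof <- profile_series(y, times, lin_vals, pixel_size = pxs)
  lbf <- build_boundary_function(lprof, geom)
  expect_equal(lbf$mode, "all_spline")
  for (t in c(300, 600, 900, 1500, 2400)) {
    expect_equal(boundary_eval(lbf, t), 0.05 * t, tolerance = 1e-9)
  }
  expect_equal(boundary_eval(lbf, 0), 0)
})

test_that("the Crank-Nicolson solver matches analytic oracles", {
  grid <- fit_grid(0, 3000, pixel_size = 1.250339)
  # zero boundary -> identically zero field
  z <- solve_crank_nicolson(400, function(t) 0, grid, 600,
                            output_times = c(300, 600))
  expect_true(all(z$values == 0))
  # step boundary, early time: semi-infinite erfc solution
  sol <- solve_crank_nicolson(400, function(t) 1, grid, 600,
                              output_times = 600)
  exact <- erfc_(sol$y_um / (2 * sqrt(400 * 600)))
  expect_lt(max(abs(sol$values[, 1] - exact)), 0.01)
  # constant boundary, long time: linear steady state, mid-node C0/2
  g2 <- fit_grid(0, 250, pixel_size = 1.250339)
  L <- max(g2$y_nodes) - min(g2$y_nodes)
  s2 <- solve_crank_nicolson(400, function(t) 1, g2, 3000,
                             output_times = 3000)
  mid <- ceiling(length(g2$y_nodes) / 2)
  expect_equal(s2$values[mid, 1], 1 - s2$y_um[mid] / L, tolerance = 1e-6)
  expect_error(solve_crank_nicolson(-1, function(t) 0, grid, 600), "positive")
})

test_that("the discrete field respects the maximum principle", {
  grid <- fit_grid(0, 1000, pixel_size = 1.250339)
  set.seed(4)
  for (rep in 1:5) {
    kn <- data.frame(time_s = c(300, 600, 900, 1200),
                     value = cumsum(runif(4, 0, 50)))
    bf <- boundary_function("all_spline", knots = kn)
    out <- solve_crank_nicolson(runif(1, 100, 600), bf, grid, 1200,
                                output_times = c(300, 600, 900, 1200))
    expect_gte(min(out$values), -1e-9)
    expect_lte(max(out$values), max(kn$value) + 1e-9)
  }
})

test_that("grid refinement changes predicted profiles by less than 0.5%", {
  bf <- boundary_function("exp_then_spline", I_inf = 1000, beta = 1 / 600,
                          t_switch = Inf)
  for (D in c(100, 600)) {
    g1 <- fit_grid(0, 2000, pixel_size = 1.250339, stride = 10, dt_s = 30)
    g2 <- fit_grid(0, 2000, pixel_size = 1.250339, stride = 5, dt_s = 15)
    t_out <- 1200
    s1 <- solve_crank_nicolson(D, bf, g1, t_out, output_times = t_out)
    s2 <- solve_crank_nicolson(D, bf, g2, t_out, output_times = t_out)
    v2 <- s2$values[seq(1, length(g2$y_nodes), by = 2), 1]
    expect_lt(max(abs(s1$values[, 1] - v2)), 0.005 * max(s1$values))
  }
})

test_that("time-point selection favours early frames in fast gels and later in slow", {
  sel_for <- function(D) {
    rs <- recovery_setup(D)
    prof <- baseline_correct(rs$profiles, "far_segment")
    select_fit_timepoints(prof, rs$geometry)
  }
  fast <- sel_for(500)
  slow <- sel_for(100)
  expect_true(all(slow >= fast))
  expect_gt(slow[1], fast[1])
})

test_that("time-point selection errors list the failing criterion", {
  y <- (0:1599) * 1.250339
  flat_high <- matrix(800, length(y), 2)  # sink end saturated everywhere
  prof <- profile_series(y, c(600, 1200), flat_high, pixel_size = 1.250339)
  geom <- gel_geometry(0, max(y), pixel_size = 1.250339)
  expect_error(select_fit_timepoints(prof, geom), "sink end")
})

test_that("the LM fit recovers a known diffusion coefficient without noise", {
  rs <- recovery_setup(400)
  prof <- baseline_correct(rs$profiles, "far_segment")
  fit <- estimate_diffusion(prof, rs$geometry)
  expect_true(fit$converged)
  expect_lt(abs(fit$D_app - 400) / 400, 0.02)
})

test_that("the fitted D is invariant to a global intensity rescaling", {
  rs <- recovery_setup(300, n_frames = 6)
  prof <- baseline_correct(rs$profiles, "far_segment")
  fit1 <- estimate_diffusion(prof, rs$geometry)
  scaled <- profile_series(prof$y_um, prof$times_s, prof$values * 10,
                           baseline_mode = prof$baseline_mode,
                           pixel_size = prof$pixel_size)
  fit2 <- estimate_diffusion(scaled, rs$geometry)
  expect_equal(fit2$D_app / fit1$D_app, 1, tolerance = 1e-6)
})

test_that("LM and golden-section search agree on the SSE minimiser", {
  rs <- recovery_setup(250, n_frames = 6)
  prof <- baseline_correct(rs$profiles, "far_segment")
  geom <- rs$geometry
  grid <- fit_grid(geom$y_lower_boundary, geom$y_upper_boundary,
                   pixel_size = geom$pixel_size)
  bf <- build_boundary_function(prof, geom)
  times <- select_fit_timepoints(prof, geom)
  meas <- profiles_on_grid(prof, geom, grid, times)
  fit <- fit_diffusion_coefficient(meas, bf, grid)
  solve_times <- round(times / grid$dt) * grid$dt
  sse_of <- function(D) geldiff:::cn_sse(D, bf, grid, meas, solve_times)$sse
  gold <- optimize(sse_of, c(fit$D_app * 0.7, fit$D_app * 1.3),
                   tol = 1e-4)$minimum
  expect_equal(fit$D_app / gold, 1, tolerance = 1e-3)
  # local convexity of the SSE around the optimum
  expect_gt(sse_of(fit$D_app * 1.05), fit$sse)
  expect_gt(sse_of(fit$D_app * 0.95), fit$sse)
})

test_that("degenerate measurements are rejected", {
  grid <- fit_grid(0, 500, pixel_size = 1.250339)
  zeros <- profile_series(grid$y_nodes - grid$y_nodes[1], c(600, 1200),
                          matrix(0, length(grid$y_nodes), 2),
                          pixel_size = grid$dy)
  bf <- boundary_function("all_spline",
                          knots = data.frame(time_s = c(600, 1200),
                                             value = c(10, 20)))
  expect_error(fit_diffusion_coefficient(zeros, bf, grid), "all-zero")
})

test_that("a diffusion fit serialises to JSON", {
  rs <- recovery_setup(300, n_frames = 6)
  prof <- baseline_correct(rs$profiles, "far_segment")
  fit <- estimate_diffusion(prof, rs$geometry)
  path <- withr::local_tempfile(fileext = ".json")
  write_diffusion_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$D_app_um2_per_s, fit$D_app, tolerance = 1e-12)
  expect_true(back$converged)
})
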