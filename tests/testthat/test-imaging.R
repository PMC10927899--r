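# imaging: I/O round trips, geometry, profile extraction, calibration

test_that("image series round-trips through TIFF exactly", {
  dir <- withr::local_tempdir()
  p <- small_params(n_cells = 2, noise_sd = 10, seed = 8)
  sim <- simulate_experiment(p, out_dir = dir)
  back <- read_image_series(dir)
  expect_equal(dim(back$channels$dox), dim(sim$series$channels$dox))
  expect_equal(back$timestamps, sim$series$timestamps)
  expect_equal(back$pixel_size, sim$series$pixel_size)
  expect_equal(back$t_lag, sim$series$t_lag)
  for (ch in c("nucblue", "dox", "dic")) {
    expect_true(max(abs(back$channels[[ch]] - sim$series$channels[[ch]])) == 0)
  }
})

test_that("mismatched page sizes are reported with the offending page", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(list(matrix(0.1, 10, 8), matrix(0.1, 12, 8)),
                  file.path(dir, "dox.tif"), bits.per.sample = 16L)
  expect_error(
    read_image_series(dir, channel_map = c(dox = "dox.tif"),
                      metadata = list(pixel_size = 1, t_lag = 60,
                                      frame_interval = 300)),
    "page 2")
})

test_that("missing timing metadata is an error", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(list(matrix(0.1, 10, 8)), file.path(dir, "dox.tif"),
                  bits.per.sample = 16L)
  expect_error(read_image_series(dir, channel_map = c(dox = "dox.tif"),
                                 metadata = list(pixel_size = 1, t_lag = 60)),
               "timestamps or frame_interval")
})

make_series <- function(frames, pixel_size = 1, t_lag = 60, dt = 300) {
  nt <- dim(frames)[3]
  image_series(list(dox = frames), pixel_size = pixel_size,
               timestamps = t_lag + (seq_len(nt) - 1) * dt, t_lag = t_lag)
}

test_that("profile extraction reproduces flat and ramp images exactly", {
  ny <- 40; nx <- 30
  geom <- gel_geometry(0, ny - 1, y_lower_boundary = 10, pixel_size = 1)
  flat <- array(100L, dim = c(ny, nx, 1))
  pf <- extract_profile(make_series(flat), geom, "dox", roi_width_um = 10)
  expect_true(all(pf$values == 100))
  ramp <- array(rep(0:(ny - 1), nx), dim = c(ny, nx, 1))
  pr <- extract_profile(make_series(ramp), geom, "dox", roi_width_um = 10)
  expect_equal(as.vector(pr$values), 0:(ny - 1))
  expect_equal(pr$y_um, 0:(ny - 1))
  expect_error(extract_profile(make_series(flat), geom, "nucblue"), "absent")
})

test_that("profile extraction is linear in the image", {
  set.seed(1)
  ny <- 30; nx <- 20
  img <- array(runif(ny * nx * 2, 0, 1000), dim = c(ny, nx, 2))
  geom <- gel_geometry(0, ny - 1, y_lower_boundary = 8, pixel_size = 1)
  p1 <- extract_profile(make_series(img), geom, "dox", roi_width_um = nx)
  p2 <- extract_profile(make_series(3 * img + 7), geom, "dox",
                        roi_width_um = nx)
  expect_equal(p2$values, 3 * p1$values + 7, tolerance = 1e-12)
})

test_that("transverse averaging reduces noise as 1/sqrt(N)", {
  set.seed(11)
  ny <- 1000; nx <- 64; sd_n <- 40
  img <- array(500 + rnorm(ny * nx, sd = sd_n), dim = c(ny, nx, 1))
  geom <- gel_geometry(0, ny - 1, y_lower_boundary = 100, pixel_size = 1)
  pf <- extract_profile(make_series(img), geom, "dox", roi_width_um = nx)
  expect_equal(sd(pf$values), sd_n / sqrt(nx), tolerance = 0.2)
})

test_that("baseline correction modes behave as specified", {
  y <- 0:299
  first <- rep(10, 300)
  later <- 10 + pmax(0, 100 - y)
  prof <- profile_series(y, c(60, 360), cbind(first, later))
  far <- baseline_correct(prof, "far_segment")
  expect_equal(far$values[, 1], first - 10)
  expect_equal(far$values[, 2], later - 10)
  full <- baseline_correct(prof, "full_profile")
  expect_true(all(full$values[, 1] == 0))
  # re-adding the first profile restores the input exactly
  expect_equal(full$values + first, prof$values, ignore_attr = TRUE)
  # negative values are retained
  dipped <- profile_series(y, c(60, 360), cbind(first, first - 5))
  expect_true(any(baseline_correct(dipped, "far_segment")$values < 0))
})

test_that("calibration fitting recovers an exact line and gates bad input", {
  cc <- c(1, 5, 10, 20)
  curve <- fit_calibration(cc, 50 * cc + 5)
  expect_equal(curve$slope, 50)
  expect_equal(curve$intercept, 5)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$valid_range, c(1, 20))
  expect_error(fit_calibration(c(1, 2), c(10, 20)), "at least 3")
  expect_error(fit_calibration(c(2, 2, 2), c(10, 20, 30)), "vary")
  expect_silent(validate_calibration(curve))
  noisy <- fit_calibration(cc, c(60, 240, 700, 790))
  expect_lt(noisy$r_squared, 0.97)
  expect_error(validate_calibration(noisy), "0.97")
})

test_that("intensity-concentration conversion inverts the calibration", {
  curve <- fit_calibration(c(1, 10, 20), 50 * c(1, 10, 20) + 5)
  expect_equal(as.numeric(to_concentration(105, curve)), 2)
  expect_equal(as.numeric(to_concentration(curve$intercept, curve)),
               0)
  # identity on the valid range to machine precision
  conc <- seq(1, 20, by = 0.5)
  back <- to_concentration(50 * conc + 5, curve)
  expect_equal(as.numeric(back), conc, tolerance = 1e-12)
  expect_false(any(attr(back, "out_of_range")))
  # out-of-range flag (self-quenching regime)
  high <- to_concentration(50 * 30 + 5, curve)
  expect_equal(as.numeric(high), 30)
  expect_true(attr(high, "out_of_range"))
  expect_true(attr(to_concentration(curve$intercept, curve), "out_of_range"))
})

test_that("gel boundaries are detected from DIC or taken from overrides", {
  p <- small_params(seed = 2, noise_sd = 10)
  sim <- simulate_experiment(p)
  geom <- detect_gel_boundaries(sim$series)
  expect_lt(abs(geom$y_donor_interface - 0), p$pixel_size + 1e-9)
  expect_lt(abs(geom$y_acceptor_interface - sim$truth$gel_length_eff),
            p$pixel_size + 1e-9)
  ov <- list(y_donor_interface = 12.50339, y_acceptor_interface = 500.1356)
  geom2 <- detect_gel_boundaries(sim$series, ov)
  expect_equal(geom2$y_donor_interface, ov$y_donor_interface,
               tolerance = 1e-6)
  expect_equal(geom2$y_acceptor_interface, ov$y_acceptor_interface,
               tolerance = 1e-6)
  blank <- image_series(list(dic = array(1000L, dim = c(50, 10, 1))),
                        pixel_size = 1, timestamps = 60, t_lag = 60)
  expect_error(detect_gel_boundaries(blank), "override")
  no_dic <- image_series(list(dox = array(0L, dim = c(50, 10, 1))),
                         pixel_size = 1, timestamps = 60, t_lag = 60)
  expect_error(detect_gel_boundaries(no_dic), "override")
})

test_that("profile CSV round-trips", {
  prof <- profile_series(0:9, c(60, 360),
                         matrix(runif(20, 0, 100), 10, 2), units = "uM")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(prof, path)
  back <- read_profiles_csv(path)
  expect_equal(back$values, prof$values, ignore_attr = TRUE)
  expect_equal(back$units, "uM")
})
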