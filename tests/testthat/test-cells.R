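# cells: nucleus detection, per-cell traces, zoning

# a small rendered scene with explicitly placed cells
scene <- function(cells, noise_sd = 10, seed = 21, n_frames = 3) {
  p <- simulation_params(gel_length = 600, gel_width = 250,
                         n_frames = n_frames, frame_interval = 300,
                         t_lag = 60, noise_sd = noise_sd,
                         n_cells = nrow(cells), seed = seed)
  simulate_experiment(p, cells = cells)
}

test_that("well-separated nuclei are detected with accurate centroids", {
  cells <- data.frame(y_um = c(80, 200, 320, 440, 540),
                      x_um = c(60, 120, 180, 60, 120),
                      radius_um = 9.9)
  sim <- scene(cells)
  found <- detect_nuclei(sim$series)
  expect_equal(nrow(found), 5)
  px <- sim$series$pixel_size
  found <- found[order(found$y_um), ]
  expect_true(all(abs(found$y_um - sort(cells$y_um)) <= px))
  expect_true(all(abs(found$x_um - cells$x_um[order(cells$y_um)]) <= px))
})

test_that("touching nuclei are split by the watershed", {
  # four singles fix the median component area; one touching pair
  cells <- data.frame(y_um = c(80, 200, 320, 440, 540, 552),
                      x_um = c(60, 120, 180, 60, 120, 130),
                      radius_um = 9)
  sim <- scene(cells, noise_sd = 5)
  found <- detect_nuclei(sim$series)
  expect_equal(nrow(found), 6)
})

test_that("a blank nuclear channel yields zero cells, not an error", {
  blank <- image_series(list(nucblue = array(0L, dim = c(60, 40, 2))),
                        pixel_size = 1, timestamps = c(60, 360), t_lag = 60)
  found <- detect_nuclei(blank)
  expect_equal(nrow(found), 0)
})

test_that("detection is invariant to a positive intensity rescaling", {
  cells <- data.frame(y_um = c(100, 300, 500), x_um = c(60, 120, 180),
                      radius_um = 9.9)
  sim <- scene(cells, noise_sd = 5)
  n1 <- nrow(detect_nuclei(sim$series))
  scaled <- sim$series
  scaled$channels$nucblue <- scaled$channels$nucblue %/% 3L
  expect_equal(nrow(detect_nuclei(scaled)), n1)
})

test_that("radius and area are consistent for every detected cell", {
  cells <- data.frame(y_um = c(100, 300, 500), x_um = c(60, 120, 180),
                      radius_um = c(8, 10, 12))
  sim <- scene(cells)
  found <- detect_nuclei(sim$series)
  expect_true(all(abs(found$radius_um - sqrt(found$area_um2 / pi)) < 1e-9))
})

test_that("cell traces average the right pixels and only those", {
  cells <- data.frame(y_um = c(150, 450), x_um = c(80, 160), radius_um = 9.9)
  sim <- scene(cells, noise_sd = 0)
  found <- detect_nuclei(sim$series)
  expect_equal(nrow(found), 2)
  # constant channel -> constant traces
  flat <- sim$series
  flat$channels$dox[] <- 123L
  tr <- measure_cell_intensities(flat, found)
  expect_true(all(tr$dox == 123))
  # locality: perturbing pixels outside a mask leaves its trace unchanged
  lab <- attr(found, "label_mask")
  tr1 <- measure_cell_intensities(sim$series, found)
  poked <- sim$series
  outside <- which(lab == 0)[1:500]
  for (k in seq_len(dim(poked$channels$dox)[3])) {
    frame <- poked$channels$dox[, , k]
    frame[outside] <- 60000L
    poked$channels$dox[, , k] <- frame
  }
  tr2 <- measure_cell_intensities(poked, found)
  expect_equal(tr2$dox, tr1$dox)
})

test_that("a programmed linear accumulation is recovered from the trace", {
  # render one cell whose disk intensity grows linearly in time
  ny <- 200; nx <- 100; nt <- 5
  arrs <- array(100L, dim = c(ny, nx, nt))
  nb <- array(10L, dim = c(ny, nx, nt))
  cy <- 100; cx <- 50; r <- 8
  dy2 <- outer(((1:ny) - cy)^2, ((1:nx) - cx)^2, `+`)
  slope_per_frame <- 200
  for (k in 1:nt) {
    frame <- arrs[, , k]
    frame[dy2 <= r^2] <- frame[dy2 <= r^2] + as.integer(slope_per_frame * (k - 1))
    arrs[, , k] <- frame
    # stained nucleus well inside the drug-filled disk: the dilated
    # nuclear mask then samples only drug-disk pixels
    nbf <- nb[, , k]
    nbf[dy2 <= (0.5 * r)^2] <- 20000L
    nb[, , k] <- nbf
  }
  ser <- image_series(list(nucblue = nb, dox = arrs), pixel_size = 1,
                      timestamps = 60 + (0:(nt - 1)) * 300, t_lag = 60)
  found <- detect_nuclei(ser, min_radius_um = 3)
  expect_equal(nrow(found), 1)
  tr <- measure_cell_intensities(ser, found)
  fit <- lm(dox ~ time_s, tr)
  expect_equal(unname(coef(fit)[2]), slope_per_frame / 300, tolerance = 0.05)
})

test_that("zone assignment partitions cells with half-open 250 um bins", {
  z <- assign_zone(c(0, 250, 1999, 2400))
  expect_equal(z$zone_index, c(0L, 1L, 7L, 9L))
  expect_equal(z$in_analysis, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(assign_zone(-1), "negative")
  # partition: every cell lands in exactly one zone or out-of-analysis
  set.seed(6)
  ys <- runif(200, 0, 2900)
  z2 <- assign_zone(ys)
  expect_equal(sum(z2$in_analysis) + sum(!z2$in_analysis), 200)
  expect_true(all(ys >= z2$zone_lo_um & ys < z2$zone_hi_um))
})

test_that("relative intensity traces are percentages of the reference frame", {
  tr <- data.frame(cell_id = rep(1:2, each = 3),
                   time_s = rep(c(60, 360, 660), 2),
                   nucblue = c(100, 80, 50, 100, 70, 50),
                   dox = c(10, 20, 20, 10, 20, 20))
  rel <- relative_intensity(tr, 1:2, "nucblue")
  expect_equal(rel$percent, c(100, 75, 50))
  reld <- relative_intensity(tr, 1:2, "dox")
  expect_equal(reld$percent[3], 200)
  expect_error(relative_intensity(tr, 3, "dox"), "empty")
})

test_that("rendered nuclear-stain decay follows the programmed coupling", {
  p <- simulation_params(gel_length = 600, gel_width = 200, n_frames = 7,
                         frame_interval = 600, t_lag = 60, noise_sd = 0,
                         n_cells = 1, D_true = 300, seed = 13,
                         nucblue_decay_coupling = 5e-4)
  cells <- data.frame(y_um = 80, x_um = 100, radius_um = 9.9)
  sim <- simulate_experiment(p, cells = cells)
  found <- detect_nuclei(sim$series)
  expect_equal(nrow(found), 1)
  tr <- measure_cell_intensities(sim$series, found)
  rel <- relative_intensity(tr, found$id, "nucblue")
  expect_lt(rel$percent[nrow(rel)], 95)      # visible decay
  expect_true(all(diff(rel$percent) <= 0.1)) # monotone depletion (within quantisation)
})
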