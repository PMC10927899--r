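#' Intracellular uptake rate of a zone
#'
#' The uptake rate (µM/min) is the ordinary least-squares slope of the
#' zone-mean intracellular concentration against time, with a free
#' intercept.
#'
#' @param times_min Times (min), at least 3.
#' @param conc_uM Zone-mean intracellular concentrations (µM).
#' @return List with `rate` (µM/min), `se`, `r_squared`, `n`.
#' @export
uptake_rate <- function(times_min, conc_uM) {
  if (length(times_min) < 3) stop("need at least 3 time points")
  fit <- stats::lm(conc_uM ~ times_min)
  sm <- suppressWarnings(summary(fit))
  list(rate = unname(stats::coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       r_squared = sm$r.squared,
       n = length(times_min))
}

#' Mean gel concentration of a zone at a given time
#'
#' Averages the axial concentration profile over the zone's y-interval;
#' times between acquired frames are linearly interpolated.
#'
#' @param profiles A [profile_series] in µM (see
#'   [profiles_to_concentration()]).
#' @param zone_lo_um,zone_hi_um Zone bounds (µm, half-open).
#' @param time_s Requested time (s); must lie in the measured range.
#' @return Mean concentration (µM).
#' @export
zone_gel_concentration <- function(profiles, zone_lo_um, zone_hi_um, time_s) {
  if (profiles$units != "uM") stop("profiles must be in concentration units")
  v <- profile_at_time(profiles, time_s)
  sel <- profiles$y_um >= zone_lo_um & profiles$y_um < zone_hi_um
  if (!any(sel)) stop("zone contains no profile pixels")
  mean(v[sel])
}

#' Transport rate constant from uptake-concentration pairs
#'
#' The overall transport rate constant of the drug into the cells
#' (k_cell, 1/min) is the ordinary least-squares slope, with free
#' intercept, of zone uptake rates against the available gel
#' concentration of the corresponding zone, pooled over all zones and
#' evaluation times.
#'
#' @param uptake_rates Uptake rates (µM/min), one per (zone, time) pair.
#' @param gel_concs Matching gel concentrations (µM).
#' @return List with `k_cell` (1/min), `se`, `r_squared`, `n`.
#' @export
transport_rate_constant <- function(uptake_rates, gel_concs) {
  if (length(uptake_rates) != length(gel_concs)) {
    stop("uptake_rates and gel_concs must have equal length")
  }
  if (length(uptake_rates) < 3) stop("need at least 3 pairs")
  if (stats::var(gel_concs) == 0) stop("zero concentration variance")
  fit <- stats::lm(uptake_rates ~ gel_concs)
  sm <- suppressWarnings(summary(fit))
  list(k_cell = unname(stats::coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       r_squared = sm$r.squared,
       n = length(uptake_rates))
}

#' Apparent cell permeability
#'
#' Converts the transport rate constant to an apparent membrane
#' permeability via `P_cell = k_cell * (V/A) / 60` with the spherical-cell
#' simplification `V/A = r/3`, i.e. `P_cell = k_cell * r / 180` in µm/s
#' for k_cell in 1/min and r in µm.
#'
#' @param k_cell Transport rate constant (1/min), non-negative.
#' @param radius_um Cell radius (µm), positive.
#' @return Apparent permeability (µm/s).
#' @export
cell_permeability <- function(k_cell, radius_um) {
  if (any(radius_um <= 0)) stop("radius must be positive")
  if (any(k_cell < 0)) stop("k_cell must be non-negative")
  k_cell * radius_um / (3 * 60)
}

#' Temperature scaling of a diffusion coefficient (Stokes-Einstein)
#'
#' For a spherical solute in water, `D = kB T / (6 pi eta(T) a)`, so
#' `D2 = D1 * (T2/T1) * eta(T1)/eta(T2)`. The dynamic viscosity of water
#' is taken from the Vogel-type correlation
#' `eta(T) = 2.414e-5 * 10^(247.8 / (T - 140))` Pa·s.
#'
#' @param D1 Diffusion coefficient at `T1` (µm²/s), positive.
#' @param T1,T2 Temperatures (K), within liquid-water range
#'   273.15-373.15 K.
#' @return Scaled diffusion coefficient at `T2` (µm²/s).
#' @export
stokes_einstein_scale <- function(D1, T1, T2) {
  if (any(D1 <= 0)) stop("D1 must be positive")
  if (any(c(T1, T2) < 273.15) || any(c(T1, T2) > 373.15)) {
    stop("temperatures must lie within [273.15, 373.15] K")
  }
  eta <- function(T) 2.414e-5 * 10^(247.8 / (T - 140))
  D1 * (T2 / T1) * eta(T1) / eta(T2)
}

#' Zone uptake kinetics and cell permeability from measured traces
#'
#' Full uptake analysis: converts per-cell drug-channel traces to
#' intracellular concentrations (subtracting the extracellular signal
#' sampled within the cell mask, estimated as the zone gel concentration),
#' averages them per 250 µm zone, fits the per-zone uptake rate over time,
#' regresses the uptake rates against the zone gel concentrations at the
#' evaluation times, and converts the resulting k_cell to an apparent
#' permeability using the mean detected cell radius.
#'
#' @param cells A `cell_set` (positions in the gel frame).
#' @param traces Trace data frame from [measure_cell_intensities()] with a
#'   `dox` column.
#' @param gel_profiles Cell-free axial [profile_series] in µM.
#' @param curve A [calibration_curve] for the cellular intensities.
#' @param eval_times_min Times (min) at which uptake is compared with the
#'   gel concentration (default 60, 120, 180).
#' @param rate_window_min Time window (min) over which the per-zone uptake
#'   rate is fitted; defaults to the span of `eval_times_min`, so the rate
#'   and the gel concentrations entering the k_cell regression describe
#'   the same period of the experiment.
#' @param radius_um Cell radius for the permeability conversion; default
#'   the mean detected radius.
#' @param min_cells_per_zone Zones with fewer cells are excluded
#'   (default 1).
#' @return List of class `uptake_result`: `zones` (per-zone data frame
#'   with n_cells, uptake rate, se, r_squared), `pairs` (the pooled
#'   regression points), `k_cell`, `k_cell_se`, `P_cell_um_per_s`,
#'   `cell_radius_used_um`, `times_used_min`.
#' @export
uptake_analysis <- function(cells, traces, gel_profiles, curve,
                            eval_times_min = c(60, 120, 180),
                            rate_window_min = range(eval_times_min),
                            radius_um = NULL,
                            min_cells_per_zone = 1L) {
  if (gel_profiles$units != "uM") stop("gel_profiles must be in uM")
  z <- assign_zone(cells$y_um)
  zone_of <- stats::setNames(ifelse(z$in_analysis, z$zone_index, NA_integer_),
                             cells$id)
  times_s <- sort(unique(traces$time_s))
  times_min <- times_s / 60
  zones <- sort(unique(zone_of[!is.na(zone_of)]))
  zone_rows <- list()
  pair_rows <- list()
  for (zk in zones) {
    ids <- cells$id[!is.na(zone_of) & zone_of == zk]
    if (length(ids) < min_cells_per_zone) next
    sub <- traces[traces$cell_id %in% ids, , drop = FALSE]
    sub <- sub[sub$time_s >= rate_window_min[1] * 60 - 1e-9 &
               sub$time_s <= rate_window_min[2] * 60 + 1e-9, , drop = FALSE]
    if (length(unique(sub$time_s)) < 3) {
      stop("fewer than 3 frames inside rate_window_min")
    }
    # per cell: convert to concentration and subtract the extracellular
    # contribution sampled within the mask, taken at the cell's own axial
    # position; then average cells within the zone
    local_gel <- function(id, t_s) {
      y_cell <- cells$y_um[cells$id == id]
      near <- abs(gel_profiles$y_um - y_cell) <= 5
      vapply(t_s, function(t) mean(profile_at_time(gel_profiles, t)[near]),
             numeric(1))
    }
    sub$conc_cell <- NA_real_
    for (id in ids) {
      ci <- sub$cell_id == id
      cm <- to_concentration(sub$dox[ci], curve)
      attributes(cm) <- NULL
      sub$conc_cell[ci] <- cm - local_gel(id, sub$time_s[ci])
    }
    agg <- stats::aggregate(sub$conc_cell, list(time_s = sub$time_s), mean)
    ur <- uptake_rate(agg$time_s / 60, agg$x)
    zone_rows[[length(zone_rows) + 1L]] <- data.frame(
      zone_index = zk, zone_lo_um = 250 * zk, zone_hi_um = 250 * (zk + 1),
      n_cells = length(ids), uptake_rate_uM_per_min = ur$rate,
      uptake_se = ur$se, r_squared = ur$r_squared)
    # one regression point per zone: its uptake rate against the zone's
    # available gel concentration over the evaluation times. The zone
    # concentration is evaluated at the positions of the zone's cells
    # (identical to the zone-interval mean as cells fill the zone, but
    # free of position mismatch when occupancy is sparse).
    gel_at_eval <- vapply(ids, function(id) {
      mean(local_gel(id, eval_times_min * 60))
    }, numeric(1))
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      zone_index = zk, gel_conc_uM = mean(gel_at_eval),
      uptake_rate_uM_per_min = ur$rate)
  }
  if (!length(zone_rows)) stop("no analysable zones (no cells in 0-2000 um)")
  zones_df <- do.call(rbind, zone_rows)
  pairs <- do.call(rbind, pair_rows)
  k <- transport_rate_constant(pairs$uptake_rate_uM_per_min,
                               pairs$gel_conc_uM)
  if (is.null(radius_um)) radius_um <- mean(cells$radius_um)
  structure(list(zones = zones_df, pairs = pairs,
                 k_cell = k$k_cell, k_cell_se = k$se,
                 k_r_squared = k$r_squared,
                 P_cell_um_per_s = cell_permeability(max(k$k_cell, 0),
                                                     radius_um),
                 cell_radius_used_um = radius_um,
                 times_used_min = eval_times_min),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat(sprintf("<uptake_result> k_cell = %.4g +/- %.2g 1/min, P_cell = %.4g um/s (r = %.3g um)\n",
              x$k_cell, x$k_cell_se, x$P_cell_um_per_s,
              x$cell_radius_used_um))
  cat(sprintf("  %d zones, uptake rates %.3g .. %.3g uM/min\n",
              nrow(x$zones), min(x$zones$uptake_rate_uM_per_min),
              max(x$zones$uptake_rate_uM_per_min)))
  invisible(x)
}

#' Write an uptake analysis as JSON
#'
#' @param uptake An `uptake_result`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_uptake_json <- function(uptake, path) {
  jsonlite::write_json(
    list(zones = uptake$zones, k_cell_per_min = uptake$k_cell,
         k_cell_se = uptake$k_cell_se,
         P_cell_um_per_s = uptake$P_cell_um_per_s,
         cell_radius_used_um = uptake$cell_radius_used_um,
         times_used_min = uptake$times_used_min),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
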