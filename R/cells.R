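#' Detect cell nuclei from the nuclear-stain channel
#'
#' Segmentation follows the particle-analysis recipe used for the chip
#' images: (i) maximum-intensity projection of the nuclear-stain channel
#' over the entire time series, (ii) global threshold (Otsu by default),
#' (iii) binary dilation of the nucleus boundaries, (iv) watershed
#' splitting of unusually large components (touching nuclei), and (v)
#' connected-component analysis yielding per-cell centroid and projected
#' area. The dilated projected area approximates the cell footprint; the
#' reported radius is `sqrt(area / pi)`.
#'
#' @param series An [image_series] with a `nucblue` channel.
#' @param threshold Manual threshold (a.u., on the 16-bit scale);
#'   default `NULL` uses Otsu's method.
#' @param dilate_radius_px Dilation radius in pixels (default 2).
#' @param min_radius_um Components with equivalent radius below this are
#'   discarded (default 3 µm).
#' @param watershed_area_factor Watershed is applied only to components
#'   larger than this multiple of the median component area (default 1.5,
#'   so a merged pair of nuclei triggers splitting while size variation
#'   among single nuclei does not; watershed cannot split a convex
#'   single-nucleus component, so a low gate is safe).
#' @return A data frame of class `cell_set` with columns `id`, `y_um`,
#'   `x_um`, `area_um2`, `radius_um`; the labelled mask is attached as
#'   attribute `label_mask`. An empty image yields zero rows.
#' @export
detect_nuclei <- function(series, threshold = NULL, dilate_radius_px = 2L,
                          min_radius_um = 3, watershed_area_factor = 1.5) {
  arr <- series$channels$nucblue
  if (is.null(arr)) stop("nucblue channel absent")
  px <- series$pixel_size
  # maximum-intensity projection over time
  proj <- arr[, , 1]
  nt <- dim(arr)[3]
  if (nt > 1) for (k in 2:nt) proj <- pmax(proj, arr[, , k])
  empty <- function() {
    out <- data.frame(id = integer(0), y_um = numeric(0), x_um = numeric(0),
                      area_um2 = numeric(0), radius_um = numeric(0))
    attr(out, "label_mask") <- matrix(0L, nrow(proj), ncol(proj))
    attr(out, "pixel_size") <- px
    class(out) <- c("cell_set", "data.frame")
    out
  }
  if (max(proj) <= min(proj)) return(empty())
  if (is.null(threshold)) {
    threshold <- 65535 * EBImage::otsu(EBImage::Image(proj / 65535),
                                       range = c(0, 1), levels = 65536)
  }
  mask <- proj > threshold
  if (!any(mask)) return(empty())
  brush <- EBImage::makeBrush(2L * as.integer(dilate_radius_px) + 1L, "disc")
  mask <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  med_area <- stats::median(areas)
  # watershed only where a component is plausibly a cluster of nuclei
  big <- which(areas > watershed_area_factor * med_area)
  if (length(big)) {
    next_id <- max(lab) + 1L
    for (b in big) {
      sel <- lab == b
      dm <- EBImage::distmap(EBImage::Image(sel * 1))
      ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
      parts <- sort(unique(ws[ws > 0]))
      if (length(parts) > 1) {
        for (ppart in parts[-1]) {
          lab[ws == ppart] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
  }
  ids <- sort(unique(lab[lab > 0]))
  min_area_px <- pi * (min_radius_um / px)^2
  rows <- row(lab); cols <- col(lab)
  out <- do.call(rbind, lapply(ids, function(i) {
    sel <- lab == i
    a <- sum(sel)
    if (a < min_area_px) return(NULL)
    data.frame(label = i,
               y_um = (mean(rows[sel]) - 1) * px,
               x_um = (mean(cols[sel]) - 1) * px,
               area_um2 = a * px^2)
  }))
  if (is.null(out)) return(empty())
  # drop labels that failed the size filter from the mask
  lab[!(lab %in% out$label)] <- 0L
  out <- out[order(out$y_um), , drop = FALSE]
  relabel <- match(lab, c(0L, out$label)) - 1L
  dim(relabel) <- dim(lab)
  out$id <- seq_len(nrow(out))
  out$radius_um <- sqrt(out$area_um2 / pi)
  out <- out[, c("id", "y_um", "x_um", "area_um2", "radius_um")]
  rownames(out) <- NULL
  attr(out, "label_mask") <- relabel
  attr(out, "pixel_size") <- px
  class(out) <- c("cell_set", "data.frame")
  out
}

#' Measure per-cell intensity traces
#'
#' For every frame and channel, the mean intensity over each cell's
#' dilated mask (the same ROI list for all frames, as cells are assumed
#' static).
#'
#' @param series An [image_series].
#' @param cells A `cell_set` from [detect_nuclei()] run on the same series.
#' @param channels Channels to trace (default nucblue and dox).
#' @return Tidy data frame: `cell_id`, `time_s`, one column per channel.
#' @export
measure_cell_intensities <- function(series, cells,
                                     channels = c("nucblue", "dox")) {
  lab <- attr(cells, "label_mask")
  if (is.null(lab)) stop("cells must carry a label_mask (from detect_nuclei)")
  d <- dim(series$channels[[1]])
  if (!identical(dim(lab), d[1:2])) stop("mask outside image bounds")
  nt <- d[3]
  sel <- lab > 0
  labv <- lab[sel]
  out <- data.frame(cell_id = rep(cells$id, times = nt),
                    time_s = rep(series$timestamps, each = nrow(cells)))
  for (ch in channels) {
    arr <- series$channels[[ch]]
    if (is.null(arr)) stop(sprintf("channel '%s' absent", ch))
    tr <- matrix(NA_real_, nrow(cells), nt)
    for (k in seq_len(nt)) {
      frame <- arr[, , k]
      m <- tapply(frame[sel], labv, mean)
      tr[as.integer(names(m)), k] <- m
    }
    out[[ch]] <- as.vector(tr)
  }
  out
}

#' Assign a cell to its 250 µm gel zone
#'
#' Zones are half-open 250 µm bins of the axial coordinate, indexed from
#' the donor interface: zone k covers `[250k, 250(k+1))` µm. The analysis
#' region spans zones 0-7 (0-2000 µm); cells at y >= 2000 µm are flagged
#' out-of-analysis.
#'
#' @param y_um Axial cell position(s), µm from the donor interface
#'   (non-negative).
#' @return Data frame with `zone_index`, `zone_lo_um`, `zone_hi_um`,
#'   `in_analysis`.
#' @export
assign_zone <- function(y_um) {
  if (any(y_um < 0)) stop("negative y position")
  k <- floor(y_um / 250)
  data.frame(zone_index = as.integer(k),
             zone_lo_um = 250 * k,
             zone_hi_um = 250 * (k + 1),
             in_analysis = y_um < 2000)
}

#' Relative zone-mean intensity trace
#'
#' Averages the traces of all cells in a zone and expresses the result as
#' a percentage of its value at a reference time (the first frame by
#' default), as used to report nuclear-stain depletion and cellular drug
#' enrichment.
#'
#' @param traces Tidy trace data frame from [measure_cell_intensities()].
#' @param cell_ids Cells belonging to the zone.
#' @param channel Channel column name.
#' @param t_ref Reference time (s); default the earliest time present.
#' @return Data frame `time_s`, `percent`.
#' @export
relative_intensity <- function(traces, cell_ids, channel, t_ref = NULL) {
  sub <- traces[traces$cell_id %in% cell_ids, , drop = FALSE]
  if (!nrow(sub)) stop("zone is empty")
  agg <- stats::aggregate(sub[[channel]], list(time_s = sub$time_s), mean)
  names(agg)[2] <- "value"
  if (is.null(t_ref)) t_ref <- min(agg$time_s)
  ref <- agg$value[abs(agg$time_s - t_ref) < 1e-9]
  if (length(ref) != 1 || is.na(ref)) stop("reference frame not found")
  if (ref <= 0) stop("reference value must be positive")
  data.frame(time_s = agg$time_s, percent = 100 * agg$value / ref)
}

#' Write a cell table to CSV
#'
#' @param cells A `cell_set`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_cells_csv <- function(cells, path) {
  df <- as.data.frame(cells)
  z <- assign_zone(df$y_um)
  df$zone <- ifelse(z$in_analysis, z$zone_index, NA_integer_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
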