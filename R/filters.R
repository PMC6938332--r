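#' Filtering configuration for occurrence data
#'
#' Defaults follow the flight-telemetry protocol: keep proofed fixes with
#' ground speed strictly between 2.78 and 30.0 m/s (birds in flight), drop
#' points offshore or within 5 km of a release site, thin to one point per
#' bird per day, and draw 10,000 background points inside the movement-point
#' convex hull buffered by 10 km.
#'
#' @param speed_min,speed_max flight-speed window bounds, m/s (strict
#'   inequalities at both ends).
#' @param exclusion_radius_km radius around release sites to discard, km.
#' @param hull_buffer_km buffer applied to the movement-point convex hull, km.
#' @param n_background number of background points.
#' @param timezone timezone defining the calendar day for daily thinning.
#' @param seed RNG seed for thinning and background sampling.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(speed_min = 2.78, speed_max = 30.0,
                          exclusion_radius_km = 5, hull_buffer_km = 10,
                          n_background = 10000, timezone = "UTC", seed = 1) {
  stopifnot(speed_min > 0, speed_min < speed_max)
  structure(as.list(environment()), class = "filter_config")
}

#' Keep proofed in-flight fixes
#'
#' Retains records with `proofed == 1` and speed strictly inside the flight
#' window (`speed_min`, `speed_max`); the strict inequalities mean a fix at
#' exactly 2.78 m/s is dropped. Input order is preserved.
#'
#' @param records telemetry data.frame with `speed_mps` and `proofed`.
#' @param config a [filter_config()].
#' @return The kept subset, with removal counts in `attr(, "removed")`.
#' @export
filter_flight_points <- function(records, config = filter_config()) {
  stopifnot(all(c("speed_mps", "proofed") %in% names(records)))
  if (nrow(records) == 0) return(records)
  if (any(!is.finite(records$speed_mps)) || any(records$speed_mps < 0))
    stop("malformed input: speeds must be finite and non-negative")
  unproofed <- records$proofed != 1
  out_window <- records$speed_mps <= config$speed_min |
    records$speed_mps >= config$speed_max
  keep <- !unproofed & !out_window
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- c(
    unproofed = sum(unproofed),
    out_of_speed_window = sum(out_window & !unproofed))
  out
}

#' Drop offshore and near-release-site points
#'
#' Removes records on ocean cells of `ocean_mask` and records within
#' `exclusion_radius` (from each site row; default 5 km) of any release site,
#' by Euclidean distance in projected metres. Flight-pen or trap sites are
#' passed as additional [release_site()] rows.
#'
#' @param records telemetry data.frame with `x`, `y` (m).
#' @param sites data.frame of [release_site()] rows (possibly empty).
#' @param ocean_mask `rf_raster` with 1 = ocean, or `NULL` to skip.
#' @param config a [filter_config()] (unused defaults kept for symmetry).
#' @param off_grid `"drop"` (default) or `"error"` for records outside the
#'   mask extent.
#' @return Kept subset with per-reason counts in `attr(, "removed")`.
#' @export
exclude_zones <- function(records, sites, ocean_mask = NULL,
                          config = filter_config(), off_grid = c("drop", "error")) {
  off_grid <- match.arg(off_grid)
  n <- nrow(records)
  offshore <- rep(FALSE, n); outside <- rep(FALSE, n)
  if (!is.null(ocean_mask)) {
    m <- raster_value_at(ocean_mask, records$x, records$y)
    outside <- is.na(m)
    if (any(outside) && off_grid == "error")
      stop(sum(outside), " record(s) outside the mask extent")
    offshore <- !is.na(m) & m == 1
  }
  near <- rep(FALSE, n)
  if (!is.null(sites) && nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      d <- sqrt((records$x - sites$x[i])^2 + (records$y - sites$y[i])^2)
      near <- near | d <= sites$exclusion_radius[i]
    }
  }
  keep <- !offshore & !near & !outside
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- c(offshore = sum(offshore & !near),
                            near_site = sum(near),
                            off_grid = sum(outside & !offshore & !near))
  out
}

#' Thin to one point per bird per day
#'
#' Selects one record uniformly at random per (bird, calendar day) pair, to
#' reduce temporal autocorrelation before presence-background modelling. The
#' calendar day is taken in `config$timezone` (UTC by default).
#'
#' @inheritParams filter_flight_points
#' @return One record per bird-day, in bird/time order.
#' @export
thin_daily <- function(records, config = filter_config()) {
  stopifnot(all(c("bird_id", "timestamp") %in% names(records)))
  if (nrow(records) == 0) return(records)
  day <- as.Date(records$timestamp, tz = config$timezone)
  key <- paste(records$bird_id, day)
  with_seed(config$seed, {
    picked <- unsplit_pick(key)
    out <- records[picked, , drop = FALSE]
    out <- out[order(out$bird_id, out$timestamp), ]
    rownames(out) <- NULL
    out
  })
}

# one uniformly chosen row index per group, deterministic given the RNG state
unsplit_pick <- function(key) {
  idx <- split(seq_along(key), key)
  vapply(idx, function(i) if (length(i) == 1L) i else i[sample.int(length(i), 1L)],
         integer(1))
}

# --- planar geometry helpers (no sf/sp available in this stack) -------------

# convex hull as closed polygon (data.frame x, y; last vertex != first)
convex_hull <- function(x, y) {
  h <- chull(x, y)
  data.frame(x = x[h], y = y[h])
}

# crossing-number point-in-polygon (polygon given as open ring)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly$x; ys <- poly$y
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# distance from points to a polygon boundary (segments)
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly$x[j]; ay <- poly$y[j]; bx <- poly$x[i]; by <- poly$y[i]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    j <- i
  }
  sqrt(d2)
}

# membership in the hull buffered by `buffer` metres
in_buffered_hull <- function(px, py, hull, buffer) {
  point_in_polygon(px, py, hull) | dist_to_polygon(px, py, hull) <= buffer
}

#' Draw background points inside the buffered movement hull
#'
#' Computes the convex hull of the movement points, buffers it by
#' `hull_buffer_km`, clips to land (via the ocean mask), and draws
#' `n_background` uniform points inside by rejection sampling over the
#' buffered hull's bounding box, excluding cells within the exclusion radius
#' of any release site.
#'
#' @param flight_points data.frame with `x`, `y` of filtered movement points
#'   (>= 3 non-collinear points).
#' @param sites release-site data.frame (exclusions applied per row).
#' @param ocean_mask `rf_raster` land/ocean mask (1 = ocean) or `NULL`.
#' @param config a [filter_config()].
#' @return data.frame `x`, `y` with `n_background` rows; the hull polygon in
#'   `attr(, "hull")`.
#' @export
build_background <- function(flight_points, sites = NULL, ocean_mask = NULL,
                             config = filter_config()) {
  stopifnot(nrow(flight_points) >= 3)
  hull <- convex_hull(flight_points$x, flight_points$y)
  if (nrow(hull) < 3) stop("degenerate hull: movement points are collinear")
  buf <- config$hull_buffer_km * 1000
  n <- config$n_background
  if (n == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0))
    attr(out, "hull") <- hull
    return(out)
  }
  bb <- c(min(hull$x) - buf, max(hull$x) + buf,
          min(hull$y) - buf, max(hull$y) + buf)
  keep_x <- numeric(0); keep_y <- numeric(0)
  with_seed(config$seed + 7L, {
    tries <- 0L
    while (length(keep_x) < n) {
      tries <- tries + 1L
      if (tries > 1000L) stop("background sampling failed to converge")
      m <- max(2L * (n - length(keep_x)), 1000L)
      px <- runif(m, bb[1], bb[2]); py <- runif(m, bb[3], bb[4])
      ok <- in_buffered_hull(px, py, hull, buf)
      if (!is.null(ocean_mask)) {
        v <- raster_value_at(ocean_mask, px, py)
        ok <- ok & !is.na(v) & v != 1
      }
      if (!is.null(sites) && nrow(sites) > 0) {
        for (i in seq_len(nrow(sites)))
          ok <- ok & sqrt((px - sites$x[i])^2 + (py - sites$y[i])^2) >
            sites$exclusion_radius[i]
      }
      keep_x <- c(keep_x, px[ok]); keep_y <- c(keep_y, py[ok])
    }
  })
  out <- data.frame(x = keep_x[seq_len(n)], y = keep_y[seq_len(n)])
  attr(out, "hull") <- hull
  out
}

#' Read/write telemetry CSV
#'
#' Columns: `bird_id`, `timestamp` (ISO-8601, UTC), `x`, `y`, `speed_mps`,
#' `proofed` (0/1).
#'
#' @param records telemetry data.frame.
#' @param path file path.
#' @return `read_telemetry_csv` returns the parsed data.frame.
#' @export
write_telemetry_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(records$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry_csv
#' @export
read_telemetry_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  d
}
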