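#' Extract map values at movement points near release sites
#'
#' Looks up the map value at each point's cell, restricted to points within
#' `max_distance_km` of any release site — current predictions are biased
#' near the ground ring, so evaluation is limited to the inner region.
#' Points on nodata cells are dropped and counted.
#'
#' @param map an `rf_raster` (e.g. a mean current map, mA).
#' @param points data.frame with `x`, `y`.
#' @param sites release-site data.frame; `NULL` disables the distance limit.
#' @param max_distance_km evaluation radius around sites (default 300 km).
#' @return Numeric vector of map values, with counts of excluded points in
#'   `attr(, "excluded")`.
#' @export
extract_at_points <- function(map, points, sites = NULL,
                              max_distance_km = 300) {
  n <- nrow(points)
  in_range <- rep(TRUE, n)
  if (!is.null(sites) && nrow(sites) > 0) {
    dmin <- rep(Inf, n)
    for (i in seq_len(nrow(sites)))
      dmin <- pmin(dmin, sqrt((points$x - sites$x[i])^2 +
                                (points$y - sites$y[i])^2))
    in_range <- dmin <= max_distance_km * 1000
  }
  if (!any(in_range)) stop("no points within the evaluation distance")
  v <- raster_value_at(map, points$x[in_range], points$y[in_range])
  out <- v[!is.na(v)]
  attr(out, "excluded") <- c(beyond_max_distance = sum(!in_range),
                             nodata_cell = sum(is.na(v)))
  out
}

#' Continuous Boyce index and P/E curve
#'
#' Compares the distribution of map values at movement points ("predicted")
#' with the distribution over the evaluation area ("expected") in moving
#' windows of width `window_fraction` (of the value range) centred at
#' `n_windows` evenly spaced positions. The P/E ratio per window is the
#' fraction of point values in the window over the fraction of map cells in
#' it (empty-expected windows skipped); the index is the Spearman rank
#' correlation between window position and P/E. +1 means predictions are
#' consistent with the observed distribution of movement, ~0 a random model,
#' negative an incorrect model.
#'
#' With the default `scale = "rank"`, windows are placed on the quantile
#' scale of the map distribution (via its empirical CDF). This makes the
#' expected fraction essentially uniform across windows, removes the
#' small-sample bias of near-empty windows in the long upper tail of current
#' maps, and renders the index invariant under any strictly monotone
#' transform of the map values; the reported window centres are mapped back
#' to the value scale (`centre_value`) for plotting P/E against mA.
#' `scale = "value"` places windows directly on the value scale. With
#' `windows = "disjoint"` the scale is cut into `n_windows` non-overlapping
#' bins (in which case the expectation-weighted mean of P/E is exactly 1).
#'
#' @param values_at_points map values at movement points (>= 20).
#' @param map_values map values over the evaluation area (all land cells of
#'   the evaluation region, excluding zones where points cannot occur).
#' @param window_fraction moving-window width as a fraction of the scale
#'   range (default 0.1).
#' @param n_windows number of window centres (default 101).
#' @param windows `"moving"` (default) or `"disjoint"`.
#' @param scale `"rank"` (default) or `"value"`.
#' @return list of class `pe_curve`: `centre` (window position on the chosen
#'   scale), `centre_value` (map-value scale), `pe`, `expected`,
#'   `boyce_index`, `window_width`, `n_points`, `n_windows_used`. For a
#'   constant map the index is `NA` with a diagnostic message rather than 0.
#' @export
boyce_continuous <- function(values_at_points, map_values,
                             window_fraction = 0.1, n_windows = 101,
                             windows = c("moving", "disjoint"),
                             scale = c("rank", "value")) {
  windows <- match.arg(windows)
  scale <- match.arg(scale)
  stopifnot(length(values_at_points) >= 20)
  map_values <- map_values[!is.na(map_values)]
  if (diff(range(map_values)) == 0) {
    message("constant map: Boyce index undefined")
    return(structure(list(centre = numeric(0), centre_value = numeric(0),
                          pe = numeric(0), expected = numeric(0),
                          boyce_index = NA_real_, window_width = 0,
                          n_points = length(values_at_points),
                          n_windows_used = 0L), class = "pe_curve"))
  }
  if (scale == "rank") {
    cdf <- stats::ecdf(map_values)
    obs <- cdf(values_at_points)
    fit <- cdf(map_values)
    rng <- c(0, 1)
    back <- function(p) as.numeric(quantile(map_values, pmin(pmax(p, 0), 1),
                                            type = 1))
  } else {
    obs <- values_at_points
    fit <- map_values
    rng <- range(map_values)
    back <- identity
  }
  if (windows == "moving") {
    w <- window_fraction * diff(rng)
    centre <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
    lo <- centre - w / 2; hi <- centre + w / 2
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_windows + 1)
    lo <- edges[-length(edges)]; hi <- edges[-1]
    centre <- (lo + hi) / 2
    w <- diff(edges)[1]
  }
  np <- length(obs); nm <- length(fit)
  in_win <- function(v, l, h, last) if (last) v >= l & v <= h else v >= l & v < h
  P <- E <- numeric(length(centre))
  for (k in seq_along(centre)) {
    last <- k == length(centre)
    P[k] <- sum(in_win(obs, lo[k], hi[k], last)) / np
    E[k] <- sum(in_win(fit, lo[k], hi[k], last)) / nm
  }
  keep <- E > 0
  pe <- P[keep] / E[keep]
  idx <- if (length(pe) >= 3 && sd(pe) > 0)
    cor(centre[keep], pe, method = "spearman") else NA_real_
  structure(list(centre = centre[keep], centre_value = back(centre[keep]),
                 pe = pe, expected = E[keep],
                 boyce_index = idx, window_width = w,
                 n_points = np, n_windows_used = sum(keep)),
            class = "pe_curve")
}

#' @export
print.pe_curve <- function(x, ...) {
  cat(sprintf("pe_curve: Boyce index %.3f over %d windows (%d points)\n",
              x$boyce_index, x$n_windows_used, x$n_points))
  invisible(x)
}

#' Reverse cumulative frequency of current at movement points
#'
#' For thresholds t = 0, 1, 2, ... mA (bin width `bin_mA`), the fraction of
#' values >= t: shows how movement frequency attenuates with decreasing
#' electrical current. The curve starts at exactly 1 and is non-increasing.
#'
#' @param values non-negative current values (mA) at movement points.
#' @param bin_mA threshold interval (default 1 mA).
#' @return data.frame `threshold_mA`, `fraction`.
#' @export
reverse_cumulative <- function(values, bin_mA = 1.0) {
  if (length(values) == 0) stop("no values supplied")
  stopifnot(all(values >= 0), bin_mA > 0)
  thr <- seq(0, max(values) + bin_mA, by = bin_mA)
  data.frame(threshold_mA = thr,
             fraction = vapply(thr, function(t) mean(values >= t), numeric(1)))
}
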