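# circular-window cell offsets for a focal radius (metres)
focal_offsets <- function(radius, cell_size) {
  rc <- floor(radius / cell_size)
  off <- expand.grid(dr = -rc:rc, dc = -rc:rc)
  off[sqrt(off$dr^2 + off$dc^2) * cell_size <= radius, , drop = FALSE]
}

# shift a matrix by (dr, dc), padding with NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Focal (neighbourhood) statistic
#'
#' Summarises a raster within a circular window: each cell receives the
#' statistic over all cells whose centres lie within `radius_km` of its
#' centre. Nodata cells are excluded from the window; an all-nodata window
#' yields nodata. Edge windows shrink (no wrapping). `"density"` returns the
#' summed value times the cell area in km^2 — for a binary habitat raster,
#' the habitat area (km^2) within the neighbourhood.
#'
#' @param r an `rf_raster`.
#' @param radius_km window radius, km (>= one cell).
#' @param stat one of `"mean"`, `"median"`, `"density"`.
#' @return An `rf_raster` of the same geometry.
#' @export
focal_statistic <- function(r, radius_km, stat = c("mean", "median", "density")) {
  stat <- match.arg(stat)
  radius <- radius_km * 1000
  if (radius < r$cell_size) stop("radius must be at least one cell")
  off <- focal_offsets(radius, r$cell_size)
  m <- r$values
  out <- r
  if (stat %in% c("mean", "density")) {
    s <- matrix(0, nrow(m), ncol(m)); cnt <- matrix(0L, nrow(m), ncol(m))
    for (i in seq_len(nrow(off))) {
      sh <- shift_mat(m, off$dr[i], off$dc[i])
      ok <- !is.na(sh)
      s[ok] <- s[ok] + sh[ok]
      cnt <- cnt + ok
    }
    if (stat == "mean") {
      res <- s / cnt
      res[cnt == 0] <- NA_real_
    } else {
      res <- s * (r$cell_size / 1000)^2
      res[cnt == 0] <- NA_real_
    }
    res[is.na(m)] <- NA_real_
  } else {
    nr <- nrow(m); nc <- ncol(m)
    res <- matrix(NA_real_, nr, nc)
    for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
      if (is.na(m[rr, cc])) next
      rs <- rr + off$dr; cs <- cc + off$dc
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      v <- m[cbind(rs[ok], cs[ok])]
      v <- v[!is.na(v)]
      if (length(v)) res[rr, cc] <- median(v)
    }
  }
  out$values <- res
  out
}

# per-cell 3-D and planar surface areas by triangulating each cell centre
# with its 8 neighbours (triangle fan over consecutive neighbour directions)
surface_areas <- function(dem) {
  m <- dem$values
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("DEM too small for surface triangulation (needs neighbours)")
  cs <- dem$cell_size
  # neighbour directions in CCW order: E, NE, N, NW, W, SW, S, SE
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  dxy <- lapply(dirs, function(d) c(x = d[2] * cs, y = -d[1] * cs))
  z <- lapply(dirs, function(d) shift_mat(m, d[1], d[2]))
  surf <- matrix(0, nrow(m), ncol(m))
  plan <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(dirs)) {
    k2 <- if (k == length(dirs)) 1L else k + 1L
    z1 <- z[[k]] - m; z2 <- z[[k2]] - m
    v1 <- dxy[[k]]; v2 <- dxy[[k2]]
    # |cross((v1, z1), (v2, z2))| / 2
    cx <- v1["y"] * z2 - z1 * v2["y"]
    cy <- z1 * v2["x"] - v1["x"] * z2
    cz <- v1["x"] * v2["y"] - v1["y"] * v2["x"]
    a3 <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
    a2 <- 0.5 * abs(cz)    # scalar: planar area of this triangle
    ok <- !is.na(a3)
    surf[ok] <- surf[ok] + a3[ok]
    plan[ok] <- plan[ok] + a2
  }
  # scale so that a full 8-triangle fan (planar extent 4*cs^2) maps to one
  # cell area; ratio is unaffected, absolute areas become per-cell
  list(surface = surf / 4, planar = plan / 4)
}

#' Terrain ruggedness (surface-area ratio)
#'
#' Ratio of 3-D surface area to planar surface area within a focal
#' neighbourhood: per-cell areas are estimated by triangulating each cell
#' centre with its 8 neighbours, then summed over the circular window;
#' the ratio is >= 1, with 1 on flat terrain and 1/cos(slope) on an inclined
#' plane.
#'
#' @param dem elevation `rf_raster`, metres, projected grid.
#' @param radius_km focal window radius, km.
#' @return An `rf_raster` of ruggedness values.
#' @export
terrain_ruggedness <- function(dem, radius_km = 10) {
  a <- surface_areas(dem)
  s <- dem; s$values <- a$surface
  p <- dem; p$values <- a$planar
  radius <- radius_km * 1000
  off <- focal_offsets(radius, dem$cell_size)
  acc <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(off))) {
      sh <- shift_mat(m, off$dr[i], off$dc[i])
      ok <- !is.na(sh)
      out[ok] <- out[ok] + sh[ok]
    }
    out
  }
  out <- dem
  out$values <- acc(s$values) / acc(p$values)
  out$values[is.na(dem$values)] <- NA_real_
  out
}

#' Slope in degrees (Horn's method)
#'
#' 3x3 finite-difference slope after Horn; edge cells reuse the nearest
#' interior values (replicated padding), so interior cells are exact for an
#' inclined plane.
#'
#' @param dem elevation `rf_raster`, metres.
#' @return An `rf_raster` of slope in degrees.
#' @export
slope <- function(dem) {
  m <- dem$values
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(dr, dc) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    m[rs, cs, drop = FALSE]
  }
  cs <- dem$cell_size
  # Horn weights: (a + 2d + g) etc., rows N->S, cols W->E
  dzdx <- ((pad(-1, 1) + 2 * pad(0, 1) + pad(1, 1)) -
             (pad(-1, -1) + 2 * pad(0, -1) + pad(1, -1))) / (8 * cs)
  dzdy <- ((pad(-1, -1) + 2 * pad(-1, 0) + pad(-1, 1)) -
             (pad(1, -1) + 2 * pad(1, 0) + pad(1, 1))) / (8 * cs)
  out <- dem
  out$values <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out$values[is.na(m)] <- NA_real_
  out
}

#' Screen covariate collinearity with Spearman correlations
#'
#' Computes pairwise Spearman rank correlations of covariate values at the
#' supplied points; whenever a pair exceeds the threshold in absolute value,
#' the lower-priority member is dropped. A covariate that is constant at the
#' points has undefined correlations; it is reported and retained.
#'
#' @param stack a `covariate_stack`.
#' @param points data.frame with `x`, `y` (>= 3 rows).
#' @param threshold drop threshold on |rs| (default 0.70).
#' @param priority character vector of covariate names, most important first;
#'   defaults to stack order.
#' @return Character vector of retained covariate names; the full correlation
#'   matrix in `attr(, "spearman")` and any constant covariates in
#'   `attr(, "constant")`.
#' @export
screen_collinearity <- function(stack, points, threshold = 0.70,
                                priority = names(stack$covariates)) {
  stopifnot(nrow(points) >= 3)
  vals <- sapply(stack$covariates[priority], function(r)
    raster_value_at(r, points$x, points$y))
  rs <- suppressWarnings(cor(vals, method = "spearman",
                             use = "pairwise.complete.obs"))
  const <- priority[apply(vals, 2, function(v) length(unique(v[!is.na(v)])) < 2)]
  keep <- priority
  for (i in seq_along(priority)) {
    for (j in seq_along(priority)) {
      if (j <= i) next
      a <- priority[i]; b <- priority[j]
      if (!(a %in% keep) || !(b %in% keep)) next
      r_ab <- rs[a, b]
      if (!is.na(r_ab) && abs(r_ab) > threshold) keep <- setdiff(keep, b)
    }
  }
  structure(keep, spearman = rs, constant = const)
}
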