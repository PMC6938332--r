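#' Configuration for the synthetic landscape and telemetry generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: spatially autocorrelated covariate fields on a projected 1-km grid,
#' a known-truth conductance surface with a logistic link to the covariates,
#' and raw GPS tables whose point density decays with distance from a release
#' site and increases with conductance, salted with known counts of unproofed
#' fixes, out-of-speed-window fixes, offshore points and a near-release-site
#' cluster so that every downstream filter removes a counted subset.
#'
#' @param grid_rows,grid_cols grid size in cells (>= 8 each).
#' @param cell_size cell edge, metres.
#' @param autocorr_range spatial correlation length of the covariate fields,
#'   metres: the lag at which field autocorrelation falls to about exp(-1).
#' @param true_coefficients named list, one entry per covariate, each a numeric
#'   vector `c(linear, quadratic)` on the logit scale.
#' @param decay_length e-folding distance (m) of movement density away from
#'   the release site. `Inf` disables the decay.
#' @param n_birds,days,fixes_per_day telemetry sampling design.
#' @param unproofed_fraction,slow_fraction,fast_fraction fractions of the main
#'   telemetry records flagged unproofed, below the flight-speed window, and
#'   above it; the remainder get in-window flight speeds.
#' @param n_offshore,n_near_site counts of injected offshore points and of the
#'   dense cluster within the release-site exclusion radius.
#' @param ocean_cols width (cells) of the contiguous ocean strip on the west
#'   edge of the grid.
#' @param dem_relief vertical relief amplitude (m) of the synthetic terrain.
#' @param seed integer; the same seed reproduces every output bit-for-bit.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows = 101, grid_cols = 101,
                             cell_size = 1000, autocorr_range = 8000,
                             true_coefficients = list(
                               terrain  = c(linear = 1.5, quadratic = 0),
                               habitat  = c(linear = 2.0, quadratic = 0),
                               canopy   = c(linear = -1.0, quadratic = -0.5)),
                             decay_length = 30000,
                             n_birds = 15, days = 120, fixes_per_day = 12,
                             unproofed_fraction = 0.08, slow_fraction = 0.08,
                             fast_fraction = 0.04,
                             n_offshore = 120, n_near_site = 300,
                             ocean_cols = 6, dem_relief = 800, seed = 42) {
  if (grid_rows < 8 || grid_cols < 8)
    stop("grid must be at least 8x8 cells")
  if (cell_size <= 0 || decay_length <= 0 || autocorr_range <= 0)
    stop("cell_size, decay_length and autocorr_range must be positive")
  if (unproofed_fraction + slow_fraction + fast_fraction >= 1)
    stop("category fractions must leave room for in-window flight records")
  structure(as.list(environment()), class = "synthetic_config")
}

# RNG hygiene: run `expr` under `seed` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Separable Gaussian smoothing with edge renormalisation, kernel sd in cells.
gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  nr <- nrow(m); nc <- ncol(m)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- seq(max(1, i - half), min(n, i + half))
      K[i, j] <- k[j - i + half + 1]
    }
    K / rowSums(K)
  }
  band(nr) %*% m %*% t(band(nc))
}

#' Generate spatially autocorrelated covariate rasters
#'
#' Builds one raster per covariate named in `config$true_coefficients` by
#' Gaussian-kernel smoothing of white noise (kernel sd = `autocorr_range/2`,
#' so correlation falls to ~exp(-1) at `autocorr_range`), standardised to zero
#' mean and unit variance over the grid; plus a synthetic DEM (smooth field
#' scaled to `dem_relief`) and an ocean mask covering a contiguous strip of
#' `ocean_cols` columns on the west edge.
#'
#' @param config a [synthetic_config()].
#' @return A `covariate_stack`: list with `covariates` (named list of
#'   `rf_raster`), `dem`, `ocean` (1 = ocean, 0 = land), all on one grid.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  cs <- config$cell_size
  sigma <- (config$autocorr_range / cs) / 2
  mk <- function(v) rf_raster(v, xll = 0, yll = 0, cell_size = cs)
  with_seed(config$seed, {
    covs <- lapply(config$true_coefficients, function(.) {
      f <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), sigma)
      (f - mean(f)) / sd(f)
    })
    dem_f <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), sigma)
    dem_f <- (dem_f - mean(dem_f)) / sd(dem_f)
    dem <- 1000 + config$dem_relief * dem_f
    ocean <- matrix(0, nr, nc)
    ocean[, seq_len(min(config$ocean_cols, nc))] <- 1
    covariate_stack(covariates = lapply(covs, mk), dem = mk(dem),
                    ocean = mk(ocean))
  })
}

#' Bundle aligned covariate rasters
#'
#' @param covariates named list of `rf_raster` layers.
#' @param dem optional elevation raster (m).
#' @param ocean optional ocean mask raster (1 = ocean).
#' @return A list of class `covariate_stack`; all layers checked for shared
#'   geometry.
#' @export
covariate_stack <- function(covariates, dem = NULL, ocean = NULL) {
  stopifnot(length(covariates) >= 1, !is.null(names(covariates)))
  ref <- covariates[[1]]
  for (l in c(covariates, Filter(Negate(is.null), list(dem, ocean))))
    stop_if_misaligned(ref, l, "stack layers")
  structure(list(covariates = covariates, dem = dem, ocean = ocean),
            class = "covariate_stack")
}

#' Known-truth conductance from a covariate stack
#'
#' Cellwise inverse-logit of the linear + quadratic predictor
#' `sum_j (b1_j * z_j + b2_j * z_j^2)`; the synthetic analogue of the fitted
#' logistic conductance surface.
#'
#' @param stack a `covariate_stack`.
#' @param coefficients named list as in [synthetic_config()]; must name every
#'   covariate in the stack.
#' @return An `rf_raster` with values in (0, 1).
#' @export
true_conductance <- function(stack, coefficients) {
  stopifnot(inherits(stack, "covariate_stack"))
  missing <- setdiff(names(stack$covariates), names(coefficients))
  if (length(missing))
    stop("missing coefficients for covariate(s): ",
         paste(missing, collapse = ", "))
  eta <- 0
  for (nm in names(stack$covariates)) {
    z <- stack$covariates[[nm]]$values
    b <- coefficients[[nm]]
    eta <- eta + b[[1]] * z + b[[2]] * z^2
  }
  out <- stack$covariates[[1]]
  out$values <- stats::plogis(eta)
  out
}

#' A release site
#' @param site_id identifier.
#' @param x,y projected coordinates, metres.
#' @param exclusion_radius radius (m) within which movement and background
#'   points are discarded (default 5 km, chosen from frequency-plot inspection
#'   of distance to release sites).
#' @return data.frame with one row.
#' @export
release_site <- function(site_id, x, y, exclusion_radius = 5000) {
  stopifnot(exclusion_radius >= 0)
  data.frame(site_id = site_id, x = x, y = y,
             exclusion_radius = exclusion_radius)
}

#' Simulate a raw telemetry table
#'
#' Draws `n_birds * days * fixes_per_day` locations with cell probability
#' proportional to `conductance * exp(-distance_to_site / decay_length)`,
#' restricted to land cells outside the release-site exclusion radius, then
#' salts the table with known counts per removal category: a fraction of
#' records flagged unproofed, fractions given below-window ("slow") and
#' above-window ("fast") ground speeds, `n_offshore` points on ocean cells and
#' `n_near_site` points inside the exclusion radius (all with valid flags and
#' in-window speeds, so each is removed by exactly one filter). Category
#' counts are returned in `attr(, "category_counts")`.
#'
#' @param surface conductance `rf_raster`, values >= 0, not all zero.
#' @param site a [release_site()] row inside the grid.
#' @param config a [synthetic_config()].
#' @param ocean optional ocean-mask raster; cells with value 1 are excluded
#'   from the main draw and used for offshore injections.
#' @return data.frame with columns `bird_id`, `timestamp` (POSIXct, UTC),
#'   `x`, `y`, `speed_mps`, `proofed`.
#' @export
simulate_telemetry <- function(surface, site, config, ocean = NULL) {
  stopifnot(inherits(surface, "rf_raster"))
  v <- surface$values
  if (all(is.na(v)) || all(v[!is.na(v)] == 0))
    stop("degenerate conductance surface: all zero or all nodata")
  cc <- cell_centres(surface)
  rc <- cells_from_xy(surface, site$x, site$y)
  if (is.na(rc$row)) stop("release site lies outside the grid")

  d <- sqrt((cc$x - site$x)^2 + (cc$y - site$y)^2)
  w <- v[cbind(cc$row, cc$col)]
  w[is.na(w)] <- 0
  if (!is.null(ocean)) {
    stop_if_misaligned(surface, ocean)
    w[ocean$values[cbind(cc$row, cc$col)] == 1] <- 0
  }
  excl <- site$exclusion_radius
  w[d <= excl] <- 0
  if (is.finite(config$decay_length)) w <- w * exp(-d / config$decay_length)
  if (sum(w) == 0) stop("no cells with positive sampling weight")

  n_main <- config$n_birds * config$days * config$fixes_per_day
  n_unp <- round(config$unproofed_fraction * n_main)
  n_slow <- round(config$slow_fraction * n_main)
  n_fast <- round(config$fast_fraction * n_main)
  n_flight <- n_main - n_unp - n_slow - n_fast

  smin <- 2.78; smax <- 30.0
  with_seed(config$seed + 1L, {
    idx <- sample.int(length(w), n_main, replace = TRUE, prob = w)
    jit <- surface$cell_size * (matrix(runif(2 * n_main), ncol = 2) - 0.5)
    px <- cc$x[idx] + jit[, 1]; py <- cc$y[idx] + jit[, 2]
    # within-cell jitter must not carry a point across the exclusion
    # boundary, or the near-site bookkeeping would drift off by the leak
    repeat {
      bad <- which(sqrt((px - site$x)^2 + (py - site$y)^2) <= excl)
      if (!length(bad)) break
      jb <- surface$cell_size * (matrix(runif(2 * length(bad)), ncol = 2) - 0.5)
      px[bad] <- cc$x[idx[bad]] + jb[, 1]; py[bad] <- cc$y[idx[bad]] + jb[, 2]
    }

    cat_lab <- sample(rep(c("flight", "unproofed", "slow", "fast"),
                          c(n_flight, n_unp, n_slow, n_fast)))
    speed <- numeric(n_main)
    speed[cat_lab %in% c("flight", "unproofed")] <-
      runif(sum(cat_lab %in% c("flight", "unproofed")), smin + 0.1, smax - 0.1)
    speed[cat_lab == "slow"] <- runif(n_slow, 0, smin)
    speed[cat_lab == "fast"] <- runif(n_fast, smax, smax + 15)
    proofed <- as.integer(cat_lab != "unproofed")

    # bird/day/time design: fixes spread through an 8h-16h UTC flight day
    bird <- rep(sprintf("bird%02d", seq_len(config$n_birds)),
                each = config$days * config$fixes_per_day)
    day <- rep(rep(seq_len(config$days), each = config$fixes_per_day),
               times = config$n_birds)
    fix <- rep(seq_len(config$fixes_per_day),
               times = config$n_birds * config$days)
    t0 <- as.POSIXct("2016-01-01 08:00:00", tz = "UTC")
    ts <- t0 + (day - 1) * 86400 +
      (fix - 1) * (8 * 3600) / max(1, config$fixes_per_day - 1)

    main <- data.frame(bird_id = bird, timestamp = ts, x = px, y = py,
                       speed_mps = speed, proofed = proofed)

    inject <- function(n, rows, cols, label) {
      if (n == 0 || length(rows) == 0) return(NULL)
      pick <- sample(length(rows), n, replace = TRUE)
      jit <- surface$cell_size * (matrix(runif(2 * n), ncol = 2) - 0.5)
      nr <- nrow(surface$values)
      data.frame(
        bird_id = sample(unique(bird), n, replace = TRUE),
        timestamp = t0 + (sample(config$days, n, replace = TRUE) - 1) * 86400,
        x = surface$xll + (cols[pick] - 0.5) * surface$cell_size + jit[, 1],
        y = surface$yll + (nr - rows[pick] + 0.5) * surface$cell_size + jit[, 2],
        speed_mps = runif(n, smin + 0.1, smax - 0.1), proofed = 1L)
    }
    off <- NULL
    if (config$n_offshore > 0) {
      if (is.null(ocean)) stop("offshore injections need an ocean mask")
      oc <- which(ocean$values == 1, arr.ind = TRUE)
      off <- inject(config$n_offshore, oc[, 1], oc[, 2])
    }
    on_land <- if (is.null(ocean)) TRUE else
      ocean$values[cbind(cc$row, cc$col)] != 1
    near_ok <- which(d <= excl & d > 0 & on_land)
    near <- inject(config$n_near_site, cc$row[near_ok], cc$col[near_ok])
    if (!is.null(near)) {
      repeat {
        bad <- which(sqrt((near$x - site$x)^2 + (near$y - site$y)^2) > excl)
        if (!length(bad)) break
        pick <- sample(length(near_ok), length(bad), replace = TRUE)
        jb <- surface$cell_size * (matrix(runif(2 * length(bad)), ncol = 2) - 0.5)
        nr <- nrow(surface$values)
        near$x[bad] <- surface$xll +
          (cc$col[near_ok][pick] - 0.5) * surface$cell_size + jb[, 1]
        near$y[bad] <- surface$yll +
          (nr - cc$row[near_ok][pick] + 0.5) * surface$cell_size + jb[, 2]
      }
    }

    out <- rbind(main, off, near)
    out <- out[order(out$bird_id, out$timestamp), ]
    rownames(out) <- NULL
    attr(out, "category_counts") <- c(
      flight = n_flight, unproofed = n_unp, slow = n_slow, fast = n_fast,
      offshore = if (is.null(off)) 0L else nrow(off),
      near_site = if (is.null(near)) 0L else nrow(near))
    out
  })
}
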