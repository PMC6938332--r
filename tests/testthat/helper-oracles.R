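# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit loops, dense linear algebra, or a
# different algorithm entirely.

# dense Laplacian voltages for a conductance raster: edges rebuilt from the
# raster with explicit loops (8-neighbour, mean conductance, sqrt(2) diagonal)
oracle_voltages <- function(values, source_rc, ground_rc, injection = 1) {
  nr <- nrow(values); nc <- ncol(values)
  id <- matrix(seq_len(nr * nc), nr, nc)
  n <- nr * nc
  L <- matrix(0, n, n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      g <- ((values[r, c] + values[r2, c2]) / 2) / d[3]
      i <- id[r, c]; j <- id[r2, c2]
      L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
      L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
    }
  }
  s <- id[source_rc[1], source_rc[2]]; gnd <- id[ground_rc[1], ground_rc[2]]
  keep <- setdiff(seq_len(n), gnd)
  b <- rep(0, n); b[s] <- injection
  v <- rep(0, n)
  v[keep] <- solve(L[keep, keep], b[keep])
  v
}

# angle-summation point-in-polygon (different algorithm from the package's
# crossing-number test)
oracle_point_in_polygon <- function(px, py, poly) {
  vapply(seq_along(px), function(i) {
    dx <- poly$x - px[i]; dy <- poly$y - py[i]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# 8-connected labelling by iterated label propagation to a fixed point
oracle_label <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(ifelse(bin, seq_len(nr * nc), NA_integer_), nr, nc)
  sh <- function(m, dr, dc) {
    out <- matrix(NA_integer_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  repeat {
    new <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- sh(lab, dr, dc)
      upd <- !is.na(new) & !is.na(nb) & nb < new
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  matrix(match(lab, sort(unique(lab[!is.na(lab)]))), nr, nc)
}

# multi-source grid shortest path via igraph on the equivalent weighted graph
oracle_cwd <- function(resistance_km, source_mask) {
  skip_if_not_installed("igraph")
  nr <- nrow(resistance_km); nc <- ncol(resistance_km)
  id <- matrix(seq_len(nr * nc), nr, nc)
  ed <- NULL; wt <- NULL
  for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(resistance_km[r, c]) || is.na(resistance_km[r2, c2])) next
      ed <- rbind(ed, c(id[r, c], id[r2, c2]))
      wt <- c(wt, 0.5 * (resistance_km[r, c] + resistance_km[r2, c2]) * d[3])
    }
  }
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = wt)
  srcs <- id[source_mask]
  dm <- igraph::distances(g, v = srcs, algorithm = "dijkstra")
  out <- apply(dm, 2, min)
  matrix(out[seq_len(nr * nc)], nr, nc)
}

# presence sampled from a single-feature Gibbs distribution over a uniform
# background feature; returns the fitted lambda rescaled to the raw feature
recover_lambda <- function(seed, lambda_true = 2.0, n_pres = 2000,
                           n_bg = 4000) {
  set.seed(seed)
  f_bg <- runif(n_bg)
  pres <- sample(f_bg, n_pres, replace = TRUE, prob = exp(lambda_true * f_bg))
  pc <- matrix(pres, ncol = 1, dimnames = list(NULL, "f"))
  bc <- matrix(f_bg, ncol = 1, dimnames = list(NULL, "f"))
  mod <- releaseflow:::fit_maxent_values(pc, bc,
                                         maxent_settings(features = "linear"))
  unname(mod$lambda[["f.linear"]] / mod$feature_range[["f.linear"]])
}

# small default synthetic configuration used across tests
tiny_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(grid_rows = 40, grid_cols = 40, n_birds = 4, days = 20,
         fixes_per_day = 6, n_offshore = 25, n_near_site = 40, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

tiny_world <- function(seed = 11, ...) {
  cfg <- tiny_config(seed = seed, ...)
  land <- generate_landscape(cfg)
  truth <- true_conductance(land, cfg$true_coefficients)
  site <- release_site("s", 20000, 20000)
  list(cfg = cfg, land = land, truth = truth, site = site)
}
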