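test_that("outside-area fill uses in-study minimum for ocean, median for land", {
  vals <- rf_raster(matrix(c(0.2, 0.4, 0.6, 0.8, 0.9, 0.1), 2, 3))
  study <- rf_raster(matrix(c(1, 1, 1, 1, 0, 0), 2, 3))
  ocean <- rf_raster(matrix(c(0, 0, 0, 0, 1, 0), 2, 3))
  out <- fill_outside(vals, study, ocean)
  expect_equal(out$values[1, 3], 0.2)              # ocean -> min
  expect_equal(out$values[2, 3], median(c(0.2, 0.4, 0.6, 0.8)))  # land outside
  expect_equal(out$values[, 1:2], vals$values[, 1:2])            # untouched
  # no outside cells: identity
  all_in <- rf_raster(matrix(1, 2, 3))
  none <- rf_raster(matrix(0, 2, 3))
  expect_equal(fill_outside(vals, all_in, none)$values, vals$values)
  expect_error(fill_outside(vals, none, none), "empty study area")

  set.seed(3)
  v <- rf_raster(matrix(runif(100), 10, 10))
  st <- rf_raster(matrix(rbinom(100, 1, 0.6), 10, 10))
  oc <- rf_raster(matrix(0, 10, 10)); oc$values[, 1] <- 1
  got <- fill_outside(v, st, oc)
  inside <- st$values == 1 & oc$values == 0
  expect_equal(got$values[oc$values == 1],
               rep(min(v$values[inside]), sum(oc$values == 1)))
  expect_equal(got$values[!inside & oc$values == 0],
               rep(median(v$values[inside]), sum(!inside & oc$values == 0)))
})

test_that("lattice construction follows the mean-conductance edge rule", {
  two <- rf_raster(matrix(c(2, 4), 1, 2))
  g <- raster_to_graph(two)
  expect_equal(g$edges$conductance, 3)
  diag2 <- rf_raster(matrix(c(1, NA, NA, 1), 2, 2))
  expect_error(raster_to_graph(rf_raster(matrix(NA_real_, 2, 2))), "nodata")
  gd <- raster_to_graph(rf_raster(matrix(1, 2, 2)))
  dg <- gd$edges$conductance[abs(gd$nodes$row[gd$edges$from] -
                                   gd$nodes$row[gd$edges$to]) == 1 &
                               abs(gd$nodes$col[gd$edges$from] -
                                     gd$nodes$col[gd$edges$to]) == 1]
  expect_equal(dg, rep(1 / sqrt(2), 2))
  g3 <- raster_to_graph(rf_raster(matrix(1, 3, 3)))
  expect_equal(nrow(g3$nodes), 9)
  expect_equal(nrow(g3$edges), 20)   # 12 orthogonal + 8 diagonal
})

test_that("a uniform series chain carries the full current with 2 V drop", {
  g <- raster_to_graph(rf_raster(matrix(1, 1, 3)))
  m <- solve_pair(g, c(1, 1), c(1, 3))
  expect_equal(as.vector(m$values), c(1, 1, 1))
  v <- attr(m, "voltages")
  expect_equal(v[1] - v[3], 2)
  expect_error(solve_pair(g, c(1, 2), c(1, 2)), "same cell")
  split <- rf_raster(matrix(c(1, NA, 1), 1, 3))
  gs <- raster_to_graph(split)
  expect_error(solve_pair(gs, c(1, 1), c(1, 3)), "disconnected")
})

test_that("two equal parallel paths each carry half the current", {
  v <- matrix(NA_real_, 3, 3)
  v[1, ] <- 1; v[3, ] <- 1; v[2, 1] <- 1; v[2, 3] <- 1
  g <- raster_to_graph(v_r <- rf_raster(v), neighborhood = 4)
  m <- solve_pair(g, c(2, 1), c(2, 3))
  expect_equal(m$values[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(m$values[3, 2], 0.5, tolerance = 1e-12)
})

test_that("sparse solve matches the dense full-Laplacian oracle", {
  set.seed(17)
  for (rep in 1:20) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    vals <- matrix(runif(nr * nc, 0.1, 2), nr, nc)
    g <- raster_to_graph(rf_raster(vals))
    cells <- expand.grid(r = seq_len(nr), c = seq_len(nc))
    pick <- sample(nrow(cells), 2)
    src <- c(cells$r[pick[1]], cells$c[pick[1]])
    gnd <- c(cells$r[pick[2]], cells$c[pick[2]])
    m <- solve_pair(g, src, gnd)
    v_or <- oracle_voltages(vals, src, gnd)
    v_got <- attr(m, "voltages")[g$node_index[cbind(cells$r, cells$c)]]
    expect_equal(v_got, v_or, tolerance = 1e-8)
  }
})

test_that("Kirchhoff current conservation holds at interior nodes", {
  set.seed(23)
  for (rep in 1:5) {
    vals <- matrix(runif(36, 0.1, 2), 6, 6)
    g <- raster_to_graph(rf_raster(vals))
    m <- solve_pair(g, c(1, 1), c(6, 6), injection = 1)
    v <- attr(m, "voltages")
    e <- g$edges
    flow <- e$conductance * (v[e$from] - v[e$to])
    net <- numeric(nrow(g$nodes))
    for (k in seq_len(nrow(e))) {
      net[e$from[k]] <- net[e$from[k]] - flow[k]
      net[e$to[k]] <- net[e$to[k]] + flow[k]
    }
    s <- g$node_index[1, 1]; gr <- g$node_index[6, 6]
    interior <- setdiff(seq_along(net), c(s, gr))
    expect_lt(max(abs(net[interior])), 1e-9)
    # total current entering ground equals total injection
    expect_equal(net[gr], 1, tolerance = 1e-9)
  }
})

test_that("current maps are symmetric on a symmetric uniform grid", {
  g <- raster_to_graph(rf_raster(matrix(1, 5, 5)))
  m <- solve_pair(g, c(3, 1), c(3, 5))
  expect_equal(m$values, m$values[5:1, ], tolerance = 1e-10)
})

test_that("raising conductance along the only path does not reduce its current", {
  # a 1-wide corridor is the unique route; doubling its conductance must not
  # decrease the through-current (it stays the full injection here)
  v <- matrix(NA_real_, 1, 5); v[] <- 0.5
  g1 <- raster_to_graph(rf_raster(v))
  m1 <- solve_pair(g1, c(1, 1), c(1, 5))
  v2 <- v * 2
  g2 <- raster_to_graph(rf_raster(v2))
  m2 <- solve_pair(g2, c(1, 1), c(1, 5))
  expect_true(all(m2$values >= m1$values - 1e-12))
})

test_that("effective resistance obeys series and parallel closed forms", {
  chain <- rf_raster(matrix(c(1, 2, 4), 1, 3))
  g <- raster_to_graph(chain)
  # edge resistances: 1/mean(1,2) and 1/mean(2,4)
  expect_equal(effective_resistance(g, c(1, 1), c(1, 3)),
               1 / 1.5 + 1 / 3)
  ring <- matrix(NA_real_, 3, 3)
  ring[1, ] <- 1; ring[3, ] <- 1; ring[2, 1] <- 1; ring[2, 3] <- 1
  gr <- raster_to_graph(rf_raster(ring), neighborhood = 4)
  r_top <- 4; r_bot <- 4   # four unit edges per branch
  expect_equal(effective_resistance(gr, c(2, 1), c(2, 3)),
               1 / (1 / r_top + 1 / r_bot))
  # Laplacian pseudoinverse formula on a random lattice
  set.seed(41)
  vals <- matrix(runif(16, 0.2, 2), 4, 4)
  g4 <- raster_to_graph(rf_raster(vals))
  L <- as.matrix(releaseflow:::graph_laplacian(g4))
  Lp <- MASS::ginv(L)
  a <- g4$node_index[1, 2]; b <- g4$node_index[4, 3]
  expect_equal(effective_resistance(g4, c(1, 2), c(4, 3)),
               Lp[a, a] + Lp[b, b] - 2 * Lp[a, b], tolerance = 1e-8)
})

test_that("mean current converts to milliamps and averages cellwise", {
  m1 <- rf_raster(matrix(0.005, 2, 2))
  expect_equal(mean_current(list(m1))$values, matrix(5, 2, 2))
  expect_equal(mean_current(list(m1, m1, m1))$values, matrix(5, 2, 2))
  set.seed(2)
  maps <- lapply(1:3, function(.) rf_raster(matrix(runif(4), 2, 2)))
  got <- mean_current(maps)$values
  byhand <- 1000 * (maps[[1]]$values + maps[[2]]$values + maps[[3]]$values) / 3
  expect_equal(got, byhand)
})

test_that("cellwise maximum overlay is idempotent with zero identity", {
  set.seed(3)
  a <- rf_raster(matrix(runif(9), 3, 3)); b <- rf_raster(matrix(runif(9), 3, 3))
  expect_equal(combine_max(a, a)$values, a$values)
  zero <- rf_raster(matrix(0, 3, 3))
  expect_equal(combine_max(a, zero)$values, a$values)
  got <- combine_max(a, b)$values
  for (i in 1:3) for (j in 1:3)
    expect_equal(got[i, j], max(a$values[i, j], b$values[i, j]))
})

test_that("ground ring geometry gives 220 nodes for one 350-km site", {
  ring <- place_ground_ring(data.frame(x = 0, y = 0), 350, 10)
  expect_equal(nrow(ring), 220)
  expect_equal(attr(ring, "perimeter"), 2 * pi * 350000, tolerance = 1e-9)
  # all nodes on the circle, spaced ~10 km apart along it
  expect_equal(sqrt(ring$x^2 + ring$y^2), rep(350000, 220), tolerance = 1e-6)
  # spacing = perimeter/4 gives 4 nodes
  r4 <- place_ground_ring(data.frame(x = 0, y = 0), buffer_km = 2 / pi,
                          spacing_km = 1)
  expect_equal(nrow(r4), 4)
  expect_error(place_ground_ring(data.frame(x = 0, y = 0), -1, 10), "positive")
})

test_that("two-site ring count matches an independent perimeter oracle", {
  sites <- data.frame(x = c(0, 100000), y = c(0, 0))
  ring <- place_ground_ring(sites, buffer_km = 80, spacing_km = 10)
  # oracle: fine polygonisation of both circles, keep points outside the
  # other disk, perimeter from the analytic two-circle union formula
  r <- 80000; d <- 100000
  alpha <- acos(d / (2 * r))
  perim <- 2 * r * (2 * pi - 2 * alpha)
  expect_equal(attr(ring, "perimeter"), perim, tolerance = 1e-9)
  expect_equal(nrow(ring), ceiling(perim / 10000))
  # every node is on a circle and not strictly inside the other disk
  d1 <- sqrt(ring$x^2 + ring$y^2)
  d2 <- sqrt((ring$x - 1e5)^2 + ring$y^2)
  on1 <- abs(d1 - r) < 1; on2 <- abs(d2 - r) < 1
  expect_true(all(on1 | on2))
  expect_true(all(d1 >= r - 1 & d2 >= r - 1))
})
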