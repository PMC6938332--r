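test_that("resistance is the cellwise reciprocal of conductance", {
  r <- rf_raster(matrix(c(0.5, 1, 0.25, 0.1), 2, 2))
  expect_equal(resistance_from_conductance(r)$values,
               matrix(c(2, 1, 4, 10), 2, 2))
  set.seed(2)
  v <- rf_raster(matrix(runif(36, 0.05, 1), 6, 6))
  expect_equal(resistance_from_conductance(v)$values, 1 / v$values)
  bad <- rf_raster(matrix(c(1, 0), 1, 2))
  expect_error(resistance_from_conductance(bad), "zero")
})

test_that("core extraction applies the 0.04 threshold and 10-km2 minimum", {
  v <- matrix(0.01, 12, 12)
  cores0 <- extract_cores(rf_raster(v, cell_size = 1000))
  expect_equal(nrow(cores0$patches), 0)
  # an 8-cell blob (8 km2) is dropped; a 12-cell blob is kept
  v[2:3, 2:5] <- 0.5          # 8 cells
  v[8:10, 8:11] <- 0.5        # 12 cells
  cores <- extract_cores(rf_raster(v, cell_size = 1000))
  expect_equal(nrow(cores$patches), 1)
  expect_equal(cores$patches$area_km2, 12)
  # exactly at threshold counts as habitat
  v2 <- matrix(0, 6, 6); v2[1:4, 1:4] <- 0.04
  expect_equal(nrow(extract_cores(rf_raster(v2, cell_size = 1000))$patches), 1)
})

test_that("patch labelling matches an independent propagation oracle", {
  set.seed(9)
  for (rep in 1:5) {
    bin <- matrix(runif(15 * 15) < 0.45, 15, 15)
    got <- releaseflow:::label_components(bin)
    want <- oracle_label(bin)
    # same partition (labels may be permuted)
    expect_equal(is.na(got), is.na(want))
    tab <- table(got, want)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("core extraction shrinks monotonically with threshold and area", {
  set.seed(30)
  v <- rf_raster(matrix(runif(400), 20, 20), cell_size = 1000)
  # habitat extent is non-increasing in threshold; patch count itself is not
  # monotone in threshold in general (a blob can split), so check extent and
  # a nested fixture where no splitting occurs
  area <- sapply(c(0.2, 0.5, 0.8), function(th)
    sum(extract_cores(v, threshold = th, min_area_km2 = 1)$patches$area_km2))
  expect_true(all(diff(area) <= 0))
  bump <- rf_raster(outer(1:20, 1:20, function(i, j)
    exp(-((i - 10)^2 + (j - 10)^2) / 40)), cell_size = 1000)
  n <- sapply(c(0.1, 0.4, 0.7, 0.95), function(th)
    nrow(extract_cores(bump, threshold = th, min_area_km2 = 1)$patches))
  expect_true(all(diff(n) <= 0))
  n2 <- sapply(c(1, 3, 6), function(a)
    nrow(extract_cores(v, threshold = 0.5, min_area_km2 = a)$patches))
  expect_true(all(diff(n2) <= 0))
})

test_that("cost-weighted distance follows the mean-resistance move cost", {
  # uniform resistance 1, 1-km cells: 5 cells due east cost 5
  res <- rf_raster(matrix(1, 3, 7), cell_size = 1000)
  src <- matrix(FALSE, 3, 7); src[2, 1] <- TRUE
  cw <- cost_weighted_distance(res, src)
  expect_equal(cw$cwd$values[2, 6], 5)
  # single diagonal step with resistances 1 and 3 costs mean * sqrt(2)
  res2 <- rf_raster(matrix(c(1, 10, 10, 3), 2, 2), cell_size = 1000)
  src2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  cw2 <- cost_weighted_distance(res2, src2)
  expect_equal(cw2$cwd$values[2, 2], 2 * sqrt(2))
})

test_that("grid Dijkstra agrees with an independent shortest-path solver", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:20) {
    vals <- matrix(runif(144, 0.1, 5), 12, 12)
    res <- rf_raster(vals, cell_size = 1000)
    src <- matrix(FALSE, 12, 12)
    src[cbind(sample(12, 2), sample(12, 2))] <- TRUE
    got <- cost_weighted_distance(res, src)$cwd$values
    want <- oracle_cwd(vals * 1, src)   # cell size 1 km: resistance as-is
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("CWD scales linearly with resistance and satisfies optimality", {
  set.seed(55)
  vals <- matrix(runif(64, 0.2, 3), 8, 8)
  res <- rf_raster(vals, cell_size = 1000)
  src <- matrix(FALSE, 8, 8); src[1, 1] <- TRUE
  a <- cost_weighted_distance(res, src)$cwd$values
  res2 <- res; res2$values <- 2 * vals
  b <- cost_weighted_distance(res2, src)$cwd$values
  expect_equal(b, 2 * a, tolerance = 1e-12)
  # shortest-path optimality: cwd <= cwd(neighbour) + move cost
  for (i in 1:8) for (j in 1:8) {
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 < 1 || i2 > 8 || j2 < 1 || j2 > 8) next
      mc <- 0.5 * (vals[i, j] + vals[i2, j2]) * sqrt(sum(d^2))
      expect_lte(a[i, j], a[i2, j2] + mc + 1e-12)
      expect_lte(a[i2, j2], a[i, j] + mc + 1e-12)
    }
  }
})

# strip world: three patches in a row on uniform resistance
strip_world <- function() {
  v <- matrix(0, 5, 21)
  v[2:4, 1:3] <- 1; v[2:4, 10:12] <- 1; v[2:4, 19:21] <- 1
  suit <- rf_raster(v, cell_size = 1000)
  cores <- extract_cores(suit, threshold = 0.5, min_area_km2 = 5)
  res <- rf_raster(matrix(1, 5, 21), cell_size = 1000)
  cwd <- lapply(cores$patches$patch_id, function(i)
    cost_weighted_distance(res, i, cores))
  list(cores = cores, res = res, cwd = cwd)
}

test_that("allocation adjacency links consecutive patches only", {
  w <- strip_world()
  expect_equal(nrow(w$cores$patches), 3)
  pairs <- adjacency_network(w$cores, w$cwd)
  expect_equal(pairs$patch_a, c(1, 2))
  expect_equal(pairs$patch_b, c(2, 3))   # no end-to-end 1-3 pair
  # allocation regions partition all reachable cells
  alloc <- attr(pairs, "allocation")$values
  expect_true(all(!is.na(alloc)))
  # two patches: exactly one candidate pair
  v2 <- matrix(0, 4, 10); v2[2:3, 1:2] <- 1; v2[2:3, 9:10] <- 1
  c2 <- extract_cores(rf_raster(v2, cell_size = 1000), 0.5, 3)
  r2 <- rf_raster(matrix(1, 4, 10), cell_size = 1000)
  cw2 <- lapply(1:2, function(i) cost_weighted_distance(r2, i, c2))
  expect_equal(nrow(adjacency_network(c2, cw2)), 1)
  expect_equal(nrow(adjacency_network(
    extract_cores(rf_raster(v2 * c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)[col(v2)],
                            cell_size = 1000), 0.5, 3),
    cw2[1])), 0)
})

test_that("least-cost links follow straight chains on uniform resistance", {
  w <- strip_world()
  pairs <- adjacency_network(w$cores, w$cwd)
  net <- least_cost_paths(w$res, pairs, w$cores, w$cwd)
  expect_equal(nrow(net$links), 2)
  # patch edges at cols 3 and 10: seven unit moves at resistance 1, 1-km cells
  expect_equal(net$links$cwd, c(7, 7))
  expect_equal(net$summary$mean_cwd, 7)
  expect_false(any(net$links$dropped))
})

test_that("corridors forced through a third patch are dropped", {
  # patches A (west), B (east), C (centre); a high-resistance wall above and
  # below C forces the A-B corridor through C
  v <- matrix(0, 5, 15)
  v[2:4, 1:2] <- 1; v[2:4, 14:15] <- 1; v[2:4, 7:9] <- 1
  suit <- rf_raster(v, cell_size = 1000)
  cores <- extract_cores(suit, threshold = 0.5, min_area_km2 = 5)
  res_v <- matrix(1, 5, 15)
  res_v[c(1, 5), 3:13] <- 1000
  res <- rf_raster(res_v, cell_size = 1000)
  cwd <- lapply(cores$patches$patch_id, function(i)
    cost_weighted_distance(res, i, cores))
  # force the A-B pair: its least-cost path must run through C
  ord <- order(cores$patches$centroid_x)
  pairs <- data.frame(patch_a = ord[1], patch_b = ord[3])
  net <- least_cost_paths(res, pairs, cores, cwd)
  expect_true(net$links$dropped[1])
  # dropped links are excluded from the summary
  expect_equal(net$summary$n_links, 0)
})
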