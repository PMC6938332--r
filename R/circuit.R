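#' Fill conductance outside the study area
#'
#' Ground-ring nodes extend beyond the modelled study area, so cells outside
#' it still need conductance values: ocean cells take the minimum conductance
#' observed inside the study area (large soaring birds avoid crossing open
#' water) and terrestrial cells outside the study area take the median — a
#' constant surface for electrical flow rather than a movement prediction.
#'
#' @param conductance `rf_raster` of in-study conductance.
#' @param study_mask `rf_raster`, 1 = inside study area.
#' @param ocean_mask `rf_raster`, 1 = ocean.
#' @return `rf_raster` with every cell filled.
#' @export
fill_outside <- function(conductance, study_mask, ocean_mask) {
  stop_if_misaligned(conductance, study_mask)
  stop_if_misaligned(conductance, ocean_mask)
  inside <- study_mask$values == 1 & ocean_mask$values != 1
  if (!any(inside, na.rm = TRUE)) stop("empty study area")
  vals <- conductance$values[inside]
  vals <- vals[!is.na(vals)]
  out <- conductance
  ocean <- ocean_mask$values == 1
  outside_land <- !ocean & !(study_mask$values == 1)
  out$values[ocean] <- min(vals)
  out$values[outside_land] <- median(vals)
  out
}

#' Build a resistor lattice from a conductance raster
#'
#' Each land (non-nodata) cell is a node; 8-neighbour edges carry the mean of
#' the two cell conductances, divided by sqrt(2) for diagonal edges (the
#' average-conductance lattice convention).
#'
#' @param conductance `rf_raster`, positive on land cells, `NA` = excluded.
#' @param neighborhood 8 (default) or 4.
#' @return list of class `circuit_graph`: `nodes` (row/col per node),
#'   `node_index` matrix, `edges` (from, to, conductance), `component` id per
#'   node, and the source raster geometry.
#' @export
raster_to_graph <- function(conductance, neighborhood = 8) {
  stopifnot(neighborhood %in% c(4, 8))
  v <- conductance$values
  land <- !is.na(v)
  if (!any(land)) stop("all-nodata raster")
  if (any(v[land] <= 0)) stop("conductance must be positive on land cells")
  nr <- nrow(v); nc <- ncol(v)
  node_index <- matrix(NA_integer_, nr, nc)
  node_index[land] <- seq_len(sum(land))
  idx <- which(land, arr.ind = TRUE)
  ord <- order(node_index[land])
  nodes <- data.frame(row = idx[, 1][ord], col = idx[, 2][ord])

  offs <- list(c(0, 1, 1), c(1, 0, 1))
  if (neighborhood == 8) offs <- c(offs, list(c(1, 1, sqrt(2)), c(1, -1, sqrt(2))))
  from <- integer(0); to <- integer(0); g <- numeric(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; scale <- o[3]
    r1 <- seq_len(nr - dr); c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- node_index[r1, c1, drop = FALSE]
    b <- node_index[r1 + dr, c1 + dc, drop = FALSE]
    va <- v[r1, c1, drop = FALSE]; vb <- v[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    from <- c(from, a[ok]); to <- c(to, b[ok])
    g <- c(g, ((va[ok] + vb[ok]) / 2) / scale)
  }
  comp <- graph_components(nrow(nodes), from, to)
  structure(list(nodes = nodes, node_index = node_index,
                 edges = data.frame(from = from, to = to, conductance = g),
                 component = comp, geometry = conductance[c("xll", "yll", "cell_size", "crs")],
                 dim = c(nr, nc)),
            class = "circuit_graph")
}

# connected components via union-find with path compression
graph_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

# node id at a (row, col) cell
node_at <- function(graph, cell) {
  id <- graph$node_index[cell[1], cell[2]]
  if (is.na(id)) stop("cell (", cell[1], ",", cell[2], ") is not a graph node")
  id
}

# sparse graph Laplacian (conductance-weighted)
graph_laplacian <- function(graph) {
  e <- graph$edges
  n <- nrow(graph$nodes)
  A <- Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                            x = c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Solve one source-to-ground circuit
#'
#' Kirchhoff solve on the lattice: the ground node is tied to 0 V (directly,
#' or through `ground_resistance` ohms), `injection` amperes enter at the
#' source, and node voltages come from a sparse symmetric positive-definite
#' solve of the grounded Laplacian. Per-cell current is half the sum of
#' absolute currents on incident edges, so a pass-through cell in a series
#' chain reports the through-current; source and ground cells report the full
#' injected current.
#'
#' @param graph a `circuit_graph`.
#' @param source,ground cells as `c(row, col)`; must differ and share a
#'   component.
#' @param injection current injected at the source, amperes.
#' @param ground_resistance resistance (ohm) of the ground tie; 0 = direct.
#' @return `rf_raster` current map in amperes, with node voltages in
#'   `attr(, "voltages")` and the pair in `attr(, "provenance")`.
#' @export
solve_pair <- function(graph, source, ground, injection = 1,
                       ground_resistance = 0) {
  s <- node_at(graph, source); g <- node_at(graph, ground)
  if (s == g) stop("source and ground are the same cell")
  if (graph$component[s] != graph$component[g])
    stop(sprintf("source (component %d) and ground (component %d) are disconnected",
                 graph$component[s], graph$component[g]))
  L <- graph_laplacian(graph)
  n <- nrow(graph$nodes)
  b <- rep(0, n); b[s] <- injection
  if (ground_resistance > 0) {
    L[g, g] <- L[g, g] + 1 / ground_resistance
    v <- as.vector(Matrix::solve(Matrix::forceSymmetric(L), b))
  } else {
    keep <- setdiff(seq_len(n), g)
    v <- numeric(n)
    v[keep] <- as.vector(Matrix::solve(Matrix::forceSymmetric(L[keep, keep]),
                                       b[keep]))
  }
  e <- graph$edges
  edge_cur <- e$conductance * (v[e$from] - v[e$to])
  cur <- numeric(n)
  acc <- tapply(abs(edge_cur), e$from, sum)
  cur[as.integer(names(acc))] <- cur[as.integer(names(acc))] + acc
  acc <- tapply(abs(edge_cur), e$to, sum)
  cur[as.integer(names(acc))] <- cur[as.integer(names(acc))] + acc
  cur <- cur / 2
  cur[c(s, g)] <- injection

  vals <- matrix(NA_real_, graph$dim[1], graph$dim[2])
  vals[cbind(graph$nodes$row, graph$nodes$col)] <- cur
  out <- rf_raster(vals, xll = graph$geometry$xll, yll = graph$geometry$yll,
                   cell_size = graph$geometry$cell_size, crs = graph$geometry$crs)
  attr(out, "voltages") <- v
  attr(out, "provenance") <- list(source = source, ground = ground,
                                  injection = injection)
  out
}

#' Effective resistance between two cells
#'
#' Voltage difference per unit injected current between `a` and `b`.
#'
#' @param graph a `circuit_graph`.
#' @param a,b cells as `c(row, col)`.
#' @return Scalar resistance (ohm).
#' @export
effective_resistance <- function(graph, a, b) {
  m <- solve_pair(graph, a, b, injection = 1)
  v <- attr(m, "voltages")
  v[node_at(graph, a)] - v[node_at(graph, b)]
}

#' Direction-neutral mean current map in milliamps
#'
#' Cellwise arithmetic mean of per-pair current maps, converted from amperes
#' to milliamps (x 1,000): averaging over all source-ground pairs removes the
#' directional bias of any single ground placement.
#'
#' @param maps list of aligned current `rf_raster`s in amperes.
#' @return `rf_raster` in mA, with the number of maps averaged in
#'   `attr(, "n_maps")`.
#' @export
mean_current <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (m in maps) {
    stop_if_misaligned(ref, m, "current maps")
    acc <- acc + m$values
  }
  out <- ref
  out$values <- 1000 * acc / length(maps)
  attr(out, "n_maps") <- length(maps)
  out
}

#' Cellwise maximum of two current maps
#'
#' Used for the post-hoc attractant overlay: the ring-based map and a
#' pairwise source-to-attractant map are combined by taking the maximum of
#' the two surfaces.
#'
#' @param map_a,map_b aligned `rf_raster`s.
#' @return `rf_raster` of cellwise maxima.
#' @export
combine_max <- function(map_a, map_b) {
  stop_if_misaligned(map_a, map_b, "current maps")
  out <- map_a
  out$values <- pmax(map_a$values, map_b$values)
  out
}

# ---- ground-ring geometry ---------------------------------------------------

# angular intervals (list of c(lo, hi), 0..2pi, possibly wrapped) of circle i
# covered by disk j; NULL if untouched, "all" if fully covered
arc_covered <- function(ci, ri, cj, rj) {
  d <- sqrt(sum((cj - ci)^2))
  if (d >= ri + rj) return(NULL)
  if (d + ri <= rj) return("all")
  if (d + rj <= ri) return(NULL)
  phi <- atan2(cj[2] - ci[2], cj[1] - ci[1])
  alpha <- acos((d^2 + ri^2 - rj^2) / (2 * d * ri))
  c(phi - alpha, phi + alpha)
}

# subtract wrapped intervals from [0, 2pi); returns matrix of kept (lo, hi)
subtract_arcs <- function(covered) {
  norm <- list()
  for (iv in covered) {
    lo <- iv[1] %% (2 * pi); hi <- iv[2] %% (2 * pi)
    if (lo <= hi) norm[[length(norm) + 1]] <- c(lo, hi)
    else { norm[[length(norm) + 1]] <- c(lo, 2 * pi)
           norm[[length(norm) + 1]] <- c(0, hi) }
  }
  if (!length(norm)) return(matrix(c(0, 2 * pi), 1))
  iv <- do.call(rbind, norm)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  # merge overlaps
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[k, 1] <= merged[last, 2]) merged[last, 2] <- max(merged[last, 2], iv[k, 2])
    else merged <- rbind(merged, iv[k, ])
  }
  kept <- NULL
  cur <- 0
  for (k in seq_len(nrow(merged))) {
    if (merged[k, 1] > cur) kept <- rbind(kept, c(cur, merged[k, 1]))
    cur <- max(cur, merged[k, 2])
  }
  if (cur < 2 * pi) kept <- rbind(kept, c(cur, 2 * pi))
  if (is.null(kept)) matrix(numeric(0), 0, 2) else kept
}

#' Place ground nodes along a buffer ring around release sites
#'
#' Builds the boundary of the union of per-site buffer disks exactly (circle
#' arcs clipped against the other disks), walks it counter-clockwise from the
#' easternmost point, and places nodes every `spacing_km` along the boundary;
#' the node count is `ceiling(perimeter / spacing)`. A single site with a
#' 350-km buffer and 10-km spacing yields `ceiling(2*pi*350/10) = 220` nodes.
#'
#' @param sites data.frame with `x`, `y` (m), one row per release site.
#' @param buffer_km buffer radius, km (default 350, the farthest observed
#'   displacement from a release site).
#' @param spacing_km node spacing along the ring, km (default 10).
#' @return data.frame `x`, `y` of ground-node coordinates (m), with the ring
#'   perimeter (m) in `attr(, "perimeter")`.
#' @export
place_ground_ring <- function(sites, buffer_km = 350, spacing_km = 10) {
  stopifnot(nrow(sites) >= 1)
  if (buffer_km <= 0) stop("buffer must be positive")
  r <- buffer_km * 1000; spacing <- spacing_km * 1000
  centres <- lapply(seq_len(nrow(sites)), function(i) c(sites$x[i], sites$y[i]))
  ns <- length(centres)

  # kept arcs per circle
  arcs <- list()   # each: list(circle, lo, hi)
  for (i in seq_len(ns)) {
    covered <- list()
    gone <- FALSE
    for (j in seq_len(ns)) {
      if (i == j) next
      cv <- arc_covered(centres[[i]], r, centres[[j]], r)
      if (identical(cv, "all")) { gone <- TRUE; break }
      if (!is.null(cv)) covered[[length(covered) + 1]] <- cv
    }
    if (gone) next
    kept <- subtract_arcs(covered)
    for (k in seq_len(nrow(kept)))
      if (kept[k, 2] - kept[k, 1] > 1e-12)
        arcs[[length(arcs) + 1]] <- list(circle = i, lo = kept[k, 1], hi = kept[k, 2])
  }
  if (!length(arcs)) stop("buffer disks cover each other entirely")
  pt_on <- function(a, t) centres[[a$circle]] + r * c(cos(t), sin(t))

  # walk arcs into closed loops by matching endpoints
  tol <- 1e-6 * r
  starts <- t(vapply(arcs, function(a) pt_on(a, a$lo), numeric(2)))
  used <- rep(FALSE, length(arcs))
  loops <- list()
  while (any(!used)) {
    # begin each loop at its easternmost arc start
    cand <- which(!used)
    first <- cand[which.max(vapply(cand, function(k) {
      a <- arcs[[k]]
      ts <- seq(a$lo, a$hi, length.out = 8)
      max(vapply(ts, function(t) pt_on(a, t)[1], numeric(1)))
    }, numeric(1)))]
    loop <- integer(0)
    cur <- first
    repeat {
      loop <- c(loop, cur); used[cur] <- TRUE
      endp <- pt_on(arcs[[cur]], arcs[[cur]]$hi)
      nxt <- which(!used & sqrt((starts[, 1] - endp[1])^2 +
                                  (starts[, 2] - endp[2])^2) < tol)
      if (!length(nxt)) break
      cur <- nxt[1]
    }
    loops[[length(loops) + 1]] <- loop
  }

  pts <- NULL; total_perim <- 0
  for (loop in loops) {
    lens <- vapply(loop, function(k) r * (arcs[[k]]$hi - arcs[[k]]$lo), numeric(1))
    perim <- sum(lens)
    total_perim <- total_perim + perim
    n_nodes <- ceiling(perim / spacing)
    if (spacing >= perim && length(loops) == 1)
      stop("spacing must be smaller than the ring perimeter")
    dists <- (seq_len(n_nodes) - 1) * spacing
    cum <- cumsum(c(0, lens))
    for (d in dists) {
      k <- findInterval(d, cum, rightmost.closed = TRUE)
      k <- min(k, length(loop))
      a <- arcs[[loop[k]]]
      t <- a$lo + (d - cum[k]) / r
      p <- pt_on(a, t)
      pts <- rbind(pts, p)
    }
  }
  out <- data.frame(x = pts[, 1], y = pts[, 2])
  attr(out, "perimeter") <- total_perim
  out
}

#' Solve all source-ground pairs and average
#'
#' Iterates one circuit solve per (source, ground) pair — each with the
#' single source active — and returns the unweighted mean of the individual
#' current maps in mA.
#'
#' @param graph a `circuit_graph`.
#' @param sources,grounds data.frames of cells with columns `row`, `col` (use
#'   [cells_from_xy()] to map coordinates).
#' @param injection amperes injected per solve.
#' @return Mean current `rf_raster` (mA), with the pair count in
#'   `attr(, "n_maps")`.
#' @export
solve_all_pairs <- function(graph, sources, grounds, injection = 1) {
  stopifnot(nrow(sources) >= 1, nrow(grounds) >= 1)
  maps <- list()
  for (i in seq_len(nrow(sources))) {
    for (j in seq_len(nrow(grounds))) {
      maps[[length(maps) + 1]] <- solve_pair(
        graph, c(sources$row[i], sources$col[i]),
        c(grounds$row[j], grounds$col[j]), injection)
    }
  }
  mean_current(maps)
}
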