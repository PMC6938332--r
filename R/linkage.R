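#' Resistance as the reciprocal of conductance
#'
#' @param surface conductance `rf_raster`, strictly positive where defined.
#' @return `rf_raster` of `1 / conductance`.
#' @export
resistance_from_conductance <- function(surface) {
  v <- surface$values
  if (any(v[!is.na(v)] <= 0))
    stop("zero or negative conductance: mask or floor these cells upstream")
  out <- surface
  out$values <- 1 / v
  out
}

#' Extract core habitat patches
#'
#' Binarises a suitability raster at `threshold` (cells >= threshold are
#' habitat), labels 8-connected components, and drops patches smaller than
#' `min_area_km2` (area = cell count x cell area). The defaults reproduce the
#' core-nesting-patch rule: threshold 0.04 on a logistic nesting-suitability
#' map, minimum patch size 10 km^2.
#'
#' @param suitability `rf_raster` with values in [0, 1].
#' @param threshold binarisation threshold (default 0.04).
#' @param min_area_km2 minimum patch area (default 10).
#' @return list of class `core_patches`: `label` (`rf_raster` of patch ids,
#'   `NA` elsewhere) and `patches` (data.frame with `patch_id`, `n_cells`,
#'   `area_km2`, `centroid_x`, `centroid_y`).
#' @export
extract_cores <- function(suitability, threshold = 0.04, min_area_km2 = 10) {
  v <- suitability$values
  bin <- !is.na(v) & v >= threshold
  lab <- label_components(bin)
  cell_area <- (suitability$cell_size / 1000)^2
  ids <- sort(unique(lab[!is.na(lab)]))
  keep <- ids[vapply(ids, function(i) sum(lab == i, na.rm = TRUE), numeric(1)) *
                cell_area >= min_area_km2]
  lab[!(lab %in% keep)] <- NA_integer_
  # renumber surviving patches 1..K
  lab <- matrix(match(lab, keep), nrow(v), ncol(v))
  out_label <- suitability
  out_label$values <- lab
  cc <- cell_centres(suitability)
  # cell_centres rows are in column-major cell order, so linear indices map 1:1
  patches <- do.call(rbind, lapply(seq_along(keep), function(i) {
    cells <- which(lab == i)
    data.frame(patch_id = i, n_cells = length(cells),
               area_km2 = length(cells) * cell_area,
               centroid_x = mean(cc$x[cells]),
               centroid_y = mean(cc$y[cells]))
  }))
  if (is.null(patches))
    patches <- data.frame(patch_id = integer(0), n_cells = integer(0),
                          area_km2 = numeric(0), centroid_x = numeric(0),
                          centroid_y = numeric(0))
  structure(list(label = out_label, patches = patches), class = "core_patches")
}

# 8-connected component labelling by flood fill (stack-based)
label_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  todo <- which(bin)
  for (start in todo) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- (cell - 1L) %% nr + 1L
      c0 <- (cell - 1L) %/% nr + 1L
      rs <- r0 + offs$dr; cs <- c0 + offs$dc
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      nb <- (cs[ok] - 1L) * nr + rs[ok]
      nb <- nb[bin[nb] & is.na(lab[nb])]
      if (length(nb)) {
        lab[nb] <- nxt
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Cost-weighted distance from a core patch
#'
#' Multi-source Dijkstra from every cell of the source patch (cost 0 inside
#' the patch): the move cost between adjacent cells is the mean of the two
#' cells' resistances times the centre-to-centre distance in km (x sqrt(2)
#' for diagonal moves). Unreachable cells get infinite cost.
#'
#' @param resistance `rf_raster`, finite positive; `NA` = impassable.
#' @param source_mask logical matrix (or `rf_raster`) marking source cells,
#'   or an integer patch id together with `label`.
#' @param label optional `core_patches` object when `source_mask` is a patch
#'   id.
#' @return list of class `cwd_result`: `cwd` (`rf_raster`, cost units) and
#'   `pred` (integer matrix of 1-based column-major predecessor indices).
#' @export
cost_weighted_distance <- function(resistance, source_mask, label = NULL) {
  if (is.numeric(source_mask) && length(source_mask) == 1 && !is.null(label))
    source_mask <- !is.na(label$label$values) & label$label$values == source_mask
  if (inherits(source_mask, "rf_raster")) source_mask <- source_mask$values == 1
  stopifnot(is.matrix(source_mask),
            all(dim(source_mask) == dim(resistance$values)))
  # distances in km: fold the cell size into the resistance scaling
  res_km <- resistance$values * (resistance$cell_size / 1000)
  r <- grid_dijkstra(res_km, source_mask)
  cwd <- resistance
  cwd$values <- r$cwd
  structure(list(cwd = cwd, pred = r$pred), class = "cwd_result")
}

#' Candidate patch pairs by cost-weighted network adjacency
#'
#' Allocates every reachable cell to its nearest patch in cost-weighted
#' distance terms; patch pairs whose allocation regions share an (8-neighbour)
#' boundary are candidate links. Distant pairs separated by an intervening
#' patch's allocation zone are excluded.
#'
#' @param cores a `core_patches` object (>= 2 patches).
#' @param cwd_list list of `cwd_result`, one per patch in patch order.
#' @return data.frame `patch_a`, `patch_b` (a < b); the allocation raster in
#'   `attr(, "allocation")`.
#' @export
adjacency_network <- function(cores, cwd_list) {
  k <- nrow(cores$patches)
  if (k < 2) {
    out <- data.frame(patch_a = integer(0), patch_b = integer(0))
    return(out)
  }
  stopifnot(length(cwd_list) == k)
  dims <- dim(cores$label$values)
  stacked <- vapply(cwd_list, function(r) as.vector(r$cwd$values),
                    numeric(prod(dims)))
  alloc <- apply(stacked, 1, function(d)
    if (all(!is.finite(d))) NA_integer_ else which.min(d))
  alloc <- matrix(as.integer(alloc), dims[1], dims[2])
  pairs <- matrix(FALSE, k, k)
  shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (s in shifts) {
    a <- shift_mat(alloc + 0, s[1], s[2])
    ok <- !is.na(alloc) & !is.na(a) & alloc != a
    if (any(ok)) {
      ij <- cbind(alloc[ok], a[ok])
      pairs[ij] <- TRUE
      pairs[ij[, c(2, 1), drop = FALSE]] <- TRUE
    }
  }
  idx <- which(pairs & upper.tri(pairs), arr.ind = TRUE)
  out <- data.frame(patch_a = idx[, 1], patch_b = idx[, 2])
  out <- out[order(out$patch_a, out$patch_b), , drop = FALSE]
  rownames(out) <- NULL
  alloc_r <- cores$label
  alloc_r$values <- alloc
  attr(out, "allocation") <- alloc_r
  out
}

# trace a path from a linear cell index back to a source via predecessors
trace_path <- function(cell, pred) {
  path <- cell
  while (pred[cell] != 0L) {
    cell <- pred[cell]
    path <- c(path, cell)
  }
  path
}

#' Least-cost-path linkage network
#'
#' For each candidate pair, finds the minimum cost-weighted path between the
#' two patches by combining their CWD surfaces (the optimal path passes
#' through the cell minimising `cwd_a + cwd_b` and is recovered from the two
#' predecessor grids). Links whose interior crosses a third patch are
#' dropped. Returns the network with per-link cost-weighted distance and
#' straight-line length and a summary (link count, mean CWD).
#'
#' @param resistance `rf_raster` used for the CWDs.
#' @param pairs data.frame from [adjacency_network()].
#' @param cores a `core_patches` object.
#' @param cwd_list list of `cwd_result` per patch (recomputed if `NULL`).
#' @return list of class `linkage_network`: `patches`, `links` (data.frame
#'   with `patch_a`, `patch_b`, `cwd`, `euclidean_km`, `dropped`), `paths`
#'   (list of row/col matrices), `summary`.
#' @export
least_cost_paths <- function(resistance, pairs, cores, cwd_list = NULL) {
  if (is.null(cwd_list))
    cwd_list <- lapply(cores$patches$patch_id, function(i)
      cost_weighted_distance(resistance, i, cores))
  nr <- nrow(resistance$values)
  lab <- cores$label$values
  links <- list(); paths <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$patch_a[i]; b <- pairs$patch_b[i]
    tot <- cwd_list[[a]]$cwd$values + cwd_list[[b]]$cwd$values
    if (all(!is.finite(tot))) {
      message("no finite path between patches ", a, " and ", b, "; skipped")
      next
    }
    m <- which.min(tot)
    cwd_ab <- tot[m]
    pa <- rev(trace_path(m, cwd_list[[a]]$pred))
    pb <- trace_path(m, cwd_list[[b]]$pred)
    cells <- c(pa, pb[-1])
    rows <- (cells - 1L) %% nr + 1L; cols <- (cells - 1L) %/% nr + 1L
    plab <- lab[cbind(rows, cols)]
    third <- !is.na(plab) & !(plab %in% c(a, b))
    dropped <- any(third)
    # euclidean length of the polyline
    xs <- resistance$xll + (cols - 0.5) * resistance$cell_size
    ys <- resistance$yll + (nr - rows + 0.5) * resistance$cell_size
    eu <- sum(sqrt(diff(xs)^2 + diff(ys)^2)) / 1000
    links[[length(links) + 1]] <- data.frame(
      patch_a = a, patch_b = b, cwd = cwd_ab, euclidean_km = eu,
      dropped = dropped)
    paths[[length(paths) + 1]] <- cbind(row = rows, col = cols)
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(patch_a = integer(0), patch_b = integer(0), cwd = numeric(0),
               euclidean_km = numeric(0), dropped = logical(0))
  kept <- links[!links$dropped, , drop = FALSE]
  structure(list(patches = cores$patches, links = links, paths = paths,
                 summary = list(n_links = nrow(kept),
                                mean_cwd = mean(kept$cwd))),
            class = "linkage_network")
}

#' @export
print.linkage_network <- function(x, ...) {
  cat(sprintf("linkage_network: %d patches, %d links (mean CWD %.1f), %d dropped\n",
              nrow(x$patches), x$summary$n_links, x$summary$mean_cwd,
              sum(x$links$dropped)))
  invisible(x)
}
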