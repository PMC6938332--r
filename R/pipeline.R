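#' Pipeline configuration
#'
#' Houses every scalar default of the analysis: the 2.78-30.0 m/s flight
#' window, 5-km release-site exclusions, 10-km hull buffer, 10,000 background
#' points, the 0.70 Spearman collinearity screen, 5 cross-validation folds
#' and 5,000 optimiser iterations, the ground-ring geometry, the 300-km
#' evaluation limit and 1-mA attenuation bins, and the 0.04 / 10-km^2 core
#' patch rule. `ring_buffer_km` defaults to 40 km to match the synthetic
#' landscape extent; the full-scale geometry (350 km) is a matter of passing
#' the larger value with a correspondingly larger grid.
#'
#' @param synthetic a [synthetic_config()].
#' @param filter a [filter_config()].
#' @param settings a [maxent_settings()].
#' @param candidates named list of covariate-name vectors, the candidate
#'   models compared by cross-validated AIC; `NULL` = nested defaults built
#'   from the retained covariates at run time.
#' @param ring_buffer_km,ring_spacing_km ground-ring geometry (km).
#' @param injection_A injected current per solve (amperes).
#' @param eval_max_km evaluation radius around release sites (km).
#' @param attenuation_bin_mA reverse-cumulative bin width (mA).
#' @param core_threshold,core_min_area_km2 core-patch extraction rule.
#' @param nesting_slope,nesting_offset logit-scale link from the habitat
#'   covariate to the synthetic nesting-suitability map.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            filter = filter_config(),
                            settings = maxent_settings(),
                            candidates = NULL,
                            ring_buffer_km = 40, ring_spacing_km = 10,
                            injection_A = 1,
                            eval_max_km = 300, attenuation_bin_mA = 1,
                            core_threshold = 0.04, core_min_area_km2 = 10,
                            nesting_slope = 3, nesting_offset = -6.4,
                            out_dir = NULL, seed = 42) {
  synthetic$seed <- seed
  filter$seed <- seed + 1L
  structure(as.list(environment()), class = "pipeline_config")
}

# minimal GeoJSON writers (no sf in this stack); coordinates in the shared
# projected CRS
write_points_geojson <- function(df, path, properties = NULL) {
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- if (is.null(properties)) setNames(list(), character(0)) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_lines_geojson <- function(paths_xy, props, path) {
  feats <- lapply(seq_along(paths_xy), function(i) {
    list(type = "Feature", properties = as.list(props[i, , drop = FALSE]),
         geometry = list(type = "LineString",
                         coordinates = unname(as.matrix(paths_xy[[i]]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> filter -> background -> covariates -> fit/select ->
#' project -> fill -> circuit -> calibrate -> linkage in order, writing each
#' stage's outputs (when `out_dir` is set) before the next begins, and
#' returns a run manifest with per-stage record counts that reconcile across
#' filters. The same seed reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines?
#' @return list of class `run_manifest`; the stage objects themselves are in
#'   `$objects` (landscape, surfaces, current map, curves, network).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  save_asc <- function(r, nm) if (!is.null(out)) write_asc(r, file.path(out, nm))

  ## simulate ---------------------------------------------------------------
  syn <- config$synthetic
  land <- generate_landscape(syn)
  truth <- true_conductance(land, syn$true_coefficients)
  nr <- syn$grid_rows; nc <- syn$grid_cols; cs <- syn$cell_size
  site <- release_site("release", x = (nc / 2) * cs, y = (nr / 2) * cs,
                       exclusion_radius = config$filter$exclusion_radius_km * 1000)
  raw <- simulate_telemetry(truth, site, syn, ocean = land$ocean)
  log_line("simulate: %d raw fixes over %dx%d grid", nrow(raw), nr, nc)
  for (nm in names(land$covariates))
    save_asc(land$covariates[[nm]], paste0("covariate_", nm, ".asc"))
  save_asc(land$dem, "dem.asc"); save_asc(land$ocean, "ocean_mask.asc")
  save_asc(truth, "true_conductance.asc")
  if (!is.null(out)) write_telemetry_csv(raw, file.path(out, "telemetry_raw.csv"))

  ## filter -----------------------------------------------------------------
  fc <- config$filter
  flight <- filter_flight_points(raw, fc)
  zoned <- exclude_zones(flight, site, land$ocean, fc)
  moves <- thin_daily(zoned, fc)
  counts <- list(raw = nrow(raw),
                 removed_speed_or_proof = unname(sum(attr(flight, "removed"))),
                 removed_zones = unname(sum(attr(zoned, "removed"))),
                 after_filters = nrow(zoned), movement_points = nrow(moves))
  log_line("filter: %d raw -> %d flight -> %d zoned -> %d daily-thinned",
           counts$raw, nrow(flight), nrow(zoned), nrow(moves))
  if (!is.null(out)) write_telemetry_csv(moves, file.path(out, "movement_points.csv"))

  ## background -------------------------------------------------------------
  bg <- build_background(moves, site, land$ocean, fc)
  log_line("background: %d points in the buffered movement hull", nrow(bg))
  if (!is.null(out)) write_points_geojson(bg, file.path(out, "background.geojson"))

  ## covariates -------------------------------------------------------------
  derived <- c(land$covariates,
               list(slope = slope(land$dem),
                    ruggedness = terrain_ruggedness(land$dem, radius_km = 10),
                    habitat_density = focal_statistic(
                      land$covariates$habitat, radius_km = 10, stat = "mean")))
  stack <- covariate_stack(derived, dem = land$dem, ocean = land$ocean)
  retained <- screen_collinearity(stack, moves, threshold = 0.70)
  log_line("covariates: %d of %d retained after |rs| > 0.70 screen",
           length(retained), length(derived))
  stack$covariates <- stack$covariates[retained]

  ## fit / select -----------------------------------------------------------
  candidates <- config$candidates
  if (is.null(candidates)) {
    r <- as.character(retained)
    candidates <- setNames(lapply(seq_along(r), function(k) r[seq_len(k)]),
                           paste0("model", seq_along(r)))
    candidates <- rev(candidates)   # full model first
  }
  evals <- lapply(candidates, function(cv_names)
    crossvalidate(moves, bg, stack, k = 5, settings = config$settings,
                  seed = config$seed + 11L, covariate_names = cv_names))
  best <- select_model(evals)
  model <- fit_maxent(moves, bg, stack, config$settings,
                      covariate_names = candidates[[best]])
  contrib <- percent_contribution(model)
  log_line("fit: selected %s (mean AIC %.1f, mean AUC %.3f)", best,
           evals[[best]]$mean_aic, evals[[best]]$mean_auc)

  ## project + fill ---------------------------------------------------------
  conductance <- predict_logistic(model, stack)
  save_asc(conductance, "conductance_fitted.asc")
  cc <- cell_centres(conductance)
  d_site <- matrix(sqrt((cc$x - site$x)^2 + (cc$y - site$y)^2), nr, nc)
  study <- conductance; study$values <- (d_site <= config$ring_buffer_km * 1000) * 1
  filled <- fill_outside(conductance, study, land$ocean)
  save_asc(filled, "conductance_filled.asc")

  ## circuit ----------------------------------------------------------------
  ring <- place_ground_ring(site, config$ring_buffer_km, config$ring_spacing_km)
  ring_cells <- unique(cells_from_xy(filled, ring$x, ring$y))
  ring_cells <- ring_cells[!is.na(ring_cells$row), , drop = FALSE]
  graph <- raster_to_graph(filled)
  src_cell <- cells_from_xy(filled, site$x, site$y)
  current <- solve_all_pairs(graph, src_cell, ring_cells,
                             injection = config$injection_A)
  log_line("circuit: %d source-ground connections averaged", attr(current, "n_maps"))
  save_asc(current, "current_mean_mA.asc")
  if (!is.null(out)) write_points_geojson(ring, file.path(out, "ground_ring.geojson"))

  ## calibrate --------------------------------------------------------------
  vals <- extract_at_points(current, moves, site, config$eval_max_km)
  # expected distribution: land cells of the evaluation region, excluding the
  # release-site exclusion disk — movement points cannot occur there, and the
  # background sample excludes it for the same reason
  in_eval <- d_site <= config$eval_max_km * 1000 & land$ocean$values != 1 &
    d_site > site$exclusion_radius
  pe <- boyce_continuous(vals, current$values[in_eval])
  att <- reverse_cumulative(vals, config$attenuation_bin_mA)
  log_line("calibrate: Boyce index %.3f over %d movement points",
           pe$boyce_index, pe$n_points)
  if (!is.null(out)) {
    write.csv(data.frame(window_centre = pe$centre,
                         window_centre_mA = pe$centre_value,
                         pe_ratio = pe$pe),
              file.path(out, "pe_curve.csv"), row.names = FALSE)
    write.csv(att, file.path(out, "reverse_cumulative.csv"), row.names = FALSE)
  }

  ## linkage ----------------------------------------------------------------
  suit <- land$covariates$habitat
  suit$values <- stats::plogis(config$nesting_slope * suit$values +
                                 config$nesting_offset)
  suit$values[land$ocean$values == 1] <- 0
  cores <- extract_cores(suit, config$core_threshold, config$core_min_area_km2)
  network <- NULL
  if (nrow(cores$patches) >= 2) {
    resistance <- resistance_from_conductance(filled)
    cwd_list <- lapply(cores$patches$patch_id, function(i)
      cost_weighted_distance(resistance, i, cores))
    pairs <- adjacency_network(cores, cwd_list)
    network <- least_cost_paths(resistance, pairs, cores, cwd_list)
    log_line("linkage: %d patches, %d links, mean CWD %.1f",
             nrow(cores$patches), network$summary$n_links,
             network$summary$mean_cwd)
    if (!is.null(out)) {
      paths_xy <- lapply(network$paths, function(p)
        data.frame(x = filled$xll + (p[, "col"] - 0.5) * filled$cell_size,
                   y = filled$yll + (nr - p[, "row"] + 0.5) * filled$cell_size))
      write_lines_geojson(paths_xy, network$links,
                          file.path(out, "linkages.geojson"))
      write_points_geojson(
        data.frame(x = cores$patches$centroid_x, y = cores$patches$centroid_y),
        file.path(out, "core_patches.geojson"), cores$patches)
    }
  } else {
    log_line("linkage: fewer than two core patches; network skipped")
  }

  manifest <- structure(list(
    seed = config$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    package_version = as.character(utils::packageVersion("releaseflow")),
    counts = counts,
    removed = list(flight = attr(flight, "removed"),
                   zones = attr(zoned, "removed")),
    n_background = nrow(bg),
    retained_covariates = as.character(retained),
    selected_model = best,
    candidate_aic = sapply(evals, function(e) e$mean_aic),
    mean_auc = evals[[best]]$mean_auc,
    percent_contribution = contrib,
    n_ground_nodes = nrow(ring_cells),
    n_connections = attr(current, "n_maps"),
    boyce_index = pe$boyce_index,
    frac_ge_2mA = mean(vals >= 2),
    n_core_patches = nrow(cores$patches),
    n_links = if (is.null(network)) 0L else network$summary$n_links,
    mean_cwd = if (is.null(network)) NA_real_ else network$summary$mean_cwd,
    objects = list(landscape = land, truth = truth, site = site,
                   movement_points = moves, background = bg,
                   model = model, evaluations = evals,
                   conductance = conductance, filled = filled,
                   current = current, pe = pe, attenuation = att,
                   cores = cores, network = network)),
    class = "run_manifest")
  if (!is.null(out)) {
    m <- manifest; m$objects <- NULL
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("releaseflow run manifest\n")
  cat(sprintf("  %d raw fixes -> %d movement points; %d background\n",
              x$counts$raw, x$counts$movement_points, x$n_background))
  cat(sprintf("  model %s over {%s}; mean AUC %.3f\n", x$selected_model,
              paste(x$retained_covariates, collapse = ", "), x$mean_auc))
  cat(sprintf("  %d source-ground connections; Boyce %.3f; %.1f%% of points >= 2 mA\n",
              x$n_connections, x$boyce_index, 100 * x$frac_ge_2mA))
  cat(sprintf("  %d core patches, %d links, mean CWD %.1f\n",
              x$n_core_patches, x$n_links, x$mean_cwd))
  invisible(x)
}
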