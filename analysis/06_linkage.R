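# Stage 6: least-cost linkage network between core habitat patches.
# Builds a synthetic nesting-suitability map from the habitat covariate,
# extracts core patches (>= 0.04, >= 10 km^2), inverts conductance to
# resistance, and links adjacent patches by least-cost paths with
# cost-weighted distances.
source("analysis/00_config.R")

stack <- load_stack()
filled <- read_asc(res_path("conductance_filled.asc"))

suit <- stack$covariates$habitat
suit$values <- plogis(CFG$nesting_slope * suit$values + CFG$nesting_offset)
suit$values[stack$ocean$values == 1] <- 0
write_asc(suit, res_path("nesting_suitability_synthetic.asc"))

cores <- extract_cores(suit, CFG$core_threshold, CFG$core_min_area_km2)
resistance <- resistance_from_conductance(filled)
cwd <- lapply(cores$patches$patch_id, function(i)
  cost_weighted_distance(resistance, i, cores))
pairs <- adjacency_network(cores, cwd)
net <- least_cost_paths(resistance, pairs, cores, cwd)

write.csv(cores$patches, res_path("core_patches.csv"), row.names = FALSE)
write.csv(net$links, res_path("linkage_links.csv"), row.names = FALSE)
jsonlite::write_json(net$summary, res_path("linkage_summary.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf(
  "%d core patches (>= %g, >= %g km^2); %d links kept of %d candidates; mean CWD %.1f",
  nrow(cores$patches), CFG$core_threshold, CFG$core_min_area_km2,
  net$summary$n_links, nrow(net$links), net$summary$mean_cwd))
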