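# Shared configuration for the analysis drivers. The study conditions: a
# 101x101 km synthetic landscape at 1-km grain with an ocean strip on the
# west edge, one central release site, movement density decaying over 30 km,
# and a ground ring at 40 km (the full-scale 350-km geometry is exercised
# analytically in 04_circuit.R).
library(releaseflow)

SEED <- 42
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

CFG <- pipeline_config(out_dir = NULL, seed = SEED)
SITE <- release_site("release",
                     x = (CFG$synthetic$grid_cols / 2) * CFG$synthetic$cell_size,
                     y = (CFG$synthetic$grid_rows / 2) * CFG$synthetic$cell_size,
                     exclusion_radius = CFG$filter$exclusion_radius_km * 1000)

res_path <- function(...) file.path(RESULTS, ...)

load_stack <- function() {
  covs <- c("terrain", "habitat", "canopy")
  covariate_stack(
    covariates = setNames(lapply(covs, function(nm)
      read_asc(res_path(paste0("covariate_", nm, ".asc")))), covs),
    dem = read_asc(res_path("dem.asc")),
    ocean = read_asc(res_path("ocean_mask.asc")))
}
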