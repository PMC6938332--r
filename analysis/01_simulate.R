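# Stage 1: synthetic landscape and raw telemetry.
# Generates the covariate fields, the known-truth conductance surface and a
# raw GPS table with counted removal categories, and writes them under
# results/ for the downstream stages.
source("analysis/00_config.R")

syn <- CFG$synthetic
land <- generate_landscape(syn)
truth <- true_conductance(land, syn$true_coefficients)
tel <- simulate_telemetry(truth, SITE, syn, ocean = land$ocean)

for (nm in names(land$covariates))
  write_asc(land$covariates[[nm]], res_path(paste0("covariate_", nm, ".asc")))
write_asc(land$dem, res_path("dem.asc"))
write_asc(land$ocean, res_path("ocean_mask.asc"))
write_asc(truth, res_path("true_conductance.asc"))
write_telemetry_csv(tel, res_path("telemetry_raw.csv"))
write.csv(SITE, res_path("release_site.csv"), row.names = FALSE)

cts <- attr(tel, "category_counts")
write.csv(data.frame(category = names(cts), count = as.integer(cts)),
          res_path("telemetry_categories.csv"), row.names = FALSE)

message(sprintf(
  "simulated %d fixes on a %dx%d km landscape (conductance %.3f-%.3f);\n%s",
  nrow(tel), syn$grid_rows, syn$grid_cols,
  min(truth$values), max(truth$values),
  paste(sprintf("  %s: %d", names(cts), cts), collapse = "\n")))
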