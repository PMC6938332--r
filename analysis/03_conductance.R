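# Stage 3: the landscape conductance surface.
# Derives terrain covariates (Horn slope, surface-ratio ruggedness, 10-km
# focal habitat density), screens collinearity at |rs| > 0.70, compares
# nested candidate covariate sets by 5-fold cross-validated AIC, fits the
# winning maximum-entropy model and projects its logistic output.
source("analysis/00_config.R")

stack <- load_stack()
moves <- read_telemetry_csv(res_path("movement_points.csv"))
bg <- read.csv(res_path("background_points.csv"))

derived <- c(stack$covariates,
             list(slope = slope(stack$dem),
                  ruggedness = terrain_ruggedness(stack$dem, radius_km = 10),
                  habitat_density = focal_statistic(stack$covariates$habitat,
                                                    radius_km = 10, "mean")))
full <- covariate_stack(derived, dem = stack$dem, ocean = stack$ocean)
retained <- screen_collinearity(full, moves, threshold = 0.70)
full$covariates <- full$covariates[retained]
message("retained after collinearity screen: ",
        paste(retained, collapse = ", "))

r <- as.character(retained)
candidates <- rev(setNames(lapply(seq_along(r), function(k) r[seq_len(k)]),
                           paste0("model", seq_along(r))))
evals <- lapply(candidates, function(nms)
  crossvalidate(moves, bg, full, k = 5, settings = CFG$settings,
                seed = SEED + 11L, covariate_names = nms))
best <- select_model(evals)
model <- fit_maxent(moves, bg, full, CFG$settings,
                    covariate_names = candidates[[best]])

sel <- data.frame(
  candidate = names(evals),
  covariates = vapply(candidates, paste, "", collapse = "+"),
  mean_gain = vapply(evals, function(e) e$mean_gain, 0),
  mean_auc = vapply(evals, function(e) e$mean_auc, 0),
  mean_aic = vapply(evals, function(e) e$mean_aic, 0))
write.csv(sel, res_path("model_selection.csv"), row.names = FALSE)
contrib <- percent_contribution(model)
write.csv(data.frame(covariate = names(contrib), percent = as.numeric(contrib)),
          res_path("percent_contribution.csv"), row.names = FALSE)
write_maxent_json(model, res_path("conductance_model.json"))
write_asc(predict_logistic(model, full), res_path("conductance_fitted.asc"))

message(paste(capture.output(print(sel, row.names = FALSE)), collapse = "\n"))
message(sprintf("selected %s; leading contribution: %s (%.1f%%)",
                best, names(which.max(contrib)), max(contrib)))
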