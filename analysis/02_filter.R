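# Stage 2: occurrence filtering and background construction.
# Keeps proofed in-flight fixes (2.78-30 m/s, strict), drops offshore and
# near-release-site points, thins to one point per bird-day, and samples
# 10,000 background points in the 10-km-buffered convex hull.
source("analysis/00_config.R")

tel <- read_telemetry_csv(res_path("telemetry_raw.csv"))
ocean <- read_asc(res_path("ocean_mask.asc"))

flight <- filter_flight_points(tel, CFG$filter)
zoned <- exclude_zones(flight, SITE, ocean, CFG$filter)
moves <- thin_daily(zoned, CFG$filter)
bg <- build_background(moves, SITE, ocean, CFG$filter)

write_telemetry_csv(moves, res_path("movement_points.csv"))
write.csv(bg, res_path("background_points.csv"), row.names = FALSE)

counts <- rbind(
  data.frame(stage = "raw", n = nrow(tel)),
  data.frame(stage = "flight (proofed, in speed window)", n = nrow(flight)),
  data.frame(stage = "after offshore/near-site removal", n = nrow(zoned)),
  data.frame(stage = "daily-thinned movement points", n = nrow(moves)),
  data.frame(stage = "background points", n = nrow(bg)))
write.csv(counts, res_path("filter_counts.csv"), row.names = FALSE)

message(paste(capture.output(print(counts, row.names = FALSE)), collapse = "\n"))
message(sprintf("removed: %s | %s",
                paste(names(attr(flight, "removed")),
                      attr(flight, "removed"), collapse = ", "),
                paste(names(attr(zoned, "removed")),
                      attr(zoned, "removed"), collapse = ", ")))
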