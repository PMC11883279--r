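#!/usr/bin/env Rscript

# Step 2: read the exported cohort back through the track-file interface
# and compute the per-jump kinematic panel.
#
# Event detection uses the documented defaults (onset k = 3, persist 5,
# 50-frame baseline; lift-off height 0.05 mm, persist 3). Positions are
# smoothed with a 9-frame centered window before differentiation: at
# 0.2 ms intervals raw double-differencing amplifies 2 um jitter into
# hundreds of m/s^2, and the 9-frame window keeps the peak-acceleration
# bias near 3% on synthetic data.

library(saltijump)

raw <- "scratch/cohort"
metas <- sort(Sys.glob(file.path(raw, "*_meta.txt")))
if (length(metas) == 0) stop("run analysis/01_simulate.R first")

trials <- lapply(metas, function(mf) {
  got <- read_trial_meta(mf)
  read_tracks_csv(sub("_meta\\.txt$", "_tracks.csv", mf), got$meta,
                  platform_y_px = got$platform_y_px)
})

cfg <- run_config(smooth_window = 9L, seed = 20)
out <- run_analyze(trials, out_dir = "results", config = cfg)

cat(sprintf("analyzed %d/%d jumps (%d failures)\n",
            nrow(out$results), length(trials), nrow(out$failures)))
cat("sex means of the recovered panel:\n")
agg <- aggregate(cbind(takeoff_duration_ms, takeoff_velocity_m_per_s,
                       peak_acceleration_m_per_s2, g_force,
                       takeoff_angle_deg) ~ sex, out$results, mean)
print(agg, digits = 4)
cat("tables written to results/results.csv, chronology.csv, events.csv\n")
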