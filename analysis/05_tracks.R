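# Comet-track post-analysis: bend-based splitting (30 degree rule),
# growth/pause event classification, per-cell dynamics and the
# four-speed-group distribution under the fastest-cell vmax rule.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- analysis_config("tracks")
suppressWarnings(run_pipeline(cfg, run_dir()))

treatments <- read_out("treatments_summary.csv")
sg <- read_out("speed_groups.csv")
for (i in seq_len(nrow(treatments))) {
  t <- treatments[i, ]
  cat(sprintf(
    "%s: growth speed %.1f um/min, growth length %.2f um, pausing %.0f%% of events (%.0f%% of time), n = %d cells\n",
    t$treatment, t$mean_growth_speed_um_min, t$mean_growth_length_um,
    t$pct_events_pause, t$pct_time_pause, t$n_cells))
}
cat(sprintf("vmax (fastest cell mean + 1 SD): %.2f um/min\n", sg$vmax[1]))
for (tr in unique(sg$treatment)) {
  s <- sg[sg$treatment == tr, ]
  cat(sprintf("  %s speed groups: %s\n", tr,
              paste(sprintf("%s %.0f%%", s$group, s$percentage),
                    collapse = ", ")))
}
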