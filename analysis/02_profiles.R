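# Junction-normal intensity profiles (21 readings over 2 um) for both
# arms, per-profile peaks, and the treated-vs-control relative peak
# change — the readout used for junctional protein reductions.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- analysis_config("profiles")
suppressWarnings(run_pipeline(cfg, run_dir()))

peaks <- read_out("peaks.csv")
chg <- read_out("peak_change.csv")
n <- table(peaks$group)
cat(sprintf("profiles: %s\n",
            paste(sprintf("%s n=%d", names(n), n), collapse = ", ")))
cat(sprintf("relative peak ratio treated/control: %.3f\n", chg$ratio))
cat(sprintf("measured junctional reduction: %.1f%% (true enrichment ratio %.2f)\n",
            chg$percent_reduction,
            cfg$puncta$arms$treated / cfg$puncta$arms$control))
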