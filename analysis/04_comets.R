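# Fixed-image comet detection (background subtraction, Otsu threshold,
# 0.2-1.2 um^2 area gate) and counts per 10 x 10 um box, checked against
# the simulation ground truth.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- analysis_config("comets")
suppressWarnings(run_pipeline(cfg, run_dir()))

det <- read_out("detections.csv")
counts <- read_out("comet_counts.csv")
truth <- read_out("comet_truth.csv")
m <- match_detections(det, truth)
cat(sprintf("detections: %d (truth %d); precision %.2f, recall %.2f\n",
            nrow(det), nrow(truth), m$precision, m$recall))
cat(sprintf("comets per 10x10 um box: mean %.1f, range %d-%d\n",
            mean(counts$n_comets), min(counts$n_comets),
            max(counts$n_comets)))
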