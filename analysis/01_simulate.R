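# Generate the synthetic study data: a junction mosaic, cortical puncta
# for a control and a treated arm (junctional enrichment halved), a
# filament field approaching junctions around 70 degrees, a comet frame
# and two-state comet tracks for both arms. All ground truth is written
# alongside the rendered images.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- analysis_config("simulate")
suppressWarnings(run_pipeline(cfg, run_dir()))

junctions <- read_out("junctions.csv")
truth_f <- read_out("filament_truth.csv")
truth_c <- read_out("comet_truth.csv")
cat(sprintf("mosaic: %d junction edges\n", length(unique(junctions$path_id))))
cat(sprintf("filaments: %d, ground-truth approach angle mean %.1f deg\n",
            nrow(truth_f), mean(truth_f$angle_truth)))
cat(sprintf("comets: %d spots, areas %.2f-%.2f um^2\n", nrow(truth_c),
            min(truth_c$area_um2), max(truth_c$area_um2)))
cat("wrote images + truth tables to", run_dir(), "\n")
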