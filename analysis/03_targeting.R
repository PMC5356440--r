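# Microtubule cortical targeting: perpendicular-approach percentage in
# 10 x 10 um cortical boxes, contacts per 10 um of junction, and the
# structure-tensor orientation of the filament texture relative to each
# junction.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- analysis_config("targeting")
suppressWarnings(run_pipeline(cfg, run_dir()))

boxes <- read_out("perpendicular_boxes.csv")
contacts <- read_out("contacts.csv")
orient <- read_out("orientation.csv")
def <- boxes[boxes$defined, ]
cat(sprintf("perpendicular approach (45-90 deg): %.1f%% mean over %d boxes\n",
            mean(def$pct_perpendicular), nrow(def)))
cat(sprintf("contacts: %.2f per 10 um of junction (mean over %d junctions)\n",
            mean(contacts$contacts_per_10um), nrow(contacts)))
okor <- orient[orient$defined, ]
cat(sprintf("texture orientation to junction: %.1f deg mean, anisotropy %.2f\n",
            mean(okor$angle_to_junction_deg), mean(okor$anisotropy)))
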