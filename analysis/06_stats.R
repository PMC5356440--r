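# Group statistics on the measured junctional peaks: the normality-routed
# decision tree (D'Agostino-Pearson, then t-test/ANOVA or Mann-Whitney/
# Kruskal-Wallis + Dunn) with its full decision trace.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- analysis_config("stats")
suppressWarnings(run_pipeline(cfg, run_dir()))

cmp <- read_out("comparison.csv")
trace <- readLines(file.path(run_dir(), "comparison_trace.txt"))
cat("decision trace:\n")
for (ln in trace) cat("  -", ln, "\n")
cat(sprintf("selected test: %s, p = %.3g\n", cmp$test, cmp$p_value))
peaks <- read_out("peaks.csv")
pc <- percent_change(peaks$peak[peaks$group == "control"],
                     peaks$peak[peaks$group == "treated"])
cat(sprintf("junctional peak change: %s\n", pc$formatted))
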