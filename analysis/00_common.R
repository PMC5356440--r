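# Shared setup for the analysis scripts: locate the config, the run
# directory, and allow `Rscript analysis/0X_*.R [seed]` to override the
# seed.
library(cortexmt)

analysis_config <- function(stages) {
  root <- if (dir.exists("analysis")) "." else ".."
  cfg <- validate_config(file.path(root, "analysis", "config.yaml"))
  args <- commandArgs(trailingOnly = TRUE)
  if (length(args) >= 1) cfg$seed <- as.integer(args[[1]])
  cfg$stages <- stages
  cfg
}

run_dir <- function() {
  root <- if (dir.exists("analysis")) "." else ".."
  d <- file.path(root, "results", "run")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

read_out <- function(name) {
  readr::read_csv(file.path(run_dir(), name), show_col_types = FALSE)
}
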