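#!/usr/bin/env Rscript
# Thin command-line wrapper over dpcrval::run_pipeline().
# Usage:
#   scripts/dpcrval <stage ...> [--config <file.R>] [--seed <int>]
#                   [--out <dir>] [--overwrite]
# Stages: simulate quantify gm_content validate robustness report
# --config names an R file that evaluates to a dpcrval::run_config() object;
# without it the default configuration is used.

suppressPackageStartupMessages(library(dpcrval))

args <- commandArgs(trailingOnly = TRUE)
stages <- character()
config_file <- NULL
seed <- NULL
out <- "."
overwrite <- FALSE
i <- 1L
while (i <= length(args)) {
  a <- args[i]
  if (a == "--config") { config_file <- args[i + 1L]; i <- i + 2L }
  else if (a == "--seed") { seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (a == "--out") { out <- args[i + 1L]; i <- i + 2L }
  else if (a == "--overwrite") { overwrite <- TRUE; i <- i + 1L }
  else { stages <- c(stages, gsub("-", "_", a)); i <- i + 1L }
}
if (!length(stages)) {
  stages <- c("simulate", "quantify", "gm_content", "validate",
              "robustness", "report")
}

cfg <- if (!is.null(config_file)) {
  eval(parse(config_file))
} else {
  run_config()
}
if (!is.null(seed)) {
  cfg$seed <- seed
  cfg$design$seed <- seed
}

status <- tryCatch({
  paths <- run_pipeline(cfg, stages = stages, out_dir = out,
                        overwrite = overwrite)
  for (p in paths) cat("wrote", p, "\n")
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
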