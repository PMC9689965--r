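#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's demonstration pipeline.
#
# Usage: Rscript scripts/demo.R [--seed <int>] [--out <dir>]

suppressPackageStartupMessages(library(restalpha))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
seed <- as.integer(get_arg("--seed", "7"))
out <- get_arg("--out", file.path(tempdir(), paste0("restalpha_demo_", seed)))
res <- run_demo(seed = seed, out_dir = out)
cat("outputs in", out, "\n")
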