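#!/usr/bin/env Rscript
# Optional real-data hook: test-retest reliability of trainee confidence
# ratings from an externally deposited CSV (e.g. the Mendeley trainee
# dataset, https://data.mendeley.com/datasets/dxn9rhh9tf/2, not bundled).
# The deposited schema is not fixed, so the paired columns are named
# explicitly:
#
#   Rscript scripts/trainee_reliability.R --csv ratings.csv \
#       --initial-col conf_initial --retest-col conf_retest [--level 0.95]
#
# Prints Spearman's rho with a Fisher-z confidence interval. Note the
# interval method is tagged: published intervals computed by other methods
# (e.g. bootstrap) are not directly comparable.

suppressPackageStartupMessages(library(cliviplan))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(level = 0.95)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
for (req in c("csv", "initial-col", "retest-col"))
  if (is.null(opt[[req]])) stop("missing --", req)

pairs <- read_trainee_pairs(opt$csv, opt$`initial-col`, opt$`retest-col`)
print(spearman_rho_ci(pairs$initial, pairs$retest, as.numeric(opt$level)))
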