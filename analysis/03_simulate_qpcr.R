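#!/usr/bin/env Rscript
# Stage 3: synthesise the validation qPCR experiment.
#
# Three cell lines measured for aromatase (CYP19A1) after 24 h of
# treatment with a vehicle plus five doses spanning 0.1-1000 nM, in
# triplicate; one line also expresses the repressor DAX1. Effect profiles
# are saturating (rising through the low doses, flattening at the top),
# with per-line strengths chosen so one line responds strongly, one
# weakly and one barely - the spread a validation panel typically shows.

suppressPackageStartupMessages({
  library(cypnet)
  library(dplyr)
})
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

series <- list(
  list(cell_line = "HeLa", gene = "CYP19A1",
    effects = c(0, 0.8, 1.6, 2.2, 2.4, 2.5), seed_off = 1L),
  # DAX1 falls with dose in the responding line
  list(cell_line = "HeLa", gene = "DAX1",
    effects = c(0, -0.6, -1.2, -1.7, -1.9, -2.0), seed_off = 2L),
  list(cell_line = "JEG3", gene = "CYP19A1",
    effects = c(0, 0.15, 0.3, 0.45, 0.5, 0.5), seed_off = 3L),
  list(cell_line = "LNCaP", gene = "CYP19A1",
    effects = c(0, 0.05, 0.1, 0.15, 0.17, 0.17), seed_off = 4L)
)

datasets <- lapply(series, function(s) {
  generate_qpcr(qpcr_sim_config(
    log2_effects = s$effects, noise_sd = 0.25,
    cell_line = s$cell_line, gene = s$gene,
    seed = seed * 101L + s$seed_off
  ))
})
all <- expression_dataset(bind_rows(lapply(datasets, tibble::as_tibble)))

path <- file.path(out_dir, "qpcr_expression.tsv")
utils::write.table(as.data.frame(all), path,
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat("Simulated qPCR panel written to", path, "\n")
cat("  series:", length(series), " (cell line x gene), 6 doses x 3 replicates each\n")
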