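#!/usr/bin/env Rscript
# Stage 1: synthesise a curated-interaction database.
#
# We emulate a literature-curated two-layer pharmacology network: a few
# hundred compounds attached to a small panel of CYP regulators with
# strongly skewed hub weights (a handful of nuclear receptors collect most
# compound interactions), and the regulators wired to a panel of CYP
# enzymes. Three paths are planted for one retinoic-acid-like compound so
# the discovery stage has a known signal to find: via regulator R001 it
# should DOWN-regulate enzyme E001 (activation then inhibition), the
# classic repressor-in-the-middle motif.

suppressPackageStartupMessages(library(cypnet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out_dir <- file.path("results", "synthetic_db")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

planted <- data.frame(
  compound = c(1, 1, 1),
  regulator = c(1, 2, 3),
  enzyme = c(1, 2, 3),
  sign_cr = c(1L, 1L, -1L),
  sign_re = c(-1L, 1L, 1L)
)
cfg <- network_sim_config(
  n_compounds = 300, n_regulators = 15, n_enzymes = 10,
  mean_compound_degree = 3,
  # Zipf-like attachment weights: cluster sizes fall off steeply from the
  # top hub, as curated compound-regulator networks do
  hub_weights = 1 / seq_len(15),
  sign_probs = c(0.45, 0.45, 0.10),
  planted_paths = planted,
  seed = seed
)
db <- generate_interaction_db(cfg)

write_network(db$table, file.path(out_dir, "edges.tsv"), "tsv")
write_roles(db$table, file.path(out_dir, "roles.tsv"))
utils::write.table(
  as.data.frame(db$truth), file.path(out_dir, "planted_truth.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

cat("Synthetic curated database written to", out_dir, "\n")
cat("  records:", nrow(db$table$records), "\n")
cat("  entities:", nrow(db$table$entities),
  "(300 compounds, 15 regulators, 10 enzymes)\n")
cat("  planted compound-enzyme truths:\n")
print(as.data.frame(db$truth))
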