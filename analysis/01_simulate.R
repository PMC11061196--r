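#!/usr/bin/env Rscript
# Stage 1: draw the synthetic fertilizer-trial study.
#
# Generates the default study (870 taxa in three fertilizer-linked clusters,
# 14 soil chemicals, 6 plots x 5 stages x 4 replicate batches) and writes
# the replicate table, the plot trait table and the generator's ground truth
# under results/study/.  Set SEED to vary the draw (default 1).

suppressPackageStartupMessages(library(soilnet))

seed <- as.integer(Sys.getenv("SEED", "1"))
outdir <- "results/study"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

study <- generate_study(synthetic_config(seed = seed))

write_replicate_table(study$replicates, file.path(outdir, "replicates.tsv"))
write.table(study$traits, file.path(outdir, "traits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(cluster = as.list(study$truth$cluster),
       trait_taxa = study$truth$trait_taxa,
       trait_sign = as.list(study$truth$trait_sign),
       stage_assoc = as.list(study$truth$stage_assoc[
         !is.na(study$truth$stage_assoc)]),
       seed = seed),
  file.path(outdir, "truth.json"), auto_unbox = TRUE)

cv <- compute_cv(study$replicates)
cat(sprintf(
  "simulated study (seed %d): %d taxa + %d chemicals over %d samples\n",
  seed, sum(study$replicates$features$kind == "taxon"),
  sum(study$replicates$features$kind == "chemical"),
  nrow(study$replicates$samples)))
cat(sprintf("replicate CVs: taxa %.2f, chemicals %.2f\n",
            cv$by_kind["taxon"], cv$by_kind["chemical"]))
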