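#!/usr/bin/env Rscript
# Stage 2: replicate aggregation, filtering and standardization.
#
# Converts taxon counts to relative frequencies per replicate, collapses the
# four batches of every plot-stage cell to medians, drops taxa absent from
# all 30 cells, and z-scales every retained feature across the cells.

suppressPackageStartupMessages(library(soilnet))

rt <- read_replicate_table("results/study/replicates.tsv")
rel <- to_relative_frequency(rt)
mm <- filter_absent_features(aggregate_medians(rel))
removal <- attr(mm, "removal_report")
sm <- standardize_features(mm)

dir.create("results", showWarnings = FALSE)
write_matrix_tsv(mm, "results/median_matrix.tsv")
write_matrix_tsv(sm, "results/standardized_matrix.tsv")
cv <- compute_cv(rt)
write.table(data.frame(feature = names(cv$per_feature),
                       mean_cv = cv$per_feature),
            "results/cv_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ts <- taxonomy_summary(mm)
cat(sprintf("retained %d taxa (removed %d absent), %d chemicals\n",
            removal$n_retained, removal$n_removed,
            sum(mm$features$kind == "chemical")))
cat("distinct lineage labels:",
    paste(names(ts$rank_counts), ts$rank_counts, collapse = ", "), "\n")
cat("plot-specific taxa:",
    paste(names(ts$plot_specific_counts), ts$plot_specific_counts,
          collapse = ", "), "\n")
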