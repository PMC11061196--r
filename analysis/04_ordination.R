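#!/usr/bin/env Rscript
# Stage 4: community ordination, chemical vector fitting, and load-quantity
# contributor scoring on the third component.
#
# The community PCA runs on the standardized taxon rows (30 plot-stage cells
# as observations).  Chemicals are projected onto the PC1-PC2 plane by
# least-squares vector fitting with permutation p-values; the third
# component is scored by LQ3 = sqrt(l3) * h3i, z-standardized, and taxa with
# |z-LQ3| > 2.33 are flagged as trait-linked contributors.

suppressPackageStartupMessages(library(soilnet))

seed <- as.integer(Sys.getenv("SEED", "1"))
sm <- read_matrix_tsv("results/standardized_matrix.tsv", standardized = TRUE)
traits <- read.delim("results/study/traits.tsv")

pc <- community_pca(sm, kind = "taxon")
cat("proportion of variance:",
    paste(sprintf("PC%d %.1f%%", 1:4, 100 * pc$prop_var[1:4]),
          collapse = ", "), "\n")

cells <- sub("_[A-Z]$", "", rownames(pc$scores))
orient <- traits$seed_yield[match(cells, traits$plot)]
lq <- load_quantity(pc, axis = 3, orient = orient)
write.table(lq$table, "results/load_quantity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n_pos <- sum(lq$table$flag == "positive")
n_neg <- sum(lq$table$flag == "negative")
cat(sprintf(
  "contributors at |z-LQ3| > 2.33: %d positive, %d negative (%.0f%% of cumulative |LQ|)\n",
  n_pos, n_neg, 100 * lq$share_abs))

chem_ids <- sm$features$id[sm$features$kind == "chemical"]
fits <- do.call(rbind, lapply(chem_ids, function(ch) {
  f <- fit_ordination_vector(pc$scores[, 1:2], sm$values[ch, ],
                             n_perm = 999, seed = seed)
  data.frame(chemical = ch, dir1 = f$direction[1], dir2 = f$direction[2],
             r2 = f$r2, p = f$p)
}))
write.table(fits, "results/vector_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- fits$chemical[fits$p < 0.01]
cat("chemicals fitting the PC1-PC2 plane at p < 0.01:",
    paste(sig, collapse = ", "), "\n")

pc3_by_plot <- tapply(pc$scores[, 3], cells, mean)
if (cor(pc3_by_plot[traits$plot], traits$seed_yield) < 0) {
  pc3_by_plot <- -pc3_by_plot   # orient as in the contributor scoring
}
ct <- correlate_traits(pc3_by_plot, traits)
cat(sprintf("PC3 vs traits: mean r %.2f +/- %.2f\n",
            attr(ct, "mean_r"), attr(ct, "sd_r")))

ctt <- contributor_trait_test(lq, sm, traits)
write.table(ctt, "results/contributor_trait_test.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sy <- ctt[ctt$trait == "seed_yield", ]
cat(sprintf(
  "seed-yield correlation, contributors vs others: positive p = %.2g, negative p = %.2g\n",
  sy$p[sy$group == "positive"], sy$p[sy$group == "negative"]))
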