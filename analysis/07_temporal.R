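#!/usr/bin/env Rscript
# Stage 7: temporal dynamics of the community via stage-to-stage frequency
# differences (delta-f), their ordination, and selection of
# cultivation-stage-associated taxa.

suppressPackageStartupMessages(library(soilnet))

seed <- as.integer(Sys.getenv("SEED", "1"))
rt <- read_replicate_table("results/study/replicates.tsv")
truth <- jsonlite::read_json("results/study/truth.json")

d <- delta_f(rt)
print(d)

res <- pca_delta(d, n_perm = 999, seed = seed)
cat(sprintf(
  "delta-f ordination: PC1 %.0f%%, PC2 %.0f%%, PC3 %.0f%% of variance\n",
  100 * res$pca$prop_var[1], 100 * res$pca$prop_var[2],
  100 * res$pca$prop_var[3]))
cat(sprintf(
  "PERMANOVA, ripening transition vs others: pseudo-F %.2f, p = %.3g\n",
  res$permanova$f, res$permanova$p))
scores <- data.frame(res$observations, res$pca$scores[, 1:3])
write.table(scores, "results/delta_f_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sel <- stage_associated_taxa(d)
sel_df <- do.call(rbind, lapply(names(unclass(sel)), function(tr) {
  if (!length(sel[[tr]])) return(NULL)
  data.frame(transition = tr, taxon = sel[[tr]])
}))
if (is.null(sel_df)) sel_df <- data.frame(transition = character(),
                                          taxon = character())
write.table(sel_df, "results/stage_associated_taxa.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(sel)

planted_r <- names(truth$stage_assoc)[unlist(truth$stage_assoc) == "R"]
cat(sprintf("planted ripening taxa recovered at transition R: %d of %d\n",
            length(intersect(sel$R, planted_r)), length(planted_r)))
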