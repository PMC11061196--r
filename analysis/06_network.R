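#!/usr/bin/env Rscript
# Stage 6: co-occurrence network over taxa + chemicals, complete-graph
# center extraction, group assignment and hub cartography.
#
# Edges join feature pairs with |Pearson r| > 0.6 over the 30 plot-stage
# cells.  The network center (group 0) is the largest complete subgraph
# found by the greedy degree-ordered procedure; groups 1-3 are the taxon
# clusters minus the center; hubs are classified by betweenness z-score
# (> 2.24), within-group degree z (> 1.96) and participation coefficient
# (> 0.5).

suppressPackageStartupMessages(library(soilnet))

sm <- read_matrix_tsv("results/standardized_matrix.tsv", standardized = TRUE)
assignment <- read.delim("results/clusters.tsv")
clusters <- structure(setNames(assignment$cluster, assignment$taxon),
                      class = "cluster_assignment")

r <- correlate_features(sm)
net <- build_network(r, threshold = 0.6, features = sm$features)
print(net)

centers <- find_complete_graph_centers(net)
cat(sprintf("extracted %d center(s) of size %s (reporting size > %d)\n",
            length(centers), paste(lengths(centers), collapse = ", "),
            attr(centers, "min_size")))
if (length(centers)) {
  in_center <- intersect(centers[[1]], CHEMICAL_NAMES)
  cat("chemicals inside the main center:",
      if (length(in_center)) paste(in_center, collapse = ", ") else "none",
      "\n")
}

groups <- assign_groups(clusters, centers, net$nodes)
topo <- cartography(net, groups)
write.table(topo, "results/node_topology.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
export_network(net, topo, graphml_path = "results/network.graphml",
               edges_path = "results/network_edges.tsv")
jsonlite::write_json(lapply(unclass(centers), identity),
                     "results/centers.json")

cat(sprintf(
  "hubs: %d network (z_b > 2.24), %d intragroup (z_k > 1.96), %d intergroup (P > 0.5)\n",
  sum(topo$is_network_hub), sum(topo$is_intragroup), sum(topo$is_intergroup)))

cc <- chemical_correlates(r, c("pH", "SO4", "TOC", "sCa"), sm$features)
cat("taxa with |r| > 0.6 against pH/SO4/TOC/sCa:",
    paste(lengths(cc$sets), collapse = "/"), "\n")
write.table(cc$overlap, "results/chemical_correlate_overlap.tsv",
            sep = "\t", quote = FALSE)

cond <- condition_networks(sm, by = "plot")
write.table(cond$summaries, "results/per_plot_network_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
deg_sig <- sum(cond$comparisons$degree$pairs$p_adj < 0.05)
cat(sprintf(
  "per-plot networks: %d of %d pairwise degree comparisons significant\n",
  deg_sig, nrow(cond$comparisons$degree$pairs)))
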