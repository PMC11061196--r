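#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one object.  The default
#' thresholds are the study's reference values: edge cutoff |r| > 0.6,
#' betweenness z > 2.24 (network hubs), within-group degree z > 1.96
#' (intragroup hubs), participation > 0.5 (intergroup hubs), |z-LQ| > 2.33
#' (ordination contributors), k = 3 clusters, alpha = 0.05.
#'
#' @param input path to a replicate-table TSV, or `NULL` to simulate.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param r_threshold absolute-correlation edge cutoff.
#' @param z_b_cutoff,z_k_cutoff,p_cutoff hub thresholds.
#' @param z_lq_cutoff ordination contributor threshold.
#' @param k number of taxon clusters.
#' @param alpha significance level.
#' @param n_perm permutations for PERMANOVA and vector fitting.
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = synthetic_config(),
                            r_threshold = 0.6, z_b_cutoff = 2.24,
                            z_k_cutoff = 1.96, p_cutoff = 0.5,
                            z_lq_cutoff = 2.33, k = 3L, alpha = 0.05,
                            n_perm = 999L, seed = 1L, outdir = NULL) {
  stopifnot(r_threshold > 0, z_b_cutoff > 0, z_k_cutoff > 0, p_cutoff > 0,
            z_lq_cutoff > 0, k >= 1, alpha > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes ingestion/simulation, replicate aggregation and
#' standardization, alpha diversity, ordination with contributor scoring,
#' clustering, the co-occurrence network with center extraction and hub
#' cartography, and the temporal delta-f analysis, writing all module
#' outputs plus a JSON run manifest when `cfg$outdir` is set.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result` with every stage's objects and
#'   the `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "ingest"
  result <- tryCatch({
    if (is.null(cfg$input)) {
      sim_cfg <- cfg$synthetic
      sim_cfg$seed <- sub_seed(cfg$seed, 1L)
      study <- generate_study(sim_cfg)
      rt <- study$replicates
      traits <- study$traits
      truth <- study$truth
    } else {
      rt <- read_replicate_table(cfg$input)
      traits <- NULL
      truth <- NULL
    }

    stage <- "preprocess"
    rel <- to_relative_frequency(rt)
    mm <- filter_absent_features(aggregate_medians(rel))
    removal <- attr(mm, "removal_report")
    sm <- standardize_features(mm)
    cv <- compute_cv(rt)
    taxsum <- taxonomy_summary(mm)

    stage <- "diversity"
    alpha_res <- alpha_diversity_table(rt, seed = sub_seed(cfg$seed, 2L))

    stage <- "ordination"
    pc <- community_pca(sm, kind = "taxon")
    orient <- NULL
    if (!is.null(traits)) {
      cells <- parse_cell_ids(rownames(pc$scores))
      orient <- traits$seed_yield[match(cells$plot, traits$plot)]
    }
    lq <- load_quantity(pc, axis = 3L, cutoff = cfg$z_lq_cutoff,
                        orient = orient)
    chem_ids <- sm$features$id[sm$features$kind == "chemical"]
    vfits <- lapply(chem_ids, function(ch) {
      fit_ordination_vector(pc$scores[, 1:2], sm$values[ch, ],
                            n_perm = cfg$n_perm,
                            seed = sub_seed(cfg$seed, 3L))
    })
    names(vfits) <- chem_ids

    stage <- "clustering"
    tree <- hierarchical_cluster(sm)
    clusters <- cut_clusters(tree, k = cfg$k)
    labels <- semantic_cluster_labels(clusters, sm)

    stage <- "network"
    r <- correlate_features(sm)
    net <- build_network(r, threshold = cfg$r_threshold,
                         features = sm$features)
    centers <- find_complete_graph_centers(net)
    groups <- assign_groups(clusters, centers, net$nodes)
    topo <- cartography(net, groups, z_b_cutoff = cfg$z_b_cutoff,
                        z_k_cutoff = cfg$z_k_cutoff,
                        p_cutoff = cfg$p_cutoff)

    stage <- "temporal"
    df <- delta_f(rt)
    pdelta <- pca_delta(df, n_perm = cfg$n_perm,
                        seed = sub_seed(cfg$seed, 4L))
    stage_taxa <- stage_associated_taxa(df, alpha = cfg$alpha)

    stage <- "report"
    manifest <- list(
      seed = cfg$seed,
      thresholds = list(r = cfg$r_threshold, z_b = cfg$z_b_cutoff,
                        z_kappa = cfg$z_k_cutoff, participation = cfg$p_cutoff,
                        z_lq = cfg$z_lq_cutoff, k = cfg$k,
                        alpha = cfg$alpha, n_perm = cfg$n_perm),
      counts = list(
        taxa_retained = removal$n_retained,
        taxa_removed = removal$n_removed,
        cluster_sizes = as.integer(table(clusters)),
        n_edges = nrow(net$edges),
        n_nodes = length(net$nodes),
        center_sizes = lengths(centers),
        n_network_hubs = sum(topo$is_network_hub),
        n_intragroup_hubs = sum(topo$is_intragroup),
        n_intergroup_hubs = sum(topo$is_intergroup),
        stage_associated = lengths(unclass(stage_taxa))),
      cv = as.list(cv$by_kind),
      pooled_shannon = alpha_res$pooled_h)

    out <- structure(list(
      replicates = rt, traits = traits, truth = truth,
      median_matrix = mm, standardized = sm, removal = removal, cv = cv,
      taxonomy = taxsum, alpha = alpha_res, pca = pc, load_quantity = lq,
      vector_fits = vfits, tree = tree, clusters = clusters,
      cluster_labels = labels, correlation = r, network = net,
      centers = centers, groups = groups, topology = topo,
      delta_f = df, pca_delta = pdelta, stage_taxa = stage_taxa,
      manifest = manifest), class = "pipeline_result")

    if (!is.null(cfg$outdir)) write_pipeline_outputs(out, cfg$outdir)
    out
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("pipeline_result: ", m$counts$taxa_retained, " taxa retained; ",
      "clusters ", paste(m$counts$cluster_sizes, collapse = "/"), "; ",
      m$counts$n_edges, " edges; centers ",
      paste(m$counts$center_sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# serialize every stage output under outdir
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_matrix_tsv(res$median_matrix, p("median_matrix.tsv"))
  write_matrix_tsv(res$standardized, p("standardized_matrix.tsv"))
  utils::write.table(
    data.frame(removed_taxon = res$removal$removed_ids),
    p("removed_taxa.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature = names(res$cv$per_feature),
               mean_cv = res$cv$per_feature),
    p("cv_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$alpha$per_cell, p("alpha_per_cell.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$alpha$per_plot, p("alpha_per_plot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell = rownames(res$pca$scores),
               res$pca$scores[, seq_len(min(5, ncol(res$pca$scores)))]),
    p("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature = rownames(res$pca$loadings),
               res$pca$loadings[, seq_len(min(5, ncol(res$pca$loadings)))]),
    p("pca_loadings.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$load_quantity$table, p("load_quantity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vf <- do.call(rbind, lapply(names(res$vector_fits), function(ch) {
    f <- res$vector_fits[[ch]]
    data.frame(chemical = ch, dir1 = f$direction[1], dir2 = f$direction[2],
               r2 = f$r2, p = f$p, n_perm = f$n_perm)
  }))
  utils::write.table(vf, p("vector_fits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cl <- data.frame(taxon = names(res$clusters),
                   cluster = as.integer(res$clusters))
  cl$label <- res$cluster_labels$label[match(cl$cluster,
                                             res$cluster_labels$cluster)]
  utils::write.table(cl, p("clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_dendrogram_newick(res$tree, p("dendrogram.nwk"))
  export_network(res$network, res$topology,
                 graphml_path = p("network.graphml"),
                 edges_path = p("network_edges.tsv"))
  jsonlite::write_json(lapply(unclass(res$centers), identity),
                       p("centers.json"), auto_unbox = FALSE)
  utils::write.table(res$topology, p("node_topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st <- do.call(rbind, lapply(names(unclass(res$stage_taxa)), function(tr) {
    hits <- res$stage_taxa[[tr]]
    if (!length(hits)) return(NULL)
    data.frame(transition = tr, taxon = hits)
  }))
  if (is.null(st)) st <- data.frame(transition = character(),
                                    taxon = character())
  utils::write.table(st, p("stage_associated_taxa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
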