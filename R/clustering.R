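#' Complete-linkage hierarchical clustering of taxa
#'
#' Agglomerative clustering of taxon rows on Euclidean distance between
#' their 30-cell standardized profiles, complete linkage.
#'
#' @param m a `standardized_matrix`.
#' @return an [stats::hclust] tree over the taxon rows.
#' @export
hierarchical_cluster <- function(m) {
  stopifnot(inherits(m, "median_matrix"))
  tax <- m$features$kind == "taxon"
  if (sum(tax) < 2) stop("need at least 2 taxa")
  vals <- m$values[tax, , drop = FALSE]
  stats::hclust(stats::dist(vals), method = "complete")
}

#' Cut a cluster tree into k clusters
#'
#' Wraps [stats::cutree()]; cluster ids are numbered by first appearance in
#' the taxon input order, so the mapping is stable.
#'
#' @param tree an [stats::hclust] tree.
#' @param k number of clusters (default 3, the fertilizer-linked partition).
#' @return object of class `cluster_assignment`: named integer vector
#'   taxon -> cluster id, with the tree kept as an attribute.
#' @export
cut_clusters <- function(tree, k = 3L) {
  if (k < 1) stop("k must be >= 1")
  n_leaves <- length(tree$order)
  if (k > n_leaves) stop("k exceeds number of leaves")
  assign <- stats::cutree(tree, k = k)
  structure(assign, class = "cluster_assignment", tree = tree, k = k)
}

#' Attach fertilizer-regime labels to taxon clusters
#'
#' Each cluster is labeled by the plot group (N / plain / compost) with the
#' highest mean standardized frequency over its member taxa.  Ties are
#' broken toward the order N < plain < compost with a warning; if two
#' clusters map to the same group a warning is raised and numeric ids kept
#' authoritative.
#'
#' @param assignment a [cut_clusters()] result.
#' @param m the `standardized_matrix` used for clustering.
#' @return data frame: cluster id, semantic label, size, and the group-mean
#'   matrix as attribute `group_means`.
#' @export
semantic_cluster_labels <- function(assignment, m) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(m, "median_matrix"))
  cells <- parse_cell_ids(colnames(m$values))
  grp <- plot_group(cells$plot)
  groups <- c("N", "plain", "compost")
  ids <- sort(unique(as.integer(assignment)))
  gm <- matrix(NA_real_, length(ids), length(groups),
               dimnames = list(ids, groups))
  for (ci in seq_along(ids)) {
    members <- names(assignment)[assignment == ids[ci]]
    sub <- m$values[members, , drop = FALSE]
    for (g in groups) gm[ci, g] <- mean(sub[, grp == g, drop = FALSE])
  }
  best <- apply(gm, 1L, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1) {
      warning("tied plot-group means; tie broken toward N < plain < compost")
      top <- top[1]
    }
    groups[top]
  })
  label_map <- c(N = "N-linked", plain = "plain", compost = "compost-linked")
  if (anyDuplicated(best)) {
    warning("two clusters map to the same plot group; keeping numeric ids")
  }
  out <- data.frame(cluster = ids, label = unname(label_map[best]),
                    size = as.integer(table(assignment)[as.character(ids)]),
                    stringsAsFactors = FALSE)
  attr(out, "group_means") <- gm
  out
}

#' Pooled correlation between cluster member frequencies and seed yield
#'
#' Pools all (member taxon, plot-stage cell) pairs of a cluster and
#' correlates the standardized frequencies with the plot's seed yield,
#' optionally collapsing stages to per-plot means first.
#'
#' @param assignment a [cut_clusters()] result.
#' @param m the `standardized_matrix`.
#' @param traits trait table with `plot` and `seed_yield` columns.
#' @param collapse_stages average each taxon within plots before pooling.
#' @return data frame: cluster, n_pairs, r, p.
#' @export
cluster_trait_correlation <- function(assignment, m, traits,
                                      collapse_stages = FALSE) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(m, "median_matrix"))
  cells <- parse_cell_ids(colnames(m$values))
  yield <- traits$seed_yield[match(cells$plot, traits$plot)]
  ids <- sort(unique(as.integer(assignment)))
  out <- lapply(ids, function(cid) {
    members <- names(assignment)[assignment == cid]
    if (!length(members)) stop("empty cluster ", cid)
    sub <- m$values[members, , drop = FALSE]
    if (collapse_stages) {
      plot_f <- factor(cells$plot, levels = PLOT_LEVELS)
      sub <- t(apply(sub, 1L, function(v) tapply(v, plot_f, mean)))
      yv <- traits$seed_yield[match(levels(plot_f), traits$plot)]
      x <- as.vector(sub)
      y <- rep(yv, each = nrow(sub))
    } else {
      x <- as.vector(sub)
      y <- rep(yield, each = nrow(sub))
    }
    ct <- correlation_test(x, y)
    data.frame(cluster = cid, n_pairs = length(x), r = ct$r, p = ct$p)
  })
  do.call(rbind, out)
}

#' Export a cluster tree as Newick
#'
#' Converts the merge tree to a phylogeny (merge heights as branch lengths)
#' and writes Newick text.
#'
#' @param tree an [stats::hclust] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
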