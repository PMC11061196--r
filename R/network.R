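#' Pearson correlation matrix over plot-stage cells
#'
#' Pairwise Pearson r between feature rows over the 30 plot-stage cells.
#' Constant rows have undefined correlations; they are flagged and excluded.
#'
#' @param m a `standardized_matrix` (or `median_matrix`).
#' @return symmetric correlation matrix with feature ids as dimnames;
#'   excluded constant features in `attr(, "excluded")`.
#' @export
correlate_features <- function(m) {
  stopifnot(inherits(m, "median_matrix"))
  vals <- m$values
  sdv <- apply(vals, 1L, stats::sd)
  const <- is.na(sdv) | sdv == 0
  if (any(const)) {
    warning("excluding ", sum(const), " constant feature(s) from correlation")
  }
  r <- stats::cor(t(vals[!const, , drop = FALSE]))
  attr(r, "excluded") <- rownames(vals)[const]
  r
}

#' Build the co-occurrence network from a correlation matrix
#'
#' Nodes are features; an undirected edge joins features i and j when
#' `|r_ij| > threshold` (strictly; a pair at exactly the threshold gets no
#' edge).  Isolated nodes are retained with degree zero.  The signed r is
#' stored on each edge.
#'
#' @param r symmetric correlation matrix.
#' @param threshold absolute-correlation cutoff (default 0.6).
#' @param features optional feature data frame (`id`, `kind`) to attach
#'   node kinds.
#' @return object of class `cooccurrence_network`: list with `graph`
#'   (igraph), `threshold`, `nodes`.
#' @export
build_network <- function(r, threshold = 0.6, features = NULL) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  ids <- rownames(r) %||% as.character(seq_len(nrow(r)))
  keep <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      r = r[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(features)) {
    igraph::V(g)$kind <- features$kind[match(ids, features$id)]
  }
  structure(list(graph = g, threshold = threshold,
                 nodes = ids, edges = edges),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (|r| >", x$threshold, ")\n")
  invisible(x)
}

#' Extract complete-graph centers by greedy degree ordering
#'
#' The center-extraction procedure: starting from all nodes as candidates,
#' (i) sort candidates by their degree within the candidate set,
#' descending (ties by node id); (ii) keep the largest n such that the n-th
#' node has within-candidate degree >= n - 1; (iii) recompute
#' within-candidate degrees and repeat.  The procedure terminates when every
#' kept node has within-set degree n - 1, i.e. the induced subgraph is
#' complete.  After extracting a center its nodes are removed and the
#' procedure reruns to find further centers; sets no larger than `min_size`
#' stop the search.
#'
#' @param net a [build_network()] result (or an igraph graph).
#' @param min_size minimum reported center size; defaults to
#'   `ceiling(0.05 * total nodes)` (centers must be strictly larger).
#' @return object of class `center_set`: list of node-name vectors, largest
#'   first, with `min_size` attribute.
#' @export
find_complete_graph_centers <- function(net, min_size = NULL) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n_total <- igraph::vcount(g)
  if (n_total == 0) stop("empty network")
  if (is.null(min_size)) min_size <- ceiling(0.05 * n_total)

  centers <- list()
  work <- g
  repeat {
    if (igraph::vcount(work) == 0) break
    center <- greedy_center(work)
    if (length(center) <= min_size) break
    centers[[length(centers) + 1L]] <- center
    work <- igraph::delete_vertices(work, center)
  }
  # the greedy pass is not monotone in size, and group 0 is defined as the
  # largest center, so report largest first
  centers <- centers[order(-lengths(centers))]
  structure(centers, class = "center_set", min_size = min_size,
            n_total = n_total)
}

# one round of the greedy complete-subgraph extraction on an igraph.
# When the kept n equals the candidate count, every within-candidate degree
# is >= n - 1; the degree bound then forces all degrees to equal n - 1, so
# the induced subgraph is complete and the loop terminates.
greedy_center <- function(g) {
  cand <- igraph::V(g)$name
  repeat {
    sub <- igraph::induced_subgraph(g, cand)
    deg <- igraph::degree(sub)
    ord <- order(-deg, igraph::V(sub)$name)
    deg_sorted <- deg[ord]
    n <- max(which(deg_sorted >= seq_along(deg_sorted) - 1L))
    if (n == length(cand)) return(sort(cand))
    cand <- igraph::V(sub)$name[ord[seq_len(n)]]
  }
}

#' @export
print.center_set <- function(x, ...) {
  cat("center_set:", length(x), "center(s) of size",
      paste(lengths(x), collapse = ", "),
      "(reporting size >", attr(x, "min_size"), ")\n")
  invisible(x)
}

#' Assign cartography groups from clusters and centers
#'
#' Group 0 is the largest extracted center (taxa and any chemicals inside
#' it); groups 1-3 are the taxon clusters minus group 0; chemicals outside
#' the center form their own group `"chem"`.
#'
#' @param clusters a [cut_clusters()] result (named taxon -> cluster id).
#' @param centers a [find_complete_graph_centers()] result (may be empty).
#' @param node_ids character vector of all network node names.
#' @return named character vector node -> group in
#'   `{"0","1","2","3","chem"}`.
#' @export
assign_groups <- function(clusters, centers, node_ids) {
  center0 <- if (length(centers)) centers[[1]] else character()
  groups <- stats::setNames(rep(NA_character_, length(node_ids)), node_ids)
  is_taxon <- node_ids %in% names(clusters)
  missing_cluster <- !is_taxon & !node_ids %in% CHEMICAL_NAMES
  if (any(missing_cluster)) {
    stop("taxon in no cluster: ",
         paste(node_ids[missing_cluster], collapse = ", "))
  }
  groups[is_taxon] <- as.character(clusters[node_ids[is_taxon]])
  groups[!is_taxon] <- "chem"
  groups[node_ids %in% center0] <- "0"
  groups
}

#' Node centralities of the co-occurrence network
#'
#' Degree, betweenness (shortest-path pair counting with even splitting over
#' equal-length paths, unweighted), closeness (within connected components,
#' over reachable pairs only) and the betweenness z-score using the
#' population sd over all nodes.
#'
#' @param net a [build_network()] result or igraph graph.
#' @return data frame: node, degree, betweenness, z_betweenness, closeness.
#' @export
node_centralities <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  n <- igraph::vcount(g)
  sd_pop <- sqrt(mean((b - mean(b))^2))
  zb <- if (n > 1 && sd_pop > 0) (b - mean(b)) / sd_pop else rep(0, n)
  cl <- suppressWarnings(igraph::closeness(g, weights = NA,
                                           mode = "all"))
  cl[igraph::degree(g) == 0] <- NA_real_
  data.frame(node = igraph::V(g)$name,
             degree = unname(igraph::degree(g)),
             betweenness = unname(b),
             z_betweenness = unname(zb),
             closeness = unname(cl),
             stringsAsFactors = FALSE)
}

#' Average shortest-path length
#'
#' Mean geodesic distance over connected node pairs; `NA` for graphs with
#' no connected pair.
#'
#' @param net a [build_network()] result or igraph graph.
#' @return real, or `NA`.
#' @export
average_path_length <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  if (igraph::ecount(g) == 0) return(NA_real_)
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Network cartography: within-group degrees, participation, hub classes
#'
#' For every node: total degree k, within-group degree kappa (edges to its
#' own group), the within-group degree z-score (standardized within each
#' group, population sd), and the participation coefficient
#' `P = 1 - sum_s (kappa_s / k)^2` over the groups.  Hub classification
#' (all comparisons strict): network hub if the betweenness z-score exceeds
#' `z_b_cutoff`; intragroup hub if the within-group degree z exceeds
#' `z_k_cutoff`; intergroup hub if P exceeds `p_cutoff`; a node can be both
#' intra- and intergroup.
#'
#' @param net a [build_network()] result or igraph graph.
#' @param groups named node -> group vector (see [assign_groups()]).
#' @param z_b_cutoff betweenness z threshold for network hubs.
#' @param z_k_cutoff within-group degree z threshold for intragroup hubs.
#' @param p_cutoff participation threshold for intergroup hubs.
#' @return data frame of class `node_topology`: node, group, degree,
#'   betweenness, z_betweenness, closeness, kappa, z_kappa, participation,
#'   is_network_hub, is_intragroup, is_intergroup, hub_class.
#' @export
cartography <- function(net, groups, z_b_cutoff = 2.24,
                        z_k_cutoff = 1.96, p_cutoff = 0.5) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(groups))) {
    stop("group assignment must cover every node")
  }
  grp <- groups[nodes]
  cen <- node_centralities(g)

  glevels <- sort(unique(grp))
  el <- igraph::as_edgelist(g, names = TRUE)
  node_f <- function(x) factor(x, levels = nodes)
  grp_f <- function(x) factor(x, levels = glevels)
  if (nrow(el)) {
    ka <- table(node_f(el[, 1]), grp_f(grp[el[, 2]]))
    kb <- table(node_f(el[, 2]), grp_f(grp[el[, 1]]))
    kappa_mat <- unclass(ka) + unclass(kb)
  } else {
    kappa_mat <- matrix(0L, length(nodes), length(glevels))
  }
  dimnames(kappa_mat) <- list(nodes, glevels)
  k <- rowSums(kappa_mat)
  kappa <- kappa_mat[cbind(seq_along(nodes), match(grp, glevels))]
  z_kappa <- numeric(length(nodes))
  for (gl in glevels) {
    idx <- grp == gl
    kv <- kappa[idx]
    sd_pop <- sqrt(mean((kv - mean(kv))^2))
    z_kappa[idx] <- if (sd_pop > 0) (kv - mean(kv)) / sd_pop else 0
  }
  participation <- ifelse(k > 0, 1 - rowSums((kappa_mat / pmax(k, 1))^2),
                          NA_real_)

  is_net <- cen$z_betweenness > z_b_cutoff
  is_intra <- z_kappa > z_k_cutoff
  is_inter <- !is.na(participation) & participation > p_cutoff
  hub_class <- ifelse(is_intra & is_inter, "both",
                ifelse(is_intra, "intragroup",
                 ifelse(is_inter, "intergroup",
                  ifelse(is_net, "network_hub", "none"))))
  out <- data.frame(node = nodes, group = unname(grp),
                    degree = cen$degree, betweenness = cen$betweenness,
                    z_betweenness = cen$z_betweenness,
                    closeness = cen$closeness,
                    kappa = unname(kappa), z_kappa = z_kappa,
                    participation = unname(participation),
                    is_network_hub = is_net, is_intragroup = is_intra,
                    is_intergroup = is_inter, hub_class = hub_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("node_topology", "data.frame")
  attr(out, "kappa_matrix") <- kappa_mat
  out
}

#' Taxa correlated with a chemical component
#'
#' Taxa whose correlation with the chemical exceeds the threshold in
#' absolute value, plus pairwise overlap counts across several chemicals
#' for Venn-style reporting.
#'
#' @param r correlation matrix from [correlate_features()].
#' @param chemicals chemical name(s) present in `r`.
#' @param features feature data frame (`id`, `kind`).
#' @param threshold absolute-r cutoff.
#' @return list with per-chemical taxon id vectors (`sets`) and the
#'   pairwise `overlap` count matrix.
#' @export
chemical_correlates <- function(r, chemicals, features, threshold = 0.6) {
  missing <- setdiff(chemicals, rownames(r))
  if (length(missing)) stop("chemical(s) not in matrix: ",
                            paste(missing, collapse = ", "))
  taxa <- intersect(rownames(r), features$id[features$kind == "taxon"])
  sets <- lapply(chemicals, function(ch) {
    taxa[abs(r[taxa, ch]) > threshold]
  })
  names(sets) <- chemicals
  overlap <- outer(seq_along(sets), seq_along(sets),
                   Vectorize(function(i, j) length(intersect(sets[[i]],
                                                             sets[[j]]))))
  dimnames(overlap) <- list(chemicals, chemicals)
  list(sets = sets, overlap = overlap)
}

#' Per-plot or per-stage networks and topology comparisons
#'
#' Restricts the standardized matrix to each condition's cells (a plot's 5
#' stages, or a stage's 6 plots), rebuilds the co-occurrence network per
#' condition, summarizes its topology, and compares the per-node degree /
#' closeness / betweenness distributions across conditions with the
#' Tukey-Kramer test.  Correlations rest on only 5-6 points per pair, so
#' these networks are low-power screens.
#'
#' @param m a `standardized_matrix`.
#' @param by `"plot"` or `"stage"`.
#' @param threshold absolute-r edge cutoff.
#' @return list with `networks` (per condition), `summaries` (data frame:
#'   condition, nodes, edges, mean degree, average path length) and
#'   `comparisons` (Tukey results per centrality).
#' @export
condition_networks <- function(m, by = c("plot", "stage"), threshold = 0.6) {
  by <- match.arg(by)
  stopifnot(inherits(m, "median_matrix"))
  cells <- parse_cell_ids(colnames(m$values))
  conditions <- if (by == "plot") PLOT_LEVELS else STAGE_LEVELS
  nets <- list(); cent <- list()
  summaries <- NULL
  for (cond in conditions) {
    cols <- if (by == "plot") cells$plot == cond else cells$stage == cond
    if (sum(cols) < 3) stop("condition ", cond, " has fewer than 3 cells")
    sub <- m
    sub$values <- m$values[, cols, drop = FALSE]
    r <- suppressWarnings(correlate_features(sub))
    net <- build_network(r, threshold = threshold, features = m$features)
    nets[[cond]] <- net
    cc <- node_centralities(net)
    cent[[cond]] <- cc
    summaries <- rbind(summaries, data.frame(
      condition = cond, nodes = length(net$nodes), edges = nrow(net$edges),
      mean_degree = mean(cc$degree),
      avg_path_length = average_path_length(net)))
  }
  comparisons <- lapply(c("degree", "closeness", "betweenness"),
                        function(metric) {
    gr <- lapply(cent, function(cc) {
      v <- cc[[metric]]
      v[is.finite(v)]
    })
    tukey_kramer(gr)
  })
  names(comparisons) <- c("degree", "closeness", "betweenness")
  list(networks = nets, summaries = summaries, comparisons = comparisons)
}

#' Export a network as GraphML and edge-list TSV
#'
#' @param net a [build_network()] result.
#' @param topology optional [cartography()] table; its columns become node
#'   attributes.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
export_network <- function(net, topology = NULL, graphml_path = NULL,
                           edges_path = NULL) {
  g <- net$graph
  if (!is.null(topology)) {
    idx <- match(igraph::V(g)$name, topology$node)
    for (col in setdiff(names(topology), "node")) {
      g <- igraph::set_vertex_attr(g, col, value = topology[[col]][idx])
    }
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}
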