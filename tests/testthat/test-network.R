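test_that("feature correlations match the covariance/sd definition", {
  set.seed(3)
  vals <- matrix(rnorm(8 * 30), 8, 30)
  vals[2, ] <- -vals[1, ]
  mm <- make_mm(vals)
  r <- correlate_features(mm)
  expect_equal(r["f01", "f02"], -1)
  expect_lt(max(abs(r - t(r))), 1e-12)
  # from-definition oracle on every pair
  for (i in 1:7) for (j in (i + 1):8) {
    xi <- vals[i, ]; xj <- vals[j, ]
    oracle <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      ((30 - 1) * sd(xi) * sd(xj))
    expect_equal(unname(r[i, j]), oracle, tolerance = 1e-10)
  }
  vals[5, ] <- 2
  mm2 <- make_mm(vals)
  expect_warning(r2 <- correlate_features(mm2), "constant")
  expect_identical(attr(r2, "excluded"), "f05")
})

test_that("edges require strictly |r| above the threshold", {
  r <- diag(3)
  rownames(r) <- colnames(r) <- c("a", "b", "c")
  r["a", "b"] <- r["b", "a"] <- 0.6      # exactly at threshold: no edge
  r["a", "c"] <- r["c", "a"] <- -0.7
  net <- build_network(r, threshold = 0.6)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(sort(c(net$edges$from, net$edges$to)), c("a", "c"))
  expect_equal(net$edges$r, -0.7)
  # all-small correlations: edgeless but nodes retained
  r0 <- diag(3); rownames(r0) <- colnames(r0) <- c("a", "b", "c")
  net0 <- build_network(r0, threshold = 0.6)
  expect_identical(nrow(net0$edges), 0L)
  expect_identical(length(net0$nodes), 3L)
  expect_true(all(igraph::degree(net0$graph) == 0))
})

test_that("greedy center extraction recovers planted complete graphs", {
  # K5 plus an isolated node
  adj <- matrix(FALSE, 6, 6)
  adj[1:5, 1:5] <- TRUE; diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
  igraph::V(g)$name <- paste0("n", 1:6)
  centers <- find_complete_graph_centers(g, min_size = 3)
  expect_identical(length(centers), 1L)
  expect_identical(centers[[1]], paste0("n", 1:5))

  # triangle with one pendant vertex
  adj2 <- matrix(FALSE, 4, 4)
  adj2[1, 2] <- adj2[1, 3] <- adj2[2, 3] <- adj2[3, 4] <- TRUE
  adj2 <- adj2 | t(adj2)
  g2 <- igraph::graph_from_adjacency_matrix(adj2, "undirected")
  igraph::V(g2)$name <- letters[1:4]
  centers2 <- find_complete_graph_centers(g2, min_size = 2)
  expect_identical(centers2[[1]], c("a", "b", "c"))
  expect_identical(brute_max_clique_size(adj2), 3L)

  # random graphs: extracted sets are always complete and never beat the
  # exhaustive maximum clique
  for (s in 1:10) {
    tc <- generate_network_testcase("random_gnp", n = 12, p = 0.5, seed = s)
    g3 <- igraph::graph_from_adjacency_matrix(tc$adjacency, "undirected")
    igraph::V(g3)$name <- sprintf("v%02d", 1:12)
    centers3 <- find_complete_graph_centers(g3, min_size = 1)
    for (cen in centers3) {
      sub <- tc$adjacency[match(cen, igraph::V(g3)$name),
                          match(cen, igraph::V(g3)$name)]
      expect_true(all(sub[upper.tri(sub)]))
    }
    expect_lte(length(centers3[[1]]), length(tc$expected$max_clique))
  }
})

test_that("center extraction finds the planted clique in noise", {
  tc <- generate_network_testcase("planted_clique", n = 80, p = 0.1,
                                  clique_size = 14, seed = 9)
  g <- igraph::graph_from_adjacency_matrix(tc$adjacency, "undirected")
  igraph::V(g)$name <- sprintf("v%02d", 1:80)
  centers <- find_complete_graph_centers(g, min_size = 4)
  planted <- sprintf("v%02d", tc$expected$planted)
  overlap <- length(intersect(centers[[1]], planted)) / length(planted)
  expect_gte(overlap, 0.9)
})

test_that("betweenness and closeness match exhaustive enumeration", {
  p3 <- generate_network_testcase("path", n = 3)
  g <- igraph::graph_from_adjacency_matrix(p3$adjacency, "undirected")
  igraph::V(g)$name <- c("a", "b", "c")
  cen <- node_centralities(g)
  expect_equal(cen$betweenness, c(0, 1, 0))

  star <- generate_network_testcase("star", n = 4)
  gs <- igraph::graph_from_adjacency_matrix(star$adjacency, "undirected")
  igraph::V(gs)$name <- letters[1:4]
  expect_equal(node_centralities(gs)$betweenness[1], 3)  # three leaf pairs

  for (s in 1:20) {
    tc <- generate_network_testcase("random_gnp", n = 10, p = 0.3, seed = 40 + s)
    gg <- igraph::graph_from_adjacency_matrix(tc$adjacency, "undirected")
    igraph::V(gg)$name <- sprintf("v%02d", 1:10)
    expect_equal(node_centralities(gg)$betweenness,
                 brute_betweenness(tc$adjacency), tolerance = 1e-10)
  }

  # z-score uses the population sd over all nodes
  b <- node_centralities(g)$betweenness
  expect_equal(node_centralities(g)$z_betweenness,
               (b - mean(b)) / sqrt(mean((b - mean(b))^2)))
  # average path length of the 3-path: (1 + 1 + 2) / 3
  expect_equal(average_path_length(g), 4 / 3)
})

test_that("cartography closed forms and invariants hold", {
  # node with 4 edges split 2/2 across two groups: P = 0.5, not intergroup
  el <- rbind(c("x", "a1"), c("x", "a2"), c("x", "b1"), c("x", "b2"))
  g <- igraph::graph_from_data_frame(as.data.frame(el), directed = FALSE)
  groups <- c(x = "A", a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  topo <- cartography(g, groups)
  xrow <- topo[topo$node == "x", ]
  expect_equal(xrow$participation, 0.5)
  expect_false(xrow$is_intergroup)        # strict >
  expect_identical(xrow$kappa, 2L)

  # all edges inside the own group: P = 0
  a1 <- topo[topo$node == "a1", ]
  expect_equal(a1$participation, 0)

  # even split over m groups: P = 1 - 1/m
  for (m in c(2, 3, 4)) {
    el2 <- cbind("hub", paste0("g", seq_len(m)))
    gg <- igraph::graph_from_data_frame(as.data.frame(el2), directed = FALSE)
    grp <- c(hub = "g1", setNames(paste0("g", seq_len(m)),
                                  paste0("g", seq_len(m))))
    tp <- cartography(gg, grp)
    expect_equal(tp$participation[tp$node == "hub"], 1 - 1 / m)
  }

  # sum of per-group degrees equals the total degree on a random graph
  tc <- generate_network_testcase("random_gnp", n = 15, p = 0.4, seed = 77)
  gr <- igraph::graph_from_adjacency_matrix(tc$adjacency, "undirected")
  igraph::V(gr)$name <- sprintf("v%02d", 1:15)
  grp <- setNames(sample(c("0", "1", "2", "chem"), 15, replace = TRUE),
                  igraph::V(gr)$name)
  tp <- cartography(gr, grp)
  km <- attr(tp, "kappa_matrix")
  expect_equal(unname(rowSums(km)), tp$degree)
  ok <- tp$degree > 0
  expect_true(all(tp$participation[ok] >= 0))
  expect_true(all(tp$participation[ok] <= 1 - 1 / length(unique(grp)) + 1e-12))
  expect_true(all(is.na(tp$participation[!ok])))
})

test_that("group assignment combines clusters and the extracted center", {
  clusters <- structure(c(t1 = 1L, t2 = 2L, t3 = 3L, t4 = 1L),
                        class = "cluster_assignment")
  nodes <- c("t1", "t2", "t3", "t4", "pH", "TOC")
  # empty center: groups equal clusters, chemicals their own group
  g0 <- assign_groups(clusters, structure(list(), class = "center_set"), nodes)
  expect_identical(unname(g0[c("t1", "t2", "t3", "t4")]),
                   c("1", "2", "3", "1"))
  expect_identical(unname(g0[c("pH", "TOC")]), c("chem", "chem"))
  # a center containing a chemical absorbs it into group 0
  centers <- structure(list(c("t1", "pH")), class = "center_set")
  g1 <- assign_groups(clusters, centers, nodes)
  expect_identical(unname(g1[c("t1", "pH", "t4", "TOC")]),
                   c("0", "0", "1", "chem"))
  expect_error(assign_groups(clusters, centers, c(nodes, "mystery")),
               "taxon in no cluster")
})

test_that("chemical correlate sets respect the threshold", {
  set.seed(19)
  vals <- matrix(rnorm(6 * 30), 6, 30)
  vals[2, ] <- vals[1, ] + rnorm(30, sd = 0.01)   # taxon tracking the chemical
  mm <- make_mm(vals, kind = c("chemical", rep("taxon", 5)))
  mm$features$id[1] <- "pH"; rownames(mm$values)[1] <- "pH"
  r <- correlate_features(mm)
  cc <- chemical_correlates(r, "pH", mm$features)
  expect_true("f02" %in% cc$sets$pH)
  expect_identical(unname(cc$overlap["pH", "pH"]), length(cc$sets$pH))
  expect_error(chemical_correlates(r, "TOC", mm$features), "not in matrix")
})

test_that("condition networks detect planted edge-density contrasts", {
  set.seed(53)
  n_feat <- 40
  cells <- as.vector(t(outer(PLOT_LEVELS, STAGE_LEVELS, paste, sep = "_")))
  vals <- matrix(rnorm(n_feat * 30), n_feat, 30,
                 dimnames = list(sprintf("f%02d", 1:n_feat), cells))
  # plot C: a strong shared factor doubles the edge density
  c_cells <- grepl("^C_", cells)
  shared <- rnorm(sum(c_cells))
  vals[1:30, c_cells] <- vals[1:30, c_cells] * 0.4 +
    matrix(rep(shared, each = 30), 30)
  mm <- make_mm(vals)
  res <- condition_networks(mm, by = "plot", threshold = 0.9)
  expect_identical(nrow(res$summaries), 6L)
  edges_c <- res$summaries$edges[res$summaries$condition == "C"]
  expect_gt(edges_c, max(res$summaries$edges[res$summaries$condition != "C"]))
  deg_pairs <- res$comparisons$degree$pairs
  c_rows <- deg_pairs$group1 == "C" | deg_pairs$group2 == "C"
  expect_true(any(deg_pairs$p_adj[c_rows] < 0.05))
})

test_that("networks export with attributes intact", {
  sm <- default_standardized()
  sub <- sm
  keep <- c(1:40, which(sub$features$kind == "chemical"))
  sub$values <- sm$values[keep, ]; sub$features <- sm$features[keep, ]
  r <- correlate_features(sub)
  net <- build_network(r, features = sub$features)
  groups <- setNames(ifelse(sub$features$kind == "chemical", "chem", "1"),
                     sub$features$id)
  topo <- cartography(net, groups)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, topo, graphml_path = gml, edges_path = tsv)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), length(net$nodes))
  expect_true("participation" %in% igraph::vertex_attr_names(g2))
  edges <- read.delim(tsv)
  expect_identical(nrow(edges), nrow(net$edges))
})
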