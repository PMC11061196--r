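# Independent oracles and small fixture builders shared by the suite.
# The oracles deliberately avoid the package's code paths (and igraph):
# betweenness by explicit shortest-path enumeration, medians by sort-and-pick,
# cliques by subset search over the adjacency matrix.

# exhaustive betweenness: enumerate every shortest path between every pair
# and split credit evenly; adj is a logical adjacency matrix
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] & d > d[v] + 1)
        d[nb] <- d[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  dmat <- t(vapply(seq_len(n), dist_from, numeric(n)))
  # enumerate all shortest s->t paths recursively, walking distances down
  paths_through <- function(s, t) {
    counts <- numeric(n)   # number of shortest paths through each interior node
    total <- 0
    walk <- function(v, visited) {
      if (v == s) {
        total <<- total + 1
        interior <- setdiff(visited, c(s, t))
        counts[interior] <<- counts[interior] + 1
        return(invisible())
      }
      for (u in which(adj[v, ] & dmat[s, ] == dmat[s, v] - 1)) {
        walk(u, c(visited, u))
      }
    }
    walk(t, t)
    list(counts = counts, total = total)
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(dmat[s, t]) || dmat[s, t] == 0) next
      pt <- paths_through(s, t)
      if (pt$total > 0) b <- b + pt$counts / pt$total
    }
  }
  b
}

# sort-and-pick median (even count: mean of the two central values)
brute_median <- function(x) {
  x <- sort(unname(x[!is.na(x)]))
  m <- length(x)
  if (m == 0) return(NA_real_)
  if (m %% 2 == 1) x[(m + 1) / 2] else (x[m / 2] + x[m / 2 + 1]) / 2
}

# brute-force maximum clique size by decreasing-size subset search
brute_max_clique_size <- function(adj) {
  n <- nrow(adj)
  for (k in n:1) {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      s <- combos[, ci]
      sub <- adj[s, s, drop = FALSE]
      if (all(sub[upper.tri(sub)])) return(k)
    }
  }
  0L
}

# adjusted Rand index from a confusion table
ari_index <- function(tab) {
  n <- sum(tab)
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  idx <- sum(choose(tab, 2))
  expected <- a * b / choose(n, 2)
  (idx - expected) / ((a + b) / 2 - expected)
}

# small replicate table: `taxa` is a taxon x sample count matrix whose
# column names follow plot_stage_rep; chemicals optional
make_rt <- function(taxa, chemicals = NULL) {
  samples <- do.call(rbind, strsplit(colnames(taxa), "_", fixed = TRUE))
  features <- data.frame(id = rownames(taxa), kind = "taxon",
                         stringsAsFactors = FALSE)
  values <- taxa
  if (!is.null(chemicals)) {
    features <- rbind(features,
                      data.frame(id = rownames(chemicals), kind = "chemical"))
    values <- rbind(taxa, chemicals)
  }
  replicate_table(features,
                  data.frame(sample = colnames(taxa),
                             plot = samples[, 1], stage = samples[, 2],
                             replicate = as.integer(samples[, 3]),
                             stringsAsFactors = FALSE),
                  values)
}

# a median_matrix built directly from a feature x 30-cell value matrix
make_mm <- function(values, kind = rep("taxon", nrow(values)),
                    standardized = FALSE) {
  colnames(values) <- as.vector(t(outer(PLOT_LEVELS, STAGE_LEVELS,
                                        paste, sep = "_")))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  }
  cls <- if (standardized) c("standardized_matrix", "median_matrix")
         else "median_matrix"
  structure(list(features = data.frame(id = rownames(values), kind = kind,
                                       stringsAsFactors = FALSE),
                 values = values),
            class = cls)
}

# adjacency matrix of an igraph-free edge list on n nodes
adj_from_edges <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  for (e in seq_len(nrow(edges))) {
    adj[edges[e, 1], edges[e, 2]] <- TRUE
    adj[edges[e, 2], edges[e, 1]] <- TRUE
  }
  adj
}

# the default synthetic study at the canonical seed, computed once per run
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(synthetic_config(seed = 1))
    cache
  }
})

default_standardized <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rel <- to_relative_frequency(default_study()$replicates)
      cache <<- standardize_features(
        filter_absent_features(aggregate_medians(rel)))
    }
    cache
  }
})
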