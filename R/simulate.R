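#' Configuration for the synthetic fertilizer-trial generator
#'
#' Defaults emulate the statistical structure of the field trial the pipeline
#' analyses: 870 taxa in three fertilizer-linked abundance clusters
#' (340/234/296, favored in the nitrogen, plain and compost plot groups
#' respectively), soil chemistry with a pH depression of 0.6 units under
#' nitrogen and a TOC surplus of 7 g/kg in the NP/NPK/C plots, phosphate-
#' driven plant traits, and replicate noise dispersions calibrated to average
#' coefficients of variation near 0.26 (chemistry) and 0.59 (taxa).
#'
#' @param n_taxa number of taxa.
#' @param cluster_sizes integer vector of three cluster sizes summing to
#'   `n_taxa`, favored in plot groups N / plain / compost in that order.
#' @param effect_size cluster log-abundance shift in the favored plot group,
#'   in units of the cross-taxon log-abundance sd (`base_log_sd`).
#' @param n_trait_taxa number of planted trait-linked taxa (extra shift in
#'   the phosphate-fertilized plots PK/NP/NPK).
#' @param trait_effect log-abundance shift of trait-linked taxa in phosphate
#'   plots, in replicate-noise sd units (positive taxa; a minority get the
#'   negative sign).
#' @param trait_background sd (in replicate-noise sd units) of the weak
#'   diffuse phosphate response carried by the rest of the community.
#' @param prop_trait_negative fraction of trait-linked taxa shifted down
#'   rather than up in phosphate plots.
#' @param n_ripening,n_flowering numbers of planted stage-associated taxa
#'   (log-rate bump from ripening onward, or at flowering only).
#' @param stage_shift log-rate bump for stage-associated taxa.
#' @param taxa_log_sd replicate log-noise sd of taxon rates.
#' @param base_log_sd spread of baseline log-abundances across taxa.
#' @param library_size,library_sd mean and sd of per-sample read totals.
#' @param ph_offset,toc_offset planted chemistry contrasts (pH units under
#'   nitrogen; g/kg TOC in NP/NPK/C).
#' @param seed RNG seed; every random draw flows through it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 870L,
                             cluster_sizes = c(340L, 234L, 296L),
                             effect_size = 1.5,
                             n_trait_taxa = 27L,
                             trait_effect = 3.0,
                             trait_background = 0.3,
                             prop_trait_negative = 10 / 27,
                             n_ripening = 9L,
                             n_flowering = 3L,
                             stage_shift = 1.2,
                             taxa_log_sd = 0.45,
                             base_log_sd = 1.0,
                             library_size = 26851,
                             library_sd = 6974,
                             ph_offset = -0.6,
                             toc_offset = 7,
                             seed = 1L) {
  if (sum(cluster_sizes) != n_taxa) {
    stop("cluster_sizes must sum to n_taxa (",
         sum(cluster_sizes), " != ", n_taxa, ")")
  }
  if (taxa_log_sd <= 0 || base_log_sd <= 0) stop("dispersions must be > 0")
  structure(as.list(environment()), class = "synthetic_config")
}

# per-component chemistry model: baseline level and replicate CV; noise is
# homoscedastic normal per component (sd = cv * baseline); NH4 and aPO4 sit
# near their detection limits, hence the large CVs
.CHEM_MODEL <- data.frame(
  chemical = CHEMICAL_NAMES,
  baseline = c(23, 10, 0.05, 20, 15, 30, 10, 40, 10, 3, 200, 50, 5, 6.0),
  cv       = c(0.08, 0.35, 0.9, 0.18, 0.18, 0.18, 0.18, 0.15, 0.15,
               0.25, 0.12, 0.12, 0.9, 0.02)
)

# expected chemistry level for one plot-stage cell
chem_cell_mean <- function(chemical, plot, stage, cfg) {
  base <- .CHEM_MODEL$baseline[.CHEM_MODEL$chemical == chemical]
  grp <- plot_group(plot)
  flags <- plot_flags(plot)
  m <- base
  if (chemical == "pH" && grp == "N") m <- m + cfg$ph_offset
  if (chemical == "TOC" && (plot %in% c("NP", "NPK", "C"))) {
    m <- m + cfg$toc_offset
  }
  if (chemical == "NO3" && flags$N) {
    m <- m + c(B = 0, A = 40, F = 15, R = 5, H = 0)[[stage]]
  }
  if (chemical == "SO4" && flags$N && stage == "F") m <- m * 1.7
  if (chemical == "eK" && (flags$K || flags$compost)) m <- m + 32
  m
}

#' Generate a synthetic fertilizer-trial study
#'
#' Draws a full 6 plots x 5 stages x 4 replicates study under a
#' log-normal-rate Poisson count model: per-taxon baseline log-abundances,
#' cluster x plot-group mean shifts, optional phosphate-linked and
#' stage-associated shifts, and replicate log-noise; counts are Poisson at a
#' per-sample library size.  Chemicals are drawn normal around plot/stage
#' means, traits are deterministic in the phosphate flag plus noise.  Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `replicates` (a [replicate_table()] of taxon counts and
#'   chemical measurements), `traits` (per-plot trait table) and `truth`
#'   (ground-truth labels: cluster, trait link sign, stage association,
#'   chemical effect table, seed).
#' @export
generate_study <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_taxa
    sigma <- cfg$taxa_log_sd
    cluster <- rep(1:3, times = cfg$cluster_sizes)
    favored <- c("N", "plain", "compost")[cluster]
    mu <- stats::rnorm(n, 0, cfg$base_log_sd)

    special <- sample.int(n, cfg$n_trait_taxa + cfg$n_ripening + cfg$n_flowering)
    trait_taxa <- special[seq_len(cfg$n_trait_taxa)]
    ripening_taxa <- special[cfg$n_trait_taxa + seq_len(cfg$n_ripening)]
    flowering_taxa <- special[cfg$n_trait_taxa + cfg$n_ripening +
                                seq_len(cfg$n_flowering)]
    # special taxa get at least an average baseline so their signal is not
    # drowned in count noise
    mu[special] <- pmax(mu[special], 0)
    trait_sign <- rep(1, cfg$n_trait_taxa)
    n_neg <- round(cfg$prop_trait_negative * cfg$n_trait_taxa)
    if (n_neg > 0) trait_sign[seq_len(n_neg)] <- -1
    trait_sign <- sample(trait_sign)
    # per-taxon magnitudes form a gradient rather than a coherent block, so
    # trait-linked taxa do not masquerade as a fourth abundance cluster;
    # the rest of the community carries a weak diffuse phosphate response
    # (real communities respond as a continuum, the flagged contributors
    # being its strong tail)
    trait_mag <- stats::runif(cfg$n_trait_taxa, 0.85, 1.15) * cfg$trait_effect
    p_background <- stats::rnorm(n, 0, cfg$trait_background * sigma)
    p_background[special] <- 0

    samples <- expand.grid(replicate = seq_len(N_REPLICATES),
                           stage = STAGE_LEVELS, plot = PLOT_LEVELS,
                           stringsAsFactors = FALSE)
    samples <- samples[, c("plot", "stage", "replicate")]
    samples$sample <- paste(samples$plot, samples$stage, samples$replicate,
                            sep = "_")
    ns <- nrow(samples)

    counts <- matrix(0L, n, ns)
    chem <- matrix(NA_real_, length(CHEMICAL_NAMES), ns,
                   dimnames = list(CHEMICAL_NAMES, samples$sample))
    for (j in seq_len(ns)) {
      p <- samples$plot[j]; st <- samples$stage[j]
      eta <- mu + cfg$effect_size * cfg$base_log_sd * (favored == plot_group(p))
      pflag <- plot_flags(p)$P
      if (pflag) {
        eta <- eta + p_background
        if (cfg$n_trait_taxa > 0) {
          eta[trait_taxa] <- eta[trait_taxa] + trait_mag * sigma * trait_sign
        }
      }
      ord <- stage_ordinal(st)
      if (ord >= 3 && cfg$n_ripening > 0) {          # R and H
        eta[ripening_taxa] <- eta[ripening_taxa] + cfg$stage_shift
      }
      if (ord == 2 && cfg$n_flowering > 0) {         # F only
        eta[flowering_taxa] <- eta[flowering_taxa] + cfg$stage_shift
      }
      eta <- eta + stats::rnorm(n, 0, sigma)
      rate <- exp(eta)
      lib <- max(1000, round(stats::rnorm(1, cfg$library_size, cfg$library_sd)))
      counts[, j] <- stats::rpois(n, lib * rate / sum(rate))

      for (k in seq_along(CHEMICAL_NAMES)) {
        cm <- chem_cell_mean(CHEMICAL_NAMES[k], p, st, cfg)
        sdv <- .CHEM_MODEL$cv[k] * .CHEM_MODEL$baseline[k]
        chem[k, j] <- max(0, stats::rnorm(1, cm, sdv))
      }
    }

    taxon_ids <- sprintf("taxon%03d", seq_len(n))
    # a small synthetic lineage: phyla shared within clusters so taxonomy
    # summaries have structure to count
    phylum <- paste0("Phylum", ((seq_len(n) - 1) %% 12) + 1)
    genus <- ifelse(seq_len(n) %% 7 == 0, "",
                    paste0("Genus", ((seq_len(n) - 1) %% 150) + 1))
    features <- data.frame(
      id = c(taxon_ids, CHEMICAL_NAMES),
      kind = c(rep("taxon", n), rep("chemical", length(CHEMICAL_NAMES))),
      phylum = c(phylum, rep(NA, length(CHEMICAL_NAMES))),
      genus = c(genus, rep(NA, length(CHEMICAL_NAMES))),
      stringsAsFactors = FALSE)
    values <- rbind(counts, chem)
    rt <- replicate_table(features, samples, values)

    pfl <- plot_flags(PLOT_LEVELS)$P
    noise <- function(s) stats::rnorm(length(PLOT_LEVELS), 0, s)
    traits <- data.frame(
      plot = PLOT_LEVELS,
      height_23DAS = 30 + 20 * pfl + noise(1.5),
      height_71DAS = 80 + 40 * pfl + noise(4),
      stem_leaf_yield = 300 + 250 * pfl + noise(20),
      seed_yield = 80 + 70 * pfl + noise(6),
      stringsAsFactors = FALSE)

    stage_assoc <- rep(NA_character_, n)
    stage_assoc[ripening_taxa] <- "R"
    stage_assoc[flowering_taxa] <- "F"
    truth <- list(
      cluster = stats::setNames(cluster, taxon_ids),
      trait_taxa = taxon_ids[trait_taxa],
      trait_sign = stats::setNames(trait_sign, taxon_ids[trait_taxa]),
      stage_assoc = stats::setNames(stage_assoc, taxon_ids),
      chemical_effects = data.frame(
        chemical = c("pH", "TOC"),
        effect = c(cfg$ph_offset, cfg$toc_offset),
        where = c("N plots", "NP/NPK/C plots")),
      seed = cfg$seed)
    list(replicates = rt, traits = traits, truth = truth, config = cfg)
  })
}

#' Generate small graph fixtures with known structure
#'
#' Emits an edge list plus the expected structure used to validate the
#' network algorithms: complete graphs, paths, stars, Erdos-Renyi draws and
#' planted-clique instances.  For graphs with at most 15 nodes the exact
#' maximum clique from exhaustive subset search is included.
#'
#' @param kind one of `"k_complete"`, `"path"`, `"star"`, `"random_gnp"`,
#'   `"planted_clique"`.
#' @param n number of nodes (planted-clique instances require `n <= 200`).
#' @param p edge probability (`random_gnp`, and background of
#'   `planted_clique`).
#' @param clique_size planted clique size.
#' @param seed RNG seed for the random kinds.
#' @return list with `n`, `edges` (2-column matrix of 1-based node indices)
#'   and `expected` (structure depending on `kind`; includes `max_clique`
#'   for `n <= 15`).
#' @export
generate_network_testcase <- function(kind = c("k_complete", "path", "star",
                                               "random_gnp", "planted_clique"),
                                      n = 5L, p = 0.3, clique_size = 4L,
                                      seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  adj <- matrix(FALSE, n, n)
  expected <- list()
  if (kind == "k_complete") {
    adj[upper.tri(adj)] <- TRUE
    expected$max_clique_size <- n
  } else if (kind == "path") {
    for (i in seq_len(n - 1)) adj[i, i + 1] <- TRUE
    b <- numeric(n)
    if (n >= 3) for (v in 2:(n - 1)) b[v] <- (v - 1) * (n - v)
    expected$betweenness <- b
  } else if (kind == "star") {
    if (n >= 2) for (i in 2:n) adj[1, i] <- TRUE
    expected$betweenness <- c(choose(n - 1, 2), numeric(n - 1))
  } else if (kind == "random_gnp") {
    with_seed(seed, {
      adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
    })
  } else if (kind == "planted_clique") {
    if (n > 200L) stop("planted-clique instances require n <= 200")
    with_seed(seed, {
      adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
      members <- sample.int(n, clique_size)
      for (i in members) for (j in members) if (i < j) adj[i, j] <- TRUE
      expected$planted <- sort(members)
    })
  }
  adj <- adj | t(adj)
  if (n <= 15L) expected$max_clique <- max_clique_exhaustive(adj)
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  colnames(edges) <- c("from", "to")
  list(n = n, edges = edges, adjacency = adj, expected = expected)
}

#' Exact maximum clique by exhaustive subset search
#'
#' Enumerates node subsets by decreasing size and returns the first complete
#' one.  Intended for small oracle graphs only.
#'
#' @param adj logical adjacency matrix (undirected, no self loops).
#' @return integer vector of clique member indices.
#' @export
max_clique_exhaustive <- function(adj) {
  n <- nrow(adj)
  if (n > 20L) stop("exhaustive search limited to n <= 20")
  if (n == 0L) return(integer())
  for (k in n:1) {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      s <- combos[, ci]
      sub <- adj[s, s, drop = FALSE]
      if (all(sub[upper.tri(sub)])) return(s)
    }
  }
  integer()
}
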