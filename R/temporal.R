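TRANSITIONS <- c("A", "F", "R", "H")   # each vs its preceding stage

#' Stage-to-stage frequency differences
#'
#' For taxon x, plot p and cultivation stage n, the temporal difference is
#' `delta_f = f_xpn - f_xp(n-1)` over the four transitions B->A, A->F,
#' F->R, R->H.  Given a `replicate_table` a replicate-level variant is also
#' produced, pairing batches by index within each plot (a labeling
#' convention; batches are independent soil samples).
#'
#' @param x a `median_matrix` of relative frequencies, or a
#'   [replicate_table()] of raw taxon counts (converted internally).
#' @return object of class `delta_f`: `median` array
#'   (taxa x 6 plots x 4 transitions) and, for replicate input,
#'   `replicate` array (taxa x plots x transitions x 4 batches).
#' @export
delta_f <- function(x) {
  if (inherits(x, "replicate_table")) {
    rt <- to_relative_frequency(x)
    mm <- filter_absent_features(aggregate_medians(rt))
    med <- delta_f_from_median(mm)
    tax_ids <- dimnames(med)[[1]]
    tax <- rt$features$id %in% tax_ids
    rep_arr <- array(NA_real_,
                     dim = c(length(tax_ids), length(PLOT_LEVELS),
                             length(TRANSITIONS), N_REPLICATES),
                     dimnames = list(tax_ids, PLOT_LEVELS, TRANSITIONS,
                                     seq_len(N_REPLICATES)))
    key <- paste(rt$samples$plot, rt$samples$stage, rt$samples$replicate,
                 sep = "_")
    for (p in PLOT_LEVELS) {
      for (ti in seq_along(TRANSITIONS)) {
        st <- STAGE_LEVELS[ti + 1L]; prev <- STAGE_LEVELS[ti]
        for (b in seq_len(N_REPLICATES)) {
          j1 <- match(paste(p, st, b, sep = "_"), key)
          j0 <- match(paste(p, prev, b, sep = "_"), key)
          if (is.na(j1) || is.na(j0)) next
          rep_arr[, p, ti, b] <- rt$values[tax, j1] - rt$values[tax, j0]
        }
      }
    }
    return(structure(list(median = med, replicate = rep_arr),
                     class = "delta_f"))
  }
  structure(list(median = delta_f_from_median(x), replicate = NULL),
            class = "delta_f")
}

delta_f_from_median <- function(m) {
  stopifnot(inherits(m, "median_matrix"))
  tax <- m$features$kind == "taxon"
  vals <- m$values[tax, , drop = FALSE]
  cells <- parse_cell_ids(colnames(vals))
  arr <- array(NA_real_,
               dim = c(nrow(vals), length(PLOT_LEVELS), length(TRANSITIONS)),
               dimnames = list(rownames(vals), PLOT_LEVELS, TRANSITIONS))
  for (p in PLOT_LEVELS) {
    for (ti in seq_along(TRANSITIONS)) {
      st <- STAGE_LEVELS[ti + 1L]; prev <- STAGE_LEVELS[ti]
      j1 <- which(cells$plot == p & cells$stage == st)
      j0 <- which(cells$plot == p & cells$stage == prev)
      if (!length(j1) || !length(j0) ||
          all(is.na(vals[, j1])) || all(is.na(vals[, j0]))) {
        stop("missing stage ", if (!length(j1) || all(is.na(vals[, j1])))
          st else prev, " for plot ", p)
      }
      arr[, p, ti] <- vals[, j1] - vals[, j0]
    }
  }
  arr
}

#' @export
print.delta_f <- function(x, ...) {
  d <- dim(x$median)
  cat("delta_f:", d[1], "taxa x", d[2], "plots x", d[3], "transitions",
      if (!is.null(x$replicate)) "(replicate-level available)" else "", "\n")
  invisible(x)
}

#' Ordination of temporal difference profiles
#'
#' PCA of the 24 (plot, transition) observations over taxa, plus a
#' PERMANOVA (Euclidean) testing the ripening transition against all
#' others.
#'
#' @param d a [delta_f()] result.
#' @param n_perm,seed PERMANOVA permutations and seed.
#' @return list: `pca` (a [pca()] result with observations named
#'   `plot.transition`), `permanova` (R vs other transitions),
#'   `observations` (data frame of plot/transition per row).
#' @export
pca_delta <- function(d, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(d, "delta_f"))
  arr <- d$median
  obs <- expand.grid(plot = PLOT_LEVELS, transition = TRANSITIONS,
                     stringsAsFactors = FALSE)
  mat <- t(vapply(seq_len(nrow(obs)),
                  function(i) arr[, obs$plot[i], obs$transition[i]],
                  numeric(dim(arr)[1])))
  rownames(mat) <- paste(obs$plot, obs$transition, sep = ".")
  res <- pca(mat)
  pm <- permanova(mat, labels = obs$transition == "R",
                  n_perm = n_perm, seed = seed)
  list(pca = res, permanova = pm, observations = obs)
}

#' Select cultivation-stage-associated taxa
#'
#' A taxon is associated with a transition when (i) its median-level
#' delta-f is positive in all six plots at that transition and (ii) a
#' t-test of its delta-f values against zero rejects at `alpha`.  With
#' replicate-level data the test pools the 6 plots x 4 batches = 24 values
#' (two-sided one-sample t); with `mode = "median"` the six plot medians
#' are tested instead.  Taxa with zero-variance delta-f vectors cannot be
#' tested and are excluded with a note.
#'
#' @param d a [delta_f()] result (replicate-level required for the default
#'   mode).
#' @param alpha significance level.
#' @param mode `"replicate"` (default) or `"median"`.
#' @return list of class `stage_taxa`: per-transition character vectors of
#'   selected taxa, `skipped` (zero-variance taxa), `alpha`, `mode`.
#' @export
stage_associated_taxa <- function(d, alpha = 0.05,
                                  mode = c("replicate", "median")) {
  stopifnot(inherits(d, "delta_f"))
  mode <- match.arg(mode)
  if (mode == "replicate" && is.null(d$replicate)) {
    stop("replicate-level delta-f not available; use mode = 'median'")
  }
  taxa <- dimnames(d$median)[[1]]
  sel <- list(); skipped <- character()
  for (ti in seq_along(TRANSITIONS)) {
    hits <- character()
    for (x in taxa) {
      med <- d$median[x, , ti]
      if (any(is.na(med)) || any(med <= 0)) next
      v <- if (mode == "replicate") as.vector(d$replicate[x, , ti, ]) else med
      v <- v[!is.na(v)]
      if (length(v) < 2 || stats::sd(v) == 0) {
        skipped <- union(skipped, x)
        next
      }
      p <- stats::t.test(v, mu = 0)$p.value
      if (p < alpha) hits <- c(hits, x)
    }
    sel[[TRANSITIONS[ti]]] <- hits
  }
  structure(sel, class = "stage_taxa", skipped = skipped, alpha = alpha,
            mode = mode)
}

#' @export
print.stage_taxa <- function(x, ...) {
  cat("stage_taxa (mode", attr(x, "mode"), ", alpha", attr(x, "alpha"), "):\n")
  for (tr in names(x)) cat(" ", tr, ":", length(x[[tr]]), "taxa\n")
  invisible(x)
}
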