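#' Principal component analysis by singular value decomposition
#'
#' Observations in rows, variables in columns.  Variables are centered (no
#' further scaling; upstream standardization already sets the variance
#' scale).  Eigenvalues are the per-component variances `d_k^2 / (n - 1)`;
#' eigenvectors are unit length with the sign fixed so each component's
#' largest-magnitude loading is positive, making runs reproducible.
#'
#' @param x numeric matrix, observations x variables (>= 2 observations).
#' @param center center columns before decomposition.
#' @return list of class `pca_result`: `eigenvalues`, `loadings`
#'   (variables x components), `scores` (observations x components),
#'   `prop_var`, `center`.
#' @export
pca <- function(x, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 observations")
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  ev <- d^2 / (n - 1)
  scores <- u %*% diag(d, k, k)
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  structure(list(eigenvalues = ev, loadings = v, scores = scores,
                 prop_var = ev / sum(ev), center = ctr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("pca_result:", nrow(x$scores), "observations,", nrow(x$loadings),
      "variables\n  prop. variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$prop_var[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' PCA of a standardized feature matrix
#'
#' Convenience wrapper: the 30 plot-stage cells become observations and the
#' selected features become variables (the orientation used for community
#' ordination).
#'
#' @param m a `standardized_matrix`.
#' @param kind which feature kind to use (`"taxon"`, `"chemical"`, or
#'   `"all"`).
#' @return a [pca()] result.
#' @export
community_pca <- function(m, kind = "taxon") {
  stopifnot(inherits(m, "median_matrix"))
  rows <- if (kind == "all") rep(TRUE, nrow(m$values)) else
    m$features$kind == kind
  pca(t(m$values[rows, , drop = FALSE]))
}

#' Load-quantity contributor scores for a principal component
#'
#' For component `a`, the load quantity of variable `i` is
#' `LQ_i = sqrt(l_a) * h_ai` (square-rooted eigenvalue times loading); z-LQ
#' standardizes LQ over the variables, and contributors are flagged where
#' `|z-LQ| > cutoff` (2.33 by default).  The cumulative contribution share
#' of the flagged set is reported both as a share of `sum |LQ|` and of
#' `sum LQ^2`.
#'
#' When `orient` is supplied (a per-observation covariate such as the plot's
#' seed yield), the axis is first oriented so its score correlation with the
#' covariate is positive, which makes "positive contributor" mean
#' trait-aligned.
#'
#' @param p a [pca()] result.
#' @param axis component index (default 3).
#' @param cutoff z-LQ threshold for contributor flags.
#' @param orient optional numeric covariate, one value per observation.
#' @return list of class `load_quantity`: data frame `table` (variable, lq,
#'   z_lq, flag), `share_abs`, `share_sq`, `axis`, `cutoff`.
#' @export
load_quantity <- function(p, axis = 3L, cutoff = 2.33, orient = NULL) {
  stopifnot(inherits(p, "pca_result"))
  if (axis > length(p$eigenvalues)) {
    stop("axis ", axis, " beyond rank ", length(p$eigenvalues))
  }
  h <- p$loadings[, axis]
  s <- p$scores[, axis]
  if (!is.null(orient)) {
    if (length(orient) != length(s)) stop("orient length must match scores")
    if (stats::cor(s, orient) < 0) { h <- -h; s <- -s }
  }
  lq <- sqrt(p$eigenvalues[axis]) * h
  z <- (lq - mean(lq)) / stats::sd(lq)
  flag <- ifelse(z > cutoff, "positive",
                 ifelse(z < -cutoff, "negative", "none"))
  sel <- flag != "none"
  structure(list(
    table = data.frame(variable = names(h) %||% seq_along(h),
                       lq = unname(lq), z_lq = unname(z), flag = flag,
                       stringsAsFactors = FALSE),
    share_abs = sum(abs(lq[sel])) / sum(abs(lq)),
    share_sq = sum(lq[sel]^2) / sum(lq^2),
    axis = axis, cutoff = cutoff, scores = s),
    class = "load_quantity")
}

#' Fit an ordination vector for an environmental variable
#'
#' Projects a variable onto a plane of two ordination score axes: the
#' direction is the normalized least-squares coefficient vector of the
#' variable on the two (centered) axes, `r^2 = 1 - RSS/TSS`, and the
#' p-value is estimated by permuting the variable,
#' `p = (1 + #{r2_perm >= r2_obs}) / (1 + n_perm)`.
#'
#' @param scores numeric matrix with two columns (score axes).
#' @param variable numeric vector, one value per observation.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `vector_fit`: `direction` (unit 2-vector), `r2`,
#'   `p`, `n_perm`, `seed`.
#' @export
fit_ordination_vector <- function(scores, variable, n_perm = 999L, seed = 1L) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly two columns")
  if (length(variable) != nrow(scores)) {
    stop("variable length must match observations")
  }
  if (stats::sd(variable) == 0) stop("zero-variance variable")
  xc <- sweep(scores, 2L, colMeans(scores))
  qr_x <- qr(xc)
  r2_of <- function(v) {
    vc <- v - mean(v)
    fit <- qr.fitted(qr_x, vc)
    sum(fit^2) / sum(vc^2)
  }
  r2 <- r2_of(variable)
  beta <- qr.coef(qr_x, variable - mean(variable))
  beta[is.na(beta)] <- 0
  dir <- beta / sqrt(sum(beta^2))
  with_seed(seed, {
    r2_perm <- vapply(seq_len(n_perm),
                      function(i) r2_of(sample(variable)), 0)
  })
  structure(list(direction = dir, r2 = r2,
                 p = (1 + sum(r2_perm >= r2)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "vector_fit")
}

#' Correlate a per-plot statistic with plant traits
#'
#' Pearson correlation (with t-based two-sided p) between a per-plot value,
#' such as an averaged ordination score, and each trait column.  When `x`
#' has one value per plot-stage cell it is averaged within plots first.
#'
#' @param x named numeric vector: one value per plot, or one per
#'   `PLOT_STAGE` cell.
#' @param traits trait table with a `plot` column (see
#'   [generate_study()]).
#' @return data frame: trait, r, p, plus the mean and sd of r across traits
#'   as attributes `mean_r` / `sd_r`.
#' @export
correlate_traits <- function(x, traits) {
  if (is.null(names(x))) stop("x must be named by plot or cell")
  if (all(names(x) %in% PLOT_LEVELS)) {
    per_plot <- x
  } else {
    cells <- parse_cell_ids(names(x))
    per_plot <- tapply(x, factor(cells$plot, levels = PLOT_LEVELS), mean)
  }
  per_plot <- per_plot[traits$plot]
  trait_cols <- setdiff(names(traits), "plot")
  res <- lapply(trait_cols, function(tc) {
    ct <- correlation_test(as.numeric(per_plot), traits[[tc]])
    data.frame(trait = tc, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "mean_r") <- mean(out$r)
  attr(out, "sd_r") <- stats::sd(out$r)
  out
}

#' Compare trait correlations of flagged contributors against other taxa
#'
#' Each taxon's standardized frequency profile is averaged per plot and
#' correlated with every trait over the six plots; the distributions of
#' these per-taxon correlations are then compared between flagged
#' contributors and the remaining taxa with the variance-gated two-sample
#' t-test, separately for positive and negative contributors.
#'
#' @param lq a [load_quantity()] result over taxa.
#' @param m the `standardized_matrix` the PCA ran on.
#' @param traits trait table with a `plot` column.
#' @return data frame: trait, group (`positive`/`negative`), `n_group`,
#'   `mean_r_group`, `mean_r_others`, `t`, `p` (NA with a warning for
#'   degenerate groups).
#' @export
contributor_trait_test <- function(lq, m, traits) {
  stopifnot(inherits(lq, "load_quantity"), inherits(m, "median_matrix"))
  ids <- lq$table$variable
  vals <- m$values[ids, , drop = FALSE]
  cells <- parse_cell_ids(colnames(vals))
  plot_f <- factor(cells$plot, levels = PLOT_LEVELS)
  per_plot <- t(apply(vals, 1L, function(v) tapply(v, plot_f, mean)))
  trait_cols <- setdiff(names(traits), "plot")
  ord <- match(PLOT_LEVELS, traits$plot)

  out <- list()
  for (tc in trait_cols) {
    tv <- traits[[tc]][ord]
    r_taxon <- apply(per_plot, 1L, function(v) {
      if (stats::sd(v) == 0) NA_real_ else stats::cor(v, tv)
    })
    for (grp in c("positive", "negative")) {
      in_grp <- lq$table$flag == grp
      others <- lq$table$flag == "none"
      rg <- r_taxon[in_grp]; ro <- r_taxon[others]
      rg <- rg[!is.na(rg)]; ro <- ro[!is.na(ro)]
      if (length(rg) < 2 || length(ro) < 2) {
        warning("group '", grp, "' too small for trait '", tc,
                "'; test skipped")
        tt <- list(t = NA_real_, p = NA_real_)
      } else {
        tt <- two_sample_t(rg, ro)
      }
      out[[length(out) + 1L]] <- data.frame(
        trait = tc, group = grp, n_group = length(rg),
        mean_r_group = mean(rg), mean_r_others = mean(ro),
        t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
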