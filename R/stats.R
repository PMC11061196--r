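#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on Euclidean distances via the sums-of-squares
#' partition from pairwise squared distances:
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and
#' pseudo-F `= (SS_between/(a-1)) / (SS_within/(N-a))`.
#' The p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` under random
#' permutation of the group labels.
#'
#' @param points numeric matrix, observations x features (or a `dist`
#'   object).
#' @param labels grouping vector, length = number of observations, at least
#'   two groups.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list of class `permanova_result`: `f`, `r2`, `p`, `n_perm`,
#'   `seed`, `group_sizes`, `ss` (between/within/total).
#' @export
permanova <- function(points, labels, n_perm = 999L, seed = 1L) {
  if (inherits(points, "dist")) {
    d2 <- as.matrix(points)^2
  } else {
    points <- as.matrix(points)
    d2 <- as.matrix(stats::dist(points))^2
  }
  labels <- as.factor(labels)
  N <- nrow(d2)
  if (length(labels) != N) stop("labels length must match observations")
  a <- nlevels(droplevels(labels))
  if (a < 2) stop("need at least two groups")
  labels <- droplevels(labels)

  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_w <- function(lab) {
    s <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      if (length(idx) > 1) {
        sub <- d2[idx, idx, drop = FALSE]
        s <- s + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_w(lab)
    ssb <- ss_total - ssw
    if (ssw == 0) return(if (ssb <= 0) 0 else Inf)
    (ssb / (a - 1)) / (ssw / (N - a))
  }
  f_obs <- f_stat(labels)
  ssw_obs <- ss_w(labels)

  with_seed(seed, {
    f_perm <- vapply(seq_len(n_perm),
                     function(i) f_stat(sample(labels)), 0)
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(list(f = f_obs, r2 = (ss_total - ssw_obs) / ss_total, p = p,
                 n_perm = n_perm, seed = seed,
                 group_sizes = table(labels),
                 ss = c(between = ss_total - ssw_obs, within = ssw_obs,
                        total = ss_total)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.3f, p = %.4g (%d perms)\n",
              x$f, x$r2, x$p, x$n_perm))
  invisible(x)
}

#' Tukey-Kramer all-pairs comparison with compact letter display
#'
#' One-way pooled-variance layout; pairwise adjusted p-values use the
#' studentized range distribution with the Tukey-Kramer unequal-n
#' correction, `q = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))`.  Letters are
#' assigned so that groups sharing a letter are not significantly different
#' at `alpha` (a clique cover of the non-significance graph, ordered by
#' descending group mean).
#'
#' @param groups named list of numeric samples (>= 2 groups).
#' @param alpha significance level for the letter display.
#' @return list of class `tukey_result`: `pairs` (data frame with adjusted
#'   p), `letters` (named character vector), `means`, `mse`, `df`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  df <- sum(n) - k
  if (df < 1) stop("no residual degrees of freedom (all groups of size 1)")
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df

  idx <- utils::combn(k, 2)
  pair_p <- numeric(ncol(idx))
  for (c1 in seq_len(ncol(idx))) {
    i <- idx[1, c1]; j <- idx[2, c1]
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(means[i] - means[j]) / se
    pair_p[c1] <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  pairs <- data.frame(group1 = names(groups)[idx[1, ]],
                      group2 = names(groups)[idx[2, ]],
                      diff = means[idx[1, ]] - means[idx[2, ]],
                      p_adj = pair_p, stringsAsFactors = FALSE)

  letters <- cld_letters(names(groups), means, pairs, alpha)
  structure(list(pairs = pairs, letters = letters, means = means,
                 mse = mse, df = df, alpha = alpha),
            class = "tukey_result")
}

# compact letter display: maximal cliques of the non-significance graph,
# lettered in order of the highest group mean they contain
cld_letters <- function(nms, means, pairs, alpha) {
  k <- length(nms)
  adj <- matrix(TRUE, k, k, dimnames = list(nms, nms))
  sig <- pairs$p_adj < alpha
  for (r in which(sig)) {
    adj[pairs$group1[r], pairs$group2[r]] <- FALSE
    adj[pairs$group2[r], pairs$group1[r]] <- FALSE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(x) nms[as.integer(x)])
  rank_of <- rank(-means, ties.method = "first")
  cl <- cl[order(vapply(cl, function(x) min(rank_of[x]), 0))]
  letters_out <- stats::setNames(rep("", k), nms)
  for (i in seq_along(cl)) {
    lab <- make_letter(i)
    letters_out[cl[[i]]] <- paste0(letters_out[cl[[i]]], lab)
  }
  letters_out
}

make_letter <- function(i) {
  if (i <= 26) letters[i] else paste0(letters[(i - 1) %/% 26], letters[(i - 1) %% 26 + 1])
}

#' Two-sample t-test with F-test variance gate
#'
#' Homoscedasticity is first assessed with the variance-ratio F-test; when
#' the F-test does not reject at `gate_alpha` the pooled-variance Student
#' t-test is used, otherwise the Welch-Satterthwaite unequal-variance
#' t-test.  Both sub-results are reported alongside the gated choice.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param gate_alpha significance level of the variance gate.
#' @return list of class `gated_t_result`: `t`, `df`, `p`, `method`,
#'   `f_test`, `student`, `welch`.
#' @export
two_sample_t <- function(x, y, gate_alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both samples")
  }
  f <- stats::var.test(x, y)
  student <- stats::t.test(x, y, var.equal = TRUE)
  welch <- stats::t.test(x, y, var.equal = FALSE)
  pick <- if (f$p.value >= gate_alpha) student else welch
  structure(list(t = unname(pick$statistic), df = unname(pick$parameter),
                 p = pick$p.value,
                 method = if (f$p.value >= gate_alpha) "student" else "welch",
                 f_test = list(f = unname(f$statistic), p = f$p.value),
                 student = list(t = unname(student$statistic),
                                p = student$p.value),
                 welch = list(t = unname(welch$statistic),
                              p = welch$p.value)),
            class = "gated_t_result")
}

#' Pearson correlation test
#'
#' Pearson r with the two-sided t-based test,
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, finite values.
#' @return list with `r`, `t`, `df`, `p`, `n`.
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = r, t = Inf * sign(r), df = n - 2, p = 0, n = n))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, t = t, df = n - 2, p = p, n = n)
}
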