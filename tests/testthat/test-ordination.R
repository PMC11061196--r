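test_that("PCA reproduces closed-form eigenstructure", {
  # perfectly collinear features: one component carries all variance
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  p <- pca(x)
  expect_equal(p$prop_var[1], 1, tolerance = 1e-12)

  set.seed(4)
  y <- matrix(rnorm(3 * 2), 3, 2)
  p2 <- pca(y)
  ev <- eigen(cov(y))$values          # brute-force 2x2 eigendecomposition
  expect_equal(p2$eigenvalues, ev[ev > 1e-12], tolerance = 1e-10)
  expect_equal(sqrt(colSums(p2$loadings^2)), c(PC1 = 1, PC2 = 1),
               tolerance = 1e-10)
  expect_error(pca(y[1, , drop = FALSE]), "2 observations")
})

test_that("PCA conserves variance and reconstructs the input", {
  set.seed(6)
  x <- matrix(rnorm(12 * 7), 12, 7)
  p <- pca(x)
  expect_equal(sum(p$eigenvalues), sum(diag(cov(x))), tolerance = 1e-8)
  xc <- scale(x, scale = FALSE)
  expect_equal(unname(p$scores), unname(xc %*% p$loadings), tolerance = 1e-8)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, xc, tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormal loadings
  expect_equal(unname(t(p$loadings) %*% p$loadings),
               diag(ncol(p$loadings)), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading of each axis is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("load quantities follow LQ = sqrt(eigenvalue) * loading", {
  fake <- structure(list(
    eigenvalues = c(3, 2, 1),
    loadings = matrix(c(0.6, 0.8, 0, 0.8, -0.6, 0, 0, 0, 1), 3, 3,
                      dimnames = list(c("t1", "t2", "t3"), NULL)),
    scores = matrix(rnorm(9), 3, 3)), class = "pca_result")
  lq <- load_quantity(fake, axis = 3)
  expect_equal(lq$table$lq, sqrt(1) * c(0, 0, 1))
  fake$eigenvalues <- c(8, 5, 4)
  lq2 <- load_quantity(fake, axis = 3)
  expect_equal(lq2$table$lq, sqrt(4) * c(0, 0, 1))   # sqrt(4) * 0.5-style
  expect_equal(mean(lq2$table$z_lq), 0, tolerance = 1e-12)
  expect_equal(sd(lq2$table$z_lq), 1, tolerance = 1e-12)
  expect_error(load_quantity(fake, axis = 7), "beyond rank")
})

test_that("load quantity is scale-equivariant and z-LQ invariant", {
  set.seed(11)
  x <- matrix(rnorm(10 * 6), 10, 6)
  l1 <- load_quantity(pca(x), axis = 2)
  l2 <- load_quantity(pca(3 * x), axis = 2)
  expect_equal(l2$table$lq, 3 * l1$table$lq, tolerance = 1e-8)
  expect_equal(l2$table$z_lq, l1$table$z_lq, tolerance = 1e-8)
})

test_that("contributor selection recovers planted trait-linked taxa", {
  # twenty strong planted responders over a weak diffuse background
  study <- generate_study(synthetic_config(n_trait_taxa = 20L,
                                           prop_trait_negative = 0.35,
                                           trait_effect = 4.5,
                                           trait_background = 0.15,
                                           seed = 1))
  rel <- to_relative_frequency(study$replicates)
  sm <- standardize_features(filter_absent_features(aggregate_medians(rel)))
  pc <- community_pca(sm)
  cells <- parse_cells <- sub("_[A-Z]$", "", rownames(pc$scores))
  orient <- study$traits$seed_yield[match(cells, study$traits$plot)]
  lq <- load_quantity(pc, orient = orient)
  flagged <- lq$table$variable[lq$table$flag != "none"]
  planted <- study$truth$trait_taxa
  expect_gte(length(intersect(flagged, planted)) / length(flagged), 0.8)
  # signs match the planted direction for the recovered taxa
  rec <- intersect(flagged, planted)
  got <- lq$table$flag[match(rec, lq$table$variable)]
  expect_gt(mean((got == "positive") ==
                   (study$truth$trait_sign[rec] > 0)), 0.9)
})

test_that("ordination vectors recover exact and null relationships", {
  set.seed(2)
  sc <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("PC1", "PC2")))
  fit <- fit_ordination_vector(sc, sc[, 1], n_perm = 99, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(abs(fit$direction), c(PC1 = 1, PC2 = 0), tolerance = 1e-8)
  expect_error(fit_ordination_vector(sc, rep(1, 30)), "zero-variance")

  # independent noise: p rarely small
  ps <- vapply(1:50, function(i) {
    set.seed(100 + i)
    v <- rnorm(30)
    fit_ordination_vector(sc, v, n_perm = 199, seed = i)$p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("vector-fit p matches exhaustive permutation enumeration", {
  set.seed(13)
  sc <- matrix(rnorm(12), 6, 2)
  v <- rnorm(6)
  xc <- sweep(sc, 2, colMeans(sc))
  r2_of <- function(vv) {
    vc <- vv - mean(vv)
    fit <- qr.fitted(qr(xc), vc)
    sum(fit^2) / sum(vc^2)
  }
  perms <- function(x) {
    if (length(x) == 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) for (r in perms(x[-i])) out <- c(out, list(c(x[i], r)))
    out
  }
  all_r2 <- vapply(perms(v), r2_of, 0)
  p_exact <- mean(all_r2 >= r2_of(v) - 1e-12)
  fit <- fit_ordination_vector(sc, v, n_perm = 4999, seed = 2)
  expect_lt(abs(fit$p - p_exact), 0.03)
})

test_that("vector-fit p-values are uniform under the null", {
  set.seed(17)
  sc <- matrix(rnorm(60), 30, 2)
  ps <- vapply(1:400, function(i) {
    fit_ordination_vector(sc, rnorm(30), n_perm = 99, seed = i)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("trait correlations behave at the exact extremes", {
  traits <- data.frame(plot = PLOT_LEVELS,
                       seed_yield = c(3, 9, 2, 8, 10, 4))
  x <- setNames(traits$seed_yield, traits$plot)
  res <- correlate_traits(x, traits)
  expect_equal(res$r[res$trait == "seed_yield"], 1)
  res2 <- correlate_traits(-x, traits)
  expect_equal(res2$r[res2$trait == "seed_yield"], -1)
})

test_that("contributor trait tests separate planted contributors", {
  study <- default_study()
  sm <- default_standardized()
  pc <- community_pca(sm)
  cells <- sub("_[A-Z]$", "", rownames(pc$scores))
  orient <- study$traits$seed_yield[match(cells, study$traits$plot)]
  lq <- load_quantity(pc, orient = orient)
  res <- contributor_trait_test(lq, sm, study$traits)
  pos <- res[res$trait == "seed_yield" & res$group == "positive", ]
  expect_gt(pos$mean_r_group, pos$mean_r_others)
  expect_lt(pos$p, 0.01)
  neg <- res[res$trait == "seed_yield" & res$group == "negative", ]
  expect_lt(neg$mean_r_group, neg$mean_r_others)

  # degenerate group: a single flagged taxon is skipped with a warning
  lq_small <- lq
  lq_small$table$flag <- "none"
  lq_small$table$flag[1] <- "positive"
  w <- testthat::capture_warnings(
    res_s <- contributor_trait_test(lq_small, sm, study$traits))
  expect_true(any(grepl("skipped", w)))
  expect_true(all(is.na(res_s$p[res_s$group == "positive"])))
})
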