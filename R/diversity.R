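#' Expected rarefied richness
#'
#' The expected number of taxa observed in a random subsample of `depth`
#' reads drawn without replacement:
#' \deqn{E[S_d] = \sum_i \left(1 - \binom{N-N_i}{d} / \binom{N}{d}\right)}
#' computed with log-gamma terms for numerical stability.
#'
#' @param counts non-negative integer taxon totals.
#' @param depth subsample depth, `0 <= depth <= sum(counts)`.
#' @return expected richness (real).
#' @export
expected_richness <- function(counts, depth) {
  stopifnot(all(counts >= 0))
  N <- sum(counts)
  if (depth < 0 || depth > N) stop("depth must be in [0, ", N, "]")
  if (depth == 0) return(0)
  ni <- counts[counts > 0]
  # log C(N-ni, d) - log C(N, d); taxa with N - ni < d are always seen
  ratio <- ifelse(N - ni < depth, 0,
                  exp(lchoose(N - ni, depth) - lchoose(N, depth)))
  sum(1 - ratio)
}

#' Slope of the rarefaction curve
#'
#' The discrete slope `E[S_depth] - E[S_depth - 1]` of the expected-richness
#' curve; used as a coverage diagnostic (a small slope means additional reads
#' discover almost no new taxa).
#'
#' @inheritParams expected_richness
#' @return non-negative real, non-increasing in `depth`.
#' @export
rarefaction_slope <- function(counts, depth) {
  if (depth < 1) stop("depth must be >= 1")
  expected_richness(counts, depth) - expected_richness(counts, depth - 1)
}

#' Rarefy a count vector to a fixed depth
#'
#' Random subsampling without replacement (multivariate hypergeometric),
#' reproducible from `seed`.
#'
#' @param counts non-negative integer taxon counts.
#' @param depth number of reads to keep, `<= sum(counts)`.
#' @param seed RNG seed.
#' @return integer vector summing to `depth`, same length as `counts`.
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  N <- sum(counts)
  if (depth > N) stop("depth (", depth, ") exceeds total count (", N, ")")
  if (depth == N) return(counts)
  with_seed(seed, {
    reads <- rep.int(seq_along(counts), counts)
    tabulate(sample(reads, depth), nbins = length(counts))
  })
}

#' Shannon diversity index
#'
#' `H' = -sum p_i ln p_i` in natural-log units (nats), with `0 ln 0 = 0`.
#' Frequencies are renormalized internally, so counts are accepted.
#'
#' @param frequencies non-negative vector with positive sum.
#' @return H' in nats.
#' @export
shannon_index <- function(frequencies) {
  if (any(frequencies < 0)) stop("negative frequencies")
  tot <- sum(frequencies)
  if (tot == 0) stop("all-zero frequency vector")
  p <- frequencies[frequencies > 0] / tot
  -sum(p * log(p))
}

#' Per-plot alpha-diversity summary
#'
#' Rarefies each plot-stage community to a common depth (the minimum cell
#' total by default), verifies the rarefaction slope at that depth against a
#' coverage threshold, computes Shannon H' per cell, per-plot mean/sd over
#' the five stages with Tukey-Kramer letters, and the pooled H' of all six
#' plots combined.
#'
#' Counts are taken at plot-stage granularity by rounding the replicate
#' medians of the raw counts (one pseudo-community per cell).
#'
#' @param rt a [replicate_table()] holding raw taxon counts.
#' @param depth rarefaction depth; default `NULL` uses the minimum cell
#'   total.
#' @param slope_threshold maximum acceptable rarefaction slope (taxa per
#'   read) at the chosen depth; violators are reported, not dropped.
#' @param seed RNG seed for the rarefaction draws.
#' @param n_draws number of rarefaction draws averaged per cell.
#' @return list of class `alpha_result` with `per_cell` (plot, stage, H'),
#'   `per_plot` (mean, sd, Tukey letter), `pooled_h`, `depth`,
#'   `slope_violations`, `seed`.
#' @export
alpha_diversity_table <- function(rt, depth = NULL, slope_threshold = 0.01,
                                  seed = 1L, n_draws = 1L) {
  stopifnot(inherits(rt, "replicate_table"))
  tax <- rt$features$kind == "taxon"
  mm <- aggregate_medians(rt)
  cells <- parse_cell_ids(colnames(mm$values))
  cnt <- round(mm$values[tax, , drop = FALSE])
  have <- colSums(!is.na(cnt)) > 0
  cnt <- cnt[, have, drop = FALSE]
  cells <- cells[have, , drop = FALSE]
  totals <- colSums(cnt)
  if (is.null(depth)) depth <- min(totals)
  if (depth > min(totals)) stop("depth exceeds smallest cell total")

  slopes <- vapply(seq_len(ncol(cnt)),
                   function(j) rarefaction_slope(cnt[, j], depth), 0)
  violations <- cells$cell[slopes > slope_threshold]

  h <- numeric(ncol(cnt))
  rarefied <- matrix(0, nrow(cnt), ncol(cnt))
  for (j in seq_len(ncol(cnt))) {
    hj <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      rc <- rarefy_counts(cnt[, j], depth, seed = sub_seed(seed, j * 100 + d))
      if (d == 1L) rarefied[, j] <- rc
      hj[d] <- shannon_index(rc)
    }
    h[j] <- mean(hj)
  }
  per_cell <- data.frame(plot = cells$plot, stage = cells$stage, h = h,
                         slope = slopes, stringsAsFactors = FALSE)

  groups <- split(per_cell$h, factor(per_cell$plot, levels = PLOT_LEVELS))
  groups <- groups[lengths(groups) > 0]
  tk <- tukey_kramer(groups)
  per_plot <- data.frame(
    plot = names(groups),
    mean_h = vapply(groups, mean, 0),
    sd_h = vapply(groups, stats::sd, 0),
    letters = tk$letters[names(groups)],
    stringsAsFactors = FALSE)

  pooled <- shannon_index(rowSums(rarefied))
  structure(list(per_cell = per_cell, per_plot = per_plot,
                 pooled_h = pooled, depth = depth,
                 slope_violations = violations, seed = seed,
                 tukey = tk),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat("alpha_result: depth", x$depth, "; pooled H'",
      format(x$pooled_h, digits = 4), "\n")
  print(x$per_plot, row.names = FALSE)
  invisible(x)
}
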