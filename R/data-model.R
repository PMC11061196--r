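#' Construct a replicate-level feature table
#'
#' A `replicate_table` holds raw feature values per (plot, stage, replicate)
#' sample: taxon read counts (non-negative integers) and chemical
#' measurements (real, mg/kg dry soil, g/kg for TOC, unitless pH).  Up to
#' 6 plots x 5 stages x 4 replicates = 120 sample columns; absent samples
#' (such as a batch that failed DNA extraction) are recorded, never imputed.
#'
#' @param features data frame with columns `id` (unique), `kind`
#'   (`"taxon"` or `"chemical"`), and optional lineage ranks
#'   `phylum`,`class`,`order`,`family`,`genus` for taxa.
#' @param samples data frame with columns `sample`, `plot`, `stage`,
#'   `replicate`.
#' @param values numeric matrix, features x samples.
#' @return object of class `replicate_table`.
#' @export
replicate_table <- function(features, samples, values) {
  stopifnot(is.data.frame(features), is.data.frame(samples), is.matrix(values))
  if (anyDuplicated(features$id)) {
    stop("duplicate feature id: ",
         paste(unique(features$id[duplicated(features$id)]), collapse = ", "))
  }
  if (!all(features$kind %in% c("taxon", "chemical"))) {
    stop("feature kind must be 'taxon' or 'chemical'")
  }
  chem <- features$kind == "chemical"
  bad_chem <- chem & !(features$id %in% CHEMICAL_NAMES)
  if (any(bad_chem)) {
    stop("unknown chemical component(s): ",
         paste(features$id[bad_chem], collapse = ", "))
  }
  plot_flags(unique(samples$plot))          # validates labels
  stage_ordinal(unique(samples$stage))
  if (nrow(samples) > 120L) stop("more than 120 sample columns")
  tax <- features$kind == "taxon"
  v_tax <- values[tax, , drop = FALSE]
  if (any(v_tax[!is.na(v_tax)] < 0)) stop("negative taxon counts")
  dimnames(values) <- list(features$id, samples$sample)

  grid <- expand.grid(replicate = seq_len(N_REPLICATES),
                      stage = STAGE_LEVELS, plot = PLOT_LEVELS,
                      stringsAsFactors = FALSE)
  key <- paste(grid$plot, grid$stage, grid$replicate, sep = "_")
  present <- key %in% paste(samples$plot, samples$stage, samples$replicate,
                            sep = "_")
  structure(list(features = features, samples = samples, values = values,
                 missing_samples = key[!present]),
            class = "replicate_table")
}

#' @export
print.replicate_table <- function(x, ...) {
  cat("replicate_table:", nrow(x$values), "features x", ncol(x$values),
      "samples (", sum(x$features$kind == "taxon"), "taxa,",
      sum(x$features$kind == "chemical"), "chemicals;",
      length(x$missing_samples), "grid samples absent )\n")
  invisible(x)
}

#' Read a replicate-level feature table from TSV/CSV
#'
#' Expected layout: row 1 holds sample headers `plot_stage_rep` (e.g.
#' `NPK_F_2`); column 1 the feature id, column 2 the kind (`taxon` or
#' `chemical`); optional lineage rank columns (`phylum` ... `genus`) may
#' precede the sample columns.  Samples absent from the header are flagged as
#' missing, not invented.
#'
#' @param path file path.
#' @param sep field delimiter; `"\t"` (default) or `","`.
#' @return a [replicate_table()].
#' @export
read_replicate_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  cn <- names(raw)
  if (cn[1] != "id" || cn[2] != "kind") {
    stop("columns 1-2 must be 'id' and 'kind'")
  }
  lineage_cols <- intersect(LINEAGE_RANKS, cn)
  sample_cols <- setdiff(cn, c("id", "kind", lineage_cols))

  parts <- strsplit(sample_cols, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed sample header(s): ",
                     paste(sample_cols[bad], collapse = ", "))
  plot <- vapply(parts, `[`, "", 1L)
  stage <- vapply(parts, `[`, "", 2L)
  repl <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (any(!plot %in% PLOT_LEVELS)) {
    stop("unknown plot label in header: ",
         paste(unique(plot[!plot %in% PLOT_LEVELS]), collapse = ", "))
  }
  if (any(!stage %in% STAGE_LEVELS)) {
    stop("unknown stage label in header: ",
         paste(unique(stage[!stage %in% STAGE_LEVELS]), collapse = ", "))
  }
  if (anyNA(repl) || any(repl < 1L | repl > N_REPLICATES)) {
    stop("replicate index out of range in header: ",
         paste(sample_cols[is.na(repl) | repl < 1L | repl > N_REPLICATES],
               collapse = ", "))
  }

  values <- matrix(NA_real_, nrow(raw), length(sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(raw[[sample_cols[j]]]))
    bad <- is.na(v) & !(raw[[sample_cols[j]]] %in% c("", "NA"))
    if (any(bad)) {
      stop(sprintf("malformed numeric value '%s' at row %d, column '%s'",
                   raw[[sample_cols[j]]][which(bad)[1]], which(bad)[1],
                   sample_cols[j]))
    }
    values[, j] <- v
  }
  kind <- raw$kind
  tax <- kind == "taxon"
  v_tax <- values[tax, , drop = FALSE]
  frac <- !is.na(v_tax) & abs(v_tax - round(v_tax)) > 1e-9
  if (any(frac)) {
    ij <- which(frac, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row %d, column '%s'",
                 which(tax)[ij[1]], sample_cols[ij[2]]))
  }

  features <- raw[, c("id", "kind", lineage_cols), drop = FALSE]
  samples <- data.frame(sample = sample_cols, plot = plot, stage = stage,
                        replicate = repl, stringsAsFactors = FALSE)
  replicate_table(features, samples, values)
}

#' Write a replicate table to TSV
#'
#' @param rt a [replicate_table()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_replicate_table <- function(rt, path, sep = "\t") {
  out <- cbind(rt$features,
               as.data.frame(rt$values, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert taxon counts to relative frequencies
#'
#' Each sample column of a taxon count matrix is divided by its total so
#' columns sum to 1.  When given a `replicate_table`, only taxon rows are
#' converted (chemical rows are left as measured).
#'
#' @param x taxon x sample count matrix, or a [replicate_table()].
#' @return object of the same shape with taxon columns/rows as frequencies.
#' @export
to_relative_frequency <- function(x) {
  if (inherits(x, "replicate_table")) {
    tax <- x$features$kind == "taxon"
    x$values[tax, ] <- to_relative_frequency(x$values[tax, , drop = FALSE])
    attr(x, "relative") <- TRUE
    return(x)
  }
  stopifnot(is.matrix(x))
  tot <- colSums(x, na.rm = TRUE)
  zero <- tot == 0 & colSums(!is.na(x)) > 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(x)[zero] %||% which(zero), collapse = ", "))
  }
  sweep(x, 2L, tot, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate replicates into per-cell medians
#'
#' Collapses the 1-4 available replicates of every (feature, plot, stage)
#' cell to their median, producing a features x 30 plot-stage matrix.  Taxa
#' should already be on the relative-frequency scale (see
#' [to_relative_frequency()]) so medians stay in \[0, 1\].  With an even
#' replicate count the median is the mean of the two central values.  Cells
#' with no surviving replicate are marked missing.
#'
#' @param rt a [replicate_table()].
#' @return object of class `median_matrix`: list with `features` and a
#'   `values` matrix over the 30 `PLOT_STAGE` cells.
#' @export
aggregate_medians <- function(rt) {
  stopifnot(inherits(rt, "replicate_table"))
  cells <- cell_ids()
  cell_of <- paste(rt$samples$plot, rt$samples$stage, sep = "_")
  values <- matrix(NA_real_, nrow(rt$values), length(cells),
                   dimnames = list(rownames(rt$values), cells))
  for (ci in seq_along(cells)) {
    cols <- which(cell_of == cells[ci])
    if (!length(cols)) next
    sub <- rt$values[, cols, drop = FALSE]
    values[, ci] <- apply(sub, 1L, stats::median, na.rm = TRUE)
  }
  values[is.nan(values)] <- NA_real_
  structure(list(features = rt$features, values = values,
                 missing_cells = cells[colSums(!is.na(values)) == 0]),
            class = "median_matrix")
}

#' @export
print.median_matrix <- function(x, ...) {
  cat("median_matrix:", nrow(x$values), "features x", ncol(x$values),
      "plot-stage cells\n")
  invisible(x)
}

#' Remove taxa absent from every plot-stage cell
#'
#' Taxa whose relative frequency is zero in all 30 cells carry no
#' information and are eliminated; chemical rows are never removed.
#'
#' @param m a `median_matrix`.
#' @return `m` with absent taxa dropped; the removal report is in
#'   `attr(, "removal_report")` (list with `n_removed`, `n_retained`,
#'   `removed_ids`).
#' @export
filter_absent_features <- function(m) {
  stopifnot(inherits(m, "median_matrix"))
  tax <- m$features$kind == "taxon"
  allzero <- tax & apply(m$values, 1L, function(v) all(is.na(v) | v == 0))
  keep <- !allzero
  out <- m
  out$features <- m$features[keep, , drop = FALSE]
  out$values <- m$values[keep, , drop = FALSE]
  attr(out, "removal_report") <- list(
    n_removed = sum(allzero),
    n_retained = sum(tax) - sum(allzero),
    removed_ids = m$features$id[allzero])
  out
}

#' Standardize features to zero mean and unit variance
#'
#' Each feature row is z-scaled across the 30 plot-stage cells (sample
#' standard deviation, n-1 denominator).  Constant rows cannot be scaled and
#' are dropped with a warning; the drop log is kept on the result.
#'
#' @param m a `median_matrix`.
#' @return object of class `standardized_matrix` (same layout); dropped
#'   constant features in `attr(, "dropped_constant")`.
#' @export
standardize_features <- function(m) {
  stopifnot(inherits(m, c("median_matrix", "standardized_matrix")))
  mu <- rowMeans(m$values, na.rm = TRUE)
  sdv <- apply(m$values, 1L, stats::sd, na.rm = TRUE)
  const <- is.na(sdv) | sdv == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature(s): ",
            paste(utils::head(m$features$id[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
  }
  keep <- !const
  values <- (m$values[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  structure(list(features = m$features[keep, , drop = FALSE], values = values),
            class = c("standardized_matrix", "median_matrix"),
            dropped_constant = m$features$id[const])
}

#' Write a median or standardized matrix to TSV
#'
#' @param m a `median_matrix` or `standardized_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  out <- cbind(m$features, as.data.frame(m$values, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a matrix written by [write_matrix_tsv()]
#'
#' @param path file path.
#' @param standardized logical; class of the returned object.
#' @return a `median_matrix` (or `standardized_matrix`).
#' @export
read_matrix_tsv <- function(path, standardized = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  meta_cols <- intersect(c("id", "kind", LINEAGE_RANKS), names(raw))
  vals <- as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE])
  rownames(vals) <- raw$id
  cls <- if (standardized) c("standardized_matrix", "median_matrix")
         else "median_matrix"
  structure(list(features = raw[, meta_cols, drop = FALSE], values = vals),
            class = cls)
}

#' Replicate coefficients of variation
#'
#' For every (feature, plot, stage) cell with at least two replicates,
#' CV = sample sd / mean.  Cells with mean zero are excluded from averaging
#' (and counted); averages are reported separately for taxa and chemicals.
#' CVs are computed on the raw replicate values as measured.
#'
#' @param rt a [replicate_table()].
#' @return list with `per_cell` (features x cells CV matrix), `by_kind`
#'   (named averages for `taxon` and `chemical`), `per_feature` (mean CV per
#'   feature) and `n_zero_mean_cells`.
#' @export
compute_cv <- function(rt) {
  stopifnot(inherits(rt, "replicate_table"))
  cells <- cell_ids()
  cell_of <- paste(rt$samples$plot, rt$samples$stage, sep = "_")
  cv <- matrix(NA_real_, nrow(rt$values), length(cells),
               dimnames = list(rownames(rt$values), cells))
  n_zero <- 0L
  for (ci in seq_along(cells)) {
    cols <- which(cell_of == cells[ci])
    if (length(cols) < 2L) next
    sub <- rt$values[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    zero <- !is.na(mu) & mu == 0
    n_zero <- n_zero + sum(zero)
    cvv <- sdv / mu
    cvv[zero] <- NA_real_
    cv[, ci] <- cvv
  }
  per_feature <- rowMeans(cv, na.rm = TRUE)
  kind <- rt$features$kind
  by_kind <- c(taxon = mean(per_feature[kind == "taxon"], na.rm = TRUE),
               chemical = mean(per_feature[kind == "chemical"], na.rm = TRUE))
  list(per_cell = cv, per_feature = per_feature, by_kind = by_kind,
       n_zero_mean_cells = n_zero)
}

# effective lineage labels: missing ranks become "unassigned@<parent>" so
# distinct unassigned lineages do not collapse when counting ranks
effective_lineage <- function(features) {
  ranks <- intersect(LINEAGE_RANKS, names(features))
  out <- matrix(NA_character_, nrow(features), length(ranks),
                dimnames = list(features$id, ranks))
  parent <- rep("root", nrow(features))
  for (r in ranks) {
    lab <- features[[r]]
    lab[is.na(lab)] <- ""
    miss <- lab == "" | lab == "unassigned"
    lab[miss] <- paste0("unassigned@", parent[miss])
    out[, r] <- lab
    parent <- lab
  }
  out
}

#' Taxonomic and plot-occupancy summaries
#'
#' Counts distinct lineage labels per rank over taxa (missing ranks encoded
#' as `unassigned@<parent>`), per-plot taxon counts (a taxon is detected in a
#' plot when nonzero in at least one of its stage cells) and plot-specific
#' taxon sets (detected in exactly one plot).
#'
#' @param m a `median_matrix` whose taxa carry lineage columns.
#' @return list with `rank_counts`, `plot_taxon_counts`,
#'   `plot_specific_counts` and `plot_specific_taxa`.
#' @export
taxonomy_summary <- function(m) {
  stopifnot(inherits(m, "median_matrix"))
  tax <- m$features$kind == "taxon"
  feats <- m$features[tax, , drop = FALSE]
  lin <- effective_lineage(feats)
  rank_counts <- c(vapply(colnames(lin),
                          function(r) length(unique(lin[, r])), 0L),
                   taxon = nrow(feats))
  cells <- parse_cell_ids(colnames(m$values))
  vals <- m$values[tax, , drop = FALSE]
  detected <- sapply(PLOT_LEVELS, function(p) {
    sub <- vals[, cells$plot == p, drop = FALSE]
    apply(sub, 1L, function(v) any(!is.na(v) & v > 0))
  })
  n_plots <- rowSums(detected)
  specific <- lapply(PLOT_LEVELS, function(p) {
    feats$id[detected[, p] & n_plots == 1L]
  })
  names(specific) <- PLOT_LEVELS
  list(rank_counts = rank_counts,
       plot_taxon_counts = colSums(detected),
       plot_specific_counts = lengths(specific),
       plot_specific_taxa = specific)
}
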