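#' Field design constants
#'
#' The trial layout: six fertilizer plots, five cultivation stages, up to four
#' replicate soil batches per plot-stage cell, and fourteen monitored soil
#' chemical components.
#'
#' @name field_design
NULL

#' @rdname field_design
#' @export
PLOT_LEVELS <- c("0", "PK", "NK", "NP", "NPK", "C")

#' @rdname field_design
#' @export
STAGE_LEVELS <- c("B", "A", "F", "R", "H")

#' @rdname field_design
#' @export
CHEMICAL_NAMES <- c("TOC", "NO3", "NH4", "Na", "Cl", "SO4",
                    "sK", "sCa", "sMg", "eK", "eCa", "eMg", "aPO4", "pH")

#' @rdname field_design
#' @export
N_REPLICATES <- 4L

# fertilizer flags per plot label
.PLOT_FLAGS <- data.frame(
  plot    = PLOT_LEVELS,
  N       = c(FALSE, FALSE, TRUE,  TRUE,  TRUE,  FALSE),
  P       = c(FALSE, TRUE,  FALSE, TRUE,  TRUE,  FALSE),
  K       = c(FALSE, TRUE,  TRUE,  FALSE, TRUE,  FALSE),
  compost = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Fertilizer flags for a plot label
#'
#' @param plot character vector of plot labels.
#' @return data frame with logical columns `N`, `P`, `K`, `compost`.
#' @examples
#' plot_flags("NPK")
#' @export
plot_flags <- function(plot) {
  idx <- match(plot, PLOT_LEVELS)
  if (anyNA(idx)) {
    stop("unknown plot label(s): ", paste(plot[is.na(idx)], collapse = ", "))
  }
  .PLOT_FLAGS[idx, , drop = FALSE]
}

#' Plot groups by fertilization regime
#'
#' Plots are grouped into nitrogen-fertilized (`N`: NK, NP, NPK), unfertilized
#' or phosphate/potassium only (`plain`: 0, PK), and compost-amended
#' (`compost`: C).  This partition drives the semantic labeling of taxon
#' clusters and the planted structure of the synthetic generator.
#'
#' @param plot character vector of plot labels.
#' @return character vector of group names, same length as `plot`.
#' @export
plot_group <- function(plot) {
  idx <- match(plot, PLOT_LEVELS)
  if (anyNA(idx)) {
    stop("unknown plot label(s): ", paste(plot[is.na(idx)], collapse = ", "))
  }
  c("plain", "plain", "N", "N", "N", "compost")[idx]
}

#' Ordinal position of a cultivation stage
#'
#' Stages follow the strict order B < A < F < R < H (before fertilization,
#' after fertilization/pre-sowing, flowering, ripening, post-harvest).
#'
#' @param stage character vector of stage labels.
#' @return integer ordinals 0-4.
#' @export
stage_ordinal <- function(stage) {
  idx <- match(stage, STAGE_LEVELS)
  if (anyNA(idx)) {
    stop("unknown stage label(s): ", paste(stage[is.na(idx)], collapse = ", "))
  }
  idx - 1L
}

# canonical "PLOT_STAGE" cell ids, plot-major, in design order
cell_ids <- function() {
  as.vector(t(outer(PLOT_LEVELS, STAGE_LEVELS, paste, sep = "_")))
}

# parse "PLOT_STAGE" ids into a data frame
parse_cell_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed cell id(s): ", paste(ids[bad], collapse = ", "))
  data.frame(cell = ids,
             plot = vapply(parts, `[`, "", 1L),
             stage = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

LINEAGE_RANKS <- c("phylum", "class", "order", "family", "genus")

# run code under a local, restored RNG state seeded deterministically
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a per-stage sub-seed from the pipeline seed (kept below 2^31)
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}
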