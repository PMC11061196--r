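test_that("replicate tables round-trip through TSV", {
  taxa <- matrix(c(3L, 0L, 5L, 2L, 1L, 4L, 0L, 7L), 2, 4,
                 dimnames = list(c("t1", "t2"),
                                 c("0_B_1", "0_B_2", "NPK_F_1", "C_H_3")))
  chem <- matrix(c(5.5, 6.1, 5.9, 6.0), 1, 4, dimnames = list("pH", NULL))
  rt <- make_rt(taxa, chem)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_replicate_table(rt, path)
  rt2 <- read_replicate_table(path)
  expect_identical(rt2$values, rt$values)
  expect_identical(rt2$samples$plot, rt$samples$plot)
  # samples absent from the header are flagged, not invented
  expect_true("NPK_F_2" %in% rt2$missing_samples)
  expect_equal(length(rt2$missing_samples), 120 - 4)
})

test_that("malformed input is rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tkind\t0_B_1\t0_B_2",
               "t1\ttaxon\t3\tabc",
               "t2\ttaxon\t1\t2"), path)
  expect_error(read_replicate_table(path), "abc.*row 1.*0_B_2")

  writeLines(c("id\tkind\tXX_B_1", "t1\ttaxon\t3"), path)
  expect_error(read_replicate_table(path), "unknown plot label.*XX")

  writeLines(c("id\tkind\t0_Q_1", "t1\ttaxon\t3"), path)
  expect_error(read_replicate_table(path), "unknown stage label.*Q")

  writeLines(c("id\tkind\t0_B_1", "t1\ttaxon\t3", "t1\ttaxon\t4"), path)
  expect_error(read_replicate_table(path), "duplicate feature id: t1")
})

test_that("relative frequencies normalize sample columns", {
  expect_equal(to_relative_frequency(cbind(c(2, 2))), cbind(c(0.5, 0.5)))
  expect_equal(to_relative_frequency(cbind(c(5, 0, 0))), cbind(c(1, 0, 0)))
  set.seed(42)
  m <- matrix(rpois(60, 8) + 1, 10, 6)
  expect_equal(colSums(to_relative_frequency(m)), rep(1, 6), tolerance = 1e-12)
  m[, 3] <- 0
  colnames(m) <- paste0("s", 1:6)
  expect_error(to_relative_frequency(m), "all-zero sample column.*s3")
})

test_that("median aggregation matches a sort-and-pick oracle", {
  taxa <- matrix(c(2, 4, 6, 8), 1, 4,
                 dimnames = list("t1", paste0("0_B_", 1:4)))
  mm <- aggregate_medians(make_rt(taxa))
  expect_equal(mm$values["t1", "0_B"], 5)  # even count: mean of central pair

  single <- matrix(3.1, 1, 1, dimnames = list("t1", "NP_R_2"))
  expect_equal(aggregate_medians(make_rt(single))$values["t1", "NP_R"], 3.1)

  set.seed(7)
  cols <- as.vector(outer(paste0(rep(PLOT_LEVELS, each = 5), "_",
                                 rep(STAGE_LEVELS, 6)), 1:4, paste, sep = "_"))
  vals <- matrix(round(runif(40 * length(cols)) * 100), 40, length(cols),
                 dimnames = list(sprintf("t%02d", 1:40), cols))
  rt <- make_rt(vals)
  mm <- aggregate_medians(rt)
  cell_of <- paste(rt$samples$plot, rt$samples$stage, sep = "_")
  for (i in sample(40, 10)) {
    for (cell in sample(colnames(mm$values), 25)) {
      expect_identical(mm$values[i, cell],
                       brute_median(vals[i, cell_of == cell]))
    }
  }
})

test_that("absent taxa are eliminated; chemicals never are", {
  vals <- rbind(rep(0, 30), c(1e-4, rep(0, 29)), runif(30))
  mm <- make_mm(vals, kind = c("taxon", "taxon", "taxon"))
  mm$features$id[3] <- "pH"; mm$features$kind[3] <- "chemical"
  rownames(mm$values)[3] <- "pH"
  mm$values["pH", ] <- 0
  out <- filter_absent_features(mm)
  rep_log <- attr(out, "removal_report")
  expect_identical(rep_log$n_removed, 1L)
  expect_identical(rep_log$removed_ids, "f01")
  expect_true(all(c("f02", "pH") %in% out$features$id))
})

test_that("standardization gives exact z-rows and is idempotent", {
  vals <- matrix(rnorm(5 * 30), 5, 30)
  vals[1, 1:3] <- c(1, 2, 3)
  mm <- make_mm(vals)
  sm <- standardize_features(mm)
  expect_equal(unname(sm$values[1, 1:3] * sd(vals[1, ]) + mean(vals[1, ])),
               c(1, 2, 3))
  expect_lt(max(abs(rowMeans(sm$values))), 1e-9)
  expect_lt(max(abs(apply(sm$values, 1, sd) - 1)), 1e-9)
  sm2 <- standardize_features(sm)
  expect_equal(sm2$values, sm$values, tolerance = 1e-12)

  simple <- structure(list(
    features = data.frame(id = c("a", "b"), kind = "taxon"),
    values = matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
                    dimnames = list(c("a", "b"), c("0_B", "0_A", "0_F")))),
    class = "median_matrix")
  expect_warning(s3 <- standardize_features(simple), "constant")
  expect_identical(attr(s3, "dropped_constant"), "b")
  expect_equal(unname(s3$values["a", ]), c(-1, 0, 1))  # sample sd = 1
})

test_that("replicate CVs follow the sd/mean definition", {
  taxa <- rbind(t1 = c(2, 2, 2, 2), t2 = c(1, 3, 1, 3))
  colnames(taxa) <- paste0("0_B_", 1:4)
  cv <- compute_cv(make_rt(taxa))
  expect_equal(cv$per_cell["t1", "0_B"], 0)
  expect_equal(cv$per_cell["t2", "0_B"], sd(c(1, 3, 1, 3)) / 2)

  two <- rbind(t1 = c(1, 3), t2 = c(0, 0))
  colnames(two) <- paste0("C_H_", 1:2)
  cv2 <- compute_cv(make_rt(two))
  expect_equal(cv2$per_cell["t1", "C_H"], sqrt(2) / 2, tolerance = 1e-12)
  expect_true(is.na(cv2$per_cell["t2", "C_H"]))  # zero-mean cell excluded
  expect_identical(cv2$n_zero_mean_cells, 1L)
})

test_that("taxonomy summaries count ranks and plot-specific taxa", {
  vals <- matrix(0, 3, 30)
  vals[1, ] <- 0.1                       # everywhere
  vals[2, 26:30] <- 0.2                  # plot C cells only (design order)
  vals[3, 1:5] <- 0.3                    # plot 0 only
  mm <- make_mm(vals)
  mm$features$phylum <- c("PhyA", "PhyA", NA)
  mm$features$genus <- c("g1", NA, NA)
  ts <- taxonomy_summary(mm)
  # two taxa share PhyA; the NA phylum is its own unassigned label
  expect_identical(unname(ts$rank_counts["phylum"]), 2L)
  # NA genus under PhyA and NA genus under unassigned phylum stay distinct
  expect_identical(unname(ts$rank_counts["genus"]), 3L)
  expect_identical(unname(ts$plot_specific_counts["C"]), 1L)
  expect_identical(ts$plot_specific_taxa$C, "f02")
  expect_identical(unname(ts$plot_specific_counts["0"]), 1L)
  expect_equal(unname(ts$plot_taxon_counts["NP"]), 1)
})
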