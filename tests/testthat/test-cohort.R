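write_toy_cohort <- function(dir, values = NULL) {
  if (is.null(values)) {
    values <- matrix(c(0, 1, 3, 2,
                       5, 5, 5, 5,
                       1, 0, 2, 4), nrow = 3, byrow = TRUE)
  }
  rownames(values) <- paste0("G", 1:3)
  colnames(values) <- paste0("s", 1:4)
  expr <- data.frame(gene = rownames(values), values, check.names = FALSE)
  meta <- data.frame(sample_id = colnames(values),
                     subject_id = c("S1", "S2", "S1", "S2"),
                     cancer_type = "CA1",
                     tissue = c("tumor", "tumor", "normal", "normal"))
  write.table(expr, file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(expr = file.path(dir, "expr.tsv"), meta = file.path(dir, "meta.tsv"))
}

test_that("load_expression aligns genes and samples and validates input", {
  dir <- withr::local_tempdir()
  paths <- write_toy_cohort(dir)
  ds <- load_expression(paths$expr, paths$meta)
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(ds$layer, "raw")
  expect_equal(ds$samples$subject_id, c("S1", "S2", "S1", "S2"))

  # sample missing from metadata
  meta <- read.delim(paths$meta)[-2, ]
  write.table(meta, paths$meta, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression(paths$expr, paths$meta), "s2",
               class = "pathmeta_input_error")

  # negative value
  paths <- write_toy_cohort(dir)
  expr <- read.delim(paths$expr, check.names = FALSE)
  expr[1, 2] <- -1
  write.table(expr, paths$expr, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression(paths$expr, paths$meta), "negative",
               class = "pathmeta_input_error")
})

test_that("log_standardize reproduces the hand-computed z-scores", {
  # raw (0, 1, 3) -> log2 (0, 1, 2) -> z (-1, 0, 1) with sample sd = 1
  vals <- matrix(c(0, 1, 3,
                   5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("G1", "G2"), c("s1", "s2", "s3")))
  ds <- expression_dataset(vals, tibble::tibble(
    sample_id = colnames(vals), subject_id = colnames(vals),
    cancer_type = "CA1", tissue = "tumor"))
  z <- log_standardize(ds)
  expect_equal(unname(z$values["G1", ]), c(-1, 0, 1))
  expect_equal(unname(z$values["G2", ]), c(0, 0, 0))  # constant -> flagged zero
  expect_equal(z$flagged_genes, "G2")
  expect_equal(z$layer, "log_standardized")
  expect_error(log_standardize(ds, scope = "s1"), ">= 2")
})

test_that("standardized rows have mean 0 and sd 1, shape and order preserved", {
  set.seed(21)
  vals <- matrix(rexp(50 * 12, 1 / 50), 50, 12,
                 dimnames = list(sprintf("G%02d", 1:50), sprintf("s%02d", 1:12)))
  ds <- expression_dataset(vals, tibble::tibble(
    sample_id = colnames(vals), subject_id = colnames(vals),
    cancer_type = "CA1", tissue = "tumor"))
  z <- log_standardize(ds)
  expect_equal(dim(z), dim(ds))
  expect_equal(rownames(z$values), rownames(ds$values))
  expect_equal(colnames(z$values), colnames(ds$values))
  keep <- setdiff(rownames(z$values), z$flagged_genes)
  expect_lt(max(abs(rowMeans(z$values[keep, ]))), 1e-10)
  expect_lt(max(abs(apply(z$values[keep, ], 1, sd) - 1)), 1e-10)
})

test_that("normal-count eligibility implements the more-than-nine rule", {
  make <- function(cancer, n_normal) {
    n <- n_normal + 2
    vals <- matrix(1, 2, n, dimnames = list(
      c("G1", "G2"), paste0(cancer, "_s", seq_len(n))))
    expression_dataset(vals, tibble::tibble(
      sample_id = colnames(vals),
      subject_id = colnames(vals),
      cancer_type = cancer,
      tissue = c(rep("tumor", 2), rep("normal", n_normal))))
  }
  ds <- list(A = make("A", 9), B = make("B", 10), C = make("C", 0))
  expect_equal(eligible_cancers_for_normals(ds), "B")
  expect_equal(eligible_cancers_for_normals(ds, min_normals = 5), c("A", "B"))
  expect_equal(eligible_cancers_for_normals(list(make("Z", 0))), character(0))
})

test_that("pair_tumor_normal pairs subjects, breaks aliquot ties, errors on none", {
  vals <- matrix(seq_len(10), 2, 5, dimnames = list(
    c("G1", "G2"), c("t1a", "t1b", "n1", "t2", "t3")))
  meta <- tibble::tibble(
    sample_id = colnames(vals),
    subject_id = c("S1", "S1", "S1", "S2", "S3"),
    cancer_type = "CA1",
    tissue = c("tumor", "tumor", "normal", "tumor", "tumor"))
  ds <- expression_dataset(vals, meta)
  pc <- pair_tumor_normal(ds)
  expect_equal(nrow(pc$pairs), 1)
  expect_equal(pc$pairs$tumor_sample, "t1a")  # lexicographically smallest aliquot
  expect_equal(pc$pairs$normal_sample, "n1")

  # column permutation leaves the pair set unchanged
  perm <- c(4, 2, 5, 1, 3)
  ds2 <- expression_dataset(vals[, perm], meta[perm, ])
  expect_equal(pair_tumor_normal(ds2)$pairs, pc$pairs)

  tumors_only <- expression_dataset(vals, dplyr::mutate(meta, tissue = "tumor"))
  expect_error(pair_tumor_normal(tumors_only), class = "pathmeta_pairing_error")
})
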