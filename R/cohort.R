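#' Expression dataset container
#'
#' Bundles a gene-by-sample expression matrix with per-sample metadata. The
#' `layer` records the transformation state: `"raw"` (non-negative processed
#' abundance), `"log"` (log2(x + 1)) or `"log_standardized"` (per-gene
#' z-scores of the log layer).
#'
#' @param values Numeric gene-by-sample matrix with gene rownames and sample
#'   colnames.
#' @param samples Tibble with columns `sample_id`, `subject_id`,
#'   `cancer_type`, `tissue` (`"tumor"`/`"normal"`), rows aligned to the
#'   matrix columns.
#' @param layer One of `"raw"`, `"log"`, `"log_standardized"`.
#' @param flagged_genes Genes with zero variance at standardization time.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(values, samples,
                               layer = c("raw", "log", "log_standardized"),
                               flagged_genes = character(0)) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  samples <- as_tibble(samples)
  needed <- c("sample_id", "subject_id", "cancer_type", "tissue")
  check_that(all(needed %in% names(samples)),
             paste0("sample metadata must have columns: ",
                    paste(needed, collapse = ", ")))
  check_that(!is.null(rownames(values)) && !is.null(colnames(values)),
             "expression matrix needs gene rownames and sample colnames")
  check_that(identical(colnames(values), samples$sample_id),
             "matrix columns and sample metadata must align on sample_id")
  check_that(!anyDuplicated(samples$sample_id), "sample_id must be unique")
  check_that(all(samples$tissue %in% c("tumor", "normal")),
             "tissue must be 'tumor' or 'normal'")
  if (layer == "raw") {
    check_that(all(values >= 0), "raw expression values must be non-negative")
  }
  structure(
    list(values = values, samples = samples, layer = layer,
         flagged_genes = flagged_genes),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples [%s layer]\n",
              nrow(x$values), ncol(x$values), x$layer))
  tab <- table(x$samples$cancer_type, x$samples$tissue)
  print(tab)
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Tidy an expression dataset into long form
#'
#' @param x An [expression_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample_id`, `value` plus the sample
#'   metadata.
#' @export
tidy.expression_dataset <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Load an expression matrix and its sample metadata from TSV files
#'
#' The expression TSV has gene rows and sample columns (first column the gene
#' identifier, header row the sample ids); the metadata TSV has columns
#' `sample_id`, `subject_id`, `cancer_type`, `tissue`.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the metadata TSV.
#' @return A raw-layer [expression_dataset()].
#' @export
load_expression <- function(expr_path, meta_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  check_that(ncol(expr) >= 2, "expression TSV needs a gene column and samples")
  genes <- as.character(expr[[1]])
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- genes
  meta <- as_tibble(utils::read.delim(meta_path, stringsAsFactors = FALSE,
                                      colClasses = "character"))
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples present in expression but absent from metadata: ",
                 paste(missing, collapse = ", ")),
          class = "pathmeta_input_error")
  }
  if (any(values < 0)) {
    abort("negative expression values found; raw input must be non-negative",
          class = "pathmeta_input_error")
  }
  meta <- meta[match(colnames(values), meta$sample_id), ]
  expression_dataset(values, meta, layer = "raw")
}

#' Load a survival table from a clinical TSV
#'
#' @param path Clinical TSV with columns `subject_id`, `time_days`, `event`,
#'   `endpoint` (`"OS"` or `"DSS"`).
#' @return A tibble with one record per subject per endpoint.
#' @export
load_survival <- function(path) {
  clin <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  needed <- c("subject_id", "time_days", "event", "endpoint")
  check_that(all(needed %in% names(clin)),
             paste0("clinical TSV must have columns: ",
                    paste(needed, collapse = ", ")))
  check_that(all(clin$time_days >= 0), "survival times must be >= 0")
  check_that(all(clin$event %in% c(0, 1)), "event must be 0/1")
  check_that(all(clin$endpoint %in% c("OS", "DSS")),
             "endpoint must be 'OS' or 'DSS'")
  check_that(!anyDuplicated(clin[, c("subject_id", "endpoint")]),
             "one record per subject per endpoint")
  clin
}

#' Log-transform and per-gene standardize expression
#'
#' Computes `(log2(x + 1) - mean_g) / sd_g` per gene, with the mean and sample
#' standard deviation (denominator n - 1) taken over the samples in `scope`.
#' Genes with zero variance over the scope are flagged and set to all-zero
#' rather than dropped, so pathway gene indexing stays stable.
#'
#' @param dataset A raw-layer [expression_dataset()].
#' @param scope Sample ids defining the standardization cohort; defaults to
#'   all samples. The returned dataset is restricted to `scope`.
#' @return A `log_standardized`-layer [expression_dataset()]; flagged genes
#'   are listed in its `flagged_genes` field.
#' @export
log_standardize <- function(dataset, scope = NULL) {
  check_that(inherits(dataset, "expression_dataset"), "need an expression_dataset")
  check_that(dataset$layer == "raw", "log_standardize expects the raw layer")
  if (is.null(scope)) scope <- dataset$samples$sample_id
  check_that(all(scope %in% dataset$samples$sample_id),
             "scope contains unknown sample ids")
  check_that(length(scope) >= 2, "scope must contain >= 2 samples (sd undefined)")
  vals <- log2(dataset$values[, scope, drop = FALSE] + 1)
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  flagged <- rownames(vals)[sdv == 0]
  sdv[sdv == 0] <- 1
  z <- (vals - mu) / sdv
  z[flagged, ] <- 0
  expression_dataset(
    z, dataset$samples[match(scope, dataset$samples$sample_id), ],
    layer = "log_standardized", flagged_genes = flagged
  )
}

#' Log2-transform expression without standardizing
#'
#' @param dataset A raw-layer [expression_dataset()].
#' @return A `log`-layer dataset with values `log2(x + 1)`.
#' @export
log_transform <- function(dataset) {
  check_that(dataset$layer == "raw", "log_transform expects the raw layer")
  out <- dataset
  out$values <- log2(dataset$values + 1)
  out$layer <- "log"
  out
}

#' Cancer types with enough adjacent-normal samples
#'
#' Tumor-versus-normal analyses require a minimum number of normal samples
#' per cancer type (default 10, i.e. "more than 9").
#'
#' @param datasets Named list of per-cancer [expression_dataset()] objects,
#'   or a single dataset spanning several cancer types.
#' @param min_normals Minimum normal-sample count. Default 10.
#' @return Character vector of eligible cancer types, sorted.
#' @export
eligible_cancers_for_normals <- function(datasets, min_normals = 10) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  counts <- purrr::map(datasets, function(d) {
    d$samples %>%
      dplyr::filter(.data$tissue == "normal") %>%
      dplyr::count(.data$cancer_type)
  }) %>% dplyr::bind_rows() %>%
    dplyr::group_by(.data$cancer_type) %>%
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  sort(counts$cancer_type[counts$n >= min_normals])
}

#' Pair tumor and normal samples by subject
#'
#' Keeps subjects owning both a tumor and a normal sample; duplicate aliquots
#' are resolved by the lexicographically smallest sample id.
#'
#' @param dataset An [expression_dataset()] containing both tissues.
#' @return A `paired_cohort`: list with `pairs` (tibble of `subject_id`,
#'   `tumor_sample`, `normal_sample`) and `dataset` (the input restricted to
#'   paired samples).
#' @export
pair_tumor_normal <- function(dataset) {
  s <- dataset$samples
  pick <- s %>%
    dplyr::group_by(.data$subject_id, .data$tissue) %>%
    dplyr::summarise(sample_id = min(.data$sample_id), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "sample_id")
  for (col in c("tumor", "normal")) if (!col %in% names(pick)) pick[[col]] <- NA_character_
  pairs <- pick %>%
    dplyr::filter(!is.na(.data$tumor), !is.na(.data$normal)) %>%
    dplyr::transmute(.data$subject_id, tumor_sample = .data$tumor,
                     normal_sample = .data$normal) %>%
    dplyr::arrange(.data$subject_id)
  if (nrow(pairs) == 0) {
    abort("no subjects with both a tumor and a normal sample",
          class = "pathmeta_pairing_error")
  }
  keep <- c(pairs$tumor_sample, pairs$normal_sample)
  keep <- dataset$samples$sample_id[dataset$samples$sample_id %in% keep]
  sub <- expression_dataset(
    dataset$values[, keep, drop = FALSE],
    dataset$samples[match(keep, dataset$samples$sample_id), ],
    layer = dataset$layer, flagged_genes = dataset$flagged_genes
  )
  structure(list(pairs = pairs, dataset = sub), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d tumor/normal pairs\n", nrow(x$pairs)))
  invisible(x)
}
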