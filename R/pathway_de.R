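#' Patient-wise pathway mean expression for a paired cohort
#'
#' For each tumor/normal pair, the mean log2(x + 1) expression over the
#' pathway genes present in the dataset. Averages deliberately use the log
#' layer without z-scoring: z-scoring across pooled tumor and normal samples
#' would distort the paired differences by construction.
#'
#' @param cohort A `paired_cohort` from [pair_tumor_normal()] (raw or log
#'   layer).
#' @param pathway A single pathway row or character vector of genes.
#' @return A `pathway_patient_means` tibble: `subject_id`, `tumor_mean`,
#'   `normal_mean`, with attributes `pathway` and `n_genes`.
#' @export
pathway_patient_mean <- function(cohort, pathway) {
  check_that(inherits(cohort, "paired_cohort"), "need a paired_cohort")
  ds <- cohort$dataset
  vals <- switch(ds$layer,
    raw = log2(ds$values + 1),
    log = ds$values,
    abort("pathway_patient_mean expects a raw or log layer (not z-scored)",
          class = "pathmeta_input_error")
  )
  genes <- intersect(pathway_genes(pathway), rownames(vals))
  if (length(genes) < 1) {
    abort(sprintf("pathway %s: no genes present in dataset",
                  pathway_name(pathway)),
          class = "pathmeta_skip")
  }
  check_that(nrow(cohort$pairs) >= 2, "need >= 2 tumor/normal pairs")
  sub <- vals[genes, , drop = FALSE]
  sample_means <- colMeans(sub)
  out <- tibble(
    subject_id = cohort$pairs$subject_id,
    tumor_mean = unname(sample_means[cohort$pairs$tumor_sample]),
    normal_mean = unname(sample_means[cohort$pairs$normal_sample])
  )
  attr(out, "pathway") <- pathway_name(pathway)
  attr(out, "n_genes") <- length(genes)
  class(out) <- c("pathway_patient_means", class(out))
  out
}

#' Paired t-test of tumor versus normal pathway means
#'
#' One-sample t-test on the per-subject differences d = tumor - normal:
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from Student's t with
#' n - 1 degrees of freedom. Direction is the sign of the mean difference.
#'
#' @param means A `pathway_patient_means` tibble (or any tibble with
#'   `tumor_mean` and `normal_mean`).
#' @param pathway,cancer Optional labels carried into the result.
#' @return A one-row tibble: `pathway`, `cancer`, `n_pairs`, `t`, `df`, `p`,
#'   `mean_diff`, `direction`, `degenerate`.
#' @export
paired_t_test <- function(means, pathway = attr(means, "pathway"),
                          cancer = NA_character_) {
  d <- means$tumor_mean - means$normal_mean
  n <- length(d)
  check_that(n >= 2, "need >= 2 pairs")
  md <- mean(d)
  sdd <- stats::sd(d)
  degenerate <- FALSE
  if (sdd == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      # all pairs shifted by exactly the same amount: evidence is off the
      # t scale; flag and report the smallest representable p
      t_stat <- sign(md) * Inf; p <- .Machine$double.xmin
      degenerate <- TRUE
      warn("zero-variance nonzero differences; p set to machine minimum")
    }
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  tibble(
    pathway = pathway %||% NA_character_, cancer = cancer,
    n_pairs = n, t = t_stat, df = n - 1, p = p, mean_diff = md,
    direction = dplyr::case_when(
      md > 0 ~ "up_in_tumor",
      md < 0 ~ "down_in_tumor",
      TRUE ~ NA_character_
    ),
    degenerate = degenerate
  )
}

#' Summarize differential-expression results per pathway
#'
#' Counts, per pathway, the cancers where the adjusted p-value falls below
#' `alpha`, split by direction of the mean paired difference.
#'
#' @param results Tibble of [paired_t_test()] rows with an `adj_p` column
#'   (see [bh_adjust()]).
#' @param alpha Significance level. Default 0.05.
#' @return A tibble per pathway: `n_cells`, `n_significant`, `n_up_in_tumor`,
#'   `n_down_in_tumor`, `significant_fraction`.
#' @export
de_summary <- function(results, alpha = 0.05) {
  check_that("adj_p" %in% names(results),
             "results need an adj_p column; run bh_adjust() first")
  results %>%
    dplyr::group_by(.data$pathway) %>%
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_significant = sum(.data$adj_p < alpha),
      n_up_in_tumor = sum(.data$adj_p < alpha &
                            .data$direction == "up_in_tumor", na.rm = TRUE),
      n_down_in_tumor = sum(.data$adj_p < alpha &
                              .data$direction == "down_in_tumor", na.rm = TRUE),
      significant_fraction = mean(.data$adj_p < alpha),
      .groups = "drop"
    )
}
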