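#' Run the full pathway analysis pipeline on a study bundle
#'
#' Sequences the three analyses over every (cancer, pathway) cell:
#' \enumerate{
#'   \item Survival: per endpoint, composite-score permutation test
#'     ([permutation_test_cges()]) on each cancer's tumor samples
#'     (standardized within the cancer), BH-adjusted jointly over all
#'     pathway x cancer cells of the endpoint.
#'   \item Meta co-expression: for cancers with enough normals,
#'     [bootstrap_effect()] of the GSNCA test (tumor vs normal, log2 scale),
#'     pooled per pathway across cancers with [pool_random_effects()].
#'   \item Paired differential expression: [paired_t_test()] on patient-wise
#'     pathway means over tumor/normal pairs, BH-adjusted over all cells.
#' }
#' Every skipped cell is recorded with a reason code so that results + skips
#' always tile the full analysis grid.
#'
#' @param study A `sim_study` from [simulate_study()], or a list with the
#'   same fields (`datasets`, `survival`, `pathways`).
#' @param endpoints Survival endpoints to analyze. Default `c("OS", "DSS")`.
#' @param n_perm Permutations for the composite-score test. Default 1000.
#' @param gsnca_perm Permutations for the GSNCA point estimate. Default 500.
#' @param n_boot,inner_perm Bootstrap replicates and inner permutations for
#'   per-dataset effect sizes. Defaults 200 and 100.
#' @param alpha Significance level. Default 0.05.
#' @param min_normals Minimum normal samples for tumor-normal analyses.
#'   Default 10.
#' @param seed Master seed; each cell derives its own substream.
#' @return A `pipeline_result` list: `survival`, `meta`, `meta_effects`,
#'   `de`, `de_summary`, `skips`, `manifest`.
#' @export
run_pipeline <- function(study, endpoints = c("OS", "DSS"),
                         n_perm = 1000, gsnca_perm = 500,
                         n_boot = 200, inner_perm = 100,
                         alpha = 0.05, min_normals = 10, seed = 1) {
  check_that(all(endpoints %in% c("OS", "DSS")), "endpoints must be OS/DSS")
  datasets <- study$datasets
  pathways <- study$pathways
  cancers <- names(datasets)
  skips <- list()
  note_skip <- function(stage, cancer, pathway, endpoint, reason) {
    skips[[length(skips) + 1]] <<- tibble(
      stage = stage, cancer = cancer, pathway = pathway,
      endpoint = endpoint, reason = reason)
  }

  ## --- stage 1: survival -------------------------------------------------
  surv_rows <- list()
  for (cancer in cancers) {
    d <- datasets[[cancer]]
    tumor_ids <- d$samples$sample_id[d$samples$tissue == "tumor"]
    zd <- log_standardize(d, scope = tumor_ids)
    for (ep in endpoints) {
      surv <- study$survival %>%
        dplyr::filter(.data$endpoint == ep,
                      .data$cancer_type == cancer)
      for (pw in pathways$name) {
        res <- tryCatch(
          permutation_test_cges(
            zd, surv, pathways[pathways$name == pw, ],
            n_perm = n_perm,
            seed = derive_seed(seed, cancer, pw, ep, "cges")),
          pathmeta_skip = function(e) e
        )
        if (inherits(res, "condition")) {
          note_skip("survival", cancer, pw, ep,
                    paste0("too_few_genes: ", conditionMessage(res)))
        } else {
          surv_rows[[length(surv_rows) + 1]] <-
            glance(res) %>%
            dplyr::mutate(cancer = cancer, endpoint = ep, .before = 1)
        }
      }
    }
  }
  survival_results <- dplyr::bind_rows(surv_rows)
  if (nrow(survival_results) > 0) {
    survival_results <- survival_results %>%
      dplyr::group_by(.data$endpoint) %>%
      dplyr::mutate(adj_p = stats::p.adjust(.data$perm_p, method = "BH")) %>%
      dplyr::ungroup()
  }

  ## --- stage 2: meta co-expression ---------------------------------------
  eligible <- eligible_cancers_for_normals(datasets, min_normals = min_normals)
  for (cancer in setdiff(cancers, eligible)) {
    for (pw in pathways$name) {
      note_skip("coexpression", cancer, pw, NA_character_, "too_few_normals")
      note_skip("de", cancer, pw, NA_character_, "too_few_normals")
    }
  }
  meta_results <- list(); effect_rows <- list()
  for (pw in pathways$name) {
    genes <- pathways$genes[[match(pw, pathways$name)]]
    eff <- list()
    for (cancer in eligible) {
      d <- log_transform(datasets[[cancer]])
      gsub <- intersect(genes, rownames(d$values))
      if (length(gsub) < 3) {
        note_skip("coexpression", cancer, pw, NA_character_, "too_few_genes")
        next
      }
      g1 <- d$values[gsub, d$samples$tissue == "tumor", drop = FALSE]
      g2 <- d$values[gsub, d$samples$tissue == "normal", drop = FALSE]
      res <- tryCatch(
        bootstrap_effect(g1, g2, dataset = cancer, n_boot = n_boot,
                         inner_perm = inner_perm, point_perm = gsnca_perm,
                         seed = derive_seed(seed, cancer, pw, "coexpr"),
                         min_samples = min_normals),
        pathmeta_skip = function(e) e
      )
      if (inherits(res, "condition")) {
        note_skip("coexpression", cancer, pw, NA_character_,
                  paste0("degenerate_fit: ", conditionMessage(res)))
      } else {
        eff[[cancer]] <- res
      }
    }
    if (length(eff) == 0) next
    effects <- dplyr::bind_rows(eff)
    pooled <- pool_random_effects(effects, pathway = pw, alpha = alpha)
    meta_results[[pw]] <- glance(pooled)
    effect_rows[[pw]] <- effects %>% dplyr::mutate(pathway = pw, .before = 1)
  }

  ## --- stage 3: paired differential expression ---------------------------
  de_rows <- list()
  for (cancer in eligible) {
    d <- datasets[[cancer]]
    cohort <- tryCatch(pair_tumor_normal(d),
                       pathmeta_pairing_error = function(e) e)
    if (inherits(cohort, "condition")) {
      for (pw in pathways$name) {
        note_skip("de", cancer, pw, NA_character_, "no_pairs")
      }
      next
    }
    for (pw in pathways$name) {
      means <- tryCatch(
        pathway_patient_mean(cohort, pathways[pathways$name == pw, ]),
        pathmeta_skip = function(e) e
      )
      if (inherits(means, "condition")) {
        note_skip("de", cancer, pw, NA_character_, "too_few_genes")
      } else {
        de_rows[[length(de_rows) + 1]] <- paired_t_test(means, pathway = pw,
                                                        cancer = cancer)
      }
    }
  }
  de_results <- dplyr::bind_rows(de_rows)
  if (nrow(de_results) > 0) de_results <- bh_adjust(de_results)

  structure(list(
    survival = survival_results,
    meta = dplyr::bind_rows(meta_results),
    meta_effects = dplyr::bind_rows(effect_rows),
    de = de_results,
    de_summary = if (nrow(de_results) > 0) de_summary(de_results, alpha),
    skips = dplyr::bind_rows(
      tibble(stage = character(), cancer = character(), pathway = character(),
             endpoint = character(), reason = character()),
      skips),
    manifest = tibble(
      n_cancers = length(cancers), n_pathways = nrow(pathways),
      endpoints = paste(endpoints, collapse = ","),
      n_perm = n_perm, gsnca_perm = gsnca_perm, n_boot = n_boot,
      inner_perm = inner_perm, alpha = alpha, min_normals = min_normals,
      seed = seed, eligible_cancers = paste(eligible, collapse = ","),
      package_version = as.character(utils::packageVersion("pathmeta"))
    )
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  survival cells: %d; meta pathways: %d; DE cells: %d; skips: %d\n",
              nrow(x$survival), nrow(x$meta), nrow(x$de), nrow(x$skips)))
  invisible(x)
}

#' Write pipeline results to TSV files
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(survival = result$survival, meta = result$meta,
                 meta_effects = result$meta_effects, de = result$de,
                 de_summary = result$de_summary, skips = result$skips,
                 manifest = result$manifest)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb)) next
    utils::write.table(tb, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Cancer-by-pathway matrix of adjusted p-values
#'
#' @param results Tibble with `cancer`, `pathway` and a value column.
#' @param value Column to spread. Default `"adj_p"`.
#' @return A numeric matrix, cancers as rows, pathways as columns.
#' @export
result_matrix <- function(results, value = "adj_p") {
  check_that(all(c("cancer", "pathway", value) %in% names(results)),
             "results need cancer, pathway and the value column")
  wide <- results %>%
    dplyr::select("cancer", "pathway", dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "pathway", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cancer
  m
}

#' Hierarchical clustering of an adjusted-p-value matrix
#'
#' Clusters both rows (cancers) and columns (pathways) under Euclidean
#' distance. Missing cells (skipped analyses) are imputed as 1.0 — the
#' conservative "not significant" reading — with a message.
#'
#' @param matrix Numeric cancers-by-pathways matrix (e.g. [result_matrix()]).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return A `pvalue_clustering` list: `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order` (leaf label orders) and the imputed `matrix`.
#' @export
cluster_pvalue_matrix <- function(matrix, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  check_that(nrow(matrix) >= 2 && ncol(matrix) >= 2,
             "need >= 2 rows and >= 2 columns to cluster")
  if (anyNA(matrix)) {
    inform(sprintf("%d missing cell(s) imputed as adjusted p = 1.0",
                   sum(is.na(matrix))))
    matrix[is.na(matrix)] <- 1.0
  }
  # deterministic orientation: feed rows/cols in sorted label order
  matrix <- matrix[order(rownames(matrix)), order(colnames(matrix)),
                   drop = FALSE]
  rh <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = linkage)
  ch <- stats::hclust(stats::dist(t(matrix), method = "euclidean"),
                      method = linkage)
  structure(list(
    row_hclust = rh, col_hclust = ch,
    row_order = rownames(matrix)[rh$order],
    col_order = colnames(matrix)[ch$order],
    matrix = matrix
  ), class = "pvalue_clustering")
}
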