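#' Logit effect size of a permutation p-value
#'
#' `ES = ln(p / (1 - p))`, the natural-log odds of the GSNCA permutation
#' p-value. Small p-values map to large negative effects; p = 0.5 maps to 0.
#' Permutation p-values are strictly inside (0, 1) by the pseudo-count
#' convention, so the transform is always finite.
#'
#' @param p Probability strictly between 0 and 1.
#' @return `ln(p / (1 - p))`.
#' @examples
#' effect_size(0.5)       # 0
#' effect_size(1 / 1001)  # -6.9078
#' @export
effect_size <- function(p) {
  check_that(all(p > 0 & p < 1), "p must lie strictly in (0, 1)")
  stats::qlogis(p)
}

# A permutation p-value with pseudo-count is bounded below by 1/(1 + n_perm)
# but can equal 1 exactly; mirror the lower bound at the top so the logit
# stays finite.
clamp_perm_p <- function(p, n_perm) pmin(p, n_perm / (n_perm + 1))

#' Bootstrap effect size and standard error for one dataset
#'
#' Runs [gsnca_test()] on the original two groups for the point estimate,
#' then resamples samples with replacement within each group (sizes
#' preserved), re-running the test with `inner_perm` permutations per
#' replicate. The standard error is the standard deviation of the bootstrap
#' effect sizes; the confidence interval is the 2.5/97.5 percentile interval.
#' Degenerate replicates (too few usable genes after resampling) are redrawn
#' up to `retry_cap` extra draws.
#'
#' @inheritParams gsnca_test
#' @param dataset Label for the dataset (e.g. cancer type).
#' @param n_boot Number of bootstrap replicates. Default 200.
#' @param inner_perm Permutations per bootstrap replicate. Default 100.
#' @param point_perm Permutations for the point estimate. Defaults to
#'   `max(inner_perm, 500)`.
#' @param retry_cap Maximum redraws of degenerate replicates. Default
#'   `n_boot`.
#' @return A `dataset_effect` tibble row: `dataset`, `p`, `es`, `se`,
#'   `ci_low`, `ci_high`, `n_boot`, `n1`, `n2`.
#' @export
bootstrap_effect <- function(group1, group2, dataset = "dataset",
                             n_boot = 200, inner_perm = 100,
                             point_perm = max(inner_perm, 500), seed = 1,
                             method = c("pearson", "spearman"),
                             min_samples = 10, retry_cap = n_boot) {
  method <- match.arg(method)
  check_that(n_boot >= 2, "n_boot must be >= 2 (se undefined otherwise)")
  point <- gsnca_test(group1, group2, n_perm = point_perm,
                      seed = derive_seed(seed, dataset, "point"),
                      method = method, min_samples = min_samples)
  n1 <- ncol(group1); n2 <- ncol(group2)
  boot_es <- with_seed(derive_seed(seed, dataset, "boot"), {
    out <- numeric(0)
    draws <- 0
    while (length(out) < n_boot && draws < n_boot + retry_cap) {
      draws <- draws + 1
      b1 <- group1[, sample.int(n1, n1, replace = TRUE), drop = FALSE]
      b2 <- group2[, sample.int(n2, n2, replace = TRUE), drop = FALSE]
      res <- tryCatch(
        gsnca_test(b1, b2, n_perm = inner_perm,
                   seed = derive_seed(seed, dataset, "inner", draws),
                   method = method, min_samples = min_samples),
        pathmeta_skip = function(e) NULL
      )
      if (!is.null(res)) out <- c(out, effect_size(clamp_perm_p(res$p, res$n_perm)))
    }
    out
  })
  if (length(boot_es) < n_boot) {
    warn(sprintf("%s: only %d of %d bootstrap replicates usable",
                 dataset, length(boot_es), n_boot))
  }
  check_that(length(boot_es) >= 2, "too few usable bootstrap replicates")
  es <- effect_size(clamp_perm_p(point$p, point$n_perm))
  ci <- stats::quantile(boot_es, c(0.025, 0.975), names = FALSE, type = 7)
  if (es < ci[1] || es > ci[2]) {
    inform(sprintf(
      "%s: point estimate %.3f outside percentile interval [%.3f, %.3f] (bootstrap skew)",
      dataset, es, ci[1], ci[2]))
  }
  out <- tibble(dataset = dataset, p = point$p, es = es,
                se = stats::sd(boot_es), ci_low = ci[1], ci_high = ci[2],
                n_boot = length(boot_es), n1 = n1, n2 = n2)
  class(out) <- c("dataset_effect", class(out))
  out
}

#' Random-effects pooling of per-dataset logit effect sizes
#'
#' DerSimonian-Laird: fixed-effect weights `w_i = 1/se_i^2` give the
#' heterogeneity statistic `Q = sum w_i (es_i - es_fixed)^2` and
#' `tau2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1 / (se_i^2 + tau2)` give the pooled effect and its standard
#' error. The meta p-value is the inverse-logit back-transform of the pooled
#' effect size.
#'
#' @param effects Tibble of per-dataset effects with columns `dataset`, `p`,
#'   `es`, `se` (e.g. rows from [bootstrap_effect()]).
#' @param pathway Optional pathway label carried into the result.
#' @param alpha Significance level for the `significant` flag. Default 0.05.
#' @return A `meta_coexpr_result`: list with `pathway`, `effects`,
#'   `pooled_es`, `pooled_se`, `tau2`, `q`, `meta_p`, `significant`.
#' @export
pool_random_effects <- function(effects, pathway = NA_character_,
                                alpha = 0.05) {
  check_that(nrow(effects) >= 1, "need at least one dataset effect")
  check_that(all(effects$se >= 0), "standard errors must be >= 0")
  es <- effects$es; se <- effects$se
  k <- length(es)
  if (all(se == 0) && length(unique(es)) > 1) {
    abort("all standard errors are zero with unequal effects; model undefined",
          class = "pathmeta_degenerate")
  }
  if (k == 1) {
    tau2 <- 0; q <- 0
    pooled_es <- es; pooled_se <- se
  } else {
    se_floor <- pmax(se, 1e-12)      # guard: a zero-se dataset among others
    w <- 1 / se_floor^2
    es_fixed <- sum(w * es) / sum(w)
    q <- sum(w * (es - es_fixed)^2)
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (se_floor^2 + tau2)
    pooled_es <- sum(w_star * es) / sum(w_star)
    pooled_se <- sqrt(1 / sum(w_star))
  }
  meta_p <- stats::plogis(pooled_es)
  structure(list(
    pathway = pathway, effects = as_tibble(effects),
    pooled_es = pooled_es, pooled_se = pooled_se, tau2 = tau2, q = q,
    meta_p = meta_p, significant = meta_p < alpha
  ), class = "meta_coexpr_result")
}

#' @export
print.meta_coexpr_result <- function(x, ...) {
  cat(sprintf("<meta_coexpr_result> pathway %s: %d datasets\n",
              x$pathway, nrow(x$effects)))
  cat(sprintf("  pooled ES = %.3f (se %.3f), tau2 = %.3f, meta p = %.4g%s\n",
              x$pooled_es, x$pooled_se, x$tau2, x$meta_p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Forest table of a meta co-expression result
#'
#' One row per dataset plus a summary row, on both the logit and the
#' back-transformed probability scale; ready for TSV export or plotting.
#'
#' @param result A `meta_coexpr_result`.
#' @return A tibble with columns `label`, `kind`, `es`, `se`, `ci_low`,
#'   `ci_high`, `prob` (inverse-logit of `es`).
#' @export
forest_table <- function(result) {
  check_that(inherits(result, "meta_coexpr_result"), "need a meta_coexpr_result")
  eff <- result$effects
  rows <- tibble(
    label = eff$dataset, kind = "dataset",
    es = eff$es, se = eff$se,
    ci_low = if ("ci_low" %in% names(eff)) eff$ci_low else eff$es - 1.96 * eff$se,
    ci_high = if ("ci_high" %in% names(eff)) eff$ci_high else eff$es + 1.96 * eff$se
  )
  summary_row <- tibble(
    label = "RE summary", kind = "summary",
    es = result$pooled_es, se = result$pooled_se,
    ci_low = result$pooled_es - 1.96 * result$pooled_se,
    ci_high = result$pooled_es + 1.96 * result$pooled_se
  )
  out <- dplyr::bind_rows(rows, summary_row)
  out$prob <- stats::plogis(out$es)
  out
}

#' @rdname pool_random_effects
#' @param x A `meta_coexpr_result`.
#' @param ... Unused.
#' @export
tidy.meta_coexpr_result <- function(x, ...) forest_table(x)

#' @rdname pool_random_effects
#' @export
glance.meta_coexpr_result <- function(x, ...) {
  tibble(pathway = x$pathway, k = nrow(x$effects), pooled_es = x$pooled_es,
         pooled_se = x$pooled_se, tau2 = x$tau2, q = x$q, meta_p = x$meta_p,
         significant = x$significant)
}
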