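#' Univariate Cox fit for one gene
#'
#' Fits a univariate Cox proportional-hazards model (Efron tie handling) of
#' survival on one gene's standardized log expression. Degenerate inputs —
#' constant expression, zero events, monotone likelihood with the coefficient
#' running beyond a cap of 10 — return `beta = 0` with `converged = FALSE`.
#'
#' @param x Per-subject standardized expression, named by subject id (or
#'   aligned with `surv`).
#' @param surv Tibble with columns `subject_id`, `time_days`, `event`.
#' @return A tibble row: `beta`, `converged`.
#' @export
fit_gene_cox <- function(x, surv) {
  if (!is.null(names(x))) {
    check_that(setequal(names(x), surv$subject_id),
               "x and surv must cover the same subjects")
    x <- x[surv$subject_id]
  } else {
    check_that(length(x) == nrow(surv), "x and surv must align by subject")
  }
  check_that(length(x) >= 2, "need >= 2 subjects")
  fit <- cox_univariate_batch(matrix(x, ncol = 1), surv$time_days, surv$event)
  if (!fit$converged) {
    warn("degenerate univariate Cox fit; beta set to 0")
  }
  tibble(beta = fit$beta, converged = fit$converged)
}

# Core score computation shared by the observed fit and each permutation:
# per-gene univariate Cox -> weighted linear predictor -> median-centered
# logistic score -> log-rank chi-square of the median score split.
cges_eval <- function(x_mat, time, status) {
  fit <- cox_univariate_batch(x_mat, time, status)
  sc <- cges_from_betas(x_mat, fit$beta)
  low <- sc$cges <= stats::median(sc$cges)
  c(list(beta = fit$beta, converged = fit$converged), sc,
    list(stat = logrank_chisq(time, status, low)))
}

# scoring formula alone: linear predictor, median normalizer, logistic score
cges_from_betas <- function(x_mat, beta) {
  lin <- as.vector(x_mat %*% beta)
  m <- stats::median(lin)
  list(linear = lin, m = m, cges = stats::plogis(lin - m))
}

#' Composite gene expression score for one pathway in one cohort
#'
#' For each pathway gene i, a univariate Cox model of survival on the
#' standardized log expression x_i yields a coefficient beta_i. Each subject's
#' linear predictor is the weighted sum over the k pathway genes, and the
#' composite score is the logistic transform after centering at the cohort
#' median m:
#' \deqn{CGES = 1 / (1 + \exp(-(\sum_i \beta_i x_i - m)))}
#' so the score lies in (0, 1) with the cohort-median subject at 0.5.
#'
#' @param dataset A `log_standardized` [expression_dataset()] of tumor
#'   samples (one sample per subject).
#' @param surv Survival tibble (`subject_id`, `time_days`, `event`) covering
#'   the dataset's subjects.
#' @param pathway A single row of a [pathway_collection()], or a character
#'   vector of gene ids.
#' @param min_genes Minimum pathway genes required after intersecting with
#'   the dataset. Default 3.
#' @return A `cges_result`: list with the pathway name, `k`, per-gene `betas`
#'   tibble, per-subject `scores` tibble (`subject_id`, `linear`, `cges`),
#'   `m`, and `observed_stat` (log-rank chi-square of the median split).
#' @export
compute_cges <- function(dataset, surv, pathway, min_genes = 3) {
  check_that(dataset$layer == "log_standardized",
             "compute_cges expects log-standardized expression")
  check_that(all(dataset$samples$tissue == "tumor"),
             "compute_cges expects tumor samples only")
  genes <- pathway_genes(pathway)
  name <- pathway_name(pathway)
  used <- intersect(genes, rownames(dataset$values))
  if (length(used) < min_genes) {
    abort(sprintf("pathway %s: %d gene(s) in dataset, need >= %d",
                  name, length(used), min_genes),
          class = "pathmeta_skip")
  }
  subjects <- dataset$samples$subject_id
  check_that(!anyDuplicated(subjects), "one tumor sample per subject required")
  check_that(all(subjects %in% surv$subject_id),
             "survival records missing for some subjects")
  surv <- surv[match(subjects, surv$subject_id), ]
  x_mat <- t(dataset$values[used, , drop = FALSE])
  ev <- cges_eval(x_mat, surv$time_days, surv$event)
  structure(list(
    pathway = name, k = length(used),
    betas = tibble(gene = used, beta = ev$beta, converged = ev$converged),
    scores = tibble(subject_id = subjects, linear = ev$linear, cges = ev$cges),
    m = ev$m, observed_stat = ev$stat,
    surv = surv, x_mat = x_mat
  ), class = "cges_result")
}

#' Permutation test for the composite gene expression score
#'
#' The composite score reuses Cox coefficients estimated on the same cohort
#' it scores, so the log-rank statistic of its median split is optimistically
#' biased. The permutation test combats this overfitting by jointly shuffling
#' the (time, event) records across subjects and re-running the entire
#' pipeline — per-gene Cox refits, new weights, new scores, new median split,
#' new log-rank statistic — for each permutation. The p-value is
#' `(1 + #permuted >= observed) / (1 + n_perm)`, strictly positive.
#'
#' @inheritParams compute_cges
#' @param n_perm Number of permutations. Default 1000.
#' @param seed Integer seed for the permutation stream.
#' @return The [compute_cges()] result with `n_perm`, `perm_stats` and
#'   `perm_p` added.
#' @export
permutation_test_cges <- function(dataset, surv, pathway, n_perm = 1000,
                                  seed = 1, min_genes = 3) {
  check_that(is.numeric(n_perm) && n_perm >= 1, "n_perm must be >= 1")
  res <- compute_cges(dataset, surv, pathway, min_genes = min_genes)
  n <- nrow(res$x_mat)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      cges_eval(res$x_mat, res$surv$time_days[idx], res$surv$event[idx])$stat
    }, numeric(1))
  })
  res$n_perm <- n_perm
  res$perm_stats <- perm_stats
  res$perm_p <- (1 + sum(perm_stats >= res$observed_stat)) / (1 + n_perm)
  res
}

#' @export
print.cges_result <- function(x, ...) {
  cat(sprintf("<cges_result> pathway %s: k = %d genes, n = %d subjects\n",
              x$pathway, x$k, nrow(x$scores)))
  cat(sprintf("  log-rank chi-square (median split) = %.3f\n", x$observed_stat))
  if (!is.null(x$perm_p)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$perm_p, x$n_perm))
  }
  invisible(x)
}

#' @rdname compute_cges
#' @param x A `cges_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-subject score tibble; `glance()`: a one-row
#'   summary tibble.
#' @export
tidy.cges_result <- function(x, ...) x$scores

#' @rdname compute_cges
#' @export
glance.cges_result <- function(x, ...) {
  tibble(pathway = x$pathway, k = x$k, n = nrow(x$scores), m = x$m,
         observed_stat = x$observed_stat,
         n_perm = x$n_perm %||% NA_integer_,
         perm_p = x$perm_p %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pathway_genes <- function(pathway) {
  if (is.character(pathway)) return(unique(pathway))
  check_that(nrow(pathway) == 1, "pass a single pathway (one row)")
  pathway$genes[[1]]
}

pathway_name <- function(pathway) {
  if (is.character(pathway)) return("(gene vector)")
  pathway$name[[1]]
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates via [survival::survfit()], one curve per group.
#'
#' @param surv Survival tibble (`subject_id`, `time_days`, `event`).
#' @param groups Per-subject group labels, named by subject id or aligned
#'   with `surv`.
#' @return A `km_curves` tibble: `group`, `time`, `survival`, `at_risk`,
#'   `n_event`.
#' @export
km_curve <- function(surv, groups) {
  if (!is.null(names(groups))) groups <- groups[surv$subject_id]
  check_that(length(groups) == nrow(surv), "groups must align with surv")
  check_that(!anyNA(groups), "every subject needs a group label")
  check_that(all(table(groups) >= 1), "each group needs >= 1 subject")
  g <- factor(groups)
  fit <- survival::survfit(
    survival::Surv(surv$time_days, surv$event) ~ g
  )
  strata <- if (is.null(fit$strata)) {
    rep(levels(g)[1], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(group = strata, time = fit$time, survival = fit$surv,
                at_risk = fit$n.risk, n_event = fit$n.event)
  class(out) <- c("km_curves", class(out))
  out
}

#' Median-split groups from a composite score
#'
#' @param result A `cges_result`.
#' @return Named character vector (`"low"`/`"high"`) per subject; scores at
#'   or below the median are `"low"`.
#' @export
cges_groups <- function(result) {
  med <- stats::median(result$scores$cges)
  stats::setNames(ifelse(result$scores$cges <= med, "low", "high"),
                  result$scores$subject_id)
}

#' Benjamini-Hochberg adjustment over a family of test cells
#'
#' Standard step-up false-discovery-rate control via [stats::p.adjust()],
#' applied jointly over all cells passed in (the family).
#'
#' @param pvalues Data frame with a `p` column (cell identifiers in the other
#'   columns), or a bare numeric vector.
#' @return The input with an `adj_p` column added (or the adjusted vector).
#' @export
bh_adjust <- function(pvalues) {
  if (is.numeric(pvalues)) {
    check_that(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
    return(stats::p.adjust(pvalues, method = "BH"))
  }
  check_that(is.data.frame(pvalues) && "p" %in% names(pvalues),
             "pvalues must have a column `p`")
  check_that(all(pvalues$p >= 0 & pvalues$p <= 1),
             "p-values must lie in [0, 1]")
  dplyr::mutate(as_tibble(pvalues), adj_p = stats::p.adjust(.data$p, method = "BH"))
}
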