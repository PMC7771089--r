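#' Gene-gene correlation matrix
#'
#' @param values Gene-by-sample numeric matrix (log scale recommended;
#'   correlation is scale-invariant so z-scoring is unnecessary).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric gene-by-gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(values, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_that(nrow(values) >= 3, "need >= 3 genes")
  check_that(ncol(values) >= 3, "need >= 3 samples")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance gene(s): ",
                 paste(rownames(values)[sds == 0], collapse = ", "),
                 "; remove before correlating"),
          class = "pathmeta_degenerate")
  }
  stats::cor(t(values), method = method)
}

#' Net-correlation weight vector of a pathway
#'
#' The weight vector summarizes each gene's total co-expression connectivity:
#' it is the principal eigenvector (largest eigenvalue) of the absolute
#' correlation matrix with zeroed diagonal, sign-fixed non-negative
#' (Perron-Frobenius) and rescaled to mean 1.
#'
#' @param corr Symmetric correlation matrix.
#' @return A tibble with columns `gene`, `weight` (mean 1, all >= 0).
#' @export
weight_vector <- function(corr) {
  check_that(isSymmetric(unname(corr), tol = 1e-10), "corr must be symmetric")
  a <- abs(corr)
  diag(a) <- 0
  e <- eigen(a, symmetric = TRUE)
  vals <- e$values
  if (length(vals) > 1 && vals[1] - vals[2] < 1e-12) {
    warn("top eigenvalue tied; weight vector chosen by first-max-component rule")
    cand <- which(vals[1] - vals < 1e-12)
    pick <- cand[which.max(vapply(cand, function(j) max(abs(e$vectors[, j])),
                                  numeric(1)))]
  } else {
    pick <- 1
  }
  v <- e$vectors[, pick]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)                     # clip numerical negatives
  check_that(mean(v) > 0, "degenerate weight vector (all-zero)")
  w <- v / mean(v)
  genes <- rownames(corr) %||% paste0("g", seq_along(w))
  tibble(gene = genes, weight = w)
}

# fast internal path used inside the permutation loop: plain numeric weight
# vector from a correlation matrix, no validation or labels
weight_raw <- function(corr) {
  a <- abs(corr)
  diag(a) <- 0
  v <- eigen(a, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / mean(v)
}

row_variance <- function(m) {
  n <- ncol(m)
  (rowSums(m * m) - n * rowMeans(m)^2) / (n - 1)
}

#' GSNCA statistic: L1 distance between two weight vectors
#'
#' @param w1,w2 Weight tibbles from [weight_vector()] with identical gene
#'   order.
#' @return Non-negative scalar, `sum(|w1 - w2|)`.
#' @export
gsnca_statistic <- function(w1, w2) {
  check_that(identical(w1$gene, w2$gene), "gene order mismatch between groups")
  sum(abs(w1$weight - w2$weight))
}

#' Two-condition differential co-expression test (GSNCA)
#'
#' Compares the net-correlation structure of a gene set between two sample
#' groups. Each group's absolute-correlation network yields a weight vector
#' ([weight_vector()]); the test statistic is the L1 distance between the two
#' vectors, and significance comes from permuting group labels over the
#' pooled samples while preserving group sizes.
#'
#' @param group1,group2 Gene-by-sample matrices with identical gene rows
#'   (log-scale values).
#' @param n_perm Number of label permutations. Default 500.
#' @param seed Integer seed.
#' @param method Correlation method, see [correlation_matrix()].
#' @param min_samples Minimum samples per group. Default 10.
#' @return A `gsnca_result`: list with `statistic`, `p`, `n_perm`,
#'   `group_sizes`, `weights` (per-gene tibble with both conditions) and
#'   `genes_used`.
#' @export
gsnca_test <- function(group1, group2, n_perm = 500, seed = 1,
                       method = c("pearson", "spearman"), min_samples = 10) {
  method <- match.arg(method)
  check_that(identical(rownames(group1), rownames(group2)),
             "groups must share the same genes in the same order")
  n1 <- ncol(group1); n2 <- ncol(group2)
  if (n1 < min_samples || n2 < min_samples) {
    abort(sprintf("group too small (%d, %d); need >= %d samples each",
                  n1, n2, min_samples),
          class = "pathmeta_skip")
  }
  # drop genes with zero variance in either group
  usable <- apply(group1, 1, stats::sd) > 0 & apply(group2, 1, stats::sd) > 0
  if (sum(usable) < 3) {
    abort(sprintf("only %d usable gene(s) after variance filtering, need >= 3",
                  sum(usable)),
          class = "pathmeta_skip")
  }
  g1 <- group1[usable, , drop = FALSE]
  g2 <- group2[usable, , drop = FALSE]
  w1 <- weight_vector(correlation_matrix(g1, method))
  w2 <- weight_vector(correlation_matrix(g2, method))
  observed <- gsnca_statistic(w1, w2)

  pooled <- cbind(g1, g2)
  n <- n1 + n2
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      a <- pooled[, idx[seq_len(n1)], drop = FALSE]
      b <- pooled[, idx[-seq_len(n1)], drop = FALSE]
      ok <- row_variance(a) > 0 & row_variance(b) > 0
      if (sum(ok) < 3) return(NA_real_)
      tryCatch({
        aa <- t(a[ok, , drop = FALSE]); bb <- t(b[ok, , drop = FALSE])
        if (method == "spearman") {
          aa <- apply(aa, 2, rank); bb <- apply(bb, 2, rank)
        }
        sum(abs(weight_raw(stats::cor(aa)) - weight_raw(stats::cor(bb))))
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  perm_stats <- perm_stats[!is.na(perm_stats)]
  p <- (1 + sum(perm_stats >= observed)) / (1 + length(perm_stats))
  structure(list(
    statistic = observed, p = p, n_perm = length(perm_stats),
    group_sizes = c(n1 = n1, n2 = n2),
    weights = tibble(gene = w1$gene, weight_group1 = w1$weight,
                     weight_group2 = w2$weight),
    genes_used = rownames(g1)
  ), class = "gsnca_result")
}

#' @export
print.gsnca_result <- function(x, ...) {
  cat(sprintf(
    "<gsnca_result> %d genes; statistic = %.4f, p = %.4g (%d perms; n1 = %d, n2 = %d)\n",
    length(x$genes_used), x$statistic, x$p, x$n_perm,
    x$group_sizes[["n1"]], x$group_sizes[["n2"]]))
  invisible(x)
}

#' @rdname gsnca_test
#' @param x A `gsnca_result`.
#' @param ... Unused.
#' @export
tidy.gsnca_result <- function(x, ...) x$weights

#' @rdname gsnca_test
#' @export
glance.gsnca_result <- function(x, ...) {
  tibble(statistic = x$statistic, p = x$p, n_perm = x$n_perm,
         n1 = x$group_sizes[["n1"]], n2 = x$group_sizes[["n2"]],
         n_genes = length(x$genes_used))
}
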