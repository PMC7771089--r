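# fixture builders and independent oracles shared across test files

# small raw-layer expression_dataset from a log-scale matrix
make_dataset <- function(log_values, tissue = "tumor", cancer = "CA1",
                         subject_id = NULL) {
  n <- ncol(log_values)
  if (is.null(colnames(log_values))) {
    colnames(log_values) <- sprintf("s%03d", seq_len(n))
  }
  if (is.null(rownames(log_values))) {
    rownames(log_values) <- sprintf("G%03d", seq_len(nrow(log_values)))
  }
  if (is.null(subject_id)) subject_id <- colnames(log_values)
  expression_dataset(
    pmax(2^log_values - 1, 0),
    tibble::tibble(sample_id = colnames(log_values), subject_id = subject_id,
                   cancer_type = cancer, tissue = rep_len(tissue, n)),
    layer = "raw"
  )
}

# gene-by-sample log-scale matrix with an optional factor hub (gene 1)
make_hub_matrix <- function(n_genes = 10, n = 50, hub_r = 0, member_r = 0,
                            prefix = "g") {
  z <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  f <- stats::rnorm(n)
  if (member_r > 0) {
    z[-1, ] <- sqrt(member_r) * matrix(f, n_genes - 1, n, byrow = TRUE) +
      sqrt(1 - member_r) * z[-1, ]
  }
  if (hub_r > 0) {
    # hub correlated hub_r with each member's latent part
    z[1, ] <- if (member_r > 0) {
      (hub_r / sqrt(member_r)) * f +
        sqrt(max(0, 1 - hub_r^2 / member_r)) * z[1, ]
    } else {
      z[1, ]
    }
  }
  rownames(z) <- paste0(prefix, seq_len(n_genes))
  colnames(z) <- sprintf("s%03d", seq_len(n))
  6 + z
}

# brute-force Benjamini-Hochberg step-up (independent of stats::p.adjust)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force DerSimonian-Laird pooling
dl_brute <- function(es, se) {
  w <- 1 / se^2
  fixed <- sum(w * es) / sum(w)
  q <- sum(w * (es - fixed)^2)
  k <- length(es)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(pooled = sum(ws * es) / sum(ws), se = sqrt(1 / sum(ws)),
       tau2 = tau2, q = q)
}

# power-iteration principal eigenvector oracle
power_iteration <- function(a, iters = 20000, tol = 1e-13) {
  v <- rep(1 / sqrt(nrow(a)), nrow(a))
  for (i in seq_len(iters)) {
    v2 <- as.vector(a %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (sum(abs(v2 - v)) < tol) break
    v <- v2
  }
  v
}

# Efron partial log-likelihood for a single covariate (grid-search oracle)
cox_partial_loglik <- function(beta, x, time, status) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; status <- status[ord]
  w <- exp(beta * x)
  ll <- 0
  for (t in unique(time[status == 1])) {
    dset <- which(time == t & status == 1)
    rset <- which(time >= t)
    m <- length(dset)
    ll <- ll + sum(beta * x[dset])
    for (l in seq_len(m) - 1) {
      ll <- ll - log(sum(w[rset]) - (l / m) * sum(w[dset]))
    }
  }
  ll
}
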