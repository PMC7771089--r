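#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Batched univariate Cox regression, Newton-Raphson with Efron ties.
#
# Fits one univariate Cox proportional-hazards model per column of `x`
# against the same (time, status) outcome. This is the inner loop of the
# composite-score permutation test, which refits every pathway gene for every
# permutation, so all genes are fitted simultaneously with matrix arithmetic.
#
# Returns list(beta, converged). Degenerate fits (no events, constant
# covariate, non-concave step, |beta| beyond `beta_cap`) give beta = 0,
# converged = FALSE.
cox_univariate_batch <- function(x, time, status, max_iter = 25,
                                 tol = 1e-9, beta_cap = 10) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  stopifnot(length(time) == n, length(status) == n)
  if (sum(status) == 0) {
    return(list(beta = numeric(k), converged = rep(FALSE, k)))
  }
  ord <- order(time)
  x <- x[ord, , drop = FALSE]
  time <- time[ord]; status <- status[ord]

  # death-time groups (Efron): one group per unique event time
  ev <- which(status == 1)
  grp <- match(time[ev], unique(time[ev]))       # group id per death
  m <- tabulate(grp)                              # deaths per group
  l_frac <- (unlist(lapply(m, seq_len)) - 1) / m[grp[order(grp)]]
  # rows of the expansion, grouped by event time in order
  ev_sorted <- ev[order(grp)]
  grp_sorted <- grp[order(grp)]
  # first row index of each risk set (first sample with time >= death time)
  risk_start <- match(unique(time[ev]), time)

  x_ev <- x[ev, , drop = FALSE]
  sum_x_death <- colSums(x_ev)

  beta <- numeric(k)
  active <- rep(TRUE, k)
  converged <- rep(FALSE, k)
  const_x <- apply(x, 2, function(v) diff(range(v)) == 0)
  active[const_x] <- FALSE

  revcumsum <- function(mat) {
    mat[n:1, , drop = FALSE] |> apply(2, cumsum) |>
      matrix(nrow = n) |> (\(z) z[n:1, , drop = FALSE])()
  }

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- x * matrix(beta, n, k, byrow = TRUE)
    eta <- pmin(eta, 500)                        # overflow guard
    w <- exp(eta)
    S0 <- revcumsum(w)[risk_start, , drop = FALSE]
    S1 <- revcumsum(w * x)[risk_start, , drop = FALSE]
    S2 <- revcumsum(w * x * x)[risk_start, , drop = FALSE]
    # per-group sums over the deaths themselves
    wd <- w[ev_sorted, , drop = FALSE]
    D0 <- rowsum(wd, grp_sorted, reorder = TRUE)
    D1 <- rowsum(wd * x[ev_sorted, , drop = FALSE], grp_sorted, reorder = TRUE)
    D2 <- rowsum(wd * x[ev_sorted, , drop = FALSE]^2, grp_sorted, reorder = TRUE)
    # Efron expansion: one row per (group, l)
    gidx <- grp_sorted
    denom <- S0[gidx, , drop = FALSE] - l_frac * D0[gidx, , drop = FALSE]
    num1 <- S1[gidx, , drop = FALSE] - l_frac * D1[gidx, , drop = FALSE]
    num2 <- S2[gidx, , drop = FALSE] - l_frac * D2[gidx, , drop = FALSE]
    r <- num1 / denom
    grad <- sum_x_death - colSums(r)
    hess <- colSums(num2 / denom - r * r)

    step <- numeric(k)
    ok <- active & hess > 1e-12
    step[ok] <- grad[ok] / hess[ok]
    step <- pmax(pmin(step, 2), -2)              # damped step
    beta[ok] <- beta[ok] + step[ok]
    bad <- active & (!is.finite(beta) | abs(beta) > beta_cap | hess <= 1e-12)
    beta[bad] <- 0
    active[bad] <- FALSE
    done <- ok & abs(grad) < tol * (1 + abs(beta))
    # genes whose gradient is tiny relative to the information are converged
    done <- done | (ok & abs(step) < 1e-10)
    converged[done] <- TRUE
    active[done] <- FALSE
  }
  beta[!converged] <- 0
  list(beta = beta, converged = converged)
}

# Two-group log-rank chi-square statistic (1 df), no p-value.
# `group` is logical/0-1: membership of group 1. Vectorized over the
# risk-set sequence because the permutation test calls it per permutation.
logrank_chisq <- function(time, status, group) {
  group <- as.logical(group)
  if (all(group) || !any(group)) return(0)
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; g <- group[ord]
  n <- length(time)
  ev <- which(status == 1)
  if (length(ev) == 0) return(0)
  ut <- unique(time[ev])                # death times, ascending
  rs <- match(ut, time)                 # first at-risk index per death time
  n_tot <- (n:1)[rs]
  n1 <- rev(cumsum(rev(g)))[rs]
  grp_id <- match(time[ev], ut)
  d_tot <- tabulate(grp_id, length(ut))
  d1 <- as.vector(rowsum(as.numeric(g[ev]), grp_id, reorder = TRUE))
  o_minus_e <- sum(d1 - d_tot * n1 / n_tot)
  ok <- n_tot > 1
  v <- sum((d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
              (n_tot - d_tot) / (n_tot - 1))[ok])
  if (v <= 0) return(0)
  o_minus_e^2 / v
}
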