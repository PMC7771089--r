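test_that("composite score formula reproduces the closed-form worked example", {
  # betas (1, -1); gene1 z-scores (-1, 0, 1), gene2 (1, 0, -1) for A, B, C
  x <- cbind(g1 = c(-1, 0, 1), g2 = c(1, 0, -1))
  sc <- pathmeta:::cges_from_betas(x, c(1, -1))
  expect_equal(sc$linear, c(-2, 0, 2))
  expect_equal(sc$m, 0)
  expect_equal(sc$cges, c(0.1192, 0.5, 0.8808), tolerance = 1e-4)

  # all-zero betas: all linear terms 0, median 0, every score exactly 0.5
  sc0 <- pathmeta:::cges_from_betas(x, c(0, 0))
  expect_equal(sc0$cges, rep(0.5, 3))
})

test_that("composite score is in (0,1), monotone, and shift-invariant", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- matrix(rnorm(n * 4), n, 4)
    beta <- rnorm(4)
    sc <- pathmeta:::cges_from_betas(x, beta)
    expect_true(all(sc$cges > 0 & sc$cges < 1))
    expect_equal(order(sc$cges), order(sc$linear))
    # adding a constant to every linear term is absorbed by the median m
    sc_shift <- pathmeta:::cges_from_betas(cbind(x, 1), c(beta, 7.3))
    expect_equal(sc_shift$cges, sc$cges)
    if (n %% 2 == 1) {
      expect_equal(sc$cges[which(sc$linear == median(sc$linear))], 0.5)
    }
  }
})

test_that("compute_cges intersects genes, validates layers and scores subjects", {
  set.seed(32)
  ds <- make_dataset(matrix(rnorm(8 * 30, 6), 8, 30))
  zd <- log_standardize(ds)
  surv <- tibble::tibble(subject_id = zd$samples$subject_id,
                         time_days = rexp(30, 1 / 300),
                         event = rbinom(30, 1, 0.8))
  res <- compute_cges(zd, surv, c("G001", "G002", "G003", "G999"))
  expect_s3_class(res, "cges_result")
  expect_equal(res$k, 3)
  expect_equal(res$m, median(res$scores$linear))
  expect_true(all(res$scores$cges > 0 & res$scores$cges < 1))
  expect_equal(nrow(tidy(res)), 30)
  expect_equal(glance(res)$k, 3)

  expect_error(compute_cges(zd, surv, c("G001", "G002")),
               class = "pathmeta_skip")
  expect_error(compute_cges(ds, surv, c("G001", "G002", "G003")),
               "log-standardized")

  # all-censored outcome: every gene fit degenerate, every score 0.5
  surv0 <- dplyr::mutate(surv, event = 0L)
  res0 <- compute_cges(zd, surv0, c("G001", "G002", "G003"))
  expect_equal(res0$scores$cges, rep(0.5, 30))
  expect_equal(res0$observed_stat, 0)
})

test_that("permutation test is deterministic and p = 1 when the statistic is 0", {
  set.seed(33)
  ds <- make_dataset(matrix(rnorm(5 * 24, 6), 5, 24))
  zd <- log_standardize(ds)
  surv <- tibble::tibble(subject_id = zd$samples$subject_id,
                         time_days = rexp(24, 1 / 200),
                         event = rbinom(24, 1, 0.8))
  r1 <- permutation_test_cges(zd, surv, paste0("G00", 1:5), n_perm = 50, seed = 4)
  r2 <- permutation_test_cges(zd, surv, paste0("G00", 1:5), n_perm = 50, seed = 4)
  expect_identical(r1$perm_p, r2$perm_p)
  expect_identical(r1$perm_stats, r2$perm_stats)
  expect_gte(r1$perm_p, 1 / 51)

  # zero events -> observed stat 0; every permuted stat >= 0 -> p = 1
  surv0 <- dplyr::mutate(surv, event = 0L)
  r0 <- permutation_test_cges(zd, surv0, paste0("G00", 1:5), n_perm = 25, seed = 1)
  expect_equal(r0$observed_stat, 0)
  expect_equal(r0$perm_p, 1)
  expect_error(permutation_test_cges(zd, surv, paste0("G00", 1:5), n_perm = 0),
               "n_perm")
})

test_that("km_curve reproduces the product-limit hand computation", {
  surv <- tibble::tibble(subject_id = c("a", "b", "c"),
                         time_days = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_curve(surv, setNames(rep("all", 3), surv$subject_id))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))

  # no events: survival stays at 1 while the risk set drains
  surv2 <- dplyr::mutate(surv, event = 0L)
  km2 <- km_curve(surv2, setNames(rep("all", 3), surv2$subject_id))
  expect_true(all(km2$survival == 1))

  # survival is non-increasing within each group
  set.seed(34)
  surv3 <- tibble::tibble(subject_id = paste0("S", 1:40),
                          time_days = rexp(40, 1 / 100),
                          event = rbinom(40, 1, 0.6))
  km3 <- km_curve(surv3, setNames(rep(c("x", "y"), 20), surv3$subject_id))
  for (g in c("x", "y")) {
    expect_true(all(diff(km3$survival[km3$group == g]) <= 1e-12))
  }
  expect_error(km_curve(surv3, setNames(rep(NA, 40), surv3$subject_id)))
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(35)
  for (rep in 1:1000) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))   # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  tb <- bh_adjust(tibble::tibble(cell = c("a", "b"), p = c(0.01, 0.04)))
  expect_equal(tb$adj_p, c(0.02, 0.04))
})
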