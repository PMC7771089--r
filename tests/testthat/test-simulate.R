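test_that("generation is a pure function of the config seed", {
  cfg <- sim_config(seed = 99, cancers = c("CA1", "CA2"), n_tumor = 15,
                    n_normal = 5, n_genes = 30, n_pathways = 2,
                    genes_per_pathway = 6)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$datasets$CA1$values, s2$datasets$CA1$values)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$truth, s2$truth)
  # regenerating one cancer alone reproduces its slice of the study
  e1 <- simulate_expression(cfg, "CA2", "tumor")
  expect_identical(e1$values,
                   s1$datasets$CA2$values[, e1$samples$sample_id])
})

test_that("within-pathway correlation levels are recovered empirically", {
  cfg <- sim_config(seed = 5, cancers = "CA1", n_tumor = 2000, n_normal = 0,
                    n_genes = 16, n_pathways = 2, genes_per_pathway = 8,
                    rho_tumor = 0.8)
  d <- simulate_expression(cfg, "CA1", "tumor")
  lg <- log2(d$values + 1)
  g1 <- cfg$pathways$genes[[1]]
  r1 <- cor(t(lg[g1, ]))
  off <- r1[upper.tri(r1)]
  expect_lt(max(abs(off - 0.8)), 0.05)
  # across-pathway correlations vanish
  g2 <- cfg$pathways$genes[[2]]
  expect_lt(mean(abs(cor(t(lg[g1, ]), t(lg[g2, ])))), 0.05)

  cfg0 <- sim_config(seed = 6, cancers = "CA1", n_tumor = 2000, n_normal = 0,
                     n_genes = 8, n_pathways = 1, genes_per_pathway = 8,
                     rho_tumor = 0)
  d0 <- simulate_expression(cfg0, "CA1", "tumor")
  r0 <- cor(t(log2(d0$values + 1)))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.05)
})

test_that("hub rewiring severs hub edges but keeps the member module", {
  cfg <- sim_config(seed = 7, cancers = "CA1", n_tumor = 2000, n_normal = 2000,
                    n_genes = 10, n_pathways = 1, genes_per_pathway = 10,
                    rho_normal = 0, rho_tumor = 0,
                    hub_rewired_pathways = "MPSIM01",
                    hub_r_normal = 0.8, hub_r_tumor = 0)
  rn <- cor(t(log2(simulate_expression(cfg, "CA1", "normal")$values + 1)))
  rt <- cor(t(log2(simulate_expression(cfg, "CA1", "tumor")$values + 1)))
  expect_lt(max(abs(rn[1, -1] - 0.8)), 0.05)      # hub connected in normal
  expect_lt(max(abs(rt[1, -1])), 0.06)            # hub severed in tumor
  expect_lt(max(abs(rt[-1, -1][upper.tri(rt[-1, -1])] - 0.64)), 0.06)
})

test_that("survival generation respects gamma, censoring and the exponential law", {
  cfg <- sim_config(seed = 8, cancers = "CA1", n_tumor = 2000, n_normal = 0,
                    n_genes = 10, n_pathways = 1, genes_per_pathway = 10)
  d <- simulate_expression(cfg, "CA1", "tumor")
  pw <- cfg$pathways[1, ]

  # gamma = 0: expression carries no survival signal
  s0 <- simulate_survival(d, pw, gamma = 0, baseline_hazard = 1 / 500,
                          censor_rate = 0, seed = 11)
  expect_true(all(s0$event == 1))
  lg <- log2(d$values[pw$genes[[1]], ] + 1)
  score <- colMeans((lg - rowMeans(lg)) / apply(lg, 1, sd))
  fit <- pathmeta:::cox_univariate_batch(matrix(score, ncol = 1),
                                         s0$time_days, s0$event)
  expect_lt(abs(fit$beta), 0.05)

  # doubling the baseline hazard halves the mean event time
  s1 <- simulate_survival(d, pw, gamma = 0, baseline_hazard = 1 / 500,
                          censor_rate = 0, seed = 12)
  s2 <- simulate_survival(d, pw, gamma = 0, baseline_hazard = 2 / 500,
                          censor_rate = 0, seed = 12)
  expect_equal(mean(s1$time_days) / mean(s2$time_days), 2, tolerance = 0.1)

  # censor_rate is hit in expectation
  sc <- simulate_survival(d, pw, gamma = 0, baseline_hazard = 1 / 500,
                          censor_rate = 0.4, seed = 13)
  expect_equal(mean(sc$event == 0), 0.4, tolerance = 0.05)

  # gamma > 0: higher pathway score, shorter survival (rank correlation < 0)
  sg <- simulate_survival(d, pw, gamma = 1, baseline_hazard = 1 / 500,
                          censor_rate = 0, seed = 14)
  expect_lt(cor(score, sg$time_days, method = "spearman"), -0.3)
  expect_error(simulate_survival(d, pw, gamma = 0, baseline_hazard = 0,
                                 censor_rate = 0, seed = 1), "baseline_hazard")
})

test_that("a written study round-trips through the cohort loaders", {
  cfg <- sim_config(seed = 15, cancers = c("CA1", "CA2"), n_tumor = 12,
                    n_normal = c(4, 0), n_genes = 20, n_pathways = 2,
                    genes_per_pathway = 5, shifted_pathways = "MPSIM01",
                    delta = 1)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- load_expression(file.path(dir, "CA1_expression.tsv"),
                          file.path(dir, "CA1_metadata.tsv"))
  expect_equal(back$values, st$datasets$CA1$values, tolerance = 1e-12)
  expect_equal(back$samples, st$datasets$CA1$samples)
  clin <- load_survival(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(clin), nrow(st$survival))
  gmt <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(purrr::map(gmt$genes, sort), purrr::map(st$pathways$genes, sort))

  # CA2 generated no normals -> ineligible for tumor-normal analyses
  expect_equal(eligible_cancers_for_normals(st$datasets, min_normals = 1), "CA1")
  # truth ledger flags exactly the configured cells
  expect_setequal(st$truth$pathway[st$truth$delta != 0], "MPSIM01")
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(rho_tumor = 1), "correlations")
  expect_error(sim_config(n_genes = 10, n_pathways = 3, genes_per_pathway = 5),
               "more genes")
  expect_error(sim_config(prognostic_pathways = "nope"), "unknown pathway")
  expect_error(sim_config(n_tumor = 5, n_normal = 8), "n_normal")
})
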