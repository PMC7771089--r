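#' Configuration for a synthetic multi-cancer study
#'
#' Defines the ground truth of a simulated study: per-cancer cohort sizes,
#' gene/pathway layout, within-pathway co-expression per condition, optional
#' hub rewiring, a survival effect of pathway activity, paired tumor-normal
#' mean shifts and right censoring.
#'
#' Expression is multivariate normal on the log2 scale with block structure:
#' genes within a pathway share correlation `rho_normal` (normal tissue) or
#' `rho_tumor` (tumor); genes outside pathways and across pathways are
#' independent. In pathways named by `hub_rewired_pathways`, the first gene
#' is a hub whose correlation to every other member is `hub_r_normal` in
#' normal tissue and `hub_r_tumor` in tumor (co-expression rewiring). The
#' stronger hub acts as a latent factor, so the remaining members correlate
#' at `h^2 + (1 - h^2) * rho` with `h = max(|hub_r_normal|, |hub_r_tumor|)`;
#' that member-member correlation is kept in both conditions — rewiring
#' severs the hub's edges, not the module — which also keeps both blocks
#' positive definite.
#' Survival is exponential with per-subject hazard
#' `baseline_hazard * exp(gamma * pathway mean z-score)` for the pathways in
#' `prognostic_pathways`; censoring is uniform, calibrated to yield
#' `censor_rate` censored subjects in expectation. Pathways in
#' `shifted_pathways` have tumor means shifted by `delta` log2 units.
#'
#' @param seed Master seed for all generation.
#' @param cancers Character vector of cancer-type names.
#' @param n_tumor,n_normal Per-cancer sample counts (recycled).
#' @param n_genes Total genes; those not in pathways are background.
#' @param n_pathways,genes_per_pathway Layout of disjoint synthetic pathways
#'   (ignored when `pathways` is given).
#' @param pathways Optional [pathway_collection()] to use instead.
#' @param rho_normal,rho_tumor Within-pathway correlations per condition.
#' @param hub_rewired_pathways Pathway names with hub rewiring.
#' @param hub_r_normal,hub_r_tumor Hub-to-member correlation per condition.
#' @param prognostic_pathways Pathway names whose mean z-score drives hazard.
#' @param gamma Log-hazard coefficient per unit pathway mean z-score.
#' @param baseline_hazard Baseline event rate per day.
#' @param censor_rate Expected censored fraction, in `[0, 1)`.
#' @param shifted_pathways Pathway names with a tumor-vs-normal mean shift.
#' @param delta Tumor minus normal mean shift (log2 units).
#' @param base_mean,noise_sd Marginal mean and sd of log2 expression.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       cancers = c("CA1", "CA2", "CA3"),
                       n_tumor = 100, n_normal = 10,
                       n_genes = 100,
                       n_pathways = 4, genes_per_pathway = 10,
                       pathways = NULL,
                       rho_normal = 0.3, rho_tumor = 0.3,
                       hub_rewired_pathways = character(0),
                       hub_r_normal = 0.8, hub_r_tumor = 0,
                       prognostic_pathways = character(0),
                       gamma = 0,
                       baseline_hazard = 1 / 1000,
                       censor_rate = 0.3,
                       shifted_pathways = character(0),
                       delta = 0,
                       base_mean = 6, noise_sd = 1) {
  if (is.null(pathways)) {
    check_that(n_pathways * genes_per_pathway <= n_genes,
               "pathways need more genes than n_genes provides")
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    idx <- unname(split(seq_len(n_pathways * genes_per_pathway),
                        rep(seq_len(n_pathways), each = genes_per_pathway)))
    pathways <- pathway_collection(
      name = sprintf("MPSIM%02d", seq_len(n_pathways)),
      source = rep("simulated", n_pathways),
      genes = purrr::map(idx, ~ gene_ids[.x])
    )
  } else {
    gene_ids <- union(sprintf("G%04d", seq_len(n_genes)),
                      unique(unlist(pathways$genes)))
  }
  cfg <- list(
    seed = seed, cancers = cancers,
    n_tumor = rep_len(n_tumor, length(cancers)),
    n_normal = rep_len(n_normal, length(cancers)),
    genes = gene_ids, pathways = pathways,
    rho_normal = rho_normal, rho_tumor = rho_tumor,
    hub_rewired_pathways = hub_rewired_pathways,
    hub_r_normal = hub_r_normal, hub_r_tumor = hub_r_tumor,
    prognostic_pathways = prognostic_pathways, gamma = gamma,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    shifted_pathways = shifted_pathways, delta = delta,
    base_mean = base_mean, noise_sd = noise_sd
  )
  check_that(all(c(rho_normal, rho_tumor) > -1 & c(rho_normal, rho_tumor) < 1),
             "correlations must lie in (-1, 1)")
  check_that(censor_rate >= 0 && censor_rate < 1, "censor_rate must be in [0, 1)")
  check_that(baseline_hazard > 0, "baseline_hazard must be > 0")
  check_that(all(cfg$n_tumor >= 2), "each cancer needs >= 2 tumor samples")
  check_that(all(cfg$n_normal <= cfg$n_tumor),
             "n_normal cannot exceed n_tumor (normals are paired subjects)")
  unknown <- setdiff(c(hub_rewired_pathways, prognostic_pathways,
                       shifted_pathways), pathways$name)
  check_that(length(unknown) == 0,
             paste0("unknown pathway name(s): ", paste(unknown, collapse = ", ")))
  # validate that every block correlation matrix is positive definite
  for (cond in c("normal", "tumor")) {
    for (nm in pathways$name) {
      r <- block_correlation(cfg, nm, cond)
      ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
      check_that(min(ev) > 1e-10,
                 sprintf("correlation block for %s (%s) not positive definite",
                         nm, cond))
    }
  }
  structure(cfg, class = "sim_config")
}

# within-pathway correlation matrix for one condition
block_correlation <- function(config, pathway_name, condition) {
  size <- length(config$pathways$genes[[match(pathway_name,
                                              config$pathways$name)]])
  rho <- if (condition == "tumor") config$rho_tumor else config$rho_normal
  r <- matrix(rho, size, size)
  diag(r) <- 1
  if (pathway_name %in% config$hub_rewired_pathways) {
    # Hub rewiring severs the hub's edges, not the module. The member-member
    # correlation is set by the reference (normal) hub strength acting as a
    # latent factor, h_ref^2 + (1 - h_ref^2) * rho, and is kept in BOTH
    # conditions; only the hub-member correlation switches between
    # hub_r_normal and hub_r_tumor. (A hub at |r| = 0.8 with mutually
    # uncorrelated members is not a positive-definite correlation matrix, so
    # the module correlation is a geometric necessity, not a choice.)
    h_ref <- max(abs(config$hub_r_normal), abs(config$hub_r_tumor))
    m <- h_ref^2 + (1 - h_ref^2) * rho
    h <- if (condition == "tumor") config$hub_r_tumor else config$hub_r_normal
    r <- matrix(m, size, size)
    r[1, ] <- h; r[, 1] <- h
    diag(r) <- 1
  }
  r
}

#' Simulate expression for one cancer and condition
#'
#' @param config A [sim_config()].
#' @param cancer Cancer-type name from `config$cancers`.
#' @param condition `"tumor"` or `"normal"`.
#' @return A raw-layer [expression_dataset()]. Subject ids are shared between
#'   conditions: the first `n_normal` subjects own the normal samples, so
#'   tumor and normal draws for the same subject pair up downstream.
#' @export
simulate_expression <- function(config, cancer, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  check_that(inherits(config, "sim_config"), "need a sim_config")
  ci <- match(cancer, config$cancers)
  check_that(!is.na(ci), paste0("unknown cancer: ", cancer))
  n <- if (condition == "tumor") config$n_tumor[ci] else config$n_normal[ci]
  genes <- config$genes
  g <- length(genes)
  z <- with_seed(derive_seed(config$seed, cancer, condition, "expr"), {
    out <- matrix(stats::rnorm(g * n), g, n)
    for (nm in config$pathways$name) {
      rows <- match(config$pathways$genes[[match(nm, config$pathways$name)]],
                    genes)
      r <- block_correlation(config, nm, condition)
      out[rows, ] <- t(chol(r)) %*% out[rows, , drop = FALSE]
    }
    out
  })
  z <- config$base_mean + config$noise_sd * z
  if (condition == "tumor" && length(config$shifted_pathways) > 0) {
    for (nm in config$shifted_pathways) {
      rows <- match(config$pathways$genes[[match(nm, config$pathways$name)]],
                    genes)
      z[rows, ] <- z[rows, ] + config$delta
    }
  }
  raw <- pmax(2^z - 1, 0)
  subjects <- sprintf("%s-S%04d", cancer, seq_len(n))
  suffix <- if (condition == "tumor") "T" else "N"
  sample_ids <- paste0(subjects, "-", suffix)
  dimnames(raw) <- list(genes, sample_ids)
  expression_dataset(
    raw,
    tibble(sample_id = sample_ids, subject_id = subjects,
           cancer_type = cancer, tissue = condition),
    layer = "raw"
  )
}

#' Simulate survival tied to pathway activity
#'
#' Exponential event times with per-subject hazard
#' `baseline_hazard * exp(gamma * pathway mean z-score)`, where the z-score
#' averages the per-gene standardized log2 expression over the pathway genes.
#' Censoring is uniform on (0, b) with b calibrated so that the expected
#' censored fraction equals `censor_rate`.
#'
#' @param dataset A raw-layer tumor [expression_dataset()].
#' @param pathway Pathway row or gene vector driving the hazard (can span
#'   several pathways' genes).
#' @param gamma Log-hazard coefficient.
#' @param baseline_hazard Event rate per day, > 0.
#' @param censor_rate Expected censored fraction, in `[0, 1)`.
#' @param seed Integer seed.
#' @param endpoint Endpoint label for the output table.
#' @return Survival tibble: `subject_id`, `time_days`, `event`, `endpoint`.
#' @export
simulate_survival <- function(dataset, pathway, gamma, baseline_hazard,
                              censor_rate, seed, endpoint = "OS") {
  check_that(baseline_hazard > 0, "baseline_hazard must be > 0")
  check_that(all(dataset$samples$tissue == "tumor"), "tumor samples only")
  genes <- intersect(pathway_genes(pathway), rownames(dataset$values))
  check_that(length(genes) >= 1, "no pathway genes in dataset")
  lg <- log2(dataset$values[genes, , drop = FALSE] + 1)
  sds <- apply(lg, 1, stats::sd)
  lg <- lg[sds > 0, , drop = FALSE]
  score <- if (nrow(lg) == 0) {
    rep(0, ncol(dataset$values))
  } else {
    colMeans((lg - rowMeans(lg)) / sds[sds > 0])
  }
  hazard <- baseline_hazard * exp(gamma * score)
  with_seed(seed, {
    t_event <- stats::rexp(length(hazard), rate = hazard)
    if (censor_rate == 0) {
      time <- t_event; event <- rep(1L, length(hazard))
    } else {
      b <- censor_bound(hazard, censor_rate)
      t_cens <- stats::runif(length(hazard), 0, b)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    tibble(subject_id = dataset$samples$subject_id,
           time_days = time, event = event, endpoint = endpoint)
  })
}

# solve for the uniform-censoring upper bound b such that the expected
# censored fraction mean_i (1 - exp(-h_i b)) / (h_i b) equals censor_rate
censor_bound <- function(hazard, censor_rate) {
  f <- function(b) mean((1 - exp(-hazard * b)) / (hazard * b)) - censor_rate
  upper <- 1 / min(hazard)
  while (f(upper) > 0) upper <- upper * 10
  stats::uniroot(f, c(1e-8, upper), tol = 1e-10)$root
}

#' Simulate a full multi-cancer study bundle
#'
#' Generates, per cancer: tumor (and, if configured, normal) expression, OS
#' and DSS survival tables, and a ground-truth ledger of which pathway x
#' cancer cells carry survival effects, mean shifts, or co-expression
#' rewiring.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `datasets` (named per-cancer
#'   [expression_dataset()], both tissues), `survival` (tibble across cancers
#'   and endpoints, with a `cancer_type` column), `pathways`, `truth`
#'   (pathway x cancer tibble), `config`.
#' @export
simulate_study <- function(config) {
  check_that(inherits(config, "sim_config"), "need a sim_config")
  datasets <- list()
  survival <- list()
  for (ci in seq_along(config$cancers)) {
    cancer <- config$cancers[ci]
    tum <- simulate_expression(config, cancer, "tumor")
    if (config$n_normal[ci] > 0) {
      nor <- simulate_expression(config, cancer, "normal")
      vals <- cbind(tum$values, nor$values)
      meta <- dplyr::bind_rows(tum$samples, nor$samples)
      datasets[[cancer]] <- expression_dataset(vals, meta, layer = "raw")
    } else {
      datasets[[cancer]] <- tum
    }
    prog_genes <- if (length(config$prognostic_pathways) > 0) {
      unique(unlist(config$pathways$genes[
        config$pathways$name %in% config$prognostic_pathways]))
    } else {
      config$genes  # no prognostic pathway: hazard flat (gamma applies to nothing)
    }
    gamma_eff <- if (length(config$prognostic_pathways) > 0) config$gamma else 0
    for (ep in c("OS", "DSS")) {
      survival[[paste(cancer, ep)]] <- simulate_survival(
        tum, prog_genes, gamma = gamma_eff,
        baseline_hazard = config$baseline_hazard,
        censor_rate = config$censor_rate,
        seed = derive_seed(config$seed, cancer, ep, "surv"),
        endpoint = ep
      ) %>% dplyr::mutate(cancer_type = cancer)
    }
  }
  truth <- tidyr::expand_grid(cancer = config$cancers,
                              pathway = config$pathways$name) %>%
    dplyr::mutate(
      gamma = ifelse(.data$pathway %in% config$prognostic_pathways,
                     config$gamma, 0),
      delta = ifelse(.data$pathway %in% config$shifted_pathways,
                     config$delta, 0),
      rewired = .data$pathway %in% config$hub_rewired_pathways
    )
  structure(list(datasets = datasets,
                 survival = dplyr::bind_rows(survival),
                 pathways = config$pathways, truth = truth, config = config),
            class = "sim_study")
}

#' Write a simulated study to disk in the formats the loaders read
#'
#' Emits, per cancer, `<cancer>_expression.tsv` and `<cancer>_metadata.tsv`,
#' plus `clinical.tsv`, `pathways.gmt` and `truth.tsv`.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cancer in names(study$datasets)) {
    d <- study$datasets[[cancer]]
    expr <- data.frame(gene = rownames(d$values), d$values,
                       check.names = FALSE)
    utils::write.table(expr, file.path(dir, paste0(cancer, "_expression.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(d$samples, file.path(dir, paste0(cancer, "_metadata.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$survival, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(study$pathways, file.path(dir, "pathways.gmt"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
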